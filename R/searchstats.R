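#' Assemble a search run
#'
#' A search run holds the outcomes of replicate heuristic tree searches on
#' one data set: one log-likelihood score per replicate and, optionally, the
#' recovered topology.
#'
#' @param lnL numeric vector of log-likelihood scores (finite).
#' @param trees optional list of `phylo` topologies, same length.
#' @param id optional replicate identifiers (default 1..n).
#' @return a tibble of class `search_run` with columns `id`, `lnL` and,
#'   when given, a `tree` list column.
#' @export
search_run <- function(lnL, trees = NULL, id = NULL) {
  if (!length(lnL) || any(!is.finite(lnL))) {
    abort("lnL must be a non-empty vector of finite scores")
  }
  out <- tibble(id = id %||% seq_along(lnL), lnL = as.numeric(lnL))
  if (!is.null(trees)) {
    trees <- as_tree_list(trees)
    if (length(trees) != length(lnL)) abort("trees and lnL lengths differ")
    out$tree <- trees
  }
  class(out) <- c("search_run", class(out))
  out
}

as_search_run <- function(run) {
  if (inherits(run, "search_run")) return(run)
  if (is.data.frame(run) && "lnL" %in% names(run)) {
    return(search_run(run$lnL, run$tree %||% NULL, run$id %||% NULL))
  }
  abort("expected a search_run or a data frame with an lnL column")
}

#' Replicates within a relative lnL threshold of the best
#'
#' Selects the replicates whose score is within `rel_threshold` of the best
#' score, relatively: `(lnL_best - lnL_i) / |lnL_best| <= rel_threshold`.
#' Note the threshold is a fraction: a published "within 10^-4 %" cutoff is
#' `rel_threshold = 1e-6`.
#'
#' @param run a [search_run()] (or data frame with `lnL`).
#' @param rel_threshold non-negative relative score gap.
#' @return the qualifying subset of `run`; always contains the best
#'   replicate.
#' @export
within_threshold_set <- function(run, rel_threshold) {
  run <- as_search_run(run)
  if (rel_threshold < 0) abort("rel_threshold must be non-negative")
  best <- max(run$lnL)
  gap <- (best - run$lnL) / abs(best)
  run[gap <= rel_threshold, , drop = FALSE]
}

#' Fraction of replicates recovering the near-best score
#'
#' @inheritParams within_threshold_set
#' @return `nrow(within_threshold_set(run, rel_threshold)) / nrow(run)`.
#' @export
recovery_fraction <- function(run, rel_threshold) {
  run <- as_search_run(run)
  nrow(within_threshold_set(run, rel_threshold)) / nrow(run)
}

#' Search replicates needed for a target recovery probability
#'
#' With per-replicate recovery probability `p_recover`, the number of
#' independent search replicates needed so that at least one recovers the
#' target with probability `confidence`:
#' `n = ln(1 - confidence) / ln(1 - p_recover)`, rounded to the nearest
#' integer (minimum 1). Rounding to nearest (not ceiling) reproduces the
#' published search-effort figures computed from replicate counts.
#'
#' @param p_recover per-replicate recovery probability in (0, 1].
#' @param confidence target probability in (0, 1).
#' @return integer count of replicates.
#' @export
#' @examples
#' replicates_needed(1827 / 4608, 0.95) # 6
#' replicates_needed(19 / 4608, 0.95)   # 725
replicates_needed <- function(p_recover, confidence = 0.95) {
  if (any(p_recover <= 0) || any(p_recover > 1)) {
    abort("p_recover must be in (0, 1]")
  }
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must be in (0, 1)")
  }
  vapply(p_recover, function(p) {
    if (p == 1) return(1L)
    max(1L, as.integer(round(log(1 - confidence) / log(1 - p))))
  }, 1L)
}

#' Classify edges of the best tree as hard or easy to recover
#'
#' For each relative lnL threshold, takes the strict-consensus bipartition
#' set of the replicates within that threshold of the best score, and
#' reports for each internal edge of the best tree whether it survives.
#' Edges absent at a tight threshold identify groups that even near-optimal
#' topologies disagree on.
#'
#' @param run a [search_run()] carrying a `tree` column.
#' @param thresholds numeric vector of relative thresholds (fractions).
#' @return tibble with columns `split`, `threshold`, `present`.
#' @export
hard_to_recover_nodes <- function(run, thresholds) {
  run <- as_search_run(run)
  if (is.null(run$tree)) abort("run must carry trees")
  best_tree <- run$tree[[which.max(run$lnL)]]
  ref <- min(best_tree$tip.label)
  best_keys <- tree_bipartitions(best_tree, ref = ref)
  out <- lapply(sort(thresholds), function(th) {
    sel <- within_threshold_set(run, th)
    keysets <- lapply(sel$tree, tree_bipartitions, ref = ref)
    common <- Reduce(intersect, keysets)
    tibble(split = best_keys, threshold = th,
           present = best_keys %in% common)
  })
  bind_rows(out)
}
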