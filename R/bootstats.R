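#' Bootstrap support of a reference tree's edges
#'
#' For each internal edge (bipartition) of `reference`, the percent of
#' `trees` containing that bipartition.
#'
#' @param reference a `phylo` tree.
#' @param trees list of `phylo` sharing the reference leaf set.
#' @return tibble with columns `split`, `count`, `support` (percent).
#' @export
bootstrap_support <- function(reference, trees) {
  trees <- as_tree_list(trees)
  labels <- sort(reference$tip.label)
  if (!identical(labels, sort(trees[[1]]$tip.label))) {
    abort("reference and trees do not share one leaf set")
  }
  ref <- min(labels)
  own <- tree_bipartitions(reference, ref = ref)
  keysets <- trees_bipartitions(trees)
  counts <- vapply(own, function(k) {
    sum(vapply(keysets, function(ks) k %in% ks, TRUE))
  }, 0L)
  tibble(split = own, count = unname(counts),
         support = 100 * unname(counts) / length(trees))
}

#' Assemble a bootstrap run
#'
#' A bootstrap run holds, for each bootstrap pseudoreplicate, the `k`
#' replicate heuristic searches performed on that pseudoreplicate's
#' resampled data set, in generation order. Support values are computed
#' from the best-scoring tree of each pseudoreplicate.
#'
#' @param trees list of `phylo` (one per search replicate, all
#'   pseudoreplicates concatenated) or a tibble with columns
#'   `pseudoreplicate`, `replicate`, `score`, `tree`.
#' @param score numeric scores aligned with `trees` (ignored for tibble
#'   input).
#' @param pseudoreplicate,replicate integer indices aligned with `trees`.
#' @return a tibble of class `bootstrap_run`.
#' @export
bootstrap_run <- function(trees, score = NULL, pseudoreplicate = NULL,
                          replicate = NULL) {
  if (is.data.frame(trees)) {
    need <- c("pseudoreplicate", "replicate", "score", "tree")
    if (!all(need %in% names(trees))) {
      abort("tibble input needs columns pseudoreplicate, replicate, score, tree")
    }
    out <- as_tibble(trees[, need])
  } else {
    trees <- as_tree_list(trees)
    out <- tibble(pseudoreplicate = as.integer(pseudoreplicate),
                  replicate = as.integer(replicate),
                  score = as.numeric(score), tree = trees)
  }
  out <- out |> arrange(.data$pseudoreplicate, .data$replicate)
  class(out) <- c("bootstrap_run", class(out))
  out
}

as_bootstrap_run <- function(x) {
  if (inherits(x, "bootstrap_run")) return(x)
  bootstrap_run(x)
}

#' Bootstrap support as a function of search effort per pseudoreplicate
#'
#' For each `k` in `ks`, selects within every pseudoreplicate the
#' best-scoring tree among its first `k` search replicates (ties: earliest)
#' and computes bootstrap support for each internal edge of `reference`
#' across pseudoreplicates. Tracking support as `k` grows reveals edges
#' whose support is underestimated when the per-pseudoreplicate search is
#' too shallow.
#'
#' @param run a [bootstrap_run()].
#' @param reference a `phylo` tree whose edges are scored.
#' @param ks integer vector of search-effort levels; every pseudoreplicate
#'   must hold at least `max(ks)` replicates.
#' @return tibble with columns `split`, `k`, `support`.
#' @export
best_of_k_supports <- function(run, reference, ks) {
  run <- as_bootstrap_run(run)
  ks <- sort(unique(as.integer(ks)))
  per_pr <- split(seq_len(nrow(run)), run$pseudoreplicate)
  n_rep <- min(lengths(per_pr))
  if (max(ks) > n_rep) abort("k exceeds available replicates")
  out <- lapply(ks, function(k) {
    sel <- vapply(per_pr, function(ix) {
      sub <- ix[run$replicate[ix] <= k]
      sub[which.max(run$score[sub])]
    }, 0L)
    bootstrap_support(reference, run$tree[sel]) |>
      mutate(k = k) |>
      select("split", "k", "support")
  })
  bind_rows(out)
}

#' Flag edges whose support is sensitive to search effort
#'
#' Given a [best_of_k_supports()] table, flags every (edge, k) whose
#' support differs from the value at the largest `k` by at least `delta`
#' percentage points, with the direction of the difference.
#'
#' @param table tibble from [best_of_k_supports()].
#' @param delta flag threshold in percentage points (default 5).
#' @return tibble with columns `split`, `k`, `support`, `support_at_kmax`,
#'   `difference`, `direction` ("lower"/"higher"); empty when no edge moves
#'   by `delta` or more.
#' @export
convergence_report <- function(table, delta = 5) {
  kmax <- max(table$k)
  ref <- table |> filter(.data$k == kmax) |>
    select("split", support_at_kmax = "support")
  table |>
    filter(.data$k < kmax) |>
    left_join(ref, by = "split") |>
    mutate(difference = .data$support - .data$support_at_kmax,
           direction = ifelse(.data$difference < 0, "lower", "higher")) |>
    filter(abs(.data$difference) >= delta) |>
    arrange(.data$split, .data$k)
}
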