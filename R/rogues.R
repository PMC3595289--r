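#' Annotation-based rogue candidates
#'
#' Screens a consensus tree against a taxon-to-group annotation (e.g.
#' superfamily membership) and flags two kinds of unstably or anomalously
#' placed taxa: (a) members of multi-exemplar groups that sit inside no
#' clade composed chiefly of their own group (a clade containing the taxon,
#' at least two members of its group, and a majority of same-group members
#' overall), and (b) sole
#' exemplars of their group attached at an unresolved node whose degree
#' exceeds `max_degree`. Taxa lacking an annotation are skipped with a
#' warning.
#'
#' @param consensus a `phylo` tree (typically a consensus, may contain
#'   polytomies).
#' @param annotation data frame with columns `taxon` and `group`.
#' @param max_degree polytomy degree limit for rule (b); a resolved
#'   internal node of an unrooted binary tree has degree 3 (default 4).
#' @return tibble with columns `taxon`, `group`, `rule` where `rule` is
#'   `"no_same_group_clade"` or `"singleton_at_polytomy"`.
#' @export
annotation_rogues <- function(consensus, annotation, max_degree = 4) {
  stopifnot(inherits(consensus, "phylo"))
  if (!all(c("taxon", "group") %in% names(annotation))) {
    abort("annotation needs columns taxon and group")
  }
  tips <- consensus$tip.label
  missing <- setdiff(tips, annotation$taxon)
  if (length(missing)) {
    warn(paste0("taxa without annotation skipped: ",
                paste(missing, collapse = ", ")))
  }
  ann <- annotation |> filter(.data$taxon %in% tips)
  grp <- setNames(ann$group, ann$taxon)
  sizes <- table(grp)

  utree <- if (ape::is.rooted(consensus)) ape::unroot(consensus) else consensus
  n <- length(utree$tip.label)
  pp <- ape::prop.part(utree)
  sides <- list()
  for (i in seq_along(pp)) {
    tipset <- utree$tip.label[pp[[i]]]
    if (length(tipset) >= 1 && length(tipset) <= n - 1) {
      sides <- c(sides, list(tipset), list(setdiff(utree$tip.label, tipset)))
    }
  }

  flags <- list()
  for (t in names(grp)) {
    g <- grp[[t]]
    if (sizes[[g]] >= 2) {
      ok <- any(vapply(sides, function(s) {
        if (!t %in% s || length(s) < 2) return(FALSE)
        n_own <- sum(grp[intersect(s, names(grp))] == g)
        n_own >= 2 && n_own > length(s) / 2
      }, TRUE))
      if (!ok) {
        flags <- c(flags, list(tibble(taxon = t, group = g,
                                      rule = "no_same_group_clade")))
      }
    } else {
      tip_idx <- match(t, utree$tip.label)
      parent <- utree$edge[utree$edge[, 2] == tip_idx, 1]
      degree <- sum(utree$edge[, 1] == parent | utree$edge[, 2] == parent)
      if (degree > max_degree) {
        flags <- c(flags, list(tibble(taxon = t, group = g,
                                      rule = "singleton_at_polytomy")))
      }
    }
  }
  if (!length(flags)) {
    return(tibble(taxon = character(), group = character(),
                  rule = character()))
  }
  bind_rows(flags) |> arrange(.data$taxon)
}

# relative bipartition information criterion of a tree set:
# sum of majority-rule (>50%) split supports over the maximum attainable
rbic_score <- function(trees) {
  trees <- as_tree_list(trees)
  n <- length(trees[[1]]$tip.label)
  if (n <= 3) abort("RBIC undefined for 3 or fewer taxa")
  freq <- split_frequencies(trees) |> filter(.data$frequency > 0.5)
  sum(100 * freq$frequency) / ((n - 3) * 100)
}

#' Greedy rogue pruning under the relative bipartition information criterion
#'
#' A deliberately simple rogue-removal procedure in the spirit of
#' RogueNaRok: RBIC of a tree set is the sum of majority-rule consensus
#' split supports divided by the maximum attainable
#' (`(n_remaining - 3) * 100`). At each step, the single taxon whose
#' removal most increases RBIC is dropped; the procedure stops when no
#' removal increases RBIC or after `max_drop` drops. The returned trace is
#' strictly increasing.
#'
#' @param trees list of `phylo` sharing >= 4 leaves.
#' @param max_drop maximum number of taxa to drop
#'   (must be < n_taxa - 3; default 1 less than that bound allows).
#' @return list with `dropped` (character vector, in drop order), `rbic`
#'   (final value), and `trace` (tibble with columns `step`, `dropped`,
#'   `rbic`; step 0 is the untouched set).
#' @export
greedy_rbic_prune <- function(trees, max_drop = NULL) {
  trees <- as_tree_list(trees)
  n <- length(trees[[1]]$tip.label)
  if (n < 4) abort("need at least 4 shared taxa")
  max_drop <- max_drop %||% (n - 4L)
  if (max_drop >= n - 3) abort("max_drop must be < n_taxa - 3")
  cur <- trees
  cur_rbic <- rbic_score(cur)
  dropped <- character()
  trace <- tibble(step = 0L, dropped = NA_character_, rbic = cur_rbic)
  while (length(dropped) < max_drop) {
    leaves <- cur[[1]]$tip.label
    cand <- sort(leaves)
    scores <- vapply(cand, function(t) {
      rbic_score(lapply(cur, ape::drop.tip, tip = t))
    }, 0)
    best <- which.max(scores)
    if (scores[best] <= cur_rbic + 1e-12) break
    t <- unname(cand[best])
    cur <- lapply(cur, ape::drop.tip, tip = t)
    cur_rbic <- unname(scores[best])
    dropped <- c(dropped, t)
    trace <- bind_rows(trace, tibble(step = length(dropped), dropped = t,
                                     rbic = cur_rbic))
  }
  list(dropped = dropped, rbic = cur_rbic, trace = trace)
}
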