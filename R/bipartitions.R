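# Canonical bipartition (split) keys for leaf-labeled trees.
#
# A nontrivial split is encoded as the sorted labels of the side NOT
# containing the reference leaf (lexicographically smallest label of the
# shared leaf set), joined by "|". This frozen form makes split sets
# comparable across trees and immune to rooting and rotation.

split_key <- function(labels, all_labels, ref = min(all_labels)) {
  side <- sort(labels)
  if (ref %in% side) side <- sort(setdiff(all_labels, side))
  paste(side, collapse = "|")
}

#' Nontrivial bipartitions of a tree
#'
#' @param tree a `phylo` object (rooted or unrooted; treated as unrooted).
#' @param ref reference leaf label fixing the canonical side (default: the
#'   lexicographically smallest tip label).
#' @return character vector of canonical split keys, one per internal edge
#'   of the unrooted tree (trivial leaf splits excluded).
#' @export
tree_bipartitions <- function(tree, ref = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  ref <- ref %||% min(labels)
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(labels)
  pp <- ape::prop.part(utree)
  keys <- character()
  for (i in seq_along(pp)) {
    tips <- labels[pp[[i]]]
    if (length(tips) <= 1 || length(tips) >= n - 1) next
    keys <- c(keys, split_key(tips, labels, ref))
  }
  unique(keys)
}

# split keys of every tree in a list; validates shared leaf sets
trees_bipartitions <- function(trees) {
  trees <- as_tree_list(trees)
  labels <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), labels)) {
      abort("trees do not share one leaf set")
    }
  }
  ref <- min(labels)
  lapply(trees, tree_bipartitions, ref = ref)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) {
    labs <- attr(trees, "TipLabel")   # compressed representation
    trees <- unclass(trees)
    if (!is.null(labs)) {
      trees <- lapply(trees, function(t) {
        t$tip.label <- labs
        t
      })
    }
    return(trees)
  }
  stopifnot(is.list(trees), all(vapply(trees, inherits, TRUE, "phylo")))
  trees
}

# frequency (fraction) of each split key across trees
split_frequencies <- function(trees) {
  keysets <- trees_bipartitions(trees)
  n <- length(keysets)
  tb <- table(unlist(keysets, use.names = FALSE))
  tibble(split = names(tb), count = as.integer(tb),
         frequency = as.integer(tb) / n) |>
    arrange(desc(.data$frequency), .data$split)
}

# Build a phylo tree from a set of pairwise-compatible splits.
# Splits are given as canonical keys over `labels`; construction nests
# clades by containment of the non-reference side.
tree_from_splits <- function(keys, labels, support = NULL) {
  ref <- min(labels)
  sides <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  names(sides) <- keys
  # nest by containment: children of a clade are its maximal sub-clades
  newick_of <- function(members, avail) {
    inside <- avail[vapply(avail, function(k) {
      all(sides[[k]] %in% members)
    }, TRUE)]
    # maximal clades strictly inside `members`
    maximal <- inside[vapply(inside, function(k) {
      !any(vapply(inside, function(k2) {
        !identical(k2, k) && all(sides[[k]] %in% sides[[k2]]) &&
          length(sides[[k2]]) > length(sides[[k]])
      }, TRUE))
    }, TRUE)]
    used <- character()
    parts <- character()
    for (k in maximal) {
      sub <- newick_of(sides[[k]], setdiff(inside, k))
      lab <- if (!is.null(support)) format(support[[k]]) else ""
      parts <- c(parts, paste0(sub, lab))
      used <- c(used, sides[[k]])
    }
    singles <- sort(setdiff(members, used))
    parts <- c(parts, singles)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(newick_of(labels, keys), ";")
  ape::read.tree(text = nwk)
}
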