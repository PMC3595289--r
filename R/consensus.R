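#' Strict consensus tree
#'
#' Retains exactly the bipartitions present in every input tree.
#'
#' @param trees a list of `phylo` (or `multiPhylo`) sharing one leaf set.
#' @return a `phylo` tree.
#' @export
strict_consensus <- function(trees) {
  keysets <- trees_bipartitions(trees)
  keys <- Reduce(intersect, keysets)
  labels <- sort(as_tree_list(trees)[[1]]$tip.label)
  tree_from_splits(keys, labels)
}

#' Majority-rule consensus tree
#'
#' Retains bipartitions whose frequency across trees exceeds `cutoff`
#' (with `cutoff = 1` treated as "present in all trees"). Percent support
#' is written to the internal node labels and returned in the `support`
#' attribute.
#'
#' @inheritParams strict_consensus
#' @param cutoff retention threshold in \[0.5, 1\] (default 0.5).
#' @return a `phylo` with node labels holding rounded percent support; the
#'   full-precision split table is in `attr(, "support")`.
#' @export
majority_consensus <- function(trees, cutoff = 0.5) {
  if (cutoff < 0.5 || cutoff > 1) abort("cutoff must be in [0.5, 1]")
  freq <- split_frequencies(trees)
  kept <- if (cutoff == 1) {
    freq |> filter(.data$frequency >= 1)
  } else {
    freq |> filter(.data$frequency > cutoff)
  }
  labels <- sort(as_tree_list(trees)[[1]]$tip.label)
  sup <- setNames(round(100 * kept$frequency), kept$split)
  tr <- tree_from_splits(kept$split, labels, support = sup)
  attr(tr, "support") <- kept |>
    mutate(support = 100 * .data$frequency) |>
    select("split", "count", "support")
  tr
}

# nested-list view of a rooted phylo: leaf = label, node = list of children
phylo_to_nested <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    lapply(kids[[as.character(node)]], build)
  }
  build(n + 1L)
}

nested_leaves <- function(node) {
  if (is.character(node)) return(node)
  unlist(lapply(node, nested_leaves), use.names = FALSE)
}

nested_restrict <- function(node, keep) {
  if (is.character(node)) {
    return(if (node %in% keep) node else NULL)
  }
  kids <- Filter(Negate(is.null), lapply(node, nested_restrict, keep = keep))
  if (length(kids) == 0) return(NULL)
  if (length(kids) == 1) return(kids[[1]])
  kids
}

nested_to_newick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(vapply(node, nested_to_newick, ""), collapse = ","), ")")
}

#' Adams consensus tree
#'
#' Classical Adams consensus of rooted trees: at each level the partitions
#' induced by the trees' root children are intersected (partition product),
#' and the construction recurses into each block. Unlike the strict
#' consensus, Adams preserves common nestings even when no full clade is
#' shared. Input trees are treated as rooted at `outgroup` (a leaf label;
#' default: the first tip of the first tree).
#'
#' @inheritParams strict_consensus
#' @param outgroup leaf label used to root every tree.
#' @return a rooted `phylo` whose leaf set equals the input leaf set.
#' @export
adams_consensus <- function(trees, outgroup = NULL) {
  trees <- as_tree_list(trees)
  labels <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), labels)) {
      abort("trees do not share one leaf set")
    }
  }
  outgroup <- outgroup %||% trees[[1]]$tip.label[1]
  if (!outgroup %in% labels) abort("outgroup is not a leaf of the trees")
  rooted <- lapply(trees, function(t) {
    t <- if (ape::is.rooted(t)) ape::unroot(t) else t
    ape::root(t, outgroup = outgroup, resolve.root = TRUE)
  })
  nested <- lapply(rooted, phylo_to_nested)

  adams_rec <- function(nodes, leaves) {
    if (length(leaves) == 1) return(leaves)
    # partition product: group leaves by the vector of root-child blocks
    # they fall into across trees
    block_id <- vapply(leaves, function(lf) {
      paste(vapply(nodes, function(nd) {
        kids <- if (is.character(nd)) list(nd) else nd
        which(vapply(kids, function(k) lf %in% nested_leaves(k), TRUE))[1]
      }, 0), collapse = ",")
    }, "")
    blocks <- split(leaves, block_id)
    # every tree's restricted root has >= 2 children, so the product has
    # >= 2 blocks whenever |leaves| > 1
    parts <- lapply(blocks, function(bl) {
      sub <- lapply(nodes, nested_restrict, keep = bl)
      adams_rec(sub, sort(bl))
    })
    unname(parts)
  }

  res <- adams_rec(nested, labels)
  nwk <- paste0(nested_to_newick(res), ";")
  ape::read.tree(text = nwk)
}
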