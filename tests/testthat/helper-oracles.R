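# Independent oracles used across tests. These deliberately avoid the
# package's own bipartition machinery.

# brute-force split extraction: delete each edge, find the connected
# component of tips by BFS over the remaining edges
oracle_splits <- function(tree) {
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  labels <- utree$tip.label
  n <- length(labels)
  ref <- min(labels)
  edges <- utree$edge
  nodes <- sort(unique(as.vector(edges)))
  keys <- character()
  for (e in seq_len(nrow(edges))) {
    rest <- edges[-e, , drop = FALSE]
    # BFS from the child endpoint
    comp <- edges[e, 2]
    repeat {
      nb <- unique(c(rest[rest[, 1] %in% comp, 2],
                     rest[rest[, 2] %in% comp, 1]))
      new <- setdiff(nb, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    side <- sort(labels[comp[comp <= n]])
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (ref %in% side) side <- sort(setdiff(labels, side))
    keys <- c(keys, paste(side, collapse = "|"))
  }
  sort(unique(keys))
}

same_topology <- function(t1, t2) {
  setequal(oracle_splits(t1), oracle_splits(t2))
}

# brute-force pairwise composition distances by explicit looping
oracle_comp_dist <- function(aln) {
  seqs <- aln$sequences
  taxa <- aln$taxa
  props <- lapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch <- ch[ch %in% c("A", "C", "G", "T")]
    c(mean(ch == "A"), mean(ch == "C"), mean(ch == "G"), mean(ch == "T"))
  })
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((props[[i]] - props[[j]])^2))
    }
  }
  d
}

# canonical key for a given side of a split, matching the package's frozen
# representation (side not containing the smallest label)
split_key_for <- function(side, tree) {
  labels <- tree$tip.label
  side <- sort(side)
  if (min(labels) %in% side) side <- sort(setdiff(labels, side))
  paste(side, collapse = "|")
}

# amino-acid translation oracle over the standard code
STD_CODE <- Biostrings::getGeneticCode("1")

random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 2)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
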