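# local, restorable seeding for every stochastic entry point
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("D must be square")
  if (is.null(rownames(D))) abort("D must carry taxon dimnames")
  if (max(abs(D - t(D))) > 1e-8) abort("D must be symmetric")
  if (any(D < -1e-12)) abort("D must be non-negative")
  invisible(D)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with deterministic behavior: taxa are put in
#' canonical (sorted-label) order before agglomeration so ties break
#' identically regardless of input order. Negative branch lengths are
#' clamped to zero; the total clamped deficit is recorded in the tree's
#' `clamp_deficit` attribute.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  check_distance_matrix(D)
  if (nrow(D) < 3) abort("need at least 3 taxa")
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  tr <- ape::nj(D)
  deficit <- -sum(pmin(tr$edge.length, 0))
  tr$edge.length <- pmax(tr$edge.length, 0)
  attr(tr, "clamp_deficit") <- deficit
  tr
}

# OLS branch lengths for a fixed unrooted topology.
# Pair (i, j) crosses edge e iff i and j fall on opposite sides of e's
# split; solve least squares on that 0/1 design matrix.
ols_branch_lengths <- function(tree, D) {
  labels <- tree$tip.label
  if (!identical(sort(labels), sort(rownames(D)))) {
    abort("tree leaves do not match distance matrix taxa")
  }
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(labels)
  E <- nrow(utree$edge)
  # tip membership below each edge's child node
  below <- matrix(FALSE, E, n)
  pp <- ape::prop.part(utree)   # clades indexed by internal node - n
  for (e in seq_len(E)) {
    child <- utree$edge[e, 2]
    tips <- if (child <= n) child else pp[[child - n]]
    below[e, tips] <- TRUE
  }
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  X <- matrix(0, np, E)
  d <- numeric(np)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    X[p, ] <- xor(below[, i], below[, j])
    d[p] <- D[labels[i], labels[j]]
  }
  fit <- stats::lsfit(X, d, intercept = FALSE)
  utree$edge.length <- unname(fit$coefficients)
  utree
}

#' Minimum-evolution refinement of a tree
#'
#' Fits ordinary-least-squares branch lengths to the given topology and
#' optionally hill-climbs over nearest-neighbor interchanges, accepting the
#' neighbor of smallest total (non-negative-clamped) length each round.
#' Total length never increases across accepted moves.
#'
#' @param tree starting `phylo` topology (leaves must match `D`).
#' @param D distance matrix.
#' @param nni_rounds maximum NNI improvement rounds (0 = OLS fit only).
#' @return a `phylo` tree with raw OLS edge lengths (negatives retained;
#'   [tree_length()] clamps when reporting).
#' @export
me_refine <- function(tree, D, nni_rounds = 10) {
  check_distance_matrix(D)
  cur <- ols_branch_lengths(tree, D)
  cur_len <- tree_length(cur)
  rounds <- 0
  while (rounds < nni_rounds && length(cur$tip.label) > 3) {
    neighbors <- phangorn::nni(cur)
    fits <- lapply(neighbors, ols_branch_lengths, D = D)
    lens <- vapply(fits, tree_length, 0)
    best <- which.min(lens)
    if (lens[best] < cur_len - 1e-12) {
      cur <- fits[[best]]
      cur_len <- lens[best]
      rounds <- rounds + 1
    } else break
  }
  cur
}

#' Total tree length
#'
#' Sum of branch lengths with negative values clamped to zero. Used as the
#' heterogeneity statistic of a composition distance tree: the longer the
#' tree, the greater the overall compositional heterogeneity.
#'
#' @param tree a `phylo` with branch lengths.
#' @return numeric scalar.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  sum(pmax(tree$edge.length, 0))
}

#' Composition distance tree with its length
#'
#' Convenience pipeline: composition distance matrix, NJ tree, optional ME
#' refinement.
#'
#' @inheritParams composition_distance_matrix
#' @param nni_rounds NNI rounds for [me_refine()] (default 5).
#' @return a `phylo`; its clamped total length is `tree_length(tree)`.
#' @export
composition_tree <- function(aln, ambiguity_rule = c("exclude", "fractional"),
                             nni_rounds = 5) {
  D <- composition_distance_matrix(aln, match.arg(ambiguity_rule))
  me_refine(nj_tree(D), D, nni_rounds = nni_rounds)
}

# fast per-taxon base counts for resampled columns
comp_count_cache <- function(aln, ambiguity_rule) {
  m <- aln_matrix(aln)
  if (ambiguity_rule == "exclude") {
    B <- match(m, c("A", "C", "G", "T"))
    dim(B) <- dim(m)
    list(rule = "exclude", B = B, n = nrow(m), taxa = aln$taxa)
  } else {
    W <- lapply(c("A", "C", "G", "T"), function(b) {
      w <- matrix(0, nrow(m), ncol(m))
      for (code in names(IUPAC_MAP)) {
        if (b %in% IUPAC_MAP[[code]]) {
          w[m == code] <- 1 / length(IUPAC_MAP[[code]])
        }
      }
      w
    })
    list(rule = "fractional", W = W, n = nrow(m), taxa = aln$taxa)
  }
}

comp_matrix_from_cache <- function(cache, cols) {
  if (cache$rule == "exclude") {
    B <- cache$B[, cols, drop = FALSE]
    counts <- t(vapply(seq_len(cache$n), function(i) {
      tabulate(B[i, ], nbins = 4)
    }, numeric(4)))
  } else {
    counts <- vapply(cache$W, function(w) {
      rowSums(w[, cols, drop = FALSE])
    }, numeric(cache$n))
  }
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    abort(paste0("taxa with zero countable sites in resample: ",
                 paste(cache$taxa[tot == 0], collapse = ", ")))
  }
  p <- counts / tot
  rownames(p) <- cache$taxa
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- list(cache$taxa, cache$taxa)
  d
}

#' Bootstrap support for a composition distance tree
#'
#' Columns are resampled with replacement; each pseudoreplicate yields a
#' composition distance matrix and a distance tree; majority-rule split
#' frequencies are mapped onto the full-data tree as percent support.
#'
#' @inheritParams composition_distance_matrix
#' @param n_pseudoreplicates number of column resamples (default 500).
#' @param seed integer seed making the run reproducible.
#' @param nni_rounds NNI refinement rounds per tree (default 0 = NJ only).
#' @return an object of class `composition_bootstrap`: list with `tree`
#'   (full-data tree, support as node labels), `support` (tibble of the
#'   full tree's splits and their percent support), `split_freq` (tibble of
#'   all splits observed across pseudoreplicates), `n_pseudoreplicates`,
#'   `seed`.
#' @export
composition_bootstrap <- function(aln, n_pseudoreplicates = 500, seed = NULL,
                                  ambiguity_rule = c("exclude", "fractional"),
                                  nni_rounds = 0) {
  ambiguity_rule <- match.arg(ambiguity_rule)
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$taxa) < 4) abort("need at least 4 taxa")
  full_D <- composition_distance_matrix(aln, ambiguity_rule)
  full <- me_refine(nj_tree(full_D), full_D, nni_rounds = max(nni_rounds, 0))
  cache <- comp_count_cache(aln, ambiguity_rule)
  L <- aln$length
  ref <- min(aln$taxa)
  keysets <- with_seed_(seed, {
    lapply(seq_len(n_pseudoreplicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      D <- comp_matrix_from_cache(cache, cols)
      tr <- nj_tree(D)
      if (nni_rounds > 0) tr <- me_refine(tr, D, nni_rounds = nni_rounds)
      tree_bipartitions(tr, ref = ref)
    })
  })
  tb <- table(unlist(keysets, use.names = FALSE))
  freq <- tibble(split = names(tb),
                 support = 100 * as.integer(tb) / n_pseudoreplicates) |>
    arrange(desc(.data$support), .data$split)
  own <- tree_bipartitions(full, ref = ref)
  sup <- setNames(rep(0, length(own)), own)
  hit <- intersect(own, freq$split)
  sup[hit] <- freq$support[match(hit, freq$split)]
  tree <- full
  tree$node.label <- NULL
  tree <- annotate_supports(tree, sup, ref)
  structure(
    list(tree = tree,
         support = tibble(split = names(sup), support = unname(sup)),
         split_freq = freq,
         n_pseudoreplicates = n_pseudoreplicates, seed = seed),
    class = "composition_bootstrap"
  )
}

# write per-split support (percent, rounded for display) into node labels
annotate_supports <- function(tree, support_by_key, ref) {
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(utree$tip.label)
  pp <- ape::prop.part(utree)
  labs <- rep("", utree$Nnode)
  for (i in seq_along(pp)) {
    tips <- utree$tip.label[pp[[i]]]
    if (length(tips) <= 1 || length(tips) >= n - 1) next
    key <- split_key(tips, utree$tip.label, ref)
    if (key %in% names(support_by_key)) {
      labs[i] <- as.character(round(support_by_key[[key]]))
    }
  }
  utree$node.label <- labs
  utree
}

#' @export
print.composition_bootstrap <- function(x, ...) {
  cat("<composition_bootstrap> ", x$n_pseudoreplicates,
      " pseudoreplicates", if (!is.null(x$seed)) paste0(", seed ", x$seed),
      "\n", sep = "")
  print(x$support, n = 10)
  invisible(x)
}

#' @rdname composition_bootstrap
#' @param x a `composition_bootstrap` object.
#' @param taxa character vector of tip labels forming one side of a split.
#' @return `split_support()`: percent of pseudoreplicate trees containing
#'   exactly that split (0 when never seen).
#' @export
split_support <- function(x, taxa) {
  stopifnot(inherits(x, "composition_bootstrap"))
  all_taxa <- x$tree$tip.label
  key <- split_key(taxa, all_taxa)
  hit <- match(key, x$split_freq$split)
  if (is.na(hit)) 0 else x$split_freq$support[hit]
}

#' Flag compositionally heterogeneous taxa
#'
#' Two screening rules for taxa whose base composition departs from the
#' rest: `centroid_z` flags taxa whose Euclidean distance to the mean
#' composition exceeds `threshold` standard deviations (of those distances);
#' `tree_tail` flags the `threshold` taxa with the greatest root-to-tip path
#' on the midpoint-rooted composition distance tree.
#'
#' @param aln a [codon_alignment()] (or a [composition_table()] tibble for
#'   `centroid_z`).
#' @param method `"centroid_z"` or `"tree_tail"`.
#' @param threshold z cutoff (centroid_z; default 3; the z score for each
#'   taxon is computed against the mean and spread of the other taxa's
#'   centroid distances) or count of taxa to flag (tree_tail).
#' @param ambiguity_rule see [composition_vector()].
#' @return tibble with columns `taxon`, `statistic`, `rule`.
#' @export
flag_heterogeneous_taxa <- function(aln,
                                    method = c("centroid_z", "tree_tail"),
                                    threshold = 3,
                                    ambiguity_rule = c("exclude",
                                                       "fractional")) {
  method <- match.arg(method)
  ambiguity_rule <- match.arg(ambiguity_rule)
  if (threshold <= 0) abort("threshold must be positive")
  if (method == "centroid_z") {
    ct <- if (inherits(aln, "codon_alignment")) {
      composition_table(aln, ambiguity_rule)
    } else {
      aln
    }
    if (nrow(ct) < 4) abort("need at least 4 taxa")
    p <- as.matrix(ct[, c("A", "C", "G", "T")])
    centroid <- colMeans(p)
    d <- sqrt(rowSums((p - matrix(centroid, nrow(p), 4, byrow = TRUE))^2))
    # leave-one-out z: an extreme taxon must not dilute its own baseline
    z <- vapply(seq_along(d), function(i) {
      mu <- mean(d[-i]); s <- sd(d[-i])
      dev <- d[i] - mu
      if (s == 0) {
        if (dev == 0) 0 else Inf
      } else {
        dev / s
      }
    }, 0)
    tibble(taxon = ct$taxon, statistic = z, rule = "centroid_z") |>
      filter(.data$statistic > threshold)
  } else {
    stopifnot(inherits(aln, "codon_alignment"))
    if (length(aln$taxa) < 4) abort("need at least 4 taxa")
    tr <- composition_tree(aln, ambiguity_rule)
    rooted <- phangorn::midpoint(tr)
    depth <- ape::node.depth.edgelength(rooted)[seq_along(rooted$tip.label)]
    tibble(taxon = rooted$tip.label, statistic = depth,
           rule = "tree_tail") |>
      arrange(desc(.data$statistic)) |>
      slice_head(n = as.integer(threshold))
  }
}
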