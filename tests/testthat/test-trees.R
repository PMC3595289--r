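test_that("NJ recovers additive matrices exactly (4-8 taxa)", {
  # hand-built 4-taxon case with known internal edge
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:4):0.5);")
  D <- ape::cophenetic.phylo(tr)
  nt <- nj_tree(D)
  expect_true(same_topology(nt, tr))
  expect_equal(tree_length(nt), sum(tr$edge.length))
  # and the recovered path distances are exact
  expect_equal(ape::cophenetic.phylo(nt)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  for (n in 4:8) {
    gen <- random_additive_matrix(n, seed = 20 + n)
    nt <- nj_tree(gen$D)
    expect_true(same_topology(nt, gen$tree))
  }
})

test_that("3 taxa give the unique star with three-point lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(length(tr$tip.label), 3)
  got <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(got[["a"]], (3 + 4 - 5) / 2)
  expect_equal(got[["b"]], (3 + 5 - 4) / 2)
  expect_equal(got[["c"]], (4 + 5 - 3) / 2)
})

test_that("nj_tree is deterministic and validates input", {
  gen <- random_additive_matrix(6, seed = 33)
  perm <- sample(rownames(gen$D))
  t1 <- nj_tree(gen$D)
  t2 <- nj_tree(gen$D[perm, perm])
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  bad <- gen$D; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
  neg <- gen$D; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(nj_tree(neg), "non-negative")
})

test_that("ME refinement fits OLS lengths and never lengthens the tree", {
  gen <- random_additive_matrix(6, seed = 40)
  ref <- me_refine(nj_tree(gen$D), gen$D)
  expect_true(same_topology(ref, gen$tree))      # additive: unchanged
  expect_equal(tree_length(ref), sum(gen$tree$edge.length),
               tolerance = 1e-8)

  # random (non-additive) matrices: refined <= NJ, equals exhaustive
  # minimum over all 105 six-taxon topologies
  all6 <- phangorn::allTrees(6, tip.label = rownames(gen$D))
  for (seed in c(51, 52)) {
    set.seed(seed)
    M <- matrix(stats::runif(36, 0.5, 2), 6, 6,
                dimnames = dimnames(gen$D))
    M <- (M + t(M)) / 2; diag(M) <- 0
    start <- nj_tree(M)
    ref <- me_refine(start, M, nni_rounds = 25)
    len_start <- tree_length(degenphy:::ols_branch_lengths(start, M))
    expect_lte(tree_length(ref), len_start + 1e-9)
    best <- min(vapply(all6, function(tp) {
      tree_length(degenphy:::ols_branch_lengths(tp, M))
    }, 0))
    expect_equal(tree_length(ref), best, tolerance = 1e-8)
  }
})

test_that("tree length clamps negatives and scales linearly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(tree_length(tr), 11)
  expect_error(tree_length(ape::read.tree(text = "((A,B),(C,D));")),
               "branch lengths")
  gen <- random_additive_matrix(6, seed = 60)
  l1 <- tree_length(me_refine(nj_tree(gen$D), gen$D))
  l5 <- tree_length(me_refine(nj_tree(gen$D * 5), gen$D * 5))
  expect_equal(l5 / l1, 5, tolerance = 1e-6)
})

test_that("composition bootstrap separates planted composition clusters", {
  set.seed(71)
  gc_seq <- function(n, p_gc) {
    paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                 prob = c(p_gc / 2, p_gc / 2, (1 - p_gc) / 2,
                          (1 - p_gc) / 2)), collapse = "")
  }
  seqs <- c(vapply(1:4, function(i) gc_seq(2000, 0.8), ""),
            vapply(1:4, function(i) gc_seq(2000, 0.2), ""))
  aln <- codon_alignment(setNames(seqs, paste0("x", 1:8)))
  bs <- composition_bootstrap(aln, 100, seed = 72)
  expect_equal(split_support(bs, paste0("x", 1:4)), 100, tolerance = 2)
  expect_true(all(bs$support$support >= 0 & bs$support$support <= 100))

  # identical runs are identical; homogeneous data show no strong split
  bs2 <- composition_bootstrap(aln, 100, seed = 72)
  expect_identical(bs$support, bs2$support)
  homog <- codon_alignment(setNames(
    vapply(1:6, function(i) gc_seq(300, 0.5), ""), paste0("h", 1:6)))
  bsh <- composition_bootstrap(homog, 100, seed = 73)
  expect_true(max(bsh$support$support) < 95)
})

test_that("bootstrap supports are invariant to taxon input order", {
  aln <- sim_codon_alignment(sim_tree(6, seed = 80), 60, seed = 81)
  bs1 <- composition_bootstrap(aln, 50, seed = 9)
  bs2 <- composition_bootstrap(subset_taxa(aln, keep = rev(aln$taxa)),
                               50, seed = 9)
  expect_equal(dplyr::arrange(bs1$split_freq, split),
               dplyr::arrange(bs2$split_freq, split))
})

test_that("heterogeneous-taxon flagging finds a planted outlier", {
  set.seed(90)
  base <- function() paste(sample(c("A", "C", "G", "T"), 1200,
                                  replace = TRUE), collapse = "")
  outlier <- paste(sample(c("G", "C"), 1200, replace = TRUE,
                          prob = c(0.5, 0.5)), collapse = "")
  aln <- codon_alignment(c(setNames(vapply(1:9, function(i) base(), ""),
                                    paste0("n", 1:9)),
                           bad = outlier))
  flags <- flag_heterogeneous_taxa(aln, "centroid_z", threshold = 3)
  expect_equal(flags$taxon, "bad")

  # removal strictly decreases the composition tree length
  before <- tree_length(composition_tree(aln))
  after <- tree_length(composition_tree(subset_taxa(aln, drop = "bad")))
  expect_lt(after, before)

  tail2 <- flag_heterogeneous_taxa(aln, "tree_tail", threshold = 2)
  expect_equal(nrow(tail2), 2)
  expect_true("bad" %in% tail2$taxon)

  same <- codon_alignment(setNames(rep("ACGTACGT", 5), paste0("s", 1:5)))
  expect_equal(nrow(flag_heterogeneous_taxa(same, "centroid_z", 3)), 0)
  expect_error(flag_heterogeneous_taxa(aln, "centroid_z", 0), "positive")
})
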