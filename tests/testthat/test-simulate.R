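test_that("tree simulation is seeded and sized correctly", {
  t1 <- sim_tree(10, seed = 1)
  t2 <- sim_tree(10, seed = 1)
  t3 <- sim_tree(10, seed = 2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
  expect_equal(length(t1$tip.label), 10)
  expect_error(sim_tree(3), "n_taxa")

  # deeper trees with more taxa at fixed rate (Yule expectation)
  depth <- function(n, seed) {
    max(ape::node.depth.edgelength(sim_tree(n, seed = seed)))
  }
  d8 <- mean(vapply(1:30, function(s) depth(8, s), 0))
  d32 <- mean(vapply(1:30, function(s) depth(32, s + 500), 0))
  expect_gt(d32, d8)
})

test_that("codon simulation honors its degenerate cases", {
  tr <- sim_tree(6, seed = 5)
  # no synonymous events, no bias: degen1 images identical wherever the
  # amino acids agree (here everywhere, between sisters sharing history)
  aln0 <- sim_codon_alignment(tr, 30, nonsyn_rate = 0, syn_rate = 0,
                              seed = 6)
  seqs <- aln0$sequences
  expect_true(all(seqs == seqs[[1]]))  # nothing ever changes

  # nonsyn_rate = 0: translations identical across taxa at every site
  aln1 <- sim_codon_alignment(tr, 30, nonsyn_rate = 0, syn_rate = 5,
                              seed = 7)
  codons <- function(s) substring(s, seq(1, nchar(s), 3),
                                  seq(3, nchar(s), 3))
  aas <- lapply(aln1$sequences, function(s) unname(STD_CODE[codons(s)]))
  expect_true(all(vapply(aas, identical, TRUE, aas[[1]])))

  # seeding: reproducible, and the seed matters
  a <- sim_codon_alignment(tr, 20, seed = 8)
  b <- sim_codon_alignment(tr, 20, seed = 8)
  c <- sim_codon_alignment(tr, 20, seed = 9)
  expect_identical(a$sequences, b$sequences)
  expect_false(identical(a$sequences, c$sequences))

  # alignments are in-frame, gapless and stop-free
  rep <- validate_frame(a)
  expect_true(all(rep$n_stop_codons == 0) && !any(rep$frame_anomaly))
  expect_false(any(grepl("[?-]", a$sequences)))
})

test_that("degen1 images agree where amino acids agree (Ser excepted)", {
  # serine is the one amino acid whose two codon blocks (TCN, AGY) keep
  # distinct degen1 images, so those sites are excluded
  tr <- sim_tree(6, seed = 15)
  aln <- sim_codon_alignment(tr, 60, nonsyn_rate = 0.3, syn_rate = 5,
                             seed = 16)
  d1 <- degen1_alignment(aln)
  codons <- function(s) substring(s, seq(1, nchar(s), 3),
                                  seq(3, nchar(s), 3))
  aa <- lapply(aln$sequences, function(s) unname(STD_CODE[codons(s)]))
  img <- lapply(d1$sequences, codons)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      comparable <- aa[[i]] == aa[[j]] & aa[[i]] != "S"
      expect_identical(img[[i]][comparable], img[[j]][comparable])
    }
  }
})

test_that("GC3 bias raises third-position G+C on biased lineages", {
  gc3_of <- function(aln, taxon) {
    s <- strsplit(aln$sequences[[match(taxon, aln$taxa)]], "")[[1]]
    third <- s[seq(3, length(s), by = 3)]
    mean(third %in% c("G", "C"))
  }
  diffs <- vapply(1:10, function(seed) {
    tr <- sim_tree(8, seed = seed)
    biased <- pick_nonsister_pair(tr)
    aln <- sim_codon_alignment(tr, 300, biased_taxa = biased,
                               gc3_weight = 10, seed = seed + 50)
    others <- setdiff(aln$taxa, biased)
    mean(vapply(biased, gc3_of, 0, aln = aln)) -
      mean(vapply(others, gc3_of, 0, aln = aln))
  }, 0)
  expect_gt(mean(diffs), 0.15)
})

test_that("search-replicate logs have binomial behavior", {
  expect_true(all(sim_search_replicates(1, 50, seed = 1)$success))
  expect_false(any(sim_search_replicates(0, 50, seed = 1)$success))
  big <- sim_search_replicates(0.3, 1e5, seed = 2)
  se <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(mean(big$success) - 0.3), 3 * se)
  expect_error(sim_search_replicates(1.2, 10), "p_success")
})

test_that("simulated bootstrap runs follow their generative model", {
  ref <- sim_tree(8, seed = 21)
  # q_find = 1: every replicate finds the latent best; support independent
  # of k
  run <- sim_bootstrap_run(ref, 40, k = 5, pi_true = 0.8, q_find = 1,
                           seed = 22)
  tab <- best_of_k_supports(run, ref, ks = c(1, 3, 5))
  wide <- tidyr::pivot_wider(tab, names_from = "k",
                             values_from = "support")
  expect_true(all(wide$`1` == wide$`3` & wide$`3` == wide$`5`))

  # pi_true = 1, q_find = 1: all reference edges at 100
  run2 <- sim_bootstrap_run(ref, 20, k = 2, pi_true = 1, q_find = 1,
                            seed = 23)
  tab2 <- best_of_k_supports(run2, ref, ks = 2)
  expect_true(all(tab2$support == 100))

  # reproducibility
  r1 <- sim_bootstrap_run(ref, 10, 3, 0.8, 0.5, seed = 24)
  r2 <- sim_bootstrap_run(ref, 10, 3, 0.8, 0.5, seed = 24)
  expect_equal(r1$score, r2$score)
  expect_error(sim_bootstrap_run(ref, 10, 3, 1.5, 0.5), "pi_true")
})
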