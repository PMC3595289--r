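test_that("strict consensus equals brute-force split intersection", {
  t1 <- ape::read.tree(text = "((((A,B),C),D),E);")
  t2 <- ape::read.tree(text = "((((A,C),B),D),E);")
  sc <- strict_consensus(list(t1, t2))
  expect_setequal(oracle_splits(sc),
                  intersect(oracle_splits(t1), oracle_splits(t2)))
  # a single tree is its own strict consensus
  expect_true(same_topology(strict_consensus(list(t1)), t1))
  # two 5-taxon trees differing in one clade: one fewer internal edge
  expect_equal(length(oracle_splits(sc)), length(oracle_splits(t1)) - 1)

  # enumerated random 5-taxon tree sets against the oracle
  all5 <- phangorn::allTrees(5, tip.label = LETTERS[1:5])
  set.seed(7)
  for (rep in 1:5) {
    trees <- all5[sample(length(all5), 3)]
    got <- oracle_splits(strict_consensus(trees))
    want <- Reduce(intersect, lapply(trees, oracle_splits))
    expect_setequal(got, want)
  }
})

test_that("majority consensus keeps >cutoff splits with percent support", {
  t1 <- ape::read.tree(text = "((((A,B),C),D),E);")
  t2 <- ape::read.tree(text = "((((A,C),B),D),E);")
  mc <- majority_consensus(list(t1, t1, t2))
  sup <- attr(mc, "support")
  # the A,B clade appears in 2 of 3 trees: retained at 67
  ab_key <- setdiff(oracle_splits(t1), oracle_splits(t2))
  expect_true(ab_key %in% sup$split)
  expect_equal(round(sup$support[sup$split == ab_key]), 67)

  idc <- majority_consensus(list(t1, t1, t1))
  expect_true(same_topology(idc, t1))
  expect_true(all(attr(idc, "support")$support == 100))

  # retained splits are pairwise compatible: they form a tree that holds
  # every one of them
  expect_setequal(oracle_splits(mc), sup$split)
  expect_error(majority_consensus(list(t1, t2), cutoff = 0.4), "cutoff")

  # cross-check against the reference implementation
  ref <- ape::consensus(list(t1, t1, t2), p = 0.5)
  expect_setequal(oracle_splits(mc), oracle_splits(ref))
})

test_that("Adams consensus preserves nestings that strict loses", {
  t1 <- ape::read.tree(text = "((((A,B),C),D),E);")
  t2 <- ape::read.tree(text = "((((A,C),B),D),E);")
  ac <- adams_consensus(list(t1, t2), outgroup = "E")
  expect_equal(ape::write.tree(ac), "(((A,B,C),D),E);")
  expect_setequal(ac$tip.label, t1$tip.label)

  # identical trees: unchanged topology
  ac2 <- adams_consensus(list(t1, t1), outgroup = "E")
  expect_true(same_topology(ac2, t1))

  # a wandering taxon: Adams keeps the (A,C) nesting that the strict
  # consensus loses entirely (hand-executed recursion:
  # root partitions agree on ABCD|E; within ABCD the partition product of
  # {ABC}{D} and {ACD}{B} is {AC}{B}{D})
  w1 <- ape::read.tree(text = "((((A,B),C),D),E);")
  w2 <- ape::read.tree(text = "((((A,D),C),B),E);")
  aw <- adams_consensus(list(w1, w2), outgroup = "E")
  expect_equal(ape::write.tree(aw), "(((A,C),B,D),E);")
  expect_length(oracle_splits(strict_consensus(list(w1, w2))), 0)

  expect_error(adams_consensus(list(
    t1, ape::read.tree(text = "((A,B),(C,F));")), outgroup = "A"),
    "leaf set")
})

test_that("every consensus split comes from some input tree", {
  all5 <- phangorn::allTrees(5, tip.label = LETTERS[1:5])
  set.seed(11)
  for (rep in 1:4) {
    trees <- all5[sample(length(all5), 4)]
    pool <- unique(unlist(lapply(trees, oracle_splits)))
    expect_true(all(oracle_splits(strict_consensus(trees)) %in% pool))
    expect_true(all(oracle_splits(majority_consensus(trees)) %in% pool))
    # strict splits are a subset of majority splits
    expect_true(all(oracle_splits(strict_consensus(trees)) %in%
                      oracle_splits(majority_consensus(trees))))
  }
})
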