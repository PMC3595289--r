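test_that("published degen1 codon images are reproduced", {
  tbl <- build_degen_table()
  expect_equal(degen_codon(tbl, "CAT"), "CAY")
  expect_equal(degen_codon(tbl, "TTA"), "YTN")
  expect_equal(degen_codon(tbl, "CTG"), "YTN")
  expect_equal(degen_codon(tbl, "AGA"), "MGN")
  expect_equal(degen_codon(tbl, "CGC"), "MGN")
  expect_equal(degen_codon(tbl, "TTT"), "TTY")
  expect_equal(degen_codon(tbl, "AGC"), "AGY")
  expect_equal(degen_codon(tbl, "TCT"), "TCN")
  expect_equal(degen_codon(tbl, "ATG"), "ATG")
  expect_equal(degen_codon(tbl, "TGG"), "TGG")
  expect_equal(degen_codon(tbl, "---"), "---")
  # ambiguity with a unique common image resolves to it
  expect_equal(degen_codon(tbl, "GCM"), "GCN")
  # ambiguity spanning families without a family image collapses to NNN
  expect_equal(degen_codon(tbl, "RAT"), "NNN")  # Asn/Asp mix
})

test_that("synonymous sense-codon pairs share one image (exhaustive)", {
  tbl <- build_degen_table()
  sense <- names(STD_CODE)[STD_CODE != "*"]
  ser1 <- sense[startsWith(sense, "TC")]
  ser2 <- c("AGT", "AGC")
  for (c1 in sense) {
    for (c2 in sense) {
      if (STD_CODE[[c1]] != STD_CODE[[c2]]) next
      if ((c1 %in% ser1 && c2 %in% ser2) ||
          (c1 %in% ser2 && c2 %in% ser1)) next
      expect_identical(degen_codon(tbl, c1), degen_codon(tbl, c2))
    }
  }
  # the serine exception: the two blocks stay apart but both remain Ser
  expect_false(degen_codon(tbl, "TCT") == degen_codon(tbl, "AGT"))
  for (cd in c("TCT", "AGT")) {
    img <- degen_codon(tbl, cd)
    res <- expand.grid(degenphy:::IUPAC_MAP[[substr(img, 1, 1)]],
                       degenphy:::IUPAC_MAP[[substr(img, 2, 2)]],
                       degenphy:::IUPAC_MAP[[substr(img, 3, 3)]])
    aas <- STD_CODE[apply(res, 1, paste, collapse = "")]
    expect_true("S" %in% aas)
  }
})

test_that("translation is preserved by the degen1 image", {
  tbl <- build_degen_table()
  sense <- names(STD_CODE)[STD_CODE != "*"]
  merged <- sense[STD_CODE[sense] %in% c("L", "F", "R", "S")]
  for (cd in sense) {
    img <- degen_codon(tbl, cd)
    res <- expand.grid(degenphy:::IUPAC_MAP[[substr(img, 1, 1)]],
                       degenphy:::IUPAC_MAP[[substr(img, 2, 2)]],
                       degenphy:::IUPAC_MAP[[substr(img, 3, 3)]])
    aas <- unique(unname(STD_CODE[apply(res, 1, paste, collapse = "")]))
    expect_true(STD_CODE[[cd]] %in% aas)
    if (!cd %in% merged) {
      expect_identical(aas, STD_CODE[[cd]])
    }
  }
})

test_that("the table is idempotent over the full ambiguity alphabet", {
  tbl <- build_degen_table(stop_policy = "passthrough")
  codes <- names(degenphy:::IUPAC_MAP)
  all_codons <- as.vector(outer(outer(codes, codes, paste0), codes, paste0))
  once <- vapply(all_codons, function(cd) degen_codon(tbl, cd), "")
  twice <- vapply(once, function(cd) degen_codon(tbl, cd), "")
  expect_identical(unname(twice), unname(once))
})

test_that("stop policies behave as declared", {
  expect_warning(
    out <- degen_codon(build_degen_table(stop_policy = "to_missing"), "TAA"),
    class = "degenphy_stop_codon")
  expect_equal(out, "NNN")
  expect_equal(
    degen_codon(build_degen_table(stop_policy = "passthrough"), "TGA"),
    "TGA")
  expect_error(
    degen_codon(build_degen_table(stop_policy = "error"), "TAG"),
    "stop codon")
  # ambiguous codon whose resolutions are all stops follows the policy too
  expect_warning(
    out2 <- degen_codon(build_degen_table(), "TRA"),
    class = "degenphy_stop_codon")
  expect_equal(out2, "NNN")
  expect_error(build_degen_table("no-such-code"), "unknown genetic code")
})

test_that("alignment recoding is codon-wise, shape-preserving, idempotent", {
  aln <- codon_alignment(c(t1 = "CATTTA", t2 = "CACCTG"))
  d1 <- degen1_alignment(aln)
  expect_equal(as_tibble(d1)$sequence, c("CAYYTN", "CAYYTN"))
  expect_equal(d1$taxa, aln$taxa)
  expect_equal(d1$length, aln$length)

  gaps <- codon_alignment(c(a = "------", b = "------"))
  expect_equal(as_tibble(degen1_alignment(gaps))$sequence,
               c("------", "------"))

  sim <- sim_codon_alignment(sim_tree(6, seed = 4), 40, seed = 5)
  once <- degen1_alignment(sim)
  expect_identical(degen1_alignment(once)$sequences, once$sequences)

  expect_error(degen1_alignment(codon_alignment(c(a = "CATT"))),
               "divisible by 3")
  straddle <- codon_alignment(c(a = "CATTTA"), excluded_columns = c(2))
  expect_error(degen1_alignment(straddle), "straddle")
})

test_that("column classification separates Leu/Arg first positions", {
  # codons [CTT|GAA]: Leu then Glu -> first and third of codon 1, third of
  # codon 2 are mostly-synonymous; the rest are nonsynonymous-only
  aln <- codon_alignment(c(a = "CTTGAA", b = "CTTGAA"))
  p <- classify_columns(aln)
  expect_equal(p$LRall1nt3, c(1, 3, 6))
  expect_equal(p$noLRall1nt2, c(2, 4, 5))

  # no Leu/Arg anywhere: LRall1nt3 is exactly the third positions
  aln2 <- codon_alignment(c(a = "GAAGGG", b = "GATGGC"))
  p2 <- classify_columns(aln2)
  expect_equal(p2$LRall1nt3, c(3, 6))
  expect_equal(p2$noLRall1nt2, c(1, 2, 4, 5))

  # all-Leu alignment: every first and third position
  aln3 <- codon_alignment(c(a = "TTACTG", b = "CTCTTG"))
  p3 <- classify_columns(aln3)
  expect_equal(p3$LRall1nt3, c(1, 3, 4, 6))

  # any_taxon vs all_taxa on a mixed column
  aln4 <- codon_alignment(c(a = "CTT", b = "GTT"))  # Leu vs Val
  expect_equal(classify_columns(aln4, "any_taxon")$LRall1nt3, c(1, 3))
  expect_equal(classify_columns(aln4, "all_taxa")$LRall1nt3, 3)
})

test_that("the partition is exhaustive and disjoint on simulated data", {
  for (seed in 1:3) {
    aln <- sim_codon_alignment(sim_tree(5, seed = seed), 30,
                               seed = seed + 100)
    p <- classify_columns(aln)
    expect_length(intersect(p$noLRall1nt2, p$LRall1nt3), 0)
    expect_setequal(c(p$noLRall1nt2, p$LRall1nt3), seq_len(aln$length))
  }
})
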