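#' Nucleotide composition of one sequence
#'
#' Proportions of A, C, G, T in a sequence, the raw material of the
#' compositional-heterogeneity diagnostics. Units are fractions
#' ("per cent / 100"). Gaps and `?` are never counted.
#'
#' @param sequence a character string over IUPAC codes, `-`, `?`.
#' @param ambiguity_rule `"exclude"` (default): only unambiguous A/C/G/T are
#'   counted; `"fractional"`: each ambiguity code contributes equal
#'   fractional weight to its compatible bases (e.g. Y adds 1/2 to C and
#'   1/2 to T).
#' @return a named numeric vector `c(A=, C=, G=, T=)` with attribute
#'   `n_counted` (number of sites contributing, possibly fractional under
#'   the fractional rule in the sense of total weight). All zero with
#'   `n_counted = 0` when nothing is countable.
#' @export
#' @examples
#' composition_vector("AAYG")                       # 2/3, 0, 1/3, 0
#' composition_vector("AAYG", "fractional")         # .5 .125 .25 .125
composition_vector <- function(sequence,
                               ambiguity_rule = c("exclude", "fractional")) {
  ambiguity_rule <- match.arg(ambiguity_rule)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  if (ambiguity_rule == "exclude") {
    tb <- table(factor(ch[ch %in% c("A", "C", "G", "T")],
                       levels = c("A", "C", "G", "T")))
    counts <- counts + as.numeric(tb)
  } else {
    for (code in names(IUPAC_MAP)) {
      k <- sum(ch == code)
      if (k > 0) {
        bases <- IUPAC_MAP[[code]]
        counts[bases] <- counts[bases] + k / length(bases)
      }
    }
  }
  n <- sum(counts)
  out <- if (n > 0) counts / n else counts * 0
  attr(out, "n_counted") <- n
  out
}

#' Per-taxon composition table
#'
#' @param aln a [codon_alignment()].
#' @param ambiguity_rule see [composition_vector()].
#' @return a tibble with columns `taxon`, `A`, `C`, `G`, `T`, `n_counted`,
#'   and `gc` (G + C fraction).
#' @export
composition_table <- function(aln,
                              ambiguity_rule = c("exclude", "fractional")) {
  ambiguity_rule <- match.arg(ambiguity_rule)
  stopifnot(inherits(aln, "codon_alignment"))
  rows <- lapply(aln$taxa, function(t) {
    v <- composition_vector(aln$sequences[[t]], ambiguity_rule)
    tibble(taxon = t, A = v[["A"]], C = v[["C"]], G = v[["G"]],
           T = v[["T"]], n_counted = attr(v, "n_counted"))
  })
  bind_rows(rows) |> mutate(gc = .data$G + .data$C)
}

#' Euclidean distance between two composition vectors
#'
#' @param v1,v2 composition vectors from [composition_vector()] (or any
#'   numeric 4-vectors of proportions).
#' @return sqrt(sum((v1 - v2)^2)); bounded by sqrt(2) for proportion
#'   vectors. Units "per cent / 100".
#' @export
composition_distance <- function(v1, v2) {
  n1 <- attr(v1, "n_counted") %||% sum(v1)
  n2 <- attr(v2, "n_counted") %||% sum(v2)
  if (n1 <= 0 || n2 <= 0) abort("composition vector with no counted sites")
  sqrt(sum((as.numeric(v1) - as.numeric(v2))^2))
}

#' Pairwise composition distance matrix
#'
#' Euclidean distances between per-taxon nucleotide-proportion vectors.
#' Distances reflect composition alone, not primary-sequence signal; a long
#' tree built from them indicates strong compositional heterogeneity.
#'
#' @inheritParams composition_table
#' @return a symmetric, zero-diagonal numeric matrix with taxon dimnames.
#' @export
composition_distance_matrix <- function(aln,
                                        ambiguity_rule = c("exclude",
                                                           "fractional")) {
  ambiguity_rule <- match.arg(ambiguity_rule)
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$taxa) < 3) abort("need at least 3 taxa")
  ct <- composition_table(aln, ambiguity_rule)
  if (any(ct$n_counted == 0)) {
    abort(paste0("taxa with zero countable sites: ",
                 paste(ct$taxon[ct$n_counted == 0], collapse = ", ")))
  }
  p <- as.matrix(ct[, c("A", "C", "G", "T")])
  rownames(p) <- ct$taxon
  d <- as.matrix(stats::dist(p, method = "euclidean"))
  dimnames(d) <- list(ct$taxon, ct$taxon)
  d
}

#' Uncorrected p-distance matrix
#'
#' Proportion of sites at which two taxa carry differing unambiguous
#' nucleotides, over sites where both are unambiguous. A deliberately
#' simple sequence distance used for desk-scale tree-recovery experiments.
#'
#' @param aln a [codon_alignment()].
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
pdistance_matrix <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$taxa) < 3) abort("need at least 3 taxa")
  m <- aln_matrix(aln)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  n <- length(aln$taxa)
  d <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- ok[i, ] & ok[j, ]
      nc <- sum(both)
      if (nc == 0) {
        abort(paste0("no comparable columns between ", aln$taxa[i], " and ",
                     aln$taxa[j]))
      }
      d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both]) / nc
    }
  }
  d
}
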