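#' In-frame codon alignment
#'
#' Container for an aligned, in-frame, protein-coding nucleotide matrix.
#' Sequences are stored as upper-case strings over the IUPAC nucleotide
#' alphabet plus `-` (gap) and `?` (missing). Columns listed in
#' `excluded_columns` are flagged (e.g. an ambiguously aligned mask) but kept
#' in place; most operations either drop them first or refuse codons that
#' straddle the mask.
#'
#' @param sequences named character vector of equal-length sequences; names
#'   are taxon labels (unique, non-empty).
#' @param frame_offset number of columns before the first complete codon
#'   (default 0).
#' @param excluded_columns integer vector of 1-based column indices flagged
#'   as excluded.
#' @param charsets optional named list of integer vectors (1-based column
#'   indices), e.g. as read from a NEXUS SETS block.
#' @return an object of class `codon_alignment`.
#' @export
#' @examples
#' aln <- codon_alignment(c(t1 = "CATTTA", t2 = "CACCTG"))
#' aln
codon_alignment <- function(sequences, frame_offset = 0L,
                            excluded_columns = integer(),
                            charsets = list()) {
  if (is.list(sequences)) sequences <- unlist(sequences)
  taxa <- names(sequences)
  if (is.null(taxa) || any(!nzchar(taxa))) {
    abort("sequences must be named by non-empty taxon labels")
  }
  if (anyDuplicated(taxa)) abort("duplicate taxon labels")
  sequences <- toupper(sequences)
  lens <- unique(nchar(sequences))
  if (length(lens) != 1) abort("all sequences must have equal length")
  bad <- stringr::str_detect(sequences, "[^ACGTRYSWKMBDHVN?-]")
  if (any(bad)) {
    abort(paste0("non-IUPAC symbols in taxa: ",
                 paste(taxa[bad], collapse = ", ")))
  }
  excluded_columns <- sort(unique(as.integer(excluded_columns)))
  if (length(excluded_columns) &&
      (min(excluded_columns) < 1 || max(excluded_columns) > lens)) {
    abort("excluded_columns out of range")
  }
  structure(
    list(taxa = taxa, sequences = setNames(unname(sequences), taxa),
         length = lens, frame_offset = as.integer(frame_offset),
         excluded_columns = excluded_columns, charsets = charsets),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", x$length,
      " columns", sep = "")
  if (x$frame_offset > 0) cat(", frame offset ", x$frame_offset, sep = "")
  if (length(x$excluded_columns)) {
    cat(", ", length(x$excluded_columns), " excluded columns", sep = "")
  }
  cat("\n")
  shown <- head(x$taxa, 5)
  for (t in shown) {
    s <- x$sequences[[t]]
    cat(format(t, width = 12), substr(s, 1, min(48, nchar(s))),
        if (nchar(s) > 48) "..." else "", "\n")
  }
  if (length(x$taxa) > 5) cat("... and", length(x$taxa) - 5, "more taxa\n")
  invisible(x)
}

#' @export
as_tibble.codon_alignment <- function(x, ...) {
  tibble(taxon = x$taxa, sequence = unname(x$sequences[x$taxa]))
}

# character matrix view (taxa x columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences[aln$taxa], "", fixed = TRUE))
  rownames(m) <- aln$taxa
  m
}

matrix_to_alignment <- function(m, frame_offset = 0L,
                                excluded_columns = integer(),
                                charsets = list()) {
  seqs <- apply(m, 1, paste, collapse = "")
  codon_alignment(setNames(seqs, rownames(m)), frame_offset,
                  excluded_columns, charsets)
}

#' Drop flagged (masked) columns from an alignment
#'
#' Removes the columns in `excluded_columns`, renumbering any charsets to the
#' retained coordinate system (indices falling in the mask are dropped).
#'
#' @param aln a [codon_alignment()].
#' @return a `codon_alignment` with no excluded columns.
#' @export
drop_excluded_columns <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!length(aln$excluded_columns)) return(aln)
  keep <- setdiff(seq_len(aln$length), aln$excluded_columns)
  remap <- match(seq_len(aln$length), keep)
  m <- aln_matrix(aln)[, keep, drop = FALSE]
  cs <- lapply(aln$charsets, function(ix) sort(remap[ix[ix %in% keep]]))
  matrix_to_alignment(m, aln$frame_offset, integer(), cs)
}

codon_starts <- function(aln) {
  first <- aln$frame_offset + 1L
  n_codons <- (aln$length - aln$frame_offset) %/% 3L
  if (n_codons < 1) return(integer())
  seq.int(first, by = 3L, length.out = n_codons)
}

# taxa x codons matrix of 3-character codon strings
codon_matrix <- function(aln) {
  st <- codon_starts(aln)
  m <- aln_matrix(aln)
  out <- vapply(st, function(s) {
    paste0(m[, s], m[, s + 1L], m[, s + 2L])
  }, character(length(aln$taxa)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(aln$taxa))
  rownames(out) <- aln$taxa
  out
}

#' Frame and internal-stop validation report
#'
#' Scans an alignment codon-wise and reports, per taxon, the number of
#' internal stop codons (codons whose sense resolutions are all stops under
#' the chosen genetic code) and whether the sequence length is consistent
#' with the declared reading frame. Purely diagnostic; the alignment is not
#' modified.
#'
#' @param aln a [codon_alignment()].
#' @param genetic_code_id translation table identifier passed to
#'   [Biostrings::getGeneticCode()] (default `"1"`, the standard code).
#' @return a tibble with columns `taxon`, `n_stop_codons`,
#'   `stop_codon_index` (list column of codon indices), and `frame_anomaly`
#'   (TRUE when trailing columns do not complete a codon).
#' @export
#' @examples
#' aln <- codon_alignment(c(a = "ATGTAAGGG", b = "ATGCACGGG"))
#' validate_frame(aln)
validate_frame <- function(aln, genetic_code_id = "1") {
  stopifnot(inherits(aln, "codon_alignment"))
  frame_anomaly <- ((aln$length - aln$frame_offset) %% 3L) != 0L
  cm <- codon_matrix(aln)
  stops <- lapply(seq_along(aln$taxa), function(i) {
    if (!ncol(cm)) return(integer())
    which(vapply(cm[i, ], is_stop_codon, TRUE,
                 genetic_code_id = genetic_code_id))
  })
  tibble(
    taxon = aln$taxa,
    n_stop_codons = lengths(stops),
    stop_codon_index = lapply(stops, unname),
    frame_anomaly = frame_anomaly
  )
}
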