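# --- NEXUS data-matrix dialect ---------------------------------------------
# Reads/writes simple NEXUS DATA/CHARACTERS blocks (sequential or
# interleaved, bracketed comments, quoted taxon names) plus SETS blocks
# with CHARSET and EXSET statements. Charset coordinates are 1-based
# inclusive, with "a-b" ranges, "a-b\step" strides and "." = last column.

strip_nexus_comments <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0
  keep <- logical(length(chars))
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1
    keep[i] <- depth == 0
    if (chars[i] == "]" && depth > 0) depth <- depth - 1
  }
  paste(chars[keep], collapse = "")
}

parse_charset_ranges <- function(spec, nchar_total, line_no = NA) {
  out <- integer()
  for (tok in strsplit(trimws(spec), "\\s+")[[1]]) {
    if (!nzchar(tok)) next
    tok <- gsub("\\.", as.character(nchar_total), tok)
    m <- regmatches(tok, regexec("^(\\d+)(?:-(\\d+))?(?:\\\\(\\d+))?$", tok))[[1]]
    if (!length(m)) {
      abort(paste0("malformed charset token '", tok, "'",
                   if (!is.na(line_no)) paste0(" at line ", line_no)))
    }
    from <- as.integer(m[2])
    to <- if (nzchar(m[3])) as.integer(m[3]) else from
    by <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    out <- c(out, seq.int(from, to, by = by))
  }
  ix <- sort(unique(out))
  if (length(ix) && (min(ix) < 1 || max(ix) > nchar_total)) {
    abort(paste0("charset index out of bounds",
                 if (!is.na(line_no)) paste0(" at line ", line_no)))
  }
  ix
}

read_nexus_alignment <- function(path) {
  text <- strip_nexus_comments(paste(readLines(path, warn = FALSE),
                                     collapse = "\n"))
  if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    abort("not a NEXUS file (missing #NEXUS header)")
  }
  # statements are ;-terminated; keep raw text for the MATRIX body
  stmts_raw <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  stmts <- trimws(gsub("\\s+", " ", stmts_raw))
  up <- toupper(stmts)

  grab <- function(stmt, key) {
    m <- regmatches(stmt, regexec(paste0("(?i)", key, "\\s*=\\s*(\\S+)"),
                                  stmt, perl = TRUE))[[1]]
    if (length(m)) m[2] else NA_character_
  }

  dim_i <- grep("^DIMENSIONS\\b", up)
  if (!length(dim_i)) abort("NEXUS file lacks a DIMENSIONS statement")
  ntax <- as.integer(grab(stmts[dim_i[1]], "NTAX"))
  nchar_total <- as.integer(grab(stmts[dim_i[1]], "NCHAR"))

  mat_i <- grep("^MATRIX\\b", up)
  if (!length(mat_i)) abort("NEXUS file lacks a MATRIX statement")
  body <- sub("(?i)^MATRIX[ \t]*\n?", "", stmts_raw[mat_i[1]], perl = TRUE)
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  seqs <- list()
  order_seen <- character()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "'")) {
      m <- regmatches(ln, regexec("^'([^']*)'\\s*(.*)$", ln))[[1]]
      name <- m[2]; rest <- m[3]
    } else {
      m <- regmatches(ln, regexec("^(\\S+)\\s*(.*)$", ln))[[1]]
      name <- m[2]; rest <- m[3]
    }
    chunk <- gsub("\\s+", "", rest)
    if (!name %in% order_seen) {
      order_seen <- c(order_seen, name)
      seqs[[name]] <- chunk
    } else {
      seqs[[name]] <- paste0(seqs[[name]], chunk)   # interleaved
    }
  }
  if (anyDuplicated(order_seen)) abort("duplicate taxa in NEXUS matrix")
  if (!is.na(ntax) && length(seqs) != ntax) {
    abort(paste0("DIMENSIONS ntax=", ntax, " but matrix holds ",
                 length(seqs), " taxa"))
  }
  lens <- nchar(unlist(seqs))
  if (!is.na(nchar_total) && any(lens != nchar_total)) {
    bad <- order_seen[lens != nchar_total][1]
    abort(paste0("DIMENSIONS nchar=", nchar_total, " but taxon '", bad,
                 "' has ", nchar(seqs[[bad]]), " characters"))
  }

  charsets <- list()
  for (i in grep("^CHARSET\\b", up)) {
    m <- regmatches(stmts[i],
                    regexec("(?i)^CHARSET\\s+(\\S+)\\s*=\\s*(.*)$",
                            stmts[i], perl = TRUE))[[1]]
    charsets[[m[2]]] <- parse_charset_ranges(m[3], nchar_total)
  }
  excluded <- integer()
  for (i in grep("^EXSET\\b", up)) {
    m <- regmatches(stmts[i],
                    regexec("(?i)^EXSET\\s+\\*?\\s*(\\S+)\\s*=\\s*(.*)$",
                            stmts[i], perl = TRUE))[[1]]
    excluded <- sort(unique(c(excluded,
                              parse_charset_ranges(m[2 + 1], nchar_total))))
  }
  codon_alignment(setNames(unlist(seqs)[order_seen], order_seen),
                  excluded_columns = excluded, charsets = charsets)
}

# compress sorted indices to NEXUS "a-b c d-e" range text
ranges_text <- function(ix) {
  ix <- sort(unique(ix))
  if (!length(ix)) return("")
  breaks <- c(0, which(diff(ix) != 1), length(ix))
  parts <- vapply(seq_len(length(breaks) - 1), function(i) {
    a <- ix[breaks[i] + 1]; b <- ix[breaks[i + 1]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, "")
  paste(parts, collapse = " ")
}

quote_taxon <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.+|-]", x)
  ifelse(needs, paste0("'", gsub("'", "''", x), "'"), x)
}

write_nexus_alignment <- function(aln, path, charsets = NULL) {
  cs <- charsets %||% aln$charsets
  if (inherits(cs, "charset_partition")) {
    cs <- list(noLRall1nt2 = cs$noLRall1nt2, LRall1nt3 = cs$LRall1nt3)
  }
  cs <- Filter(length, cs %||% list())
  names_q <- quote_taxon(aln$taxa)
  pad <- max(nchar(names_q)) + 2
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    paste0("  DIMENSIONS NTAX=", length(aln$taxa), " NCHAR=", aln$length,
           ";"),
    "  FORMAT DATATYPE=DNA GAP=- MISSING=?;",
    "  MATRIX",
    paste0("    ", formatC(names_q, width = -pad), aln$sequences[aln$taxa]),
    "  ;",
    "END;"
  )
  if (length(cs) || length(aln$excluded_columns)) {
    sets <- c("BEGIN SETS;")
    for (nm in names(cs)) {
      sets <- c(sets, paste0("  CHARSET ", nm, " = ", ranges_text(cs[[nm]]),
                             ";"))
    }
    if (length(aln$excluded_columns)) {
      sets <- c(sets, paste0("  EXSET * mask = ",
                             ranges_text(aln$excluded_columns), ";"))
    }
    lines <- c(lines, sets, "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

# --- public readers/writers -------------------------------------------------

#' Read an alignment from NEXUS or FASTA
#'
#' NEXUS DATA/CHARACTERS blocks (sequential or interleaved) are parsed
#' together with any SETS block: CHARSETs populate the alignment's
#' `charsets` and an EXSET populates `excluded_columns`. FASTA sequences
#' may be line-wrapped.
#'
#' @param path input file.
#' @param format `"auto"` (default; sniffs the `#NEXUS` header), `"nexus"`
#'   or `"fasta"`.
#' @return a [codon_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "nexus", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
      "nexus"
    } else {
      "fasta"
    }
  }
  if (format == "nexus") return(read_nexus_alignment(path))
  fa <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  codon_alignment(setNames(toupper(unlist(fa)), names(fa)))
}

#' Write an alignment to NEXUS or FASTA
#'
#' NEXUS output contains DIMENSIONS, a `FORMAT DATATYPE=DNA GAP=- MISSING=?`
#' statement, the matrix, and (when charsets or excluded columns exist) a
#' SETS block with 1-based inclusive CHARSET/EXSET coordinates.
#'
#' @param aln a [codon_alignment()].
#' @param path output file.
#' @param format `"nexus"` (default) or `"fasta"`.
#' @param charsets optional named list of column-index vectors or a
#'   [classify_columns()] partition, written as CHARSETs (defaults to the
#'   alignment's own charsets).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("nexus", "fasta"),
                            charsets = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "codon_alignment"))
  if (format == "nexus") return(write_nexus_alignment(aln, path, charsets))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in aln$taxa) {
    writeLines(paste0(">", t), con)
    s <- aln$sequences[[t]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

#' Read trees from newick or NEXUS
#'
#' @param path input file (newick: one tree per line; NEXUS: TREES block,
#'   TRANSLATE tables honored by the underlying reader).
#' @param format `"auto"`, `"newick"` or `"nexus"`.
#' @return a list of `phylo` trees.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
      "nexus"
    } else {
      "newick"
    }
  }
  out <- if (format == "nexus") ape::read.nexus(path) else {
    ape::read.tree(path)
  }
  as_tree_list(out)
}

#' Write trees to newick or NEXUS
#'
#' @param trees a `phylo`, `multiPhylo` or list of `phylo`.
#' @param path output file.
#' @param format `"newick"` (default, one per line) or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- as_tree_list(trees)
  class(trees) <- "multiPhylo"
  if (format == "newick") {
    ape::write.tree(trees, file = path)
  } else {
    ape::write.nexus(trees, file = path)
  }
  invisible(path)
}

#' Write a distance matrix
#'
#' @param D symmetric matrix with taxon dimnames.
#' @param path output file.
#' @param format `"phylip"` (square, taxon count header) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  check_distance_matrix(D)
  if (format == "phylip") {
    lines <- c(as.character(nrow(D)),
               vapply(seq_len(nrow(D)), function(i) {
                 paste(c(formatC(rownames(D)[i], width = -12),
                         formatC(D[i, ], format = "f", digits = 6)),
                       collapse = " ")
               }, ""))
    writeLines(lines, path)
  } else {
    utils::write.table(data.frame(taxon = rownames(D), D,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a taxon annotation table
#'
#' Two-column TSV (`taxon`, `group`) as used by [annotation_rogues()].
#'
#' @param path file path.
#' @return `read_annotation()`: tibble with columns `taxon`, `group`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("taxon", "group") %in% names(df))) {
    abort("annotation file needs columns taxon and group")
  }
  as_tibble(df)
}

#' @rdname read_annotation
#' @param annotation data frame with columns `taxon`, `group`.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
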