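#' Build a degen1 codon-degeneration table
#'
#' Constructs the degen1 mapping: every sense codon is replaced by the fully
#' synonymous-degenerate IUPAC representation of its amino-acid family, so
#' that all codons encoding one amino acid share a single image and
#' synonymous differences vanish while nonsynonymous differences are kept.
#' Two deliberate cross-family merges are part of the scheme: the Leu family
#' (TTR + CTN) degenerates to `YTN`, whose resolutions also cover Phe, and
#' the Arg family (AGR + CGN) degenerates to `MGN`, covering Ser2; Phe and
#' Ser2 themselves remain `TTY` and `AGY`. Serine's two codon blocks (TCN
#' and AGY) are never merged because their union would also match stop and
#' foreign-family codons.
#'
#' The construction is generic over a translation table: within each amino
#' acid, codons sharing their first two positions collapse to a
#' third-position IUPAC union; multi-block families are merged into one
#' image only when that image matches no stop codon and matches every block
#' it touches in full.
#'
#' Ambiguous input codons map to the common degen1 image of all their sense
#' resolutions when it is unique; when the resolutions span one of the
#' merged families (e.g. the codon `YTN` itself resolves to both Leu and
#' Phe codons), the position-wise union of those images is used if it is
#' itself a family image, so the table is idempotent over the full IUPAC
#' ambiguity alphabet; anything else maps to `NNN`.
#'
#' @param genetic_code_id translation table identifier understood by
#'   [Biostrings::getGeneticCode()] (default `"1"`, the standard code).
#' @param stop_policy what to do with codons all of whose resolutions are
#'   stops: `"to_missing"` (default) recodes them as `NNN` with a warning,
#'   `"passthrough"` leaves them unchanged, `"error"` aborts.
#' @return an object of class `degen_table`.
#' @export
#' @examples
#' tbl <- build_degen_table()
#' degen_codon(tbl, "CAT") # "CAY"
#' degen_codon(tbl, "TTA") # "YTN"
build_degen_table <- function(genetic_code_id = "1",
                              stop_policy = c("to_missing", "passthrough",
                                              "error")) {
  stop_policy <- match.arg(stop_policy)
  code <- tryCatch(Biostrings::getGeneticCode(as.character(genetic_code_id)),
                   error = function(e) abort(paste0(
                     "unknown genetic code id: ", genetic_code_id)))
  codons <- names(code)
  sense <- codons[code != "*"]
  stops <- codons[code == "*"]
  aa <- code[sense]

  # blocks: codons of one amino acid sharing their first two positions
  block_key <- paste0(aa, ":", substr(sense, 1, 2))
  blocks <- split(sense, block_key)
  block_image <- vapply(blocks, function(cs) {
    paste0(substr(cs[1], 1, 2), iupac_union(substr(cs, 3, 3)))
  }, "")

  matches_pattern <- function(codon, pattern) {
    all(vapply(1:3, function(i) {
      substr(codon, i, i) %in% IUPAC_MAP[[substr(pattern, i, i)]]
    }, TRUE))
  }

  image <- setNames(character(length(sense)), sense)
  for (a in unique(aa)) {
    keys <- names(blocks)[startsWith(names(blocks), paste0(a, ":"))]
    if (length(keys) == 1) {
      image[blocks[[keys]]] <- block_image[[keys]]
      next
    }
    # multi-block family: try the merged image
    u <- vapply(1:3, function(i) {
      iupac_union(substr(block_image[keys], i, i))
    }, "")
    u <- paste(u, collapse = "")
    stop_hit <- any(vapply(stops, matches_pattern, TRUE, pattern = u))
    # every block touched by u must be covered in full
    covered <- vapply(names(blocks), function(k) {
      hits <- vapply(blocks[[k]], matches_pattern, TRUE, pattern = u)
      all(hits) || !any(hits)
    }, TRUE)
    if (!stop_hit && all(covered)) {
      image[unlist(blocks[keys], use.names = FALSE)] <- u
    } else {
      for (k in keys) image[blocks[[k]]] <- block_image[[k]]
    }
  }

  structure(
    list(genetic_code_id = as.character(genetic_code_id),
         stop_policy = stop_policy, code = code,
         sense_image = image, images = unique(unname(image)),
         cache = new.env(parent = emptyenv())),
    class = "degen_table"
  )
}

#' @export
print.degen_table <- function(x, ...) {
  cat("<degen_table> genetic code", x$genetic_code_id, "| stop policy",
      x$stop_policy, "\n", length(x$sense_image), "sense codons ->",
      length(x$images), "degenerate images\n")
  invisible(x)
}

# sense (non-stop) resolutions of an unambiguous-IUPAC codon
sense_resolutions <- function(codon, code) {
  parts <- lapply(1:3, function(i) IUPAC_MAP[[substr(codon, i, i)]])
  if (any(vapply(parts, is.null, TRUE))) return(NULL)
  res <- as.vector(outer(outer(parts[[1]], parts[[2]], paste0),
                         parts[[3]], paste0))
  res[code[res] != "*"]
}

#' Is a codon an (unambiguous) stop?
#'
#' TRUE when the codon has at least one resolution and every resolution
#' translates to a stop. Codons containing `-` or `?` are never stops.
#'
#' @param codon 3-character codon string.
#' @param genetic_code_id translation table identifier.
#' @return logical scalar.
#' @export
is_stop_codon <- function(codon, genetic_code_id = "1") {
  code <- Biostrings::getGeneticCode(as.character(genetic_code_id))
  codon <- toupper(codon)
  if (grepl("[?-]", codon)) return(FALSE)
  parts <- lapply(1:3, function(i) IUPAC_MAP[[substr(codon, i, i)]])
  if (any(vapply(parts, is.null, TRUE))) return(FALSE)
  res <- as.vector(outer(outer(parts[[1]], parts[[2]], paste0),
                         parts[[3]], paste0))
  all(code[res] == "*")
}

#' Apply a degen1 table to one codon
#'
#' @param table a [build_degen_table()] result.
#' @param codon 3-character codon string (IUPAC codes, `-`, `?`).
#' @return the degen1 image codon. Codons containing `-` or `?` pass
#'   through unchanged; all-stop codons follow the table's stop policy.
#' @export
degen_codon <- function(table, codon) {
  stopifnot(inherits(table, "degen_table"), nchar(codon) == 3)
  codon <- toupper(codon)
  cached <- table$cache[[codon]]
  if (!is.null(cached)) return(cached)
  out <- degen_codon_impl(table, codon)
  assign(codon, out, envir = table$cache)
  out
}

degen_codon_impl <- function(table, codon) {
  if (grepl("[?-]", codon)) return(codon)
  res <- sense_resolutions(codon, table$code)
  if (is.null(res)) abort(paste0("not an IUPAC codon: ", codon))
  if (!length(res)) {
    # all resolutions are stops
    return(switch(table$stop_policy,
      to_missing = {
        warn(paste0("stop codon ", codon, " recoded to NNN"),
             class = "degenphy_stop_codon")
        "NNN"
      },
      passthrough = codon,
      error = abort(paste0("stop codon encountered: ", codon))
    ))
  }
  imgs <- unique(unname(table$sense_image[res]))
  if (length(imgs) == 1) return(imgs)
  u <- paste(vapply(1:3, function(i) iupac_union(substr(imgs, i, i)), ""),
             collapse = "")
  if (u %in% table$images) u else "NNN"
}

#' Degenerate an in-frame alignment (degen1)
#'
#' Applies [degen_codon()] codon-wise to every taxon. The output has the
#' same dimensions and taxon order and is idempotent under re-application.
#' Codons overlapping flagged (excluded) columns must be either wholly
#' included or wholly excluded; wholly excluded codons pass through
#' unchanged. Stop-codon warnings are aggregated into a single message.
#'
#' @param aln a [codon_alignment()], frame-validated.
#' @param table a [build_degen_table()] result (built with defaults when
#'   omitted).
#' @return a recoded `codon_alignment`.
#' @export
#' @examples
#' aln <- codon_alignment(c(t1 = "CATTTA"))
#' as_tibble(degen1_alignment(aln))$sequence # "CAYYTN"
degen1_alignment <- function(aln, table = build_degen_table()) {
  stopifnot(inherits(aln, "codon_alignment"))
  if ((aln$length - aln$frame_offset) %% 3L != 0L) {
    abort("alignment length minus frame offset is not divisible by 3")
  }
  st <- codon_starts(aln)
  if (length(aln$excluded_columns)) {
    excl <- vapply(st, function(s) sum((s:(s + 2L)) %in%
                                         aln$excluded_columns), 0L)
    if (any(excl %in% 1:2)) {
      bad <- st[excl %in% 1:2]
      abort(paste0("codons straddle the excluded-column mask at columns: ",
                   paste(bad, collapse = ", ")))
    }
    keep_codon <- excl == 0L
  } else {
    keep_codon <- rep(TRUE, length(st))
  }
  cm <- codon_matrix(aln)
  n_stop <- 0L
  recoded <- withCallingHandlers({
    uc <- unique(as.vector(cm[, keep_codon, drop = FALSE]))
    setNames(vapply(uc, function(cd) degen_codon(table, cd), ""), uc)
  }, degenphy_stop_codon = function(w) {
    n_stop <<- n_stop + 1L
    invokeRestart("muffleWarning")
  })
  if (n_stop > 0) {
    warn(paste0(n_stop, " distinct stop codon(s) recoded to NNN"))
  }
  out <- cm
  out[, keep_codon] <- recoded[cm[, keep_codon, drop = FALSE]]
  m <- aln_matrix(aln)
  for (j in seq_along(st)) {
    s <- st[j]
    m[, s] <- substr(out[, j], 1, 1)
    m[, s + 1L] <- substr(out[, j], 2, 2)
    m[, s + 2L] <- substr(out[, j], 3, 3)
  }
  matrix_to_alignment(m, aln$frame_offset, aln$excluded_columns,
                      aln$charsets)
}

#' Partition columns into nonsynonymous-only and mostly-synonymous sets
#'
#' Splits all in-frame, non-excluded columns into the two complementary
#' character sets used to separate nonsynonymous-only from mostly
#' synonymous change: `LRall1nt3` holds every third codon position plus the
#' first positions of Leu/Arg codons (where first-position change can be
#' synonymous), and `noLRall1nt2` holds all second positions plus the
#' remaining first positions.
#'
#' @param aln a [codon_alignment()].
#' @param rule `"any_taxon"` (default): a first-position column joins
#'   `LRall1nt3` if any taxon's codon there is Leu or Arg (ambiguous codons
#'   count only when all their sense resolutions are Leu/Arg);
#'   `"all_taxa"`: every taxon with a resolvable codon must be Leu/Arg.
#' @param genetic_code_id translation table identifier.
#' @return an object of class `charset_partition`: a list with sorted
#'   1-based column index vectors `noLRall1nt2` and `LRall1nt3`.
#' @export
#' @examples
#' aln <- codon_alignment(c(a = "CTTGAA", b = "CTTGAA"))
#' classify_columns(aln) # LRall1nt3 = {1, 3, 6}
classify_columns <- function(aln, rule = c("any_taxon", "all_taxa"),
                             genetic_code_id = "1") {
  rule <- match.arg(rule)
  stopifnot(inherits(aln, "codon_alignment"))
  if ((aln$length - aln$frame_offset) %% 3L != 0L) {
    abort("unresolvable frame: length minus offset not divisible by 3")
  }
  code <- Biostrings::getGeneticCode(as.character(genetic_code_id))
  cm <- codon_matrix(aln)
  st <- codon_starts(aln)

  is_lr <- function(codon) {
    if (grepl("[?-]", codon)) return(NA)
    res <- sense_resolutions(codon, code)
    if (!length(res)) return(NA)
    all(code[res] %in% c("L", "R"))
  }
  uc <- unique(as.vector(cm))
  lr_of <- setNames(vapply(uc, is_lr, NA), uc)
  lr_codon <- vapply(seq_along(st), function(j) {
    v <- lr_of[cm[, j]]
    v <- v[!is.na(v)]
    if (!length(v)) return(FALSE)
    if (rule == "any_taxon") any(v) else all(v)
  }, TRUE)

  nt1 <- st
  nt2 <- st + 1L
  nt3 <- st + 2L
  lr3 <- sort(c(nt1[lr_codon], nt3))
  no2 <- sort(c(nt1[!lr_codon], nt2))
  if (length(aln$excluded_columns)) {
    lr3 <- setdiff(lr3, aln$excluded_columns)
    no2 <- setdiff(no2, aln$excluded_columns)
  }
  structure(list(noLRall1nt2 = no2, LRall1nt3 = lr3),
            class = "charset_partition")
}

#' @export
print.charset_partition <- function(x, ...) {
  cat("<charset_partition>\n noLRall1nt2:", length(x$noLRall1nt2),
      "columns\n LRall1nt3:  ", length(x$LRall1nt3), "columns\n")
  invisible(x)
}

#' @export
as_tibble.charset_partition <- function(x, ...) {
  tibble(
    column = c(x$noLRall1nt2, x$LRall1nt3),
    charset = rep(c("noLRall1nt2", "LRall1nt3"),
                  c(length(x$noLRall1nt2), length(x$LRall1nt3)))
  ) |> arrange(.data$column)
}
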