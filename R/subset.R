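#' Restrict objects to a taxon subset
#'
#' Consistently restricts alignments, trees, tree lists and annotation
#' tables to a kept (or complement of a dropped) taxon set. Pruned trees
#' suppress degree-2 nodes, merging branch lengths, so tip-to-tip path
#' lengths are preserved.
#'
#' @param x a [codon_alignment()], `phylo`, `multiPhylo`/list of `phylo`,
#'   or data frame with a `taxon` column.
#' @param keep,drop character vectors of taxon labels (give exactly one).
#' @param unknown what to do with names that do not resolve: `"warn"`
#'   (default) or `"error"`.
#' @return the restricted object, same class as the input.
#' @export
subset_taxa <- function(x, keep = NULL, drop = NULL,
                        unknown = c("warn", "error")) {
  UseMethod("subset_taxa")
}

resolve_keep <- function(taxa, keep, drop, unknown) {
  unknown <- match.arg(unknown, c("warn", "error"))
  if (is.null(keep) == is.null(drop)) {
    abort("give exactly one of keep or drop")
  }
  named <- keep %||% drop
  bad <- setdiff(named, taxa)
  if (length(bad)) {
    msg <- paste0("unknown taxa: ", paste(bad, collapse = ", "))
    if (unknown == "error") abort(msg) else warn(msg)
  }
  if (!is.null(keep)) intersect(taxa, keep) else setdiff(taxa, drop)
}

#' @export
subset_taxa.codon_alignment <- function(x, keep = NULL, drop = NULL,
                                        unknown = c("warn", "error")) {
  kept <- resolve_keep(x$taxa, keep, drop, unknown)
  if (length(kept) < 1) abort("no taxa left")
  codon_alignment(x$sequences[match(kept, x$taxa)] |> setNames(kept),
                  x$frame_offset, x$excluded_columns, x$charsets)
}

#' @export
subset_taxa.phylo <- function(x, keep = NULL, drop = NULL,
                              unknown = c("warn", "error")) {
  kept <- resolve_keep(x$tip.label, keep, drop, unknown)
  if (length(kept) < 2) abort("fewer than 2 taxa left")
  ape::keep.tip(x, kept)
}

#' @export
subset_taxa.multiPhylo <- function(x, keep = NULL, drop = NULL,
                                   unknown = c("warn", "error")) {
  out <- lapply(unclass(x), subset_taxa, keep = keep, drop = drop,
                unknown = unknown)
  class(out) <- "multiPhylo"
  out
}

#' @export
subset_taxa.list <- function(x, keep = NULL, drop = NULL,
                             unknown = c("warn", "error")) {
  lapply(x, subset_taxa, keep = keep, drop = drop, unknown = unknown)
}

#' @export
subset_taxa.data.frame <- function(x, keep = NULL, drop = NULL,
                                   unknown = c("warn", "error")) {
  if (!"taxon" %in% names(x)) abort("data frame needs a taxon column")
  kept <- resolve_keep(unique(x$taxon), keep, drop, unknown)
  x[x$taxon %in% kept, , drop = FALSE]
}
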