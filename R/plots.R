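#' Plot a composition distance tree
#'
#' Draws the (optionally bootstrap-annotated) composition distance tree
#' with a scale bar in "per cent / 100" units. Branch lengths reflect
#' compositional divergence only, never phylogenetic signal.
#'
#' @param tree a `phylo` (e.g. from [composition_tree()]) or a
#'   [composition_bootstrap()] object.
#' @param show_support display node labels (bootstrap percent) when present.
#' @param ... passed to [ape::plot.phylo()].
#' @return the tree, invisibly.
#' @export
plot_composition_tree <- function(tree, show_support = TRUE, ...) {
  if (inherits(tree, "composition_bootstrap")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  shown <- phangorn::midpoint(tree)
  ape::plot.phylo(shown, cex = 0.7, no.margin = TRUE, ...)
  if (show_support && !is.null(shown$node.label)) {
    ape::nodelabels(shown$node.label, frame = "none", adj = c(1.2, -0.3),
                    cex = 0.6)
  }
  ape::add.scale.bar()
  invisible(tree)
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Per-taxon composition scatter
#'
#' GC content against the A/T skew for every taxon, a quick visual check
#' for compositional outliers.
#'
#' @param object a [composition_table()] tibble (or codon_alignment).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.codon_alignment <- function(object, ...) {
  ct <- composition_table(object)
  ggplot(ct, aes(x = .data$gc, y = .data$A - .data$T,
                 label = .data$taxon)) +
    geom_point() +
    ggplot2::geom_text(aes(label = .data$taxon), size = 2.5, vjust = -0.6) +
    labs(x = "GC proportion", y = "A - T skew",
         title = "Per-taxon nucleotide composition") +
    theme_minimal()
}

#' @export
autoplot.composition_bootstrap <- function(object, ...) {
  ggplot(object$support,
         aes(x = stats::reorder(.data$split, .data$support),
             y = .data$support)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "bootstrap support (%)",
         title = "Composition-tree split support") +
    theme_minimal()
}

#' Support-versus-search-effort curves
#'
#' One line per edge of the reference tree: bootstrap support as a function
#' of the number of search replicates per pseudoreplicate (best-of-k).
#' Rising curves identify edges whose support shallow searches
#' underestimate.
#'
#' @param table tibble from [best_of_k_supports()].
#' @return a ggplot object.
#' @export
plot_support_convergence <- function(table) {
  ggplot(table, aes(x = .data$k, y = .data$support, group = .data$split)) +
    geom_line(alpha = 0.5) +
    geom_point(size = 0.8) +
    labs(x = "search replicates per pseudoreplicate (k)",
         y = "bootstrap support (%)",
         title = "Best-of-k bootstrap convergence") +
    theme_minimal()
}
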