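#' @importFrom generics tidy glance
#' @export
tibble::as_tibble

#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.degen_table <- function(x, ...) {
  tibble(codon = names(x$sense_image),
         amino_acid = unname(x$code[names(x$sense_image)]),
         image = unname(x$sense_image)) |>
    arrange(.data$amino_acid, .data$codon)
}

#' @export
tidy.composition_bootstrap <- function(x, ...) {
  x$split_freq
}

#' @export
glance.composition_bootstrap <- function(x, ...) {
  tibble(
    n_pseudoreplicates = x$n_pseudoreplicates,
    n_tree_splits = nrow(x$support),
    mean_support = mean(x$support$support),
    tree_length = tree_length(x$tree)
  )
}

#' @export
tidy.charset_partition <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.search_run <- function(x, rel_threshold = 1e-6, ...) {
  tibble(
    n_replicates = nrow(x),
    lnL_best = max(x$lnL),
    lnL_worst = min(x$lnL),
    n_within_threshold = nrow(within_threshold_set(x, rel_threshold)),
    recovery_fraction = recovery_fraction(x, rel_threshold),
    replicates_needed_95 = replicates_needed(
      max(recovery_fraction(x, rel_threshold), 1e-12), 0.95)
  )
}
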