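#' Simulate a Yule tree
#'
#' Pure-birth tree with `n_taxa` tips and exponentially distributed branch
#' lengths, deterministic per seed.
#'
#' @param n_taxa number of tips (>= 4).
#' @param birth_rate speciation rate (default 1).
#' @param seed integer seed.
#' @return a `phylo` tree with tips `t1..tn`.
#' @export
sim_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 4) abort("n_taxa must be >= 4")
  if (birth_rate <= 0) abort("birth_rate must be positive")
  with_seed_(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
}

# per-codon sampling weights for a lineage: gamma^(G/C count at positions
# that are degenerate in the codon's degen1 image)
codon_profile_weights <- function(table, gc3_weight) {
  sense <- names(table$sense_image)
  vapply(sense, function(cd) {
    img <- table$sense_image[[cd]]
    w <- 1
    for (i in 1:3) {
      if (!substr(img, i, i) %in% c("A", "C", "G", "T") &&
          substr(cd, i, i) %in% c("G", "C")) {
        w <- w * gc3_weight
      }
    }
    w
  }, 0)
}

#' Simulate an in-frame codon alignment with separable signals
#'
#' Two-layer simulator designed so that synonymous and nonsynonymous signal
#' are separable by construction. The amino-acid layer is a continuous-time
#' process with uniform exchangeabilities at rate `nonsyn_rate`
#' substitutions per site per unit branch length; the degen1 image of every
#' site therefore depends on this layer alone. Conditional on the amino
#' acid, the codon is resampled as a Poisson process at rate `syn_rate`
#' from the lineage's codon-usage profile. Lineages listed in
#' `biased_taxa` (bias acts on each such tip's stem branch and, for whole
#' clades, all descendant branches) draw codons with weight
#' `gc3_weight^(G/C count at degenerate positions)`, producing the elevated
#' GC3 that drives compositional attraction between unrelated biased taxa.
#' The output is gapless and stop-free.
#'
#' @param tree a rooted `phylo` with branch lengths (e.g. [sim_tree()]).
#' @param n_codons number of codon sites.
#' @param nonsyn_rate amino-acid substitution rate per unit branch length.
#' @param syn_rate synonymous resampling rate per unit branch length.
#' @param biased_taxa tip labels whose lineages use the GC-weighted profile;
#'   an edge is biased when every tip below it is in this set.
#' @param gc3_weight gamma >= 1; 1 disables the bias.
#' @param genetic_code_id translation table identifier.
#' @param seed integer seed.
#' @return a [codon_alignment()] of `3 * n_codons` columns.
#' @export
sim_codon_alignment <- function(tree, n_codons, nonsyn_rate = 0.05,
                                syn_rate = 10, biased_taxa = character(),
                                gc3_weight = 1, genetic_code_id = "1",
                                seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (n_codons < 1) abort("n_codons must be >= 1")
  if (nonsyn_rate < 0 || syn_rate < 0) abort("rates must be >= 0")
  if (gc3_weight < 1) abort("gc3_weight must be >= 1")
  bad <- setdiff(biased_taxa, tree$tip.label)
  if (length(bad)) {
    abort(paste0("biased_taxa not in tree: ", paste(bad, collapse = ", ")))
  }
  table <- build_degen_table(genetic_code_id)
  code <- table$code
  sense <- names(table$sense_image)
  aas <- sort(unique(unname(code[sense])))
  codons_of <- split(sense, code[sense])
  w_plain <- codon_profile_weights(table, 1)
  w_bias <- codon_profile_weights(table, gc3_weight)

  draw_codons <- function(aa_vec, biased) {
    w <- if (biased) w_bias else w_plain
    out <- character(length(aa_vec))
    for (a in unique(aa_vec)) {
      ix <- which(aa_vec == a)
      cands <- codons_of[[a]]
      out[ix] <- cands[sample.int(length(cands), length(ix), replace = TRUE,
                                  prob = w[cands])]
    }
    out
  }

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # an edge is biased when all tips below it belong to biased_taxa
  pp <- ape::prop.part(tree)
  edge_biased <- vapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) tree$tip.label[child]
            else tree$tip.label[pp[[child - ntip]]]
    length(biased_taxa) > 0 && all(tips %in% biased_taxa)
  }, TRUE)

  with_seed_(seed, {
    state_aa <- vector("list", ntip + tree$Nnode)
    state_cd <- vector("list", ntip + tree$Nnode)
    state_aa[[root]] <- sample(aas, n_codons, replace = TRUE)
    state_cd[[root]] <- draw_codons(state_aa[[root]], biased = FALSE)
    # preorder over edges (ape cladewise order is parent-before-child)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      bl <- tree$edge.length[e]
      aa <- state_aa[[par]]
      cd <- state_cd[[par]]
      n_aa <- rpois(n_codons, nonsyn_rate * bl)
      n_syn <- rpois(n_codons, syn_rate * bl)
      changed <- which(n_aa > 0)
      for (s in changed) {
        for (jump in seq_len(n_aa[s])) {
          aa[s] <- sample(setdiff(aas, aa[s]), 1)
        }
      }
      redraw <- unique(c(changed, which(n_syn > 0)))
      if (length(redraw)) {
        cd[redraw] <- draw_codons(aa[redraw], biased = edge_biased[e])
      }
      state_aa[[child]] <- aa
      state_cd[[child]] <- cd
    }
    seqs <- vapply(seq_len(ntip), function(i) {
      paste(state_cd[[i]], collapse = "")
    }, "")
    codon_alignment(setNames(seqs, tree$tip.label))
  })
}

#' Simulate replicate-search outcomes
#'
#' Bernoulli outcome log used to validate search-effort arithmetic
#' empirically.
#'
#' @param p_success per-replicate success probability in \[0, 1\].
#' @param n number of replicates.
#' @param seed integer seed.
#' @return tibble with columns `id`, `success`.
#' @export
sim_search_replicates <- function(p_success, n, seed = NULL) {
  if (p_success < 0 || p_success > 1) abort("p_success must be in [0, 1]")
  with_seed_(seed, tibble(id = seq_len(n),
                          success = rbinom(n, 1, p_success) == 1))
}

#' Simulate a bootstrap run with imperfect per-pseudoreplicate search
#'
#' Generative model behind best-of-k convergence: each pseudoreplicate has a
#' latent best topology that equals `reference` with probability `pi_true`
#' and otherwise is a random NNI neighbor of it. Each of the `k` search
#' replicates finds the latent best with probability `q_find`; a failed
#' search returns a random NNI neighbor of the latent best with a strictly
#' lower score. As `k` grows, best-of-k support for the reference edges
#' converges to their latent frequency.
#'
#' @param reference a `phylo` tree (>= 4 tips).
#' @param n_pseudoreplicates number of pseudoreplicates.
#' @param k search replicates per pseudoreplicate.
#' @param pi_true probability the latent best equals `reference`.
#' @param q_find per-replicate probability of finding the latent best.
#' @param seed integer seed.
#' @return a [bootstrap_run()].
#' @export
sim_bootstrap_run <- function(reference, n_pseudoreplicates, k, pi_true,
                              q_find, seed = NULL) {
  stopifnot(inherits(reference, "phylo"))
  if (length(reference$tip.label) < 4) abort("reference needs >= 4 tips")
  for (p in c(pi_true, q_find)) {
    if (p < 0 || p > 1) abort("pi_true and q_find must be in [0, 1]")
  }
  if (k < 1) abort("k must be >= 1")
  ref_u <- ape::unroot(reference)
  neighbor_cache <- new.env(parent = emptyenv())
  neighbors_of <- function(tr, key) {
    got <- neighbor_cache[[key]]
    if (is.null(got)) {
      got <- as_tree_list(phangorn::nni(tr))
      assign(key, got, envir = neighbor_cache)
    }
    got
  }
  ref_nb <- neighbors_of(ref_u, "ref")
  with_seed_(seed, {
    rows <- vector("list", n_pseudoreplicates)
    for (b in seq_len(n_pseudoreplicates)) {
      if (runif(1) < pi_true) {
        latent <- ref_u; lkey <- "ref"
      } else {
        i <- sample.int(length(ref_nb), 1)
        latent <- ref_nb[[i]]; lkey <- paste0("nb", i)
      }
      base_score <- -1000
      found <- runif(k) < q_find
      trees <- vector("list", k)
      scores <- numeric(k)
      deg_nb <- NULL
      for (r in seq_len(k)) {
        if (found[r]) {
          trees[[r]] <- latent
          scores[r] <- base_score
        } else {
          if (is.null(deg_nb)) deg_nb <- neighbors_of(latent, lkey)
          trees[[r]] <- deg_nb[[sample.int(length(deg_nb), 1)]]
          scores[r] <- base_score - 0.5 - rexp(1)
        }
      }
      rows[[b]] <- tibble(pseudoreplicate = b, replicate = seq_len(k),
                          score = scores, tree = trees)
    }
    bootstrap_run(bind_rows(rows))
  })
}
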