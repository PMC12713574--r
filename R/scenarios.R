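#' Individual-level heritability implied by a line-level target
#'
#' Inverse of [h2_geno_from_indiv()]: the `H2indiv` that yields a given
#' `H2geno` with `r` replicate blocks, `H2indiv = H2geno / (r - (r-1) H2geno)`.
#'
#' @param h2_geno target line-level heritability in \[0, 1\].
#' @param r replicate blocks.
#' @return the matching `H2indiv`.
#' @export
h2_indiv_from_geno <- function(h2_geno, r) {
  stopifnot(all(h2_geno >= 0 & h2_geno <= 1), r >= 1)
  h2_geno / (r - (r - 1) * h2_geno)
}

#' Reference benchmark scenarios
#'
#' Frozen study conditions used by the package's synthetic benchmarks (and
#' by `scripts/acceptance.R`). Each preset returns a [sim_config()]:
#'
#' * `"structured_trait"` — the enriched-vs-spaced prediction contrast: a
#'   313-genotype two-deme population (Fst 0.1) and a line-level
#'   heritability of 0.6 (r = 3) from an adaptively structured
#'   architecture: 8 strongly deme-differentiated QTNs (Fst 0.35, effect
#'   signs aligned with the frequency divergence, as for the TPS5-like
#'   variant at 77% vs 1.6%) carrying 70% of the genetic variance, a
#'   neutral polygenic background (15%) and a residual deme-mean shift
#'   (15%), emulating traits whose variation is correlated with geoclimate
#'   (roughly 40% of the genetic variance lies between demes).
#' * `"planted_qtn"` — a single QTN explaining 20% of the variance of the
#'   genotype means, 300 genotypes x 5,000 SNPs, otherwise null.
#' * `"null_trait"` — same panel, no genetic signal at all.
#' * `"confounded_marker"` — a deme-linked polygenic trait plus one
#'   zero-effect marker at per-deme frequencies 0.77 / 0.016, for
#'   structure-confounding controls.
#' * `"importance_qtn"` — 500 markers with one QTN explaining 30% of the
#'   genotype-mean variance, for variable-importance recovery.
#'
#' @param name scenario name.
#' @return a [sim_config()].
#' @export
benchmark_scenario <- function(name = c("structured_trait", "planted_qtn",
                                        "null_trait", "confounded_marker",
                                        "importance_qtn")) {
  name <- match.arg(name)
  switch(name,
    structured_trait = sim_config(
      n_individuals = 313, n_snps = 5000, fst = 0.1, ld_block_len = 1,
      n_qtns = 8, qtn_fst = 0.35, qtn_aligned = TRUE,
      qtn_frac = 0.7, polygenic_frac = 0.15, polygenic_aligned = FALSE,
      deme_shift_frac = 0.15, n_polygenes = 1000,
      target_h2_indiv = h2_indiv_from_geno(0.6, 3), r = 3),
    planted_qtn = sim_config(
      n_individuals = 300, n_snps = 5000, fst = 0.1, ld_block_len = 1,
      n_qtns = 1, qtn_frac = 1, polygenic_frac = 0, n_polygenes = 0,
      target_h2_indiv = h2_indiv_from_geno(0.2, 3), r = 3),
    null_trait = sim_config(
      n_individuals = 300, n_snps = 5000, fst = 0.1, ld_block_len = 1,
      n_qtns = 0, qtn_frac = 0, polygenic_frac = 0, n_polygenes = 0,
      target_h2_indiv = 0, r = 3),
    confounded_marker = sim_config(
      n_individuals = 300, n_snps = 5000, fst = 0.1, ld_block_len = 1,
      n_qtns = 0, qtn_frac = 0, polygenic_frac = 0.5,
      polygenic_aligned = TRUE, deme_shift_frac = 0.5, n_polygenes = 1000,
      target_h2_indiv = h2_indiv_from_geno(0.6, 3), r = 3,
      confounded = data.frame(freq_deme1 = 0.77, freq_deme2 = 0.016)),
    importance_qtn = sim_config(
      n_individuals = 300, n_snps = 500, fst = 0.1, ld_block_len = 1,
      n_qtns = 1, qtn_frac = 1, polygenic_frac = 0, n_polygenes = 0,
      target_h2_indiv = h2_indiv_from_geno(0.3, 3), r = 3)
  )
}
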