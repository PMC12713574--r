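# shared fixture builders: everything generated in code, no stored data

# tiny hand-written VCF with optional extras (multiallelic line, missing calls)
write_tiny_vcf <- function(path, lines) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# small structured study used across tests
small_study <- function(seed = 1, n = 120, m = 600, n_qtns = 2,
                        h2 = 0.5, fst = 0.1,
                        qtn_frac = if (n_qtns) 0.7 else 0,
                        polygenic_frac = if (n_qtns) 0.3 else 0,
                        n_polygenes = 100, ...) {
  cfg <- sim_config(n_individuals = n, n_snps = m, fst = fst,
                    n_qtns = n_qtns, qtn_frac = qtn_frac,
                    polygenic_frac = polygenic_frac,
                    n_polygenes = n_polygenes, target_h2_indiv = h2, ...)
  simulate_study(cfg, seed)
}

# plain dosage matrix without structure, columns iid Binom(2, p)
random_dosages <- function(n, m, seed, p_range = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, p_range[1], p_range[2])
  matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
}

as_geno <- function(D, spacing = 1000L, chrom = "chr01") {
  genotype_matrix(D, chrom = rep(chrom, ncol(D)),
                  pos = seq_len(ncol(D)) * spacing,
                  ref = rep("A", ncol(D)), alt = rep("T", ncol(D)),
                  imputed = any(D != round(D)), recode_minor = FALSE)
}

# balanced phenotype table with prescribed genetic values and residual sd
balanced_phenotypes <- function(gvals, r, sd_e, trait = "t", seed = 1) {
  set.seed(seed)
  n <- length(gvals)
  ids <- sprintf("G%03d", seq_len(n))
  do.call(rbind, lapply(seq_len(r), function(b)
    data.frame(genotype_id = ids, block_id = paste0("B", b), trait = trait,
               value = gvals + rnorm(n, 0, sd_e))))
}
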