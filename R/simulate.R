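#' Simulation configuration
#'
#' Study-design parameters of the synthetic-data generator: a two-deme
#' Balding-Nichols structured population genotyped at biallelic SNPs, with a
#' replicated common-garden phenotype controlled by a few large-effect QTNs
#' plus a polygenic background, and optional structure-confounded null
#' markers whose per-deme allele frequencies are fixed by the user.
#'
#' The genetic value is a weighted sum of three standardized components:
#' sparse QTNs (`qtn_frac`), a polygenic background of many tiny effects
#' (`polygenic_frac`), and an optional deme-mean shift (`deme_shift_frac`),
#' with weights summing to 1 within a genetic variance of `target_h2_indiv`
#' (per-observation phenotypic variance is 1). Replicate block residuals
#' then realize the target individual-level heritability, and the line-level
#' heritability follows from the repeatability relations with `r` blocks.
#'
#' @param n_individuals number of genotypes (default 313).
#' @param deme_props proportions of the two demes (default 0.5/0.5).
#' @param fst target Balding-Nichols differentiation for neutral loci.
#' @param n_snps,n_chrom,snp_spacing_bp panel size and map layout
#'   (`n_snps` split over `n_chrom` chromosomes, one SNP every
#'   `snp_spacing_bp` bp).
#' @param ld_block_len markers per correlated block (1 = linkage
#'   equilibrium); within a block consecutive columns are Markov copies with
#'   per-individual switch probability `ld_switch_prob`.
#' @param ld_switch_prob per-individual, per-step resampling probability
#'   inside an LD block (default 0.05).
#' @param n_qtns number of sparse large-effect QTNs.
#' @param qtn_fst differentiation at QTN loci (defaults to `fst`; elevated
#'   values emulate local adaptation).
#' @param qtn_aligned if `TRUE`, QTN effect signs are aligned with the
#'   allele-frequency difference between demes (directional local
#'   adaptation), creating between-deme genetic variance.
#' @param n_polygenes number of tiny-effect background loci (default 1000).
#' @param polygenic_aligned as `qtn_aligned`, for the polygenic term.
#' @param qtn_frac,polygenic_frac,deme_shift_frac fractions of the genetic
#'   variance carried by each component (must sum to 1 unless all are 0).
#' @param target_h2_indiv target broad-sense heritability of single
#'   observations (0 gives a pure-noise trait).
#' @param r replicate blocks per genotype (default 3).
#' @param missing_rate fraction of dosage calls masked as missing in the
#'   emitted genotype matrix (genetic values use the complete data).
#' @param confounded optional data.frame with columns `freq_deme1`,
#'   `freq_deme2`: zero-effect markers drawn at these per-deme frequencies,
#'   placed at the end of the panel.
#' @param trait_name trait label used in the phenotype table.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 313, deme_props = c(0.5, 0.5),
                       fst = 0.1, n_snps = 5000, n_chrom = 5,
                       snp_spacing_bp = 5000, ld_block_len = 1,
                       ld_switch_prob = 0.05,
                       n_qtns = 8, qtn_fst = NULL, qtn_aligned = FALSE,
                       n_polygenes = 1000, polygenic_aligned = FALSE,
                       qtn_frac = 0.7, polygenic_frac = 0.3,
                       deme_shift_frac = 0,
                       target_h2_indiv = 0.4, r = 3,
                       missing_rate = 0, confounded = NULL,
                       trait_name = "sim_trait") {
  stopifnot(n_individuals >= 4, length(deme_props) == 2,
            abs(sum(deme_props) - 1) < 1e-8,
            fst > 0, fst < 1, n_snps >= 1, r >= 1,
            target_h2_indiv >= 0, target_h2_indiv < 1,
            missing_rate >= 0, missing_rate < 1)
  fracs <- c(qtn_frac, polygenic_frac, deme_shift_frac)
  stopifnot(all(fracs >= 0))
  if (target_h2_indiv > 0 && abs(sum(fracs) - 1) > 1e-8)
    stop("qtn_frac + polygenic_frac + deme_shift_frac must sum to 1")
  if (is.null(qtn_fst)) qtn_fst <- fst
  if (!is.null(confounded))
    stopifnot(is.data.frame(confounded),
              all(c("freq_deme1", "freq_deme2") %in% names(confounded)))
  structure(list(
    n_individuals = as.integer(n_individuals), deme_props = deme_props,
    fst = fst, n_snps = as.integer(n_snps), n_chrom = as.integer(n_chrom),
    snp_spacing_bp = as.integer(snp_spacing_bp),
    ld_block_len = as.integer(ld_block_len),
    ld_switch_prob = ld_switch_prob,
    n_qtns = as.integer(n_qtns), qtn_fst = qtn_fst,
    qtn_aligned = isTRUE(qtn_aligned),
    n_polygenes = as.integer(n_polygenes),
    polygenic_aligned = isTRUE(polygenic_aligned),
    qtn_frac = qtn_frac, polygenic_frac = polygenic_frac,
    deme_shift_frac = deme_shift_frac,
    target_h2_indiv = target_h2_indiv, r = as.integer(r),
    missing_rate = missing_rate, confounded = confounded,
    trait_name = trait_name
  ), class = "sim_config")
}

# Balding-Nichols per-deme frequency draw for one locus (or vector of loci)
bn_deme_freq <- function(p, fst) {
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("invalid Beta parameters: fst too close to 0 or 1")
  stats::rbeta(length(p), a, b)
}

#' Simulate a structured genotype panel
#'
#' Two-deme Balding-Nichols model: each LD block draws an ancestral
#' frequency from Uniform(0.05, 0.95) and per-deme frequencies from the
#' Balding-Nichols Beta; dosages are Binomial(2, deme frequency). Within an
#' LD block, successive columns are Markov copies of the previous column
#' (per-individual resampling probability `ld_switch_prob`), so correlation
#' decays geometrically with marker distance. QTN loci are drawn
#' independently at differentiation `qtn_fst`; confounded null markers are
#' drawn at their specified per-deme frequencies and carry no effect.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed; all outputs are fully determined by it.
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (a
#'   `sim_truth` list: deme labels, per-locus realized per-deme frequencies,
#'   QTN/confounded indices, complete dosage matrix before missingness).
#' @export
simulate_genotypes <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n <- cfg$n_individuals
  n1 <- round(cfg$deme_props[1] * n)
  deme <- c(rep(1L, n1), rep(2L, n - n1))
  n_conf <- if (is.null(cfg$confounded)) 0L else nrow(cfg$confounded)
  m_bn <- cfg$n_snps
  m <- m_bn + n_conf

  blk <- ((seq_len(m_bn) - 1L) %/% cfg$ld_block_len) + 1L
  n_blk <- max(blk)
  p_anc_blk <- stats::runif(n_blk, 0.05, 0.95)
  f1_blk <- bn_deme_freq(p_anc_blk, cfg$fst)
  f2_blk <- bn_deme_freq(p_anc_blk, cfg$fst)

  D <- matrix(0L, n, m)
  f_loc <- matrix(0, m, 2)
  for (b in seq_len(n_blk)) {
    cols <- which(blk == b)
    f <- ifelse(deme == 1L, f1_blk[b], f2_blk[b])
    col <- stats::rbinom(n, 2L, f)
    D[, cols[1]] <- col
    for (j in cols[-1]) {
      sw <- stats::runif(n) < cfg$ld_switch_prob
      col[sw] <- stats::rbinom(sum(sw), 2L, f[sw])
      D[, j] <- col
    }
    f_loc[cols, 1] <- f1_blk[b]
    f_loc[cols, 2] <- f2_blk[b]
  }

  # sparse QTN loci: independent draws at qtn_fst differentiation
  qtn_idx <- integer(0)
  if (cfg$n_qtns > 0) {
    qtn_idx <- sort(sample.int(m_bn, cfg$n_qtns))
    p_anc_q <- stats::runif(cfg$n_qtns, 0.1, 0.9)
    f1q <- bn_deme_freq(p_anc_q, cfg$qtn_fst)
    f2q <- bn_deme_freq(p_anc_q, cfg$qtn_fst)
    for (k in seq_along(qtn_idx)) {
      f <- ifelse(deme == 1L, f1q[k], f2q[k])
      D[, qtn_idx[k]] <- stats::rbinom(n, 2L, f)
      f_loc[qtn_idx[k], ] <- c(f1q[k], f2q[k])
    }
  }

  conf_idx <- integer(0)
  if (n_conf > 0) {
    conf_idx <- m_bn + seq_len(n_conf)
    for (k in seq_len(n_conf)) {
      f <- ifelse(deme == 1L, cfg$confounded$freq_deme1[k],
                  cfg$confounded$freq_deme2[k])
      D[, conf_idx[k]] <- stats::rbinom(n, 2L, f)
      f_loc[conf_idx[k], ] <- c(cfg$confounded$freq_deme1[k],
                                cfg$confounded$freq_deme2[k])
    }
  }

  # genome layout: m SNPs split over n_chrom chromosomes in panel order
  per_chr <- ceiling(m / cfg$n_chrom)
  chr_i <- ((seq_len(m) - 1L) %/% per_chr) + 1L
  chrom <- sprintf("chr%02d", chr_i)
  pos <- (((seq_len(m) - 1L) %% per_chr)) * cfg$snp_spacing_bp + 1L

  D_complete <- D
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m)
    D[mask] <- NA_integer_
  }
  # orient every column to count the minor allele (as observed, matching
  # what any loader would compute), keeping truth in the same orientation
  af <- colMeans(D, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    D[, flip] <- 2L - D[, flip, drop = FALSE]
    D_complete[, flip] <- 2L - D_complete[, flip, drop = FALSE]
    f_loc[flip, ] <- 1 - f_loc[flip, ]
  }
  ref <- ifelse(flip, "T", "A")
  alt <- ifelse(flip, "A", "T")
  ids <- sprintf("G%03d", seq_len(n))
  rownames(D) <- ids
  g <- genotype_matrix(D, chrom = chrom, pos = pos,
                       ref = ref, alt = alt,
                       sample_ids = ids, recode_minor = FALSE)

  # realized per-deme counted-allele frequencies on the complete data
  f_real <- cbind(colMeans(D_complete[deme == 1L, , drop = FALSE]) / 2,
                  colMeans(D_complete[deme == 2L, , drop = FALSE]) / 2)
  truth <- structure(list(
    deme = deme, sample_ids = ids,
    freq_deme1 = f_loc[, 1], freq_deme2 = f_loc[, 2],
    freq_deme1_realized = f_real[, 1], freq_deme2_realized = f_real[, 2],
    qtn_idx = qtn_idx, confounded_idx = conf_idx,
    dosages_complete = D_complete,
    cfg = cfg, seed = seed
  ), class = "sim_truth")
  list(genotypes = g, truth = truth)
}

#' Simulate replicated common-garden phenotypes
#'
#' Builds the genetic value from the simulated genotypes and draws `r`
#' replicate-block measurements per genotype. Components (sparse QTNs,
#' polygenic background, deme shift) are standardized and weighted so the
#' realized genetic variance equals `target_h2_indiv` on a unit
#' per-observation phenotypic variance; block residuals are iid normal with
#' variance `1 - target_h2_indiv`. When `qtn_aligned`/`polygenic_aligned`
#' is set, effect signs follow the sign of the between-deme frequency
#' difference of the counted allele (directional local adaptation).
#'
#' @param g the [genotype_matrix()] from [simulate_genotypes()].
#' @param truth the matching `sim_truth`.
#' @param seed integer RNG seed for effects and residuals.
#' @return list with `phenotypes` (long-format data.frame), `truth`
#'   (updated with effects, genetic values and variance components).
#' @export
simulate_phenotypes <- function(g, truth, seed) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$cfg
  set.seed(seed + 1000003L)
  D <- truth$dosages_complete
  n <- nrow(D)
  vg <- cfg$target_h2_indiv
  ve <- 1 - vg

  std <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  gval <- rep(0, n)
  qtn_beta <- numeric(0)
  poly_idx <- integer(0)
  poly_beta <- numeric(0)

  if (vg > 0 && cfg$qtn_frac > 0 && cfg$n_qtns > 0) {
    qtn_beta <- abs(stats::rnorm(cfg$n_qtns))
    sgn <- if (cfg$qtn_aligned) {
      s <- sign(truth$freq_deme1_realized[truth$qtn_idx] -
                truth$freq_deme2_realized[truth$qtn_idx])
      ifelse(s == 0, 1, s)
    } else sample(c(-1, 1), cfg$n_qtns, replace = TRUE)
    qtn_beta <- qtn_beta * sgn
    raw <- drop(D[, truth$qtn_idx, drop = FALSE] %*% qtn_beta)
    sc <- stats::sd(raw)
    if (sc == 0) stop("degenerate QTN component (monomorphic QTNs)")
    qtn_beta <- qtn_beta / sc * sqrt(cfg$qtn_frac * vg)
    gval <- gval + std(raw) * sqrt(cfg$qtn_frac * vg)
  }
  if (vg > 0 && cfg$polygenic_frac > 0 && cfg$n_polygenes > 0) {
    pool <- setdiff(seq_len(cfg$n_snps), truth$qtn_idx)
    poly_idx <- sort(sample(pool, min(cfg$n_polygenes, length(pool))))
    poly_beta <- abs(stats::rnorm(length(poly_idx)))
    sgn <- if (cfg$polygenic_aligned) {
      s <- sign(truth$freq_deme1_realized[poly_idx] -
                truth$freq_deme2_realized[poly_idx])
      ifelse(s == 0, 1, s)
    } else sample(c(-1, 1), length(poly_idx), replace = TRUE)
    poly_beta <- poly_beta * sgn
    raw <- drop(D[, poly_idx, drop = FALSE] %*% poly_beta)
    sc <- stats::sd(raw)
    if (sc == 0) stop("degenerate polygenic component")
    poly_beta <- poly_beta / sc * sqrt(cfg$polygenic_frac * vg)
    gval <- gval + std(raw) * sqrt(cfg$polygenic_frac * vg)
  }
  if (vg > 0 && cfg$deme_shift_frac > 0) {
    gval <- gval + std(truth$deme == 1L) * sqrt(cfg$deme_shift_frac * vg)
  }

  blocks <- sprintf("B%d", seq_len(cfg$r))
  ph <- do.call(rbind, lapply(seq_len(cfg$r), function(b) {
    data.frame(genotype_id = truth$sample_ids, block_id = blocks[b],
               trait = cfg$trait_name,
               value = gval + stats::rnorm(n, 0, sqrt(ve)),
               stringsAsFactors = FALSE)
  }))

  truth$qtn_beta <- qtn_beta
  truth$polygene_idx <- poly_idx
  truth$polygene_beta <- poly_beta
  truth$genetic_values <- gval
  truth$vg <- stats::var(gval)
  truth$ve <- ve
  truth$h2_indiv_target <- cfg$target_h2_indiv
  truth$h2_geno_target <- if (vg > 0)
    h2_geno_from_indiv(cfg$target_h2_indiv, cfg$r) else 0
  list(phenotypes = validate_phenotypes(ph), truth = truth)
}

#' One-call simulation of genotypes and phenotypes
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return list with `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_study <- function(cfg, seed) {
  gsim <- simulate_genotypes(cfg, seed)
  psim <- simulate_phenotypes(gsim$genotypes, gsim$truth, seed)
  list(genotypes = gsim$genotypes, phenotypes = psim$phenotypes,
       truth = psim$truth)
}

#' Genotype means across replicate blocks
#'
#' The phenotype used for genomic prediction: the mean of a genotype's
#' replicate-block values, ordered to match `sample_ids`.
#'
#' @param p long-format phenotype data.frame.
#' @param trait trait name.
#' @param sample_ids ordering of the output vector.
#' @return named numeric vector of genotype means.
#' @export
genotype_means <- function(p, trait, sample_ids) {
  d <- p[p$trait == trait, , drop = FALSE]
  mu <- tapply(d$value, d$genotype_id, mean)
  out <- as.numeric(mu[sample_ids])
  names(out) <- sample_ids
  if (any(is.na(out))) stop("phenotype table lacks some requested samples")
  out
}

#' Hudson Fst estimator from known deme labels
#'
#' Ratio-of-averages Hudson estimator over loci:
#' numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`, with allele frequencies computed per
#' deme from dosages.
#'
#' @param g a [genotype_matrix()] or complete dosage matrix.
#' @param deme integer vector of deme labels (two levels).
#' @return the multi-locus Fst estimate.
#' @export
hudson_fst <- function(g, deme) {
  D <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  lv <- sort(unique(deme))
  stopifnot(length(lv) == 2)
  d1 <- D[deme == lv[1], , drop = FALSE]
  d2 <- D[deme == lv[2], , drop = FALSE]
  n1 <- 2 * colSums(!is.na(d1))
  n2 <- 2 * colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den) & den > 0
  sum(num[ok]) / sum(den[ok])
}

#' Export a simulated study as plain-text fixtures
#'
#' Writes `genotypes.vcf` (biallelic VCF), `phenotypes.tsv` (long format)
#' and `truth.json` (deme labels, QTN indices and effects, variance
#' components). The VCF round-trips losslessly through [load_vcf()].
#'
#' @param g [genotype_matrix()].
#' @param p phenotype data.frame.
#' @param truth `sim_truth`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
export_fixture <- function(g, p, truth, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  vcf <- file.path(out_dir, "genotypes.vcf")
  tsv <- file.path(out_dir, "phenotypes.tsv")
  js <- file.path(out_dir, "truth.json")
  write_vcf(g, vcf)
  write_phenotype_tsv(p, tsv)
  tr <- truth[c("deme", "sample_ids", "qtn_idx", "qtn_beta",
                "polygene_idx", "polygene_beta", "confounded_idx",
                "genetic_values", "vg", "ve",
                "h2_indiv_target", "h2_geno_target", "seed")]
  jsonlite::write_json(tr, js, auto_unbox = FALSE, digits = 12, pretty = TRUE)
  c(vcf = vcf, phenotypes = tsv, truth = js)
}
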