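test_that("realized Fst tracks the Balding-Nichols target", {
  cfg <- sim_config(n_individuals = 300, n_snps = 5000, n_qtns = 0,
                    qtn_frac = 0, polygenic_frac = 0, target_h2_indiv = 0)
  sim <- simulate_genotypes(cfg, seed = 91)
  fst <- hudson_fst(sim$genotypes, sim$truth$deme)
  expect_lt(abs(fst - 0.1), 0.02)
})

test_that("confounded null markers realize their per-deme frequencies", {
  conf <- data.frame(freq_deme1 = 0.77, freq_deme2 = 0.016)
  cfg <- sim_config(n_individuals = 400, n_snps = 200, n_qtns = 0,
                    qtn_frac = 0, polygenic_frac = 0, target_h2_indiv = 0,
                    confounded = conf)
  sim <- simulate_genotypes(cfg, seed = 92)
  idx <- sim$truth$confounded_idx
  expect_length(idx, 1L)
  pooled <- mean(sim$truth$dosages_complete[, idx]) / 2
  # pooled frequency ~ deme-proportion-weighted mean (possibly minor-flipped)
  target <- 0.5 * 0.77 + 0.5 * 0.016
  expect_lt(min(abs(pooled - target), abs((1 - pooled) - target)), 0.06)
  # strong per-deme differentiation is realized
  f1 <- sim$truth$freq_deme1_realized[idx]
  f2 <- sim$truth$freq_deme2_realized[idx]
  expect_gt(abs(f1 - f2), 0.6)
})

test_that("LD blocks create geometrically decaying correlation", {
  cfg <- sim_config(n_individuals = 400, n_snps = 300, ld_block_len = 50,
                    n_qtns = 0, qtn_frac = 0, polygenic_frac = 0,
                    target_h2_indiv = 0)
  sim <- simulate_genotypes(cfg, seed = 93)
  D <- sim$truth$dosages_complete
  r_adj <- mean(vapply(1:20, function(j)
    abs(cor(D[, j], D[, j + 1])), numeric(1)))
  r_far <- abs(cor(D[, 1], D[, 45]))
  expect_gt(r_adj, 0.8)        # adjacent markers tightly linked
  expect_lt(r_far, r_adj)      # correlation decays along the block
  # across block boundaries markers are unlinked
  expect_lt(abs(cor(D[, 50], D[, 51])), 0.25)
})

test_that("realized heritability hits the target over replicates", {
  ests <- vapply(1:25, function(i) {
    cfg <- sim_config(n_individuals = 150, n_snps = 300, n_qtns = 4,
                      qtn_frac = 0.6, polygenic_frac = 0.4, n_polygenes = 100,
                      target_h2_indiv = 0.47)
    sim <- simulate_study(cfg, seed = 900 + i)
    heritability_repeatability(sim$phenotypes, "sim_trait")$h2_indiv
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.47), 0.05)
})

test_that("degenerate phenotype regimes behave as designed", {
  # zero residual variance: replicates identical within genotype
  cfg1 <- sim_config(n_individuals = 40, n_snps = 100, n_qtns = 2,
                     qtn_frac = 1, polygenic_frac = 0, n_polygenes = 0,
                     target_h2_indiv = 0.999999)
  sim1 <- simulate_study(cfg1, seed = 94)
  spread <- tapply(sim1$phenotypes$value, sim1$phenotypes$genotype_id,
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-2)
  # no genetic signal at all: estimated heritability near zero
  ests <- vapply(1:20, function(i) {
    cfg0 <- sim_config(n_individuals = 100, n_snps = 50, n_qtns = 0,
                       qtn_frac = 0, polygenic_frac = 0, target_h2_indiv = 0)
    sim0 <- simulate_study(cfg0, seed = 950 + i)
    suppressWarnings(
      heritability_repeatability(sim0$phenotypes, "sim_trait")$h2_indiv)
  }, numeric(1))
  expect_lt(mean(ests), 0.05)
})

test_that("aligned QTN effects create between-deme genetic variance", {
  cfg <- sim_config(n_individuals = 300, n_snps = 500, n_qtns = 6,
                    qtn_fst = 0.35, qtn_aligned = TRUE,
                    qtn_frac = 0.8, polygenic_frac = 0.2, n_polygenes = 200,
                    target_h2_indiv = 0.5)
  sim <- simulate_study(cfg, seed = 95)
  g <- sim$truth$genetic_values
  deme <- sim$truth$deme
  between <- abs(mean(g[deme == 1]) - mean(g[deme == 2]))
  # neutral (unaligned) control
  cfg0 <- sim_config(n_individuals = 300, n_snps = 500, n_qtns = 6,
                     qtn_frac = 0.8, polygenic_frac = 0.2, n_polygenes = 200,
                     target_h2_indiv = 0.5)
  sim0 <- simulate_study(cfg0, seed = 95)
  g0 <- sim0$truth$genetic_values
  between0 <- abs(mean(g0[sim0$truth$deme == 1]) -
                    mean(g0[sim0$truth$deme == 2]))
  expect_gt(between, between0)
  expect_gt(between, 0.3)
})

test_that("fixtures are deterministic and carry complete truth", {
  cfg <- sim_config(n_individuals = 30, n_snps = 60, n_qtns = 3,
                    qtn_frac = 0.7, polygenic_frac = 0.3, n_polygenes = 20,
                    target_h2_indiv = 0.4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sim_a <- simulate_study(cfg, seed = 96)
  sim_b <- simulate_study(cfg, seed = 96)
  pa <- export_fixture(sim_a$genotypes, sim_a$phenotypes, sim_a$truth, d1)
  pb <- export_fixture(sim_b$genotypes, sim_b$phenotypes, sim_b$truth, d2)
  expect_identical(unname(tools::md5sum(pa)), unname(tools::md5sum(pb)))
  truth <- jsonlite::read_json(pa["truth"], simplifyVector = TRUE)
  expect_length(truth$qtn_beta, 3L)
  expect_length(truth$deme, 30L)
  # VCF round-trip
  g2 <- load_vcf(pa["vcf"])
  expect_equal(unname(g2$dosages), unname(sim_a$genotypes$dosages) + 0)
})
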