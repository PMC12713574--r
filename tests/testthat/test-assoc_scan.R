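test_that("PCA covariates separate simulated demes and are orthogonal", {
  sim <- small_study(seed = 21, n = 150, m = 800, fst = 0.1)
  gi <- impute_mean(sim$genotypes)
  cov <- pca_covariates(gi, 2)
  expect_equal(colnames(cov), c("(Intercept)", "PC1", "PC2"))
  expect_gt(abs(cor(cov[, "PC1"], sim$truth$deme)), 0.9)
  gram <- crossprod(cov[, -1])
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # k = 0: intercept only; k >= n rejected
  expect_equal(ncol(pca_covariates(gi, 0)), 1L)
  expect_error(pca_covariates(gi, 150), "smaller")
})

test_that("near-panmictic populations show no PC-deme separation", {
  sim <- small_study(seed = 22, n = 150, m = 800, fst = 0.001)
  cov <- pca_covariates(impute_mean(sim$genotypes), 2)
  expect_lt(abs(cor(cov[, "PC1"], sim$truth$deme)), 0.3)
})

test_that("single_marker_scan matches an independent lm() oracle", {
  set.seed(23)
  n <- 40
  D <- random_dosages(n, 12, seed = 23)
  g <- as_geno(D)
  cov <- cbind(1, rnorm(n))
  y <- 2 * D[, 5] + 0.5 * cov[, 2] + rnorm(n, sd = 0.5)
  res <- single_marker_scan(g, y, cov)
  # oracle: per-variant lm fit
  for (j in c(1, 5, 9)) {
    fit <- summary(lm(y ~ cov[, 2] + D[, j]))$coefficients
    expect_lt(abs(res$p_value[j] - fit["D[, j]", "Pr(>|t|)"]), 1e-8)
    expect_lt(abs(res$effect[j] - fit["D[, j]", "Estimate"]), 1e-8)
  }
  expect_equal(which.min(res$p_value), 5L)
  expect_lt(abs(res$effect[5] - 2), 0.3)
})

test_that("variants collinear with the fixed set get p = 1", {
  D <- random_dosages(30, 6, seed = 24)
  D[, 3] <- D[, 1]                       # duplicate column
  g <- as_geno(D)
  y <- rnorm(30)
  res <- single_marker_scan(g, y, extra_fixed = 1L)
  expect_equal(res$p_value[3], 1)
  expect_equal(res$effect[3], 0)
  expect_true(is.na(res$p_value[1]))     # fixed variant not tested
  Fbad <- cbind(1, 2, deparse.level = 0)[rep(1, 30), ]
  expect_error(single_marker_scan(g, y, covariates = Fbad), "rank-deficient")
})

test_that("null p-values are uniformly calibrated", {
  # pooled over replicate null scans, fraction of p < 0.05 is near 0.05
  hits <- 0L
  total <- 0L
  for (i in 1:10) {
    D <- random_dosages(120, 1500, seed = 30 + i)
    y <- rnorm(120)
    p <- single_marker_scan(as_geno(D), y)$p_value
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  expect_lt(abs(hits / total - 0.05), 0.01)
})

test_that("multilocus scan finds a planted QTN and reports it as pseudo-QTN", {
  sim <- small_study(seed = 26, n = 200, m = 1000, n_qtns = 1, h2 = 0.25,
                     qtn_frac = 1, polygenic_frac = 0, n_polygenes = 0)
  gi <- impute_mean(sim$genotypes)
  y <- genotype_means(sim$phenotypes, "sim_trait", gi$sample_ids)
  sc <- multilocus_scan(gi, y, pca_covariates(gi, 2))
  qtn <- sim$truth$qtn_idx
  expect_equal(which.min(sc$p_value), qtn)
  expect_true(qtn %in% sc$pseudo_qtns)
  # exhaustive single-marker oracle agrees on the top hit
  sm <- single_marker_scan(gi, y, pca_covariates(gi, 2))
  expect_equal(which.min(sm$p_value), qtn)
})

test_that("pure-noise traits yield no significant pseudo-QTNs", {
  sim <- small_study(seed = 27, n = 150, m = 1000, n_qtns = 0, h2 = 0)
  gi <- impute_mean(sim$genotypes)
  cov <- pca_covariates(gi, 2)
  bonf <- bonferroni_threshold(ncol(gi$dosages))
  for (s in 1:3) {
    set.seed(400 + s)
    sc <- multilocus_scan(gi, rnorm(150), cov)
    sig <- sc$p_value[sc$pseudo_qtns] < bonf
    expect_true(length(sc$pseudo_qtns) == 0 || !any(sig))
  }
})

test_that("perfect-LD duplicates enter the pseudo-QTN set only once", {
  sim <- small_study(seed = 28, n = 200, m = 500, n_qtns = 1, h2 = 0.3,
                     qtn_frac = 1, polygenic_frac = 0, n_polygenes = 0)
  g <- sim$genotypes
  qtn <- sim$truth$qtn_idx
  dup <- if (qtn < 400) qtn + 50L else qtn - 50L
  g$dosages[, dup] <- g$dosages[, qtn]    # identical column elsewhere
  gi <- impute_mean(g)
  y <- genotype_means(sim$phenotypes, "sim_trait", gi$sample_ids)
  sc <- multilocus_scan(gi, y, pca_covariates(gi, 2))
  expect_equal(sum(sc$pseudo_qtns %in% c(qtn, dup)), 1L)
  # reported pseudo-QTNs respect the collinearity cap
  if (length(sc$pseudo_qtns) > 1) {
    r2 <- cor(gi$dosages[, sc$pseudo_qtns])^2
    expect_lte(max(r2[upper.tri(r2)]), 0.7 + 1e-8)
  }
})

test_that("bonferroni threshold and reporting truncation", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(100), 5e-4)
  expect_equal(truncate_signif(bonferroni_threshold(5641729)), 8.8e-9)
  expect_equal(truncate_signif(0.0599, 2), 0.059)  # truncation, not rounding
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("p-value and spaced marker selection rules", {
  p <- rep(0.5, 20)
  expect_length(select_by_pvalue(p, 1e-4)$indices, 0)
  p[c(3, 11, 17)] <- c(1e-5, 9e-5, 2e-6)
  expect_equal(select_by_pvalue(p, 1e-4)$indices, c(3L, 11L, 17L))
  expect_length(select_by_pvalue(p, 1)$indices, 20L)

  expect_equal(select_spaced(10, 5)$indices, c(1L, 3L, 5L, 7L, 9L))
  expect_equal(select_spaced(7, 7)$indices, 1:7)
  expect_equal(select_spaced(10, 1)$indices, 1L)
  expect_error(select_spaced(5, 6), "n_select")
})

test_that("exclusive intersection counts follow UpSet semantics", {
  res <- intersection_counts(list(A = c(1, 2), B = c(2, 3)))
  expect_equal(res$count[res$combination == "A"], 1L)
  expect_equal(res$count[res$combination == "B"], 1L)
  expect_equal(res$count[res$combination == "A & B"], 1L)
  disj <- intersection_counts(list(A = 1:3, B = 5:6))
  expect_true(all(disj$degree == 1))
  # conservation: counts sum to the union size (random sets, brute force)
  set.seed(29)
  sets <- lapply(1:12, function(i) sample(5000, sample(50:300, 1)))
  names(sets) <- paste0("t", 1:12)
  res <- intersection_counts(sets)
  expect_equal(sum(res$count), length(unique(unlist(sets))))
})
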