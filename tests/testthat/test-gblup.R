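test_that("VanRaden kinship matches hand-computed arithmetic", {
  D <- matrix(c(0, 1, 2, 1,
                2, 2, 0, 1,
                0, 1, 1, 0), nrow = 4)
  k <- vanraden_kinship(D)
  p <- colMeans(D) / 2
  Z <- sweep(D, 2, 2 * p)
  K_manual <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  expect_equal(unname(k$K), K_manual, tolerance = 1e-12)
  expect_lt(max(abs(k$K - t(k$K))), 1e-10)          # symmetric
  expect_lt(max(abs(rowSums(k$K))), 1e-8)           # rows sum to zero
  ev <- eigen(k$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)                          # PSD up to tolerance
})

test_that("duplicate samples have identical kinship entries", {
  D <- random_dosages(6, 50, seed = 31)
  D[2, ] <- D[1, ]
  k <- vanraden_kinship(D)
  expect_equal(k$K[1, 1], k$K[2, 2], tolerance = 1e-12)
  expect_equal(k$K[1, 1], k$K[1, 2], tolerance = 1e-12)
  expect_error(vanraden_kinship(matrix(0, 4, 3)), "monomorphic")
})

test_that("REML optimum matches a dense grid over log delta", {
  set.seed(32)
  D <- random_dosages(150, 400, seed = 32)
  K <- vanraden_kinship(D)$K
  L <- t(chol(K + diag(1e-8, 150)))
  y <- drop(L %*% rnorm(150)) * sqrt(0.5) + rnorm(150, sd = sqrt(0.5))
  vc <- reml_fit(y, K)
  # independent 200-point grid oracle over the profiled likelihood
  X <- matrix(1, 150, 1)
  qx <- qr.Q(qr(X))
  SKS <- K - qx %*% crossprod(qx, K)
  SKS <- SKS - (SKS %*% qx) %*% t(qx)
  eg <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values[1:149], 0)
  eta <- crossprod(eg$vectors[, 1:149], y)[, 1]
  grid_ll <- vapply(seq(-10, 10, length.out = 200), function(ld) {
    d <- exp(ld)
    r <- sum(eta^2 / (lam + d))
    0.5 * (149 * log(149 / (2 * pi)) - 149 - 149 * log(r) -
             sum(log(lam + d)))
  }, numeric(1))
  expect_gte(vc$reml_loglik, max(grid_ll) - 1e-6)
})

test_that("REML recovers generating heritability regimes", {
  h2_est <- function(h2, seed) {
    set.seed(seed)
    n <- 150
    D <- random_dosages(n, 400, seed = seed)
    K <- vanraden_kinship(D)$K
    L <- t(chol(K + diag(1e-8, n)))
    g <- drop(L %*% rnorm(n))
    g <- g / sd(g) * sqrt(h2)
    y <- g + rnorm(n, sd = sqrt(1 - h2))
    reml_fit(y, K)$h2
  }
  ests <- vapply(1:10, function(i) h2_est(0.5, 500 + i), numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 0.1)
  # pure noise on a structured kinship: h2 small in most replicates
  null_ests <- vapply(1:10, function(i) {
    sim <- small_study(seed = 600 + i, n = 150, m = 400, n_qtns = 0, h2 = 0)
    K <- vanraden_kinship(impute_mean(sim$genotypes))$K
    set.seed(i)
    reml_fit(rnorm(150), K)$h2
  }, numeric(1))
  expect_gte(sum(null_ests < 0.1), 9)
  # noiseless genetic signal: h2 near 1
  expect_gt(h2_est(0.999, 700), 0.95)
})

test_that("GBLUP equals the rrBLUP ridge-regression identity", {
  for (i in 1:10) {
    set.seed(40 + i)
    n <- sample(20:50, 1)
    m <- sample(30:100, 1)
    D <- random_dosages(n, m, seed = 40 + i)
    kin <- vanraden_kinship(D)
    y <- rnorm(n)
    tr <- sort(sample(n, round(0.7 * n)))
    te <- setdiff(seq_len(n), tr)
    vc <- reml_fit(y[tr], kin$K[tr, tr])
    gbv <- gblup_predict(y[tr], kin, tr, te, vc)$gbv
    # independent marker-effect route
    p <- colMeans(D) / 2
    Z <- sweep(D, 2, 2 * p)
    beta_hat <- gblup_predict(y[tr], kin, tr, te, vc)$beta
    r <- y[tr] - beta_hat
    eff <- t(Z[tr, ]) %*% solve(tcrossprod(Z[tr, ]) +
                                  vc$delta * kin$c * diag(length(tr)), r)
    gbv_rr <- beta_hat + drop(Z[te, , drop = FALSE] %*% eff)
    expect_lt(max(abs(gbv - gbv_rr)), 1e-6)
  }
})

test_that("a test sample identical to a training sample gets its fitted value", {
  D <- random_dosages(30, 80, seed = 51)
  D[30, ] <- D[1, ]
  kin <- vanraden_kinship(D)
  set.seed(52)
  y <- rnorm(30)
  tr <- 1:29
  vc <- reml_fit(y[tr], kin$K[tr, tr])
  pr <- gblup_predict(y[tr], kin, tr, 30L, vc)
  expect_equal(unname(pr$gbv), unname(pr$fitted_train[1]), tolerance = 1e-8)
})

test_that("noiseless additive traits are predicted almost perfectly", {
  set.seed(53)
  n <- 120
  D <- random_dosages(n, 60, seed = 53)
  beta <- rnorm(60, sd = 0.3)
  p <- colMeans(D) / 2
  y <- drop(sweep(D, 2, 2 * p) %*% beta)
  cv <- crossval_gblup(D, y, seed = 54)
  expect_gt(cv$r2_mean, 0.95)
})

test_that("cross-validation is deterministic under a fixed seed", {
  D <- random_dosages(60, 100, seed = 55)
  set.seed(56)
  y <- rnorm(60)
  cv1 <- crossval_gblup(D, y, seed = 99)
  cv2 <- crossval_gblup(D, y, seed = 99)
  expect_identical(cv1$fold_r2, cv2$fold_r2)
  expect_identical(cv1$predictions$fold, cv2$predictions$fold)
  expect_false(identical(crossval_gblup(D, y, seed = 100)$predictions$fold,
                         cv1$predictions$fold))
  # constant trait: degenerate R2 reported as 0 with a flag
  cv0 <- crossval_gblup(D, rep(1, 60), seed = 99)
  expect_true(all(cv0$fold_r2 == 0))
  expect_true(cv0$degenerate)
  # fold sizes differ by at most one
  expect_lte(diff(range(table(cv1$predictions$fold))), 1)
})
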