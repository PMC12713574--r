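test_that("the network fits a noiseless linear target almost exactly", {
  set.seed(61)
  X <- matrix(rnorm(200 * 20), 200, 20)
  w <- rnorm(20)
  y <- drop(X %*% w)
  cfg <- net_config(h1 = 40, h2 = 40, activation = "relu",
                    l1 = 0, l2 = 0, dropout = 0,
                    learning_rate = 0.02, stop_tol = 1e-6, seed = 62)
  net <- train_network(X, y, cfg)
  r2_train <- cor(predict(net, X), y)^2
  expect_gt(r2_train, 0.99)
})

test_that("constant traits converge to a constant output", {
  set.seed(63)
  X <- matrix(rnorm(60 * 10), 60, 10)
  net <- train_network(X, rep(3.7, 60),
                       net_config(seed = 64, dropout = 0, l1 = 0, l2 = 0,
                                  stop_tol = 0, max_epochs = 600))
  expect_lt(mean((predict(net, X) - 3.7)^2), 1e-4)
})

test_that("training is bitwise deterministic under a fixed seed", {
  set.seed(65)
  X <- matrix(rnorm(80 * 15), 80, 15)
  y <- rnorm(80)
  cfg <- net_config(seed = 66, max_epochs = 20)
  n1 <- train_network(X, y, cfg)
  n2 <- train_network(X, y, cfg)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$layer1$W, n2$layer1$W)
})

test_that("early stopping replays against the stored history", {
  set.seed(67)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(100, sd = 0.2)
  cfg <- net_config(seed = 68, max_epochs = 200)
  net <- train_network(X, y, cfg)
  h <- net$history
  expect_equal(net$stopped_epoch, length(h))
  if (net$stopped_epoch < cfg$max_epochs) {
    # the moving-average rule must hold exactly at the stopping epoch
    expect_true(gwadl:::early_stop_fired(h, cfg))
    expect_false(any(vapply(seq_len(length(h) - 1L), function(t)
      gwadl:::early_stop_fired(h[seq_len(t)], cfg), logical(1))))
  }
})

test_that("with regularization off, the net matches OLS on a linear target", {
  set.seed(69)
  n <- 150
  X <- matrix(rnorm(n * 8), n, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(n, sd = 0.3)
  tr <- 1:100
  te <- 101:150
  cfg <- net_config(h1 = 40, h2 = 40, activation = "tanh",
                    l1 = 0, l2 = 0, dropout = 0, seed = 70)
  net <- train_network(X[tr, ], y[tr], cfg)
  r2_net <- cor(predict(net, X[te, ]), y[te])^2
  ols <- lm(y ~ ., data = data.frame(y = y[tr], X[tr, ]))
  r2_ols <- cor(predict(ols, data.frame(X[te, ])), y[te])^2
  expect_gt(r2_net, r2_ols - 0.05)
})

test_that("the default grid has the full 3,840 configurations", {
  g <- full_grid()
  expect_equal(nrow(g), 3840L)
  expect_setequal(unique(g$activation), c("tanh", "relu", "maxout"))
  expect_equal(sort(unique(g$h1)), c(40L, 126L, 213L, 300L))
  expect_equal(sort(unique(g$dropout)), c(0.04, 0.15, 0.275, 0.40, 0.50))
  expect_equal(range(g$l1), c(2e-6, 1e-4))
  s <- sample_grid(48, seed = 3)
  expect_equal(nrow(s), 48L)
})

test_that("grid search returns the arg-min configuration", {
  set.seed(71)
  X <- matrix(rnorm(90 * 10), 90, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(90, sd = 0.5)
  one <- full_grid()[5, ]
  gs1 <- grid_search(X, y, one, folds = 3, seed = 72, max_epochs = 10)
  expect_equal(gs1$best$h1, one$h1)
  expect_equal(gs1$best$activation, as.character(one$activation))
  two <- full_grid()[c(5, 100), ]
  gs2 <- grid_search(X, y, two, folds = 3, seed = 72, max_epochs = 10)
  expect_equal(gs2$best_index, which.min(gs2$scores$cv_mse))
})

test_that("Gedeon importance: single-path and symmetric networks", {
  set.seed(73)
  X <- matrix(rnorm(50 * 4), 50, 4)
  net <- train_network(X, rnorm(50), net_config(seed = 74, max_epochs = 2))
  # single-path: only input 1 has nonzero first-layer weights
  net$layer1$W[[1]][-1, ] <- 0
  imp <- gedeon_importance(net)
  expect_equal(imp$score, c(1, 0, 0, 0), tolerance = 1e-12)
  # symmetric: identical rows for inputs 1 and 2 give equal scores
  net2 <- train_network(X, rnorm(50), net_config(seed = 75, max_epochs = 2))
  net2$layer1$W[[1]][2, ] <- net2$layer1$W[[1]][1, ]
  imp2 <- gedeon_importance(net2)
  expect_equal(imp2$score[1], imp2$score[2], tolerance = 1e-12)
  expect_equal(sum(imp2$score), 1, tolerance = 1e-10)
  expect_true(all(imp2$score >= 0))
})

test_that("importance is invariant to relabeling hidden units", {
  set.seed(76)
  X <- matrix(rnorm(60 * 6), 60, 6)
  net <- train_network(X, rnorm(60), net_config(seed = 77, max_epochs = 3))
  perm <- sample(net$cfg$h1)
  net_p <- net
  net_p$layer1$W[[1]] <- net$layer1$W[[1]][, perm]
  net_p$layer1$b[[1]] <- net$layer1$b[[1]][perm]
  net_p$layer2$W[[1]] <- net$layer2$W[[1]][perm, ]
  expect_equal(gedeon_importance(net_p)$score, gedeon_importance(net)$score,
               tolerance = 1e-10)
})

test_that("network and GBLUP cross-validation share fold partitions", {
  sim <- small_study(seed = 78, n = 60, m = 200)
  gi <- impute_mean(sim$genotypes)
  y <- genotype_means(sim$phenotypes, "sim_trait", gi$sample_ids)
  cvb <- crossval_gblup(gi, y, seed = 5)
  X <- gi$dosages[, 1:50]
  cvn <- crossval_gwadl(X, y, net_config(seed = 79, max_epochs = 5), seed = 5)
  expect_identical(cvb$predictions$fold, cvn$predictions$fold)
})

test_that("maxout networks train and expose importance", {
  set.seed(80)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- drop(X %*% rnorm(10))
  net <- train_network(X, y, net_config(activation = "maxout", seed = 81,
                                        max_epochs = 30))
  expect_length(net$layer1$W, 2L)
  expect_gt(cor(predict(net, X), y)^2, 0.8)
  imp <- gedeon_importance(net)
  expect_equal(sum(imp$score), 1, tolerance = 1e-10)
})

test_that("config validation enforces the tuning ranges", {
  expect_error(net_config(h1 = 20, seed = 1), "h1")
  expect_error(net_config(dropout = 0.6, seed = 1), "dropout")
  expect_error(net_config(l1 = 1e-3, seed = 1), "l1")
  expect_error(net_config(h1 = 40), "seed")
})
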