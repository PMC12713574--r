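#' Network hyperparameter configuration
#'
#' Hyperparameters of the two-hidden-layer feed-forward regressor. Hidden
#' widths lie in \[40, 300\]; lasso (L1) and ridge (L2) penalties in
#' \[2e-6, 1e-4\]; the shared dropout fraction (applied to the input layer
#' and both hidden layers) in \[0.04, 0.50\]. Training runs mini-batch SGD
#' with momentum on the MSE loss for at most `max_epochs` epochs, stopping
#' early when the relative reduction of the 3-epoch moving-average training
#' MSE falls below `stop_tol`.
#'
#' @param h1,h2 hidden-layer widths, in \[40, 300\].
#' @param activation `"tanh"`, `"relu"` or `"maxout"` (2 linear pieces).
#' @param l1,l2 lasso / ridge penalties, in \[2e-6, 1e-4\].
#' @param dropout shared drop fraction, in \[0.04, 0.50\].
#' @param learning_rate,momentum,batch_size SGD settings.
#' @param max_epochs,stop_window,stop_tol early-stopping rule: halt when the
#'   `stop_window`-epoch moving-average MSE improves by less than `stop_tol`
#'   (relatively, or absolutely with `stop_mode = "absolute"`).
#' @param stop_mode `"relative"` (default) or `"absolute"`.
#' @param seed mandatory integer seed; identical seeds give identical
#'   training runs.
#' @return object of class `net_config`.
#' @export
net_config <- function(h1 = 40, h2 = 40, activation = c("relu", "tanh", "maxout"),
                       l1 = 2e-6, l2 = 2e-6, dropout = 0.04,
                       learning_rate = 0.01, momentum = 0.9, batch_size = 32,
                       max_epochs = 200, stop_window = 3, stop_tol = 0.01,
                       stop_mode = c("relative", "absolute"), seed) {
  activation <- match.arg(activation)
  stop_mode <- match.arg(stop_mode)
  if (missing(seed)) stop("seed is mandatory in net_config()")
  # tuned values live in the grid ranges; 0 switches a regularizer off
  stopifnot(h1 >= 40, h1 <= 300, h2 >= 40, h2 <= 300,
            l1 == 0 || (l1 >= 2e-6 && l1 <= 1e-4),
            l2 == 0 || (l2 >= 2e-6 && l2 <= 1e-4),
            dropout == 0 || (dropout >= 0.04 && dropout <= 0.5),
            learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2),
                 activation = activation, l1 = l1, l2 = l2, dropout = dropout,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 stop_window = as.integer(stop_window), stop_tol = stop_tol,
                 stop_mode = stop_mode, seed = as.integer(seed)),
            class = "net_config")
}

# activation forward pass; maxout keeps 2 linear pieces per unit.
act_forward <- function(pre, activation) {
  switch(activation,
         relu = pmax(pre, 0),
         tanh = tanh(pre))
}
act_grad <- function(pre, a, activation) {
  switch(activation,
         relu = (pre > 0) * 1,
         tanh = 1 - a^2)
}

init_weight <- function(nin, nout, activation) {
  sd <- if (activation == "relu") sqrt(2 / nin) else sqrt(1 / nin)
  matrix(stats::rnorm(nin * nout, sd = sd), nin, nout)
}

new_layer <- function(nin, nout, activation) {
  pieces <- if (activation == "maxout") 2L else 1L
  list(W = lapply(seq_len(pieces), function(i)
         init_weight(nin, nout, activation)),
       b = lapply(seq_len(pieces), function(i) numeric(nout)))
}

# forward through one hidden layer; returns activation and backprop context
layer_forward <- function(A, layer, activation) {
  pres <- lapply(seq_along(layer$W), function(i)
    sweep(A %*% layer$W[[i]], 2, layer$b[[i]], "+"))
  if (activation == "maxout") {
    out <- pmax(pres[[1]], pres[[2]])
    list(a = out, pres = pres, which2 = pres[[2]] >= pres[[1]])
  } else {
    list(a = act_forward(pres[[1]], activation), pres = pres)
  }
}

#' Train the two-hidden-layer regression network
#'
#' Inputs are standardized to zero mean / unit variance per column (constant
#' columns pass through as zeros); the response is standardized internally
#' and predictions are returned on the original scale. Training is
#' mini-batch stochastic gradient descent with momentum on the penalized MSE
#' loss `MSE + l1 * sum|w| + l2 * sum w^2`, with inverted dropout applied to
#' the input and both hidden layers during training (evaluation uses the
#' full network, which equals expectation scaling). After each epoch the
#' unregularized training MSE (no dropout) is recorded; training halts when
#' the moving-average early-stopping rule of [net_config()] fires or at
#' `max_epochs`.
#'
#' @param X numeric matrix of selected-marker dosages (samples x markers).
#' @param y numeric trait vector.
#' @param cfg a [net_config()].
#' @return object of class `trained_network`: weight/bias lists `layer1`,
#'   `layer2` (maxout pieces kept separately), output weights `W3`, `b3`,
#'   standardization parameters, per-epoch `history`, `stopped_epoch`, `cfg`.
#' @export
train_network <- function(X, y, cfg) {
  stopifnot(inherits(cfg, "net_config"))
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, all(is.finite(y)), all(is.finite(X)))
  set.seed(cfg$seed)

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1
  ys <- (y - y_center) / y_scale

  p <- ncol(Xs)
  act <- cfg$activation
  l1 <- new_layer(p, cfg$h1, act)
  l2 <- new_layer(cfg$h1, cfg$h2, act)
  W3 <- init_weight(cfg$h2, 1L, "tanh")
  b3 <- 0
  vel <- list(l1 = lapply(l1$W, function(w) w * 0),
              l1b = lapply(l1$b, function(b) b * 0),
              l2 = lapply(l2$W, function(w) w * 0),
              l2b = lapply(l2$b, function(b) b * 0),
              W3 = W3 * 0, b3 = 0)
  keep <- 1 - cfg$dropout
  lr <- cfg$learning_rate
  mom <- cfg$momentum

  forward_full <- function(Xin) {
    f1 <- layer_forward(Xin, l1, act)
    f2 <- layer_forward(f1$a, l2, act)
    drop(f2$a %*% W3) + b3
  }

  history <- numeric(0)
  stopped_epoch <- NA_integer_
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    for (s in starts) {
      bi <- ord[s:min(s + cfg$batch_size - 1L, n)]
      nb <- length(bi)
      Xb <- Xs[bi, , drop = FALSE]
      yb <- ys[bi]
      # inverted dropout masks
      m0 <- matrix(stats::rbinom(nb * p, 1, keep), nb, p) / keep
      Xb <- Xb * m0
      f1 <- layer_forward(Xb, l1, act)
      m1 <- matrix(stats::rbinom(nb * cfg$h1, 1, keep), nb, cfg$h1) / keep
      A1 <- f1$a * m1
      f2 <- layer_forward(A1, l2, act)
      m2 <- matrix(stats::rbinom(nb * cfg$h2, 1, keep), nb, cfg$h2) / keep
      A2 <- f2$a * m2
      yhat <- drop(A2 %*% W3) + b3
      if (any(!is.finite(yhat)))
        stop("non-finite loss during training: reduce learning_rate")
      dout <- matrix(2 * (yhat - yb) / nb, ncol = 1)

      gW3 <- crossprod(A2, dout) + l1_l2_grad(W3, cfg)
      gb3 <- sum(dout)
      dA2 <- (dout %*% t(W3)) * m2
      bp2 <- layer_backward(A1, f2, dA2, l2, act, cfg)
      dA1 <- bp2$dA * m1
      bp1 <- layer_backward(Xb, f1, dA1, l1, act, cfg)

      vel$W3 <- mom * vel$W3 - lr * gW3;  W3 <- W3 + vel$W3
      vel$b3 <- mom * vel$b3 - lr * gb3;  b3 <- b3 + vel$b3
      for (i in seq_along(l2$W)) {
        vel$l2[[i]] <- mom * vel$l2[[i]] - lr * bp2$gW[[i]]
        l2$W[[i]] <- l2$W[[i]] + vel$l2[[i]]
        vel$l2b[[i]] <- mom * vel$l2b[[i]] - lr * bp2$gb[[i]]
        l2$b[[i]] <- l2$b[[i]] + vel$l2b[[i]]
      }
      for (i in seq_along(l1$W)) {
        vel$l1[[i]] <- mom * vel$l1[[i]] - lr * bp1$gW[[i]]
        l1$W[[i]] <- l1$W[[i]] + vel$l1[[i]]
        vel$l1b[[i]] <- mom * vel$l1b[[i]] - lr * bp1$gb[[i]]
        l1$b[[i]] <- l1$b[[i]] + vel$l1b[[i]]
      }
    }
    mse <- mean((forward_full(Xs) - ys)^2)
    if (!is.finite(mse))
      stop("non-finite loss during training: reduce learning_rate")
    history <- c(history, mse)
    st <- early_stop_fired(history, cfg)
    if (st) {
      stopped_epoch <- epoch
      break
    }
  }
  if (is.na(stopped_epoch)) stopped_epoch <- length(history)

  structure(list(layer1 = l1, layer2 = l2, W3 = W3, b3 = b3,
                 activation = act,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 history = history, stopped_epoch = stopped_epoch,
                 cfg = cfg),
            class = "trained_network")
}

l1_l2_grad <- function(W, cfg) cfg$l1 * sign(W) + 2 * cfg$l2 * W

layer_backward <- function(Ain, fwd, dA, layer, activation, cfg) {
  if (activation == "maxout") {
    d2 <- dA * fwd$which2
    d1 <- dA * (!fwd$which2)
    gW <- list(crossprod(Ain, d1) + l1_l2_grad(layer$W[[1]], cfg),
               crossprod(Ain, d2) + l1_l2_grad(layer$W[[2]], cfg))
    gb <- list(colSums(d1), colSums(d2))
    dAin <- d1 %*% t(layer$W[[1]]) + d2 %*% t(layer$W[[2]])
  } else {
    dpre <- dA * act_grad(fwd$pres[[1]], fwd$a, activation)
    gW <- list(crossprod(Ain, dpre) + l1_l2_grad(layer$W[[1]], cfg))
    gb <- list(colSums(dpre))
    dAin <- dpre %*% t(layer$W[[1]])
  }
  list(gW = gW, gb = gb, dA = dAin)
}

# TRUE when the moving-average early-stopping rule fires at the last epoch
early_stop_fired <- function(history, cfg) {
  w <- cfg$stop_window
  t <- length(history)
  if (t < w + 1L) return(FALSE)
  ma_cur <- mean(history[(t - w + 1L):t])
  ma_prev <- mean(history[(t - w):(t - 1L)])
  red <- ma_prev - ma_cur
  if (cfg$stop_mode == "relative") {
    ma_prev > 0 && red / ma_prev < cfg$stop_tol
  } else {
    red < cfg$stop_tol
  }
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf(
    "trained_network: %d inputs -> %d -> %d -> 1 (%s), stopped at epoch %d, final MSE %.4g\n",
    length(x$x_center), x$cfg$h1, x$cfg$h2, x$activation, x$stopped_epoch,
    x$history[length(x$history)]))
  invisible(x)
}

#' Predict from a trained network
#' @param object a `trained_network`.
#' @param newdata matrix with the same columns as the training input.
#' @param ... unused.
#' @return numeric predictions on the original trait scale.
#' @export
predict.trained_network <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  f1 <- layer_forward(Xs, object$layer1, object$activation)
  f2 <- layer_forward(f1$a, object$layer2, object$activation)
  out <- drop(f2$a %*% object$W3) + object$b3
  out * object$y_scale + object$y_center
}

#' The full 3,840-configuration hyperparameter grid
#'
#' Factorization: 3 activations x 4 widths for each hidden layer
#' (40, 126, 213, 300) x 4 L1 levels x 4 L2 levels (2e-6, 1e-5, 5e-5, 1e-4)
#' x 5 dropout levels (0.04, 0.15, 0.275, 0.40, 0.50) = 3,840.
#'
#' @return data.frame of configurations (one row each).
#' @export
full_grid <- function() {
  expand.grid(activation = c("tanh", "relu", "maxout"),
              h1 = c(40L, 126L, 213L, 300L),
              h2 = c(40L, 126L, 213L, 300L),
              l1 = c(2e-6, 1e-5, 5e-5, 1e-4),
              l2 = c(2e-6, 1e-5, 5e-5, 1e-4),
              dropout = c(0.04, 0.15, 0.275, 0.40, 0.50),
              stringsAsFactors = FALSE)
}

#' Random subsample of a hyperparameter grid
#' @param grid data.frame of configurations (default [full_grid()]).
#' @param n number of configurations to keep.
#' @param seed RNG seed.
#' @return data.frame subset of `grid`.
#' @export
sample_grid <- function(n, grid = full_grid(), seed = 1) {
  set.seed(seed)
  grid[sort(sample.int(nrow(grid), min(n, nrow(grid)))), , drop = FALSE]
}

grid_row_to_config <- function(row, seed, ...) {
  net_config(h1 = row$h1, h2 = row$h2, activation = as.character(row$activation),
             l1 = row$l1, l2 = row$l2, dropout = row$dropout, seed = seed, ...)
}

#' Grid search over network configurations by cross-validated MSE
#'
#' Scores every configuration by mean k-fold cross-validation MSE using
#' folds shared across configurations (and with [crossval_gblup()] at the
#' same seed), and returns the arg-min configuration plus the full score
#' table (CV MSE and both R2 definitions per configuration).
#'
#' @param X marker matrix (samples x markers).
#' @param y trait vector.
#' @param grid data.frame of configurations, e.g. [full_grid()] or
#'   [sample_grid()].
#' @param folds number of CV folds.
#' @param seed seed for the fold partition and per-config training seeds.
#' @param ... extra arguments passed to [net_config()] (e.g. `max_epochs`).
#' @return list with `best` (a [net_config()]), `scores` (data.frame), and
#'   `best_index`.
#' @export
grid_search <- function(X, y, grid, folds = 5, seed = 1, ...) {
  stopifnot(nrow(grid) >= 1)
  n <- nrow(as.matrix(X))
  fold <- make_folds(n, folds, seed)
  scores <- grid
  scores$cv_mse <- NA_real_
  scores$cv_r2_pearson <- NA_real_
  scores$cv_r2_mse <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- grid_row_to_config(grid[i, ], seed = seed + i, ...)
    # a diverging configuration is disqualified, not fatal
    cv <- tryCatch(crossval_net_core(X, y, cfg, fold),
                   error = function(e) NULL)
    if (is.null(cv)) {
      scores$cv_mse[i] <- Inf
      next
    }
    scores$cv_mse[i] <- cv$mse
    scores$cv_r2_pearson[i] <- mean(cv$fold_r2_pearson)
    scores$cv_r2_mse[i] <- mean(cv$fold_r2_mse)
  }
  if (!any(is.finite(scores$cv_mse)))
    stop("every configuration diverged during training: reduce learning_rate")
  best_index <- which.min(scores$cv_mse)
  best <- grid_row_to_config(grid[best_index, ], seed = seed + best_index, ...)
  list(best = best, scores = scores, best_index = best_index)
}

crossval_net_core <- function(X, y, cfg, fold) {
  X <- as.matrix(X)
  folds <- max(fold)
  pred <- numeric(length(y))
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + f
    net <- train_network(X[tr, , drop = FALSE], y[tr], cfg_f)
    pred[te] <- predict(net, X[te, , drop = FALSE])
  }
  r2p <- r2m <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    m <- r2_metrics(y[te], pred[te])
    r2p[f] <- m$pearson
    r2m[f] <- m$mse_based
  }
  list(mse = mean((pred - y)^2), pred = pred,
       fold_r2_pearson = r2p, fold_r2_mse = r2m, fold = fold)
}

#' Cross-validated GWADL network prediction
#'
#' Same fold protocol (and seed convention) as [crossval_gblup()], so that
#' method comparisons are paired on identical partitions.
#'
#' @param X marker matrix (samples x markers).
#' @param y trait vector.
#' @param cfg a [net_config()].
#' @param folds number of folds.
#' @param seed fold seed (shared with GBLUP).
#' @param r2_method `"pearson"` or `"mse"`.
#' @return a `prediction_result` (see [crossval_gblup()]).
#' @export
crossval_gwadl <- function(X, y, cfg, folds = 5, seed = 1,
                           r2_method = c("pearson", "mse")) {
  r2_method <- match.arg(r2_method)
  X <- as.matrix(X)
  fold <- make_folds(nrow(X), folds, seed)
  cv <- crossval_net_core(X, y, cfg, fold)
  fold_r2 <- if (r2_method == "pearson") cv$fold_r2_pearson else cv$fold_r2_mse
  ids <- rownames(X) %||% paste0("S", seq_len(nrow(X)))
  structure(list(
    predictions = data.frame(sample = ids, fold = fold, observed = y,
                             predicted = cv$pred),
    fold_r2 = fold_r2, r2_mean = mean(fold_r2), r2_sd = stats::sd(fold_r2),
    r2_method = r2_method, method = "gwadl",
    fold_r2_pearson = cv$fold_r2_pearson, fold_r2_mse = cv$fold_r2_mse
  ), class = "prediction_result")
}

#' Gedeon weight-magnitude variable importance
#'
#' For a two-hidden-layer network, the contribution of input i to hidden-1
#' unit j is `P_ij = |W1_ij| / sum_p |W1_pj|` (normalized over inputs), the
#' contribution of hidden-1 unit j to hidden-2 unit k is
#' `Q_jk = |W2_jk| / sum_q |W2_qk|`, and the output contribution of hidden-2
#' unit k is `R_k = |W3_k| / sum_s |W3_s|`. The raw importance of input i is
#' `sum_k (sum_j P_ij Q_jk) R_k`, renormalized to sum to one. For maxout
#' layers the element-wise maximum of |weights| across the linear pieces is
#' used. Columns with all-zero weights contribute zero.
#'
#' @param net a `trained_network`.
#' @return data.frame with `input` (column name or index), `score`
#'   (non-negative, summing to 1), `rank`.
#' @export
gedeon_importance <- function(net) {
  stopifnot(inherits(net, "trained_network"))
  absmax <- function(ws) Reduce(pmax, lapply(ws, abs))
  col_norm <- function(M) {
    cs <- colSums(M)
    cs[cs == 0] <- Inf
    sweep(M, 2, cs, "/")
  }
  P <- col_norm(absmax(net$layer1$W))
  Q <- col_norm(absmax(net$layer2$W))
  w3 <- abs(net$W3[, 1])
  R <- if (sum(w3) > 0) w3 / sum(w3) else w3
  raw <- drop((P %*% Q) %*% R)
  total <- sum(raw)
  score <- if (total > 0) raw / total else raw
  nm <- names(net$x_center)
  if (is.null(nm)) nm <- as.character(seq_along(raw))
  data.frame(input = nm, score = score,
             rank = rank(-score, ties.method = "min"),
             row.names = NULL)
}

#' Write importance scores as TSV
#' @param imp data.frame from [gedeon_importance()].
#' @param path file path.
#' @param significant optional logical vector flagging scan-significant
#'   markers.
#' @export
write_importance_tsv <- function(imp, path, significant = NULL) {
  if (!is.null(significant)) imp$is_scan_significant <- significant
  utils::write.table(imp[order(imp$rank), ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
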