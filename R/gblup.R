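#' VanRaden realized relationship matrix
#'
#' Method-1 VanRaden kinship: dosage columns are centered by twice the
#' observed allele frequency, `Z = D - 2p`, and
#' `K = Z Z' / (2 * sum_j p_j (1 - p_j))`. Rows of K sum to zero because the
#' centering uses the observed frequencies of the same samples.
#'
#' @param g an imputed [genotype_matrix()], or a plain numeric dosage matrix.
#' @param subset variant column indices to build the kinship from
#'   (default: all).
#' @return object of class `kinship_matrix`: list with `K` (n x n), `c`
#'   (the scaling constant), `sample_ids`.
#' @export
vanraden_kinship <- function(g, subset = NULL) {
  if (inherits(g, "genotype_matrix")) {
    if (!g$imputed && any(is.na(g$dosages)))
      stop("kinship requires a complete (imputed) dosage matrix")
    d <- g$dosages
    ids <- g$sample_ids
  } else {
    d <- as.matrix(g)
    ids <- rownames(d)
    if (is.null(ids)) ids <- paste0("S", seq_len(nrow(d)))
  }
  if (!is.null(subset)) d <- d[, subset, drop = FALSE]
  if (ncol(d) == 0L) stop("empty variant subset")
  p <- colMeans(d) / 2
  cc <- 2 * sum(p * (1 - p))
  if (cc <= .Machine$double.eps * ncol(d))
    stop("monomorphic variant subset: zero VanRaden scaling constant")
  z <- sweep(d, 2, 2 * p)
  K <- tcrossprod(z) / cc
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, c = cc, sample_ids = ids), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d samples, scaling constant c = %.4g\n",
              length(x$sample_ids), x$c))
  invisible(x)
}

#' Write a kinship matrix as square TSV
#' @param k a `kinship_matrix`.
#' @param path file path.
#' @export
write_kinship_tsv <- function(k, path) {
  df <- data.frame(sample_id = k$sample_ids, k$K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' REML variance components on the kinship eigenbasis
#'
#' Fits `y = X beta + u + e`, `u ~ N(0, sigma2_g K)`, `e ~ N(0, sigma2_e I)`,
#' by restricted maximum likelihood. The restricted likelihood is profiled
#' down to the single variance ratio `delta = sigma2_e / sigma2_g` using the
#' spectral decomposition of the kinship projected off the fixed effects
#' (EMMA-style), and maximized by golden-section search over
#' `log(delta) in [-10, 10]` (tolerance 1e-8), with the bracket endpoints
#' checked for boundary optima.
#'
#' @param y numeric response, length n.
#' @param K a `kinship_matrix` or a plain n x n symmetric matrix.
#' @param X fixed-effect design matrix (default: intercept only).
#' @return object of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `delta`, `h2` (= sigma2_g/(sigma2_g + sigma2_e)), `reml_loglik`.
#' @export
reml_fit <- function(y, K, X = NULL) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, all(is.finite(y)))
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  q <- qr(X)$rank
  if (q != ncol(X)) stop("fixed-effect design X is rank deficient")
  # project K and y off the column space of X
  qx <- qr.Q(qr(X))
  SKS <- K - qx %*% crossprod(qx, K)
  SKS <- SKS - (SKS %*% qx) %*% t(qx)
  SKS <- (SKS + t(SKS)) / 2
  eg <- eigen(SKS, symmetric = TRUE)
  keep <- seq_len(n - q)
  lam <- pmax(eg$values[keep], 0)
  eta <- crossprod(eg$vectors[, keep, drop = FALSE], y)[, 1]
  nq <- n - q
  rll <- function(logd) {
    d <- exp(logd)
    denom <- lam + d
    rss <- sum(eta^2 / denom)
    0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(rss) - sum(log(denom)))
  }
  opt <- stats::optimize(rll, interval = c(-10, 10), maximum = TRUE,
                         tol = 1e-8)
  cands <- rbind(c(opt$maximum, opt$objective),
                 c(-10, rll(-10)), c(10, rll(10)))
  best <- cands[which.max(cands[, 2]), ]
  if (!is.finite(best[2]))
    stop("REML optimization failed to bracket a finite optimum")
  delta <- exp(best[1])
  sigma2_g <- sum(eta^2 / (lam + delta)) / nq
  sigma2_e <- delta * sigma2_g
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, delta = delta,
                 h2 = sigma2_g / (sigma2_g + sigma2_e),
                 reml_loglik = best[2]),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "REML: sigma2_g = %.4g, sigma2_e = %.4g, delta = %.4g, h2 = %.3f, logL = %.3f\n",
    x$sigma2_g, x$sigma2_e, x$delta, x$h2, x$reml_loglik))
  invisible(x)
}

#' GBLUP prediction for held-out samples
#'
#' With variance components fit on the training samples, the genomic breeding
#' values of test samples are
#' `u_test = K[test, train] (K[train, train] + delta I)^-1 (y_train - X_train beta)`
#' with `beta` the GLS estimate, and `GBV = X_test beta + u_test`.
#'
#' @param y_train training response.
#' @param K full `kinship_matrix` (or matrix) covering train and test.
#' @param train,test integer index vectors into the kinship.
#' @param vc `variance_components` fit on the training samples.
#' @param X optional fixed-effect design over all samples (default intercept).
#' @return list with `gbv` (test predictions), `beta`, `fitted_train`.
#' @export
gblup_predict <- function(y_train, K, train, test, vc, X = NULL) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  n <- nrow(K)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  Ktt <- K[train, train, drop = FALSE]
  V <- Ktt + diag(vc$delta, length(train))
  Vc <- tryCatch(chol(V), error = function(e)
    stop("singular GBLUP system: ", conditionMessage(e)))
  Vinv_y <- backsolve(Vc, forwardsolve(t(Vc), y_train))
  Xtr <- X[train, , drop = FALSE]
  Vinv_X <- backsolve(Vc, forwardsolve(t(Vc), Xtr))
  beta <- solve(crossprod(Xtr, Vinv_X), crossprod(Xtr, Vinv_y))
  resid <- y_train - Xtr %*% beta
  Vinv_r <- backsolve(Vc, forwardsolve(t(Vc), resid))
  u_test <- K[test, train, drop = FALSE] %*% Vinv_r
  u_train <- Ktt %*% Vinv_r
  list(gbv = drop(X[test, , drop = FALSE] %*% beta + u_test),
       beta = drop(beta),
       fitted_train = drop(Xtr %*% beta + u_train))
}

#' Seeded balanced cross-validation folds
#'
#' Shared by GBLUP and the GWADL network so that paired comparisons use
#' identical partitions. Fold sizes differ by at most one.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return integer vector of fold labels, length n.
#' @export
make_folds <- function(n, k = 5, seed) {
  stopifnot(n >= k)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

r2_metrics <- function(obs, pred) {
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    return(list(pearson = 0, mse_based = 0, degenerate = TRUE))
  }
  list(pearson = stats::cor(obs, pred)^2,
       mse_based = 1 - mean((obs - pred)^2) / stats::var(obs),
       degenerate = FALSE)
}

#' Cross-validated GBLUP
#'
#' Seeded random 5-fold partition; variance components are refit on each
#' training split and the held-out fold predicted by [gblup_predict()].
#' The reported R2 is the squared Pearson correlation between observed and
#' predicted on the held-out fold (`r2_method = "pearson"`, the genomic
#' prediction convention); `"mse"` gives `1 - MSE/Var(obs)` instead.
#'
#' @param g imputed [genotype_matrix()] or dosage matrix.
#' @param y phenotype vector (one value per sample, e.g. genotype means).
#' @param subset variant indices used to build the kinship.
#' @param folds number of folds.
#' @param seed RNG seed for the fold partition.
#' @param r2_method `"pearson"` or `"mse"`.
#' @return object of class `prediction_result`: data.frame `predictions`
#'   (sample, fold, observed, predicted), `fold_r2`, `r2_mean`, `r2_sd`,
#'   `method`, plus per-fold variance components.
#' @export
crossval_gblup <- function(g, y, subset = NULL, folds = 5, seed = 1,
                           r2_method = c("pearson", "mse")) {
  r2_method <- match.arg(r2_method)
  kin <- vanraden_kinship(g, subset)
  n <- length(y)
  stopifnot(nrow(kin$K) == n)
  fold <- make_folds(n, folds, seed)
  pred <- numeric(n)
  vcs <- vector("list", folds)
  degenerate <- FALSE
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    vc <- reml_fit(y[tr], kin$K[tr, tr, drop = FALSE])
    vcs[[f]] <- vc
    pred[te] <- gblup_predict(y[tr], kin$K, tr, te, vc)$gbv
  }
  fold_r2 <- vapply(seq_len(folds), function(f) {
    te <- which(fold == f)
    m <- r2_metrics(y[te], pred[te])
    if (m$degenerate) degenerate <<- TRUE
    m[[if (r2_method == "pearson") "pearson" else "mse_based"]]
  }, numeric(1))
  ids <- if (inherits(g, "genotype_matrix")) g$sample_ids else
    (rownames(as.matrix(g)) %||% paste0("S", seq_len(n)))
  structure(list(
    predictions = data.frame(sample = ids, fold = fold, observed = y,
                             predicted = pred),
    fold_r2 = fold_r2, r2_mean = mean(fold_r2), r2_sd = stats::sd(fold_r2),
    r2_method = r2_method, method = "gblup", vc = vcs,
    degenerate = degenerate
  ), class = "prediction_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (%d folds, R2 = %s): mean R2 = %.3f (sd %.3f)\n",
              x$method, length(x$fold_r2), x$r2_method, x$r2_mean, x$r2_sd))
  invisible(x)
}

#' Write cross-validation predictions as TSV
#' @param x a `prediction_result`.
#' @param path file path.
#' @export
write_predictions_tsv <- function(x, path) {
  utils::write.table(x$predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
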