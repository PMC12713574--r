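#' Principal-component covariates for population structure
#'
#' Column-standardizes the imputed dosage matrix (monomorphic columns are set
#' to zero) and returns an intercept column plus the top-k principal
#' component scores, the standard PCA correction for cryptic population
#' stratification in GWAS.
#'
#' @param g imputed [genotype_matrix()] (or complete dosage matrix).
#' @param k number of principal components (`k = 0` gives intercept only).
#' @return numeric matrix with columns `(Intercept), PC1..PCk`; rows follow
#'   the sample order of `g`.
#' @export
pca_covariates <- function(g, k = 2) {
  d <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  if (any(is.na(d))) stop("PCA requires a complete (imputed) dosage matrix")
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of samples")
  out <- matrix(1, n, 1, dimnames = list(rownames(d), "(Intercept)"))
  if (k > 0) {
    mu <- colMeans(d)
    sdv <- apply(d, 2, stats::sd)
    sdv[sdv == 0] <- Inf            # monomorphic -> zero contribution
    z <- sweep(sweep(d, 2, mu), 2, sdv, "/")
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
    sc <- pc$x[, seq_len(k), drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(k))
    out <- cbind(out, sc)
  }
  out
}

# residualize y and the dosage columns against the fixed-effect matrix F,
# then test each column by OLS t-test. Returns p (collinear columns -> 1),
# effect, and the residual degrees of freedom.
ols_scan_core <- function(D, y, F) {
  n <- length(y)
  qrf <- qr(F)
  if (qrf$rank < ncol(F)) {
    bad <- colnames(F)[qrf$pivot[-seq_len(qrf$rank)]]
    stop("rank-deficient covariate matrix (offending columns: ",
         paste(bad %||% "unnamed", collapse = ", "), ")")
  }
  qx <- qr.Q(qrf)
  My <- drop(y - qx %*% crossprod(qx, y))
  MD <- D - qx %*% crossprod(qx, D)
  denom <- colSums(MD^2)
  df <- n - ncol(F) - 1L
  if (df < 1L) stop("not enough residual degrees of freedom")
  col_scale <- colSums(D^2)
  collinear <- denom <= 1e-10 * pmax(col_scale, 1)
  b <- colSums(MD * My) / ifelse(collinear, 1, denom)
  rss <- pmax(sum(My^2) - b^2 * denom, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / ifelse(collinear, 1, denom))
  tt <- ifelse(se > 0, b / se, 0)
  p <- 2 * stats::pt(-abs(tt), df)
  p[collinear] <- 1
  b[collinear] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(p_value = unname(p), effect = unname(b), df = df)
}

#' Single-marker OLS scan
#'
#' For each variant not in `extra_fixed`, regresses the trait on the
#' covariates, the `extra_fixed` pseudo-QTN dosages, and the variant's dosage,
#' and reports the two-sided t-test p-value and the additive effect per
#' minor-allele copy. Variants collinear with the fixed set get p = 1 and
#' effect 0; `extra_fixed` variants themselves get `NA` (they are covariates
#' here, not tests).
#'
#' @param g imputed [genotype_matrix()] or complete dosage matrix.
#' @param y numeric trait vector (typically Box-Cox transformed).
#' @param covariates covariate matrix from [pca_covariates()] (default
#'   intercept only).
#' @param extra_fixed variant indices appended as fixed covariates.
#' @return list with `p_value`, `effect` (both length = panel size).
#' @export
single_marker_scan <- function(g, y, covariates = NULL,
                               extra_fixed = integer(0)) {
  D <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  n <- nrow(D)
  stopifnot(length(y) == n)
  if (any(is.na(D))) stop("scan requires a complete (imputed) dosage matrix")
  if (is.null(covariates)) covariates <- matrix(1, n, 1)
  F <- cbind(covariates, D[, extra_fixed, drop = FALSE])
  res <- ols_scan_core(D, y, F)
  if (length(extra_fixed)) {
    res$p_value[extra_fixed] <- NA_real_
    res$effect[extra_fixed] <- NA_real_
  }
  res[c("p_value", "effect")]
}

# p-value/effect of a single variant tested with covariates + other fixed
# variants, used for the leave-one-out pseudo-QTN assignment.
test_one_variant <- function(D, y, covariates, j, others) {
  F <- cbind(covariates, D[, others, drop = FALSE])
  res <- ols_scan_core(D[, j, drop = FALSE], y, F)
  list(p_value = res$p_value[1], effect = res$effect[1])
}

# greedy collinearity pruning: indices ordered by priority (best first);
# drop any later index with squared dosage correlation > cap vs a kept one.
prune_collinear <- function(D, idx, r2_cap) {
  if (length(idx) <= 1L) return(idx)
  kept <- idx[1]
  for (j in idx[-1]) {
    r <- suppressWarnings(stats::cor(D[, j], D[, kept, drop = FALSE]))
    r[is.na(r)] <- 1     # zero-variance column: treat as collinear
    if (all(r^2 <= r2_cap)) kept <- c(kept, j)
  }
  kept
}

#' FarmCPU-style multilocus association scan
#'
#' Iterates a fixed-effect step and a random-effect bin-optimization step.
#' Each iteration: (1) a [single_marker_scan()] with the current pseudo-QTNs
#' as fixed covariates; (2) the genome is partitioned into bins at each
#' candidate bin size, the best-p variant per bin is taken and bins are
#' ranked by that p-value; (3) for every (bin size, bin count) combination,
#' a VanRaden kinship is built from the top candidate pseudo-QTNs and the
#' intercept-plus-polygene model is scored by REML log-likelihood; the
#' combination with the highest likelihood defines the new pseudo-QTN set;
#' (4) pseudo-QTNs with pairwise dosage r-squared above the cap are pruned
#' (the smaller-p member is kept). The scan converges when the pseudo-QTN
#' set repeats. Final p-values come from the last fixed step; each
#' pseudo-QTN's own p-value is obtained by testing it with the remaining
#' pseudo-QTNs as covariates (leave-one-out).
#'
#' If no marker reaches `qtn_p_threshold` (default `0.01/m`) in the first
#' fixed step, the scan stops immediately with an empty pseudo-QTN set, so
#' that pure-noise traits fall back to the plain covariate-adjusted scan.
#'
#' @param g imputed [genotype_matrix()].
#' @param y Box-Cox-transformed trait vector.
#' @param covariates covariate matrix (default intercept only).
#' @param max_iter maximum fixed/random iterations.
#' @param bin_sizes candidate genomic bin sizes in bp.
#' @param bin_counts candidate numbers of pseudo-QTN bins.
#' @param collinearity_r2_cap maximum pairwise dosage r-squared among
#'   pseudo-QTNs.
#' @param qtn_p_threshold first-iteration entry gate (default `0.01/m`).
#' @return object of class `scan_result`: `p_value`, `effect`,
#'   `pseudo_qtns` (variant indices), `n_iterations`, `converged`.
#' @export
multilocus_scan <- function(g, y, covariates = NULL, max_iter = 10,
                            bin_sizes = c(5e5, 5e6, 5e7),
                            bin_counts = c(10, 50, 100),
                            collinearity_r2_cap = 0.7,
                            qtn_p_threshold = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$imputed && any(is.na(g$dosages)))
    stop("multilocus_scan requires an imputed genotype matrix")
  D <- g$dosages
  n <- nrow(D); m <- ncol(D)
  if (is.null(covariates)) covariates <- matrix(1, n, 1)
  if (is.null(qtn_p_threshold)) qtn_p_threshold <- 0.01 / m

  pseudo <- integer(0)
  seen <- list(integer(0))
  converged <- FALSE
  iter <- 0L
  res <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    res <- single_marker_scan(g, y, covariates, pseudo)
    p_all <- res$p_value
    # current pseudo-QTNs: leave-one-out p for bin ranking
    for (q in pseudo) {
      p_all[q] <- test_one_variant(D, y, covariates, q,
                                   setdiff(pseudo, q))$p_value
    }
    if (iter == 1L && min(p_all, na.rm = TRUE) > qtn_p_threshold) {
      converged <- TRUE
      break
    }
    # candidate ranking per bin size, REML model selection over the grid
    best <- list(ll = -Inf, set = pseudo)
    cache <- new.env(parent = emptyenv())
    for (bs in bin_sizes) {
      bin_id <- paste0(g$variants$chrom, "_",
                       (g$variants$pos - 1) %/% bs)
      ordp <- order(p_all)                       # genome order breaks ties
      first <- !duplicated(bin_id[ordp])
      bin_best <- ordp[first]                    # best variant per bin, ranked
      for (bc in bin_counts) {
        cand <- bin_best[seq_len(min(bc, length(bin_best)))]
        cand <- prune_collinear(D, cand, collinearity_r2_cap)
        key <- paste(sort(cand), collapse = ",")
        if (!is.null(cache[[key]])) next
        ll <- tryCatch({
          kin <- vanraden_kinship(D, cand)
          reml_fit(y, kin)$reml_loglik
        }, error = function(e) -Inf)
        cache[[key]] <- ll
        if (ll > best$ll) best <- list(ll = ll, set = cand)
      }
    }
    new_pseudo <- sort(best$set)
    if (any(vapply(seen, identical, logical(1), y = new_pseudo))) {
      pseudo <- new_pseudo
      converged <- TRUE
      break
    }
    seen[[length(seen) + 1L]] <- new_pseudo
    pseudo <- new_pseudo
  }

  final <- single_marker_scan(g, y, covariates, pseudo)
  p_final <- final$p_value
  e_final <- final$effect
  for (q in pseudo) {
    t1 <- test_one_variant(D, y, covariates, q, setdiff(pseudo, q))
    p_final[q] <- t1$p_value
    e_final[q] <- t1$effect
  }
  structure(list(p_value = p_final, effect = e_final,
                 pseudo_qtns = pseudo, n_iterations = iter,
                 converged = converged),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "multilocus scan: %d variants, %d pseudo-QTNs, %d iteration(s)%s\n",
    length(x$p_value), length(x$pseudo_qtns), x$n_iterations,
    if (x$converged) " (converged)" else " (max_iter reached)"))
  invisible(x)
}

#' Bonferroni multiple-testing threshold
#'
#' `alpha / m` for a panel of m tests. [truncate_signif()] reproduces the
#' two-significant-figure truncation convention used when such thresholds
#' are reported (e.g. 0.05 / 5,641,729 -> 8.8e-9).
#'
#' @param m number of tests (panel size).
#' @param alpha family-wise error rate.
#' @return the threshold `alpha/m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' @rdname bonferroni_threshold
#' @param x positive number to truncate.
#' @param digits significant figures to keep (truncation, not rounding).
#' @export
truncate_signif <- function(x, digits = 2) {
  stopifnot(x > 0)
  e <- floor(log10(x))
  scale <- 10^(e - digits + 1)
  floor(x / scale) * scale
}

#' Select variants below a p-value cutoff
#'
#' The enrichment rule: indices of all variants with `p < cutoff`, in genome
#' order. An empty selection is allowed (with a message).
#'
#' @param s a `scan_result` (or bare p-value vector).
#' @param cutoff p-value cutoff (default 1e-4).
#' @return object of class `selection_set`: `indices`, `rule`.
#' @export
select_by_pvalue <- function(s, cutoff = 1e-4) {
  p <- if (inherits(s, "scan_result")) s$p_value else as.numeric(s)
  idx <- which(p < cutoff)
  if (!length(idx)) message("empty selection at cutoff ", cutoff)
  structure(list(indices = sort(idx),
                 rule = sprintf("p < %g", cutoff)),
            class = "selection_set")
}

#' Select genomically spaced variants
#'
#' The control rule: every n-th variant. With stride
#' `floor(m_total / n_select)`, returns the 1-based indices
#' `1, 1 + stride, ..., 1 + (n_select - 1) * stride`.
#'
#' @param m_total panel size.
#' @param n_select number of variants to select (1 <= n_select <= m_total).
#' @return a `selection_set`.
#' @export
select_spaced <- function(m_total, n_select) {
  if (n_select < 1 || n_select > m_total)
    stop("n_select must lie in [1, m_total]")
  stride <- m_total %/% n_select
  structure(list(indices = 1L + (seq_len(n_select) - 1L) * stride,
                 rule = sprintf("every %d-th of %d", stride, m_total)),
            class = "selection_set")
}

#' @export
print.selection_set <- function(x, ...) {
  cat(sprintf("selection_set (%s): %d variants\n", x$rule, length(x$indices)))
  invisible(x)
}

#' Exclusive intersection counts across selection sets
#'
#' UpSet semantics: for every non-empty combination of sets, the number of
#' variants belonging to exactly that combination. Counts sum to the size of
#' the union.
#'
#' @param sets named list of `selection_set`s or integer index vectors.
#' @return data.frame with columns `combination` (set names joined by
#'   `&`), `degree`, `count`.
#' @export
intersection_counts <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  idx <- lapply(sets, function(s)
    if (inherits(s, "selection_set")) s$indices else as.integer(s))
  universe <- sort(unique(unlist(idx)))
  if (!length(universe))
    return(data.frame(combination = character(0), degree = integer(0),
                      count = integer(0)))
  member <- vapply(idx, function(v) universe %in% v, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = " & "))
  tab <- table(pattern)
  data.frame(combination = names(tab),
             degree = vapply(strsplit(names(tab), " & ", fixed = TRUE),
                             length, integer(1)),
             count = as.integer(tab), row.names = NULL)
}

#' Write a scan result as TSV for Manhattan plotting
#'
#' Columns: chrom, pos, p_value, effect, is_pseudo_qtn.
#'
#' @param s a `scan_result`.
#' @param g the [genotype_matrix()] the scan was run on.
#' @param path file path.
#' @export
write_scan_tsv <- function(s, g, path) {
  df <- data.frame(chrom = g$variants$chrom, pos = g$variants$pos,
                   p_value = s$p_value, effect = s$effect,
                   is_pseudo_qtn = seq_along(s$p_value) %in% s$pseudo_qtns)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
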