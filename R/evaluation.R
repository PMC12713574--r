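#' Heritable variance explained
#'
#' Normalizes a prediction accuracy by the line-level heritability:
#' `HVE = 100 * R2 / H2geno` (in percent). Values above 100% are permitted
#' and flagged, since cross-validated accuracies can exceed the heritability
#' estimate when accuracy is inflated (e.g. by residual relatedness between
#' folds).
#'
#' @param r2 prediction R2 (scalar or vector, e.g. per fold).
#' @param h2_geno line-level heritability (> 0).
#' @return percentage(s), with attribute `inflated` flagging values > 100.
#' @export
heritable_variance_explained <- function(r2, h2_geno) {
  if (!is.numeric(h2_geno) || length(h2_geno) != 1 || h2_geno <= 0)
    stop("h2_geno must be a single positive number")
  hve <- 100 * r2 / h2_geno
  attr(hve, "inflated") <- hve > 100
  hve
}

# compact letter display from a logical "not significantly different"
# matrix: maximal cliques of the non-significance graph each get a letter.
cld_letters <- function(nonsig) {
  k <- nrow(nonsig)
  gr <- igraph::graph_from_adjacency_matrix(nonsig, mode = "undirected",
                                            diag = FALSE)
  cl <- igraph::max_cliques(gr)
  # order cliques by the best (largest) group mean they contain, via attr
  ord <- order(vapply(cl, function(x) min(as.integer(x)), integer(1)))
  cl <- cl[ord]
  letters_out <- rep("", k)
  for (i in seq_along(cl)) {
    members <- as.integer(cl[[i]])
    letters_out[members] <- paste0(letters_out[members], letters[i])
  }
  letters_out
}

#' Compare prediction methods on shared cross-validation folds
#'
#' Takes fold-level R2 values for several (method, marker set) cells that
#' share the same fold partition, runs a one-way ANOVA of R2 on cell,
#' followed by Tukey's HSD, and emits compact letter groupings (cells
#' sharing a letter are not significantly different at `alpha`) plus the
#' full pairwise table and heritable-variance-explained summaries.
#'
#' @param results named list of `prediction_result` objects (or bare
#'   fold-R2 numeric vectors), one per method/marker-set cell.
#' @param h2_geno optional line-level heritability for HVE normalization.
#' @param alpha significance level for the Tukey groups.
#' @return object of class `method_comparison`: `summary` (data.frame with
#'   mean/sd R2, HVE and group letter per cell), `tukey` (pairwise table),
#'   `anova_p`.
#' @export
compare_methods <- function(results, h2_geno = NULL, alpha = 0.05) {
  stopifnot(length(results) >= 2, !is.null(names(results)))
  r2l <- lapply(results, function(x)
    if (inherits(x, "prediction_result")) x$fold_r2 else as.numeric(x))
  nf <- lengths(r2l)
  if (length(unique(nf)) != 1)
    stop("all cells must have the same number of folds")
  df <- data.frame(
    cell = factor(rep(names(r2l), each = nf[1]), levels = names(r2l)),
    r2 = unlist(r2l, use.names = FALSE))
  fit <- stats::aov(r2 ~ cell, data = df)
  an_p <- summary(fit)[[1]]$`Pr(>F)`[1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$cell
  k <- length(r2l)
  nonsig <- matrix(TRUE, k, k, dimnames = list(names(r2l), names(r2l)))
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    sig <- tk[rn, "p adj"] < alpha
    if (sig && all(pair %in% names(r2l))) {
      nonsig[pair[1], pair[2]] <- FALSE
      nonsig[pair[2], pair[1]] <- FALSE
    }
  }
  means <- vapply(r2l, mean, numeric(1))
  ord <- order(-means)
  letters_vec <- character(k)
  letters_vec[ord] <- cld_letters(nonsig[ord, ord, drop = FALSE])
  summ <- data.frame(
    cell = names(r2l),
    r2_mean = means,
    r2_sd = vapply(r2l, stats::sd, numeric(1)),
    group = letters_vec,
    row.names = NULL)
  if (!is.null(h2_geno)) {
    summ$hve_mean <- as.numeric(heritable_variance_explained(summ$r2_mean,
                                                             h2_geno))
    summ$hve_sd <- 100 * summ$r2_sd / h2_geno
  }
  structure(list(summary = summ, tukey = as.data.frame(tk), anova_p = an_p,
                 alpha = alpha),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("method comparison (one-way ANOVA p = %.3g; Tukey HSD at alpha = %g)\n",
              x$anova_p, x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a method-comparison report as TSV
#' @param x a `method_comparison`.
#' @param path file path.
#' @export
write_comparison_tsv <- function(x, path) {
  utils::write.table(x$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
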