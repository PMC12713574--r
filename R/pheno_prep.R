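#' Read / write long-format phenotype tables
#'
#' Long format: one row per measurement with columns `genotype_id`,
#' `block_id`, `trait`, `value`. Each (genotype, block, trait) combination
#' may appear at most once.
#'
#' @param path TSV file path.
#' @return a validated phenotype data.frame.
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_phenotypes(df)
}

#' @rdname read_phenotype_tsv
#' @param p phenotype data.frame.
#' @export
write_phenotype_tsv <- function(p, path) {
  utils::write.table(validate_phenotypes(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_phenotypes <- function(p) {
  need <- c("genotype_id", "block_id", "trait", "value")
  if (!all(need %in% names(p)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(p$value))) stop("phenotype values must be finite")
  key <- paste(p$genotype_id, p$block_id, p$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (genotype, block, trait) measurement(s)")
  p
}

#' Box-Cox transform
#'
#' `(y^lambda - 1)/lambda` for `lambda != 0`, `log(y)` for `lambda == 0`.
#' @param y positive numeric vector.
#' @param lambda exponent.
#' @return transformed vector.
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0)) stop("Box-Cox transform requires strictly positive values")
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Grid search for the Box-Cox exponent by Shapiro-Wilk normality
#'
#' Scans lambda over a regular grid (default -5 to +5 in steps of 0.1),
#' transforms the trait at each value, and selects the lambda maximizing the
#' Shapiro-Wilk W statistic of the transformed vector. Ties in W (within
#' 1e-12) are broken toward the lambda closest to 1, i.e. the gentlest
#' transform. Non-positive traits are first shifted by `1 - min(y)` so all
#' values are strictly positive (ordering is preserved).
#'
#' @param y numeric trait vector, length >= 3, not constant.
#' @param grid_lo,grid_hi,step grid of candidate exponents.
#' @param shift allow the automatic positivity shift; if `FALSE` and any
#'   `y <= 0`, an error is raised.
#' @return list with `lambda`, `w_statistic`, `transformed`, `shift`.
#' @export
boxcox_search <- function(y, grid_lo = -5, grid_hi = 5, step = 0.1,
                          shift = TRUE) {
  y <- as.numeric(y)
  if (length(y) < 3L) stop("need at least 3 observations")
  if (stats::sd(y) == 0) stop("constant vector: Shapiro-Wilk W is undefined")
  shift_val <- 0
  if (min(y) <= 0) {
    if (!shift) stop("non-positive values present and shift disabled")
    shift_val <- 1 - min(y)
  }
  ys <- y + shift_val
  lambdas <- seq(grid_lo, grid_hi, by = step)
  w <- vapply(lambdas, function(l) {
    ty <- boxcox_transform(ys, l)
    if (!all(is.finite(ty)) || stats::sd(ty) == 0) return(NA_real_)
    unname(stats::shapiro.test(ty)$statistic)
  }, numeric(1))
  if (all(is.na(w))) stop("Shapiro-Wilk W undefined on the whole grid")
  top <- which(w >= max(w, na.rm = TRUE) - 1e-12)
  best <- top[which.min(abs(lambdas[top] - 1))]
  list(lambda = lambdas[best], w_statistic = w[best],
       transformed = boxcox_transform(ys, lambdas[best]), shift = shift_val)
}

#' Broad-sense heritability by the repeatability method
#'
#' One-way ANOVA of the trait on genotype over `r` replicate blocks yields
#' the genotype and residual mean squares MS(G) and MS(E); then
#' `Vg = (MS(G) - MS(E))/r`, `Ve = MS(E)`,
#' `H2indiv = Vg/(Vg + Ve)` (heritability of single observations) and
#' `H2geno = Vg/(Vg + Ve/r)` (line-level heritability of genotype means).
#' Negative `Vg` (MS(G) < MS(E)) is truncated to 0 and flagged. Genotypes
#' lacking the full complement of `r` blocks are dropped (with a message) so
#' the analyzed design is balanced.
#'
#' @param p phenotype data.frame (see [read_phenotype_tsv()]).
#' @param trait trait name to analyze.
#' @return object of class `heritability_estimate`: list with `ms_g`, `ms_e`,
#'   `vg`, `ve`, `r`, `h2_indiv`, `h2_geno`, `n_genotypes`, `truncated`.
#' @export
heritability_repeatability <- function(p, trait) {
  p <- validate_phenotypes(p)
  d <- p[p$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("no records for trait '", trait, "'")
  counts <- table(d$genotype_id)
  r <- max(counts)
  if (r < 2L) stop("r = 1 replicate block: Vg is not estimable")
  full <- names(counts)[counts == r]
  dropped <- length(counts) - length(full)
  if (dropped > 0) {
    message(dropped, " genotype(s) dropped for lacking the full ", r, " blocks")
    d <- d[d$genotype_id %in% full, , drop = FALSE]
  }
  if (length(full) < 2L) stop("need >= 2 genotypes with the full block count")
  g <- factor(d$genotype_id)
  an <- stats::anova(stats::lm(d$value ~ g))
  ms_g <- an$`Mean Sq`[1]
  ms_e <- an$`Mean Sq`[2]
  vg <- (ms_g - ms_e) / r
  truncated <- FALSE
  if (vg < 0) {
    vg <- 0
    truncated <- TRUE
    warning("MS(G) < MS(E): Vg truncated to 0")
  }
  ve <- ms_e
  denom_i <- vg + ve
  denom_g <- vg + ve / r
  h2_indiv <- if (denom_i > 0) vg / denom_i else NA_real_
  h2_geno <- if (denom_g > 0) vg / denom_g else NA_real_
  structure(list(ms_g = ms_g, ms_e = ms_e, vg = vg, ve = ve, r = r,
                 h2_indiv = h2_indiv, h2_geno = h2_geno,
                 n_genotypes = length(full), truncated = truncated),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf(
    "heritability (repeatability, %d genotypes x r = %d blocks)\n",
    x$n_genotypes, x$r))
  cat(sprintf("  MS(G) = %.4g  MS(E) = %.4g  Vg = %.4g  Ve = %.4g\n",
              x$ms_g, x$ms_e, x$vg, x$ve))
  cat(sprintf("  H2indiv = %.3f  H2geno = %.3f%s\n", x$h2_indiv, x$h2_geno,
              if (x$truncated) "  [Vg truncated at 0]" else ""))
  invisible(x)
}

#' Line-level heritability implied by an individual-level heritability
#'
#' Inverts the repeatability relations: treating `H2indiv` as
#' `sigma2G/(sigma2G + sigma2E)` on an arbitrary common scale (e.g.
#' `sigma2G = H2indiv`, `sigma2E = 1 - H2indiv`), the heritability of the
#' genotype mean across `r` blocks is `sigma2G/(sigma2G + sigma2E/r)`.
#'
#' @param h2_indiv broad-sense heritability of single observations, in (0, 1).
#' @param r number of replicate blocks per genotype.
#' @return `H2geno`.
#' @export
h2_geno_from_indiv <- function(h2_indiv, r) {
  stopifnot(all(h2_indiv >= 0 & h2_indiv <= 1), r >= 1)
  vg <- h2_indiv
  ve <- 1 - h2_indiv
  vg / (vg + ve / r)
}

#' Heritability report for every trait in a phenotype table
#'
#' @param p phenotype data.frame.
#' @param path optional TSV output path.
#' @return data.frame with one row per trait: trait, ms_g, ms_e, vg, ve,
#'   h2_indiv, h2_geno.
#' @export
heritability_report <- function(p, path = NULL) {
  traits <- unique(p$trait)
  rows <- lapply(traits, function(tr) {
    h <- heritability_repeatability(p, tr)
    data.frame(trait = tr, ms_g = h$ms_g, ms_e = h$ms_e, vg = h$vg,
               ve = h$ve, h2_indiv = h$h2_indiv, h2_geno = h$h2_geno)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
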