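#' Construct a genotype matrix
#'
#' The central genotype container: a samples x variants dosage matrix of
#' minor-allele counts together with per-variant metadata. Dosages are 0, 1,
#' 2 or `NA` (missing); after mean imputation they may be fractional in
#' \[0, 2\]. Variants are kept sorted by `(chrom, pos)` and oriented so that
#' the `alt` field always holds the counted (panel-wide minor) allele.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}` (or fractional when `imputed = TRUE`).
#' @param chrom,pos,ref,alt per-variant chromosome label, 1-based bp
#'   position, and allele strings (one alt allele per variant).
#' @param sample_ids unique sample identifiers; defaults to rownames or
#'   `S1..Sn`.
#' @param imputed logical; `TRUE` only for matrices produced by
#'   [impute_mean()].
#' @param recode_minor if `TRUE` (default), columns whose counted-allele
#'   frequency exceeds 0.5 are flipped (`2 - dosage`) and their `ref`/`alt`
#'   labels swapped so dosage always counts the minor allele.
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `variants` (data.frame: chrom, pos, ref, alt, maf, missing_rate),
#'   `sample_ids`, `imputed`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, ref, alt,
                            sample_ids = NULL, imputed = FALSE,
                            recode_minor = TRUE) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  n <- nrow(dosages)
  if (n == 0L) stop("genotype matrix has zero samples")
  if (length(chrom) != m || length(pos) != m ||
      length(ref) != m || length(alt) != m)
    stop("variant metadata length does not match number of dosage columns")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (any(pos < 1)) stop("positions must be >= 1")
  bad <- dosages < 0 | dosages > 2
  if (any(bad, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  if (!imputed && any(!(dosages %in% c(0, 1, 2, NA))))
    stop("unimputed dosages must be 0, 1, 2 or NA")

  ord <- order(chrom, pos)
  dosages <- dosages[, ord, drop = FALSE]
  chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]

  af <- colMeans(dosages, na.rm = TRUE) / 2
  if (recode_minor) {
    flip <- !is.na(af) & af > 0.5
    if (any(flip)) {
      dosages[, flip] <- 2 - dosages[, flip, drop = FALSE]
      tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
      af[flip] <- 1 - af[flip]
    }
  }
  maf <- pmin(af, 1 - af)
  missing_rate <- colMeans(is.na(dosages))

  rownames(dosages) <- sample_ids
  colnames(dosages) <- variant_id(chrom, pos, ref, alt)
  structure(list(
    dosages = dosages,
    variants = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                          ref = as.character(ref), alt = as.character(alt),
                          maf = unname(maf), missing_rate = unname(missing_rate),
                          stringsAsFactors = FALSE),
    sample_ids = as.character(sample_ids),
    imputed = isTRUE(imputed)
  ), class = "genotype_matrix")
}

variant_id <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, "_", ref, "/", alt)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s)\n",
              length(x$sample_ids), nrow(x$variants),
              if (x$imputed) "imputed" else "raw"))
  cat(sprintf("  MAF range [%.3f, %.3f]; mean missing rate %.4f\n",
              min(x$variants$maf), max(x$variants$maf),
              mean(x$variants$missing_rate)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Load biallelic SNPs from a VCF file
#'
#' Reads a VCF (v4.x), keeps only biallelic SNP records (single-base REF and
#' ALT, exactly one ALT allele), converts GT calls to dosages and recodes so
#' that the counted allele is the panel-wide minor allele.
#'
#' @param path VCF file path (plain text or gzip).
#' @return a [genotype_matrix()].
#' @export
load_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF contains zero samples")
  keep <- grepl("^[ACGT]$", fix[, "REF"]) & grepl("^[ACGT]$", fix[, "ALT"])
  if (!any(keep)) stop("no biallelic SNP records in VCF")
  fix <- fix[keep, , drop = FALSE]
  gtm <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # count of the ALT allele per call; tolerate phased separators
  dose <- matrix(NA_real_, nrow = ncol(gtm), ncol = nrow(gtm))
  g <- gsub("\\|", "/", gtm)
  dose_t <- matrix(NA_real_, nrow = nrow(g), ncol = ncol(g))
  dose_t[g == "0/0"] <- 0
  dose_t[g == "0/1" | g == "1/0"] <- 1
  dose_t[g == "1/1"] <- 2
  dose <- t(dose_t)
  rownames(dose) <- colnames(gtm)
  genotype_matrix(dose,
                  chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  sample_ids = colnames(gtm))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a minimal VCF v4.2 with GT-only genotype fields. Dosages must be
#' unimputed (0/1/2/NA). Because the container orients `alt` as the counted
#' minor allele, `load_vcf(write_vcf(g))` reproduces the dosage matrix
#' exactly.
#'
#' @param g a [genotype_matrix()], not imputed.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$imputed) stop("cannot write fractional (imputed) dosages as VCF")
  v <- g$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- g$dosages
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  obs <- !is.na(d)
  gt[obs] <- gt_code[as.character(d[obs])]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=gwadl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(j) {
      paste(c(v$chrom[j], v$pos[j], variant_id(v$chrom[j], v$pos[j],
                                               v$ref[j], v$alt[j]),
              v$ref[j], v$alt[j], ".", "PASS", ".", "GT", gt[, j]),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Filter variants on missingness and minor-allele frequency
#'
#' Retains biallelic variants with `missing_rate < max_missing` and
#' `maf > min_maf` (strict inequalities). Idempotent; variant order is
#' preserved.
#'
#' @param g a [genotype_matrix()], not imputed.
#' @param max_missing maximum tolerated missing-call fraction (default 0.05).
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @return the filtered [genotype_matrix()].
#' @export
filter_variants <- function(g, max_missing = 0.05, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$imputed) stop("filter_variants() expects an unimputed genotype matrix")
  keep <- g$variants$missing_rate < max_missing & g$variants$maf > min_maf
  if (!any(keep)) stop("all variants removed by filtering: empty panel")
  subset_variants(g, which(keep))
}

subset_variants <- function(g, idx) {
  out <- g
  out$dosages <- g$dosages[, idx, drop = FALSE]
  out$variants <- g$variants[idx, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

#' Mean-impute missing dosages
#'
#' Replaces each missing dosage by the per-variant mean of the observed
#' dosages; observed cells are untouched. The per-variant mean is therefore
#' preserved exactly.
#'
#' @param g a filtered [genotype_matrix()].
#' @return the imputed [genotype_matrix()] (`imputed = TRUE`).
#' @export
impute_mean <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0L))
    stop("variant(s) with zero observed calls cannot be mean-imputed: ",
         paste(colnames(d)[n_obs == 0L], collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  miss <- which(is.na(d), arr.ind = TRUE)
  if (nrow(miss)) d[miss] <- mu[miss[, 2]]
  out <- g
  out$dosages <- d
  out$imputed <- TRUE
  out
}

#' Write / read the TSV dosage dialect
#'
#' Tab-separated dosage matrix: first column `sample_id`, remaining columns
#' named `chrom:pos_ref/alt`, missing encoded as `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param path file path.
#' @return `path` invisibly (write) or a [genotype_matrix()] (read).
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(sample_id = g$sample_ids, g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param imputed logical: whether the stored dosages are imputed
#'   (fractional values allowed).
#' @export
read_dosage_tsv <- function(path, imputed = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  d <- as.matrix(df[, -1, drop = FALSE])
  vn <- colnames(d)
  mt <- regmatches(vn, regexec("^([^:]+):([0-9]+)_([^/]+)/(.+)$", vn))
  if (any(lengths(mt) != 5L))
    stop("malformed variant id in dosage TSV header (expected chrom:pos_ref/alt)")
  meta <- do.call(rbind, mt)
  genotype_matrix(d, chrom = meta[, 2], pos = as.integer(meta[, 3]),
                  ref = meta[, 4], alt = meta[, 5], sample_ids = ids,
                  imputed = imputed, recode_minor = !imputed)
}

#' Write per-variant metadata TSV
#'
#' Columns: chrom, pos, ref, alt, maf, missing_rate.
#'
#' @param g a [genotype_matrix()].
#' @param path file path.
#' @export
write_variant_tsv <- function(g, path) {
  utils::write.table(g$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
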