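#' Default end-to-end run configuration
#'
#' Settings for [run_pipeline()]: either paths to genotype (VCF or dosage
#' TSV) and phenotype (long TSV) inputs, or a `sim_config` to generate a
#' synthetic study. The master seed deterministically derives every stage
#' seed, so a re-run with the same configuration reproduces all outputs.
#'
#' @param genotypes path to VCF/dosage TSV, or `NULL` to simulate.
#' @param phenotypes path to phenotype TSV, or `NULL` to simulate.
#' @param sim a [sim_config()] used when no input paths are given.
#' @param traits traits to analyze (`NULL` = all traits present).
#' @param max_missing,min_maf variant filter thresholds.
#' @param pcs number of principal-component covariates for the scan.
#' @param cutoff enrichment p-value cutoff (default 1e-4).
#' @param grid_n number of network configurations sampled from the full
#'   grid (`NULL` = the full 3,840).
#' @param folds cross-validation folds.
#' @param seed master seed.
#' @param scan_bin_sizes,scan_bin_counts,scan_max_iter multilocus-scan
#'   settings.
#' @param net_max_epochs cap on training epochs.
#' @return a `run_config` list.
#' @export
run_config <- function(genotypes = NULL, phenotypes = NULL,
                       sim = sim_config(), traits = NULL,
                       max_missing = 0.05, min_maf = 0.05, pcs = 2,
                       cutoff = 1e-4, grid_n = 12, folds = 5, seed = 1,
                       scan_bin_sizes = c(5e5, 5e6, 5e7),
                       scan_bin_counts = c(10, 50, 100),
                       scan_max_iter = 10, net_max_epochs = 200) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields of [run_config()] may be overridden from a YAML mapping; a
#' `sim:` mapping is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else sim_config()
  y$sim <- NULL
  do.call(run_config, c(y, list(sim = sim)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full enrichment-and-prediction pipeline
#'
#' Stages: (1) load or simulate genotypes and phenotypes; (2) filter and
#' mean-impute the panel; (3) Box-Cox-normalize each trait's genotype means
#' and estimate heritability from the replicated data; (4) multilocus
#' association scan with PCA covariates; (5) marker selection by p-value
#' enrichment and by genomic spacing (equal size); (6) cross-validated
#' GBLUP on both marker sets; (7) cross-validated GWADL network (grid
#' search) on both marker sets, Gedeon importance of the enriched model,
#' and the four-cell method comparison. All artifacts are written under
#' `out_dir` and listed, with MD5 hashes, in `manifest.json`.
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory.
#' @return the manifest (invisibly): list of stage outputs, file hashes and
#'   effective seeds.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed
  manifest <- list(seed = seed, stages = list())
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  ## stage 1: inputs
  inputs <- stage("inputs", {
    if (is.null(cfg$genotypes)) {
      sim <- simulate_study(cfg$sim, seed)
      paths <- export_fixture(sim$genotypes, sim$phenotypes, sim$truth,
                              file.path(out_dir, "sim"))
      for (p in paths) emit(p)
      list(g = sim$genotypes, ph = sim$phenotypes, truth = sim$truth)
    } else {
      g <- if (grepl("\\.vcf(\\.gz)?$", cfg$genotypes))
        load_vcf(cfg$genotypes) else read_dosage_tsv(cfg$genotypes)
      list(g = g, ph = read_phenotype_tsv(cfg$phenotypes), truth = NULL)
    }
  })
  g <- inputs$g
  ph <- inputs$ph
  manifest$stages$inputs <- list(
    n_samples = length(g$sample_ids), n_variants = nrow(g$variants))

  ## stage 2: filter + impute
  gi <- stage("panel", {
    gf <- filter_variants(g, cfg$max_missing, cfg$min_maf)
    emit(write_variant_tsv(gf, file.path(out_dir, "variants.tsv")))
    impute_mean(gf)
  })
  manifest$stages$panel <- list(n_variants = nrow(gi$variants))

  traits <- cfg$traits %||% unique(ph$trait)
  herit <- stage("heritability", {
    h <- heritability_report(ph, file.path(out_dir, "heritability.tsv"))
    emit(file.path(out_dir, "heritability.tsv"))
    h
  })
  manifest$stages$heritability <- herit

  cov <- stage("covariates", pca_covariates(gi, cfg$pcs))
  m <- ncol(gi$dosages)
  manifest$stages$scan <- list()
  manifest$stages$predict <- list()

  for (tr in traits) {
    y_mean <- genotype_means(ph, tr, gi$sample_ids)
    bc <- stage("boxcox", boxcox_search(y_mean))
    y <- bc$transformed
    scan <- stage("scan", multilocus_scan(
      gi, y, cov, max_iter = cfg$scan_max_iter,
      bin_sizes = cfg$scan_bin_sizes, bin_counts = cfg$scan_bin_counts))
    emit(write_scan_tsv(scan, gi, file.path(out_dir,
                                            paste0("scan_", tr, ".tsv"))))
    enr <- select_by_pvalue(scan, cfg$cutoff)
    n_sel <- max(length(enr$indices), 1L)
    spc <- select_spaced(m, n_sel)
    sel_path <- file.path(out_dir, paste0("selection_", tr, ".tsv"))
    utils::write.table(
      data.frame(index = c(enr$indices, spc$indices),
                 rule = rep(c("enriched", "spaced"),
                            c(length(enr$indices), length(spc$indices)))),
      sel_path, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(sel_path)
    manifest$stages$scan[[tr]] <- list(
      lambda = bc$lambda, n_pseudo_qtns = length(scan$pseudo_qtns),
      n_enriched = length(enr$indices),
      bonferroni = bonferroni_threshold(m))

    res <- list()
    if (length(enr$indices) >= 2) {
      res$gblup_enriched <- stage("gblup",
        crossval_gblup(gi, y, enr$indices, cfg$folds, seed))
      grid <- if (is.null(cfg$grid_n)) full_grid() else
        sample_grid(cfg$grid_n, seed = seed)
      Xe <- gi$dosages[, enr$indices, drop = FALSE]
      gs <- stage("gwadl", grid_search(Xe, y, grid, cfg$folds, seed,
                                       max_epochs = cfg$net_max_epochs))
      res$gwadl_enriched <- crossval_gwadl(Xe, y, gs$best, cfg$folds, seed)
      net <- stage("importance", train_network(Xe, y, gs$best))
      imp <- gedeon_importance(net)
      emit(write_importance_tsv(
        imp, file.path(out_dir, paste0("importance_", tr, ".tsv")),
        significant = scan$p_value[enr$indices] <
          bonferroni_threshold(m)))
    }
    res$gblup_spaced <- stage("gblup",
      crossval_gblup(gi, y, spc$indices, cfg$folds, seed))
    Xs <- gi$dosages[, spc$indices, drop = FALSE]
    grid <- if (is.null(cfg$grid_n)) full_grid() else
      sample_grid(cfg$grid_n, seed = seed)
    gss <- stage("gwadl", grid_search(Xs, y, grid, cfg$folds, seed,
                                      max_epochs = cfg$net_max_epochs))
    res$gwadl_spaced <- crossval_gwadl(Xs, y, gss$best, cfg$folds, seed)

    for (nm in names(res))
      emit(write_predictions_tsv(res[[nm]], file.path(
        out_dir, paste0("pred_", tr, "_", nm, ".tsv"))))
    h2g <- herit$h2_geno[herit$trait == tr][1]
    cmp <- stage("evaluate", compare_methods(
      res, h2_geno = if (is.finite(h2g) && h2g > 0) h2g else NULL))
    emit(write_comparison_tsv(cmp, file.path(out_dir,
                                             paste0("compare_", tr, ".tsv"))))
    manifest$stages$predict[[tr]] <- list(
      cells = stats::setNames(vapply(res, function(x) x$r2_mean, numeric(1)),
                              names(res)),
      groups = stats::setNames(cmp$summary$group, cmp$summary$cell))
  }

  manifest$files <- data.frame(
    file = basename(written),
    md5 = unname(tools::md5sum(written)))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
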