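## End-to-end pipeline: QC -> encoding -> cross-validated forward
## selection -> best-model choice -> report bundle, all driven by one
## configuration object and one seed, with a JSON run manifest so every
## number is recomputable.

#' Pipeline run configuration
#'
#' @param mode analysis mode: `"snp"`, `"ge"` or `"snp+ge"`
#' @param genotypes path to a genotype TSV/VCF, or a [genotype_matrix()]
#' @param expression path to an expression TSV, or an
#'   [expression_matrix()]
#' @param labels path to a labels TSV, or a [population_labels()]
#' @param marker_annotation optional path/data frame with `marker_id`,
#'   `chrom` (needed for the sex-chromosome SNP rule when the genotype
#'   source carries no chromosome)
#' @param probe_annotation optional path/data frame of probe annotation
#' @param populations optional subset of population labels to analyse
#' @param qc a [snp_qc_config()]
#' @param selection a [selection_config()]
#' @param folds number of cross-validation folds (default 10)
#' @param seed master seed for partitioning and QC permutations
#' @param out_dir optional output directory for the report tables
#' @param plots also render PDF plots into `out_dir` (default `FALSE`)
#' @return a `run_config`
#' @export
run_config <- function(mode = c("snp+ge", "snp", "ge"), genotypes = NULL,
                       expression = NULL, labels, marker_annotation = NULL,
                       probe_annotation = NULL, populations = NULL,
                       qc = NULL, selection = selection_config(),
                       folds = 10, seed = 1L, out_dir = NULL, plots = FALSE) {
  mode <- match.arg(mode)
  if (mode %in% c("snp", "snp+ge") && is.null(genotypes))
    stop("mode '", mode, "' requires genotype input")
  if (mode %in% c("ge", "snp+ge") && is.null(expression))
    stop("mode '", mode, "' requires expression input")
  if (is.null(qc)) qc <- snp_qc_config(seed = seed)
  structure(list(mode = mode, genotypes = genotypes, expression = expression,
                 labels = labels, marker_annotation = marker_annotation,
                 probe_annotation = probe_annotation,
                 populations = populations, qc = qc, selection = selection,
                 folds = as.integer(folds), seed = as.integer(seed),
                 out_dir = out_dir, plots = isTRUE(plots)),
            class = "run_config")
}

.load_genotypes <- function(x, annotation = NULL) {
  if (inherits(x, "genotype_matrix")) return(x)
  if (grepl("\\.vcf(\\.gz)?$", x)) read_genotypes_vcf(x)
  else read_genotypes_tabular(x, annotation = annotation)
}

.load_expression <- function(x, annotation = NULL) {
  if (inherits(x, "expression_matrix")) {
    if (!is.null(annotation))
      x <- set_probe_annotation(x, if (is.character(annotation))
        read_probe_annotation(annotation) else annotation)
    return(x)
  }
  read_expression(x, annotation = annotation)
}

#' Run the full selection pipeline
#'
#' Reads (or accepts) the inputs, restricts to the requested population
#' combination, applies SNP and probe QC, runs the cross-validated
#' forward selection, picks the best model, and assembles the report
#' bundle.  When `cfg$out_dir` is set, all tables are written as TSV,
#' the best model as a plain-text model file, and a JSON manifest
#' recording configuration, seed and package version alongside.
#'
#' @param cfg a [run_config()]
#' @return a `report_bundle`: list with `models`
#'   (the `candidate_model_set`), `best_model`, `qc_snp`, `qc_probe`,
#'   `overlay`, `parallel`, `selection_report`, `selection_times`,
#'   `marker_impact`, `misclassification`, `mds`,
#'   `genotype_frequencies`, `expression_summary`, `manifest`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  labels <- if (inherits(cfg$labels, "population_labels")) cfg$labels
            else read_labels(cfg$labels)
  g <- e <- NULL
  if (cfg$mode %in% c("snp", "snp+ge"))
    g <- .load_genotypes(cfg$genotypes, cfg$marker_annotation)
  if (cfg$mode %in% c("ge", "snp+ge"))
    e <- .load_expression(cfg$expression, cfg$probe_annotation)
  al <- align_samples(labels, g = g, e = e, populations = cfg$populations)
  g <- al$genotypes; e <- al$expression; labels <- al$labels

  qc_snp <- qc_probe <- NULL
  if (!is.null(g)) {
    res <- filter_snps(g, cfg$qc)
    g <- res$genotypes; qc_snp <- res$report
    if (!length(g$marker_ids)) stop("no SNP marker survived QC")
  }
  if (!is.null(e)) {
    res <- filter_probes(e)
    e <- res$expression; qc_probe <- res$report
    if (!length(e$probe_ids)) stop("no expression probe survived QC")
  }

  cv <- make_cv_partition(labels, k = cfg$folds, seed = cfg$seed)
  models <- run_cross_validation(g, e, labels, cv, cfg$selection)
  best <- models$best

  all_x <- encode_features(g, e, impute_from = best$model)
  sel <- best$trace$markers
  mds <- mds_coordinates(all_x, markers = sel)
  sel_snps <- sel[best$trace$steps$type == "snp"]
  sel_ge <- sel[best$trace$steps$type == "ge"]
  geno_freq <- NULL
  if (length(sel_snps) > 0) {
    singles <- lapply(sel_snps, function(mk)
      data.frame(marker = mk, genotype_frequency_report(mk, g, labels),
                 check.names = FALSE))
    geno_freq <- do.call(rbind, lapply(singles, function(d) {
      names(d) <- c("marker", "population", "AA", "AB", "BB"); d
    }))
  }
  expr_sum <- if (length(sel_ge) > 0)
    expression_summary_report(sel_ge, e, labels) else NULL

  manifest <- list(
    package = "aimsel",
    version = as.character(utils::packageVersion("aimsel")),
    mode = cfg$mode, folds = cfg$folds, seed = cfg$seed,
    populations = sort(unique(labels$label)),
    n_samples = length(labels$sample_ids),
    qc = unclass(cfg$qc),
    selection = unclass(cfg$selection)[c("max_markers", "target_accuracy",
                                         "min_increment")],
    best_fold = models$best_fold,
    best_markers = sel,
    best_testing_accuracy = best$testing_accuracy,
    model_cvc = models$model_cvc)

  bundle <- structure(list(models = models, best_model = best$model,
                           qc_snp = qc_snp, qc_probe = qc_probe,
                           overlay = accuracy_overlay_table(models),
                           parallel = parallel_coordinates_table(models),
                           selection_report = models$selection_report,
                           selection_times = models$selection_times,
                           marker_impact = marker_impact_report(models),
                           misclassification = misclassification_report(models),
                           mds = mds, genotype_frequencies = geno_freq,
                           expression_summary = expr_sum,
                           manifest = manifest),
                      class = "report_bundle")
  if (!is.null(cfg$out_dir)) write_report_bundle(bundle, cfg$out_dir,
                                                 plots = cfg$plots)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  cat(sprintf("  best fold %d: %d marker(s) [%s], testing accuracy %.3f, CVC %d\n",
              x$manifest$best_fold, length(x$manifest$best_markers),
              paste(x$manifest$best_markers, collapse = ", "),
              x$manifest$best_testing_accuracy, x$manifest$model_cvc))
  cat(sprintf("  mean testing accuracy over folds: %.3f\n",
              mean(x$parallel$test_accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' @param bundle a `report_bundle`
#' @param out_dir output directory (created if needed)
#' @param plots also render PDF plots (default `FALSE`)
#' @return `out_dir`, invisibly
#' @export
write_report_bundle <- function(bundle, out_dir, plots = FALSE) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  tsv <- function(d, f) if (!is.null(d))
    write.table(d, pth(f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(bundle$overlay, "selection_trace.tsv")
  tsv(bundle$parallel, "candidate_models.tsv")
  tsv(bundle$selection_report, "selection_report.tsv")
  tsv(data.frame(marker = names(bundle$selection_times),
                 selection_times = as.integer(bundle$selection_times)),
      "selection_times.tsv")
  tsv(bundle$marker_impact, "marker_impact.tsv")
  tsv(bundle$misclassification, "misclassification.tsv")
  tsv(data.frame(sample_id = rownames(bundle$mds), bundle$mds),
      "mds_coordinates.tsv")
  tsv(bundle$genotype_frequencies, "genotype_frequencies.tsv")
  tsv(bundle$expression_summary, "expression_summary.tsv")
  if (!is.null(bundle$qc_snp)) write_qc_report(bundle$qc_snp, pth("qc_snp.tsv"))
  if (!is.null(bundle$qc_probe))
    write_qc_report(bundle$qc_probe, pth("qc_probe.tsv"))
  write_fda_model(bundle$best_model, pth("best_model.txt"))
  jsonlite::write_json(bundle$manifest, pth("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plots) {
    grDevices::pdf(pth("plots.pdf"), width = 8, height = 6)
    on.exit(grDevices::dev.off())
    plot_accuracy_overlay(bundle$models)
    lab <- population_labels(rownames(bundle$mds),
                             bundle$misclassification$label[
                               match(rownames(bundle$mds),
                                     bundle$misclassification$sample_id)])
    plot_mds(bundle$mds, lab)
  }
  invisible(out_dir)
}
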