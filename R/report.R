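## Tabular reports mirroring the classical graphical outputs: accuracy
## overlay, parallel coordinates, MDS of samples on the selected panel,
## marker distributions, per-sample misclassification and marker impact.
## Tables are the contract; plots are best-effort renderings.

#' Per-step accuracy overlay table
#'
#' One row per fold and selection step with the training accuracy after
#' the step and the testing accuracy of the model truncated at that step.
#'
#' @param c a `candidate_model_set` from [run_cross_validation()]
#' @return data frame (fold, step, marker, type, train_accuracy,
#'   test_accuracy)
#' @export
accuracy_overlay_table <- function(c) {
  stopifnot(inherits(c, "candidate_model_set"))
  do.call(rbind, lapply(c$folds, function(f) {
    st <- f$trace$steps
    data.frame(fold = f$fold, st,
               test_accuracy = if (length(f$test_accuracy_by_step))
                 f$test_accuracy_by_step else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Parallel-coordinates table
#'
#' One row per fold: panel size, final training accuracy, testing
#' accuracy.
#'
#' @param c a `candidate_model_set`
#' @return data frame
#' @export
parallel_coordinates_table <- function(c) {
  stopifnot(inherits(c, "candidate_model_set"))
  data.frame(fold = vapply(c$folds, `[[`, integer(1), "fold"),
             n_markers = vapply(c$folds, function(f) length(f$trace$markers),
                                integer(1)),
             train_accuracy = vapply(c$folds, function(f)
               f$trace$final_accuracy, numeric(1)),
             test_accuracy = vapply(c$folds, `[[`, numeric(1),
                                    "testing_accuracy"))
}

#' Per-sample misclassification report
#'
#' For every sample: the proportion of folds in which it was
#' misclassified while a test sample and while a training sample.  The
#' attribute `"per_step"` carries the per-fold, per-step aggregate
#' training misclassification (1 - training accuracy after each step).
#'
#' @param c a `candidate_model_set`
#' @return data frame (sample_id, label, n_test, test_misclassification,
#'   n_train, train_misclassification)
#' @export
misclassification_report <- function(c) {
  stopifnot(inherits(c, "candidate_model_set"))
  ids <- unique(unlist(lapply(c$folds, function(f) c(f$train_ids, f$test_ids))))
  tally <- data.frame(sample_id = ids, n_test = 0L, test_errors = 0L,
                      n_train = 0L, train_errors = 0L,
                      stringsAsFactors = FALSE)
  rownames(tally) <- ids
  lab <- rep(NA_character_, length(ids)); names(lab) <- ids
  add <- function(res, which) {
    wrong <- res$predicted_label != res$true_label
    lab[res$sample_ids] <<- res$true_label
    tally[res$sample_ids, paste0("n_", which)] <<-
      tally[res$sample_ids, paste0("n_", which)] + 1L
    tally[res$sample_ids, paste0(which, "_errors")] <<-
      tally[res$sample_ids, paste0(which, "_errors")] + as.integer(wrong)
  }
  for (f in c$folds) {
    add(f$train_result, "train")
    if (!is.null(f$test_result)) add(f$test_result, "test")
  }
  out <- data.frame(sample_id = ids, label = unname(lab[ids]),
                    n_test = tally$n_test,
                    test_misclassification = ifelse(tally$n_test > 0,
                                                    tally$test_errors / tally$n_test, NA),
                    n_train = tally$n_train,
                    train_misclassification = ifelse(tally$n_train > 0,
                                                     tally$train_errors / tally$n_train, NA),
                    stringsAsFactors = FALSE)
  per_step <- do.call(rbind, lapply(c$folds, function(f)
    data.frame(fold = f$fold, step = f$trace$steps$step,
               train_misclassification = 1 - f$trace$steps$train_accuracy)))
  attr(out, "per_step") <- per_step
  out
}

#' Marker impact report
#'
#' One row per marker that was selected in at least one fold: how many
#' folds selected it and at which step.
#'
#' @param c a `candidate_model_set`
#' @return data frame (marker, type, selection_times, folds, steps)
#' @export
marker_impact_report <- function(c) {
  stopifnot(inherits(c, "candidate_model_set"))
  rows <- do.call(rbind, lapply(c$folds, function(f)
    data.frame(fold = f$fold, f$trace$steps, stringsAsFactors = FALSE)))
  if (is.null(rows) || !nrow(rows))
    return(data.frame(marker = character(0), type = character(0),
                      selection_times = integer(0), folds = character(0),
                      steps = character(0)))
  sp <- split(rows, rows$marker)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(marker = d$marker[1L], type = d$type[1L],
               selection_times = nrow(d),
               folds = paste(d$fold, collapse = ","),
               steps = paste(d$step, collapse = ","),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$selection_times, out$marker), ]
  rownames(out) <- NULL
  out
}

#' Genotype frequencies of selected SNPs per population
#'
#' Single-SNP mode gives the AA/AB/BB frequencies per population (rows
#' sum to 1 over non-missing calls); pair mode gives the frequencies of
#' the nine genotype combinations of a SNP pair.
#'
#' @param markers character vector of SNP marker ids (1 for single mode,
#'   2 for pair mode)
#' @param g a [genotype_matrix()]
#' @param labels a [population_labels()]
#' @return data frame, one row per population
#' @export
genotype_frequency_report <- function(markers, g, labels) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(labels, "population_labels"))
  if (!all(markers %in% g$marker_ids))
    stop("unknown marker(s): ",
         paste(setdiff(markers, g$marker_ids), collapse = ", "))
  if (!length(markers) %in% 1:2)
    stop("supply one SNP (single mode) or two SNPs (pair mode)")
  pops <- sort(unique(labels$label))
  ids <- intersect(g$sample_ids, labels$sample_ids)
  lv <- c("AA", "AB", "BB")
  if (length(markers) == 1L) {
    combos <- lv
    obs <- function(rows) g$calls[rows, markers]
  } else {
    combos <- as.vector(outer(lv, lv, function(a, b) paste0(a, "/", b)))
    obs <- function(rows) {
      a <- g$calls[rows, markers[1L]]; b <- g$calls[rows, markers[2L]]
      ifelse(is.na(a) | is.na(b), NA, paste0(a, "/", b))
    }
  }
  out <- t(vapply(pops, function(p) {
    rows <- ids[labels$label[ids] == p]
    v <- obs(rows)
    v <- v[!is.na(v)]
    tab <- table(factor(v, levels = combos))
    if (sum(tab) == 0) rep(NA_real_, length(combos)) else
      as.numeric(tab) / sum(tab)
  }, numeric(length(combos))))
  colnames(out) <- combos
  data.frame(population = pops, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Per-population summary of selected expression probes
#'
#' @param probes character vector of probe ids
#' @param e an [expression_matrix()]
#' @param labels a [population_labels()]
#' @return data frame (probe_id, population, mean, sd, n)
#' @export
expression_summary_report <- function(probes, e, labels) {
  stopifnot(inherits(e, "expression_matrix"))
  if (!all(probes %in% e$probe_ids))
    stop("unknown probe(s): ", paste(setdiff(probes, e$probe_ids), collapse = ", "))
  pops <- sort(unique(labels$label))
  ids <- intersect(e$sample_ids, labels$sample_ids)
  do.call(rbind, lapply(probes, function(pr)
    do.call(rbind, lapply(pops, function(p) {
      v <- e$values[ids[labels$label[ids] == p], pr]
      data.frame(probe_id = pr, population = p, mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v, na.rm = TRUE), n = sum(!is.na(v)),
                 stringsAsFactors = FALSE)
    }))))
}

#' Classical MDS coordinates of samples on selected markers
#'
#' Torgerson (classical) multidimensional scaling of the Euclidean
#' distances between samples over the selected markers, each feature
#' standardized to unit variance first (mixed 0-2 genotype and arbitrary
#' intensity scales would otherwise weight unevenly).  Signs are fixed
#' so the first nonzero entry of each axis is positive.
#'
#' @param x a `feature_matrix` restricted (or restrictable) to the
#'   selected markers
#' @param markers optional character vector selecting features of `x`
#' @return numeric matrix, samples x 2 (second axis zero-filled when the
#'   configuration is one-dimensional)
#' @export
mds_coordinates <- function(x, markers = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  if (!is.null(markers)) x <- .subset_features(x, markers)
  v <- x$values
  if (nrow(v) < 2) stop("at least two samples required")
  sds <- apply(v, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    warning("all selected features are constant; returning zero coordinates")
    out <- matrix(0, nrow(v), 2, dimnames = list(rownames(v), c("MDS1", "MDS2")))
    return(out)
  }
  z <- scale(v[, keep, drop = FALSE])
  d <- dist(z)
  ndim <- min(2L, nrow(v) - 1L)
  co <- cmdscale(d, k = ndim)
  if (is.null(dim(co))) co <- matrix(co, ncol = 1L)
  if (ncol(co) < 2) co <- cbind(co, 0)
  for (j in 1:2) {
    nz <- which(abs(co[, j]) > 1e-12)
    if (length(nz) && co[nz[1L], j] < 0) co[, j] <- -co[, j]
  }
  dimnames(co) <- list(rownames(v), c("MDS1", "MDS2"))
  co
}

## ---- optional plots ---------------------------------------------------

#' Overlay line plot of training/testing accuracy by step
#' @param c a `candidate_model_set`
#' @return `NULL`, invisibly (draws on the active device)
#' @export
plot_accuracy_overlay <- function(c) {
  tab <- accuracy_overlay_table(c)
  graphics::plot(NULL, xlim = range(tab$step), ylim = c(0, 1),
                 xlab = "markers in model", ylab = "accuracy",
                 main = "training (solid) / testing (dashed) accuracy")
  for (f in unique(tab$fold)) {
    d <- tab[tab$fold == f, ]
    graphics::lines(d$step, d$train_accuracy, col = f, lty = 1)
    if (!all(is.na(d$test_accuracy)))
      graphics::lines(d$step, d$test_accuracy, col = f, lty = 2)
  }
  invisible(NULL)
}

#' Scatter plot of MDS sample coordinates
#' @param co coordinates from [mds_coordinates()]
#' @param labels a [population_labels()]
#' @return `NULL`, invisibly
#' @export
plot_mds <- function(co, labels) {
  lab <- labels$label[rownames(co)]
  pops <- sort(unique(lab))
  graphics::plot(co, col = match(lab, pops), pch = match(lab, pops),
                 xlab = "MDS1", ylab = "MDS2", main = "samples on selected panel")
  graphics::legend("topright", legend = pops, col = seq_along(pops),
                   pch = seq_along(pops), bty = "n")
  invisible(NULL)
}
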