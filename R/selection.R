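## Forward stepwise marker selection under stratified k-fold
## cross-validation.
##
## Per fold: fit FDA for the current marker set plus each candidate,
## add the candidate with the largest training accuracy (ties broken by
## the candidate's own univariate SSW/SSB ratio, then lexicographic
## marker id), and stop when the training accuracy reaches the target,
## the increment falls below the threshold, or the marker cap is hit.
## Testing accuracy never influences selection; it only ranks the k
## candidate models afterwards.

#' Stratified cross-validation partition
#'
#' Samples are partitioned within each population so fold sizes per
#' population differ by at most one; populations smaller than `k`
#' spread their samples over distinct folds.
#'
#' @param labels a [population_labels()]
#' @param k number of folds (default 10)
#' @param seed integer seed; identical seeds give identical partitions
#' @return a `cv_partition`: list with `fold` (named integer vector in
#'   `1..k`), `k`, `seed`
#' @export
make_cv_partition <- function(labels, k = 10, seed = 1L) {
  stopifnot(inherits(labels, "population_labels"))
  if (k < 2) stop("k >= 2 required")
  k <- as.integer(k)
  fold <- integer(length(labels$sample_ids))
  names(fold) <- labels$sample_ids
  .with_seed(seed, {
    for (pop in sort(unique(labels$label))) {
      ids <- labels$sample_ids[labels$label == pop]
      ## cycle a random fold order, then shuffle across the samples:
      ## per-population fold counts differ by at most 1
      assign <- rep_len(sample.int(k), length(ids))
      fold[ids] <- assign[sample.int(length(ids))]
    }
  })
  structure(list(fold = fold, k = k, seed = as.integer(seed)),
            class = "cv_partition")
}

#' Forward-selection configuration
#'
#' The three stopping modes can be combined; selection halts as soon as
#' any of them triggers.
#'
#' @param max_markers optional cap on the number of selected markers
#'   (`Inf` = no cap)
#' @param target_accuracy stop once training accuracy reaches this value
#'   (default 1.0)
#' @param min_increment stop when the best candidate improves training
#'   accuracy by less than this (default 0.001); the offending candidate
#'   is not added.  The first marker is always added, measured against
#'   the majority-class baseline.
#' @param prescreen optional cap: keep only the top `prescreen`
#'   candidates by univariate SSB/SSW before the stepwise loop (for
#'   genome-scale pools; `NULL` = off)
#' @return a `selection_config`
#' @export
selection_config <- function(max_markers = Inf, target_accuracy = 1.0,
                             min_increment = 0.001, prescreen = NULL) {
  stopifnot(min_increment > 0, min_increment <= 1,
            target_accuracy > 0, target_accuracy <= 1,
            is.infinite(max_markers) || max_markers >= 1)
  structure(list(max_markers = max_markers,
                 target_accuracy = target_accuracy,
                 min_increment = min_increment,
                 prescreen = prescreen),
            class = "selection_config")
}

#' Forward stepwise marker selection on a training set
#'
#' @param train a `feature_matrix` of the (QC-filtered, encoded)
#'   training samples
#' @param labels a [population_labels()] covering the training samples
#' @param cfg a [selection_config()]
#' @param ridge ridge passed to the FDA fits
#' @return a `selection_trace`: data frame `steps` (step, marker, type,
#'   train_accuracy, ssw_ssb) plus `markers`, `final_accuracy`,
#'   `baseline_accuracy`
#' @export
forward_select <- function(train, labels, cfg = selection_config(),
                           ridge = 1e-8) {
  stopifnot(inherits(train, "feature_matrix"),
            inherits(cfg, "selection_config"))
  y <- labels$label[train$sample_ids]
  if (anyNA(y)) stop("unlabeled training sample")
  class_labels <- sort(unique(y))
  k <- length(class_labels)
  n <- length(y)
  yind <- matrix(0, n, k)
  yind[cbind(seq_len(n), match(y, class_labels))] <- 1
  prop <- colMeans(yind)
  baseline <- max(prop)

  vals <- train$values
  cand <- colnames(vals)
  if (length(cand) < 1) stop("at least one candidate marker required")
  ratio <- vapply(cand, function(id) ssw_ssb(vals[, id], y), numeric(1))
  if (!is.null(cfg$prescreen) && length(cand) > cfg$prescreen)
    cand <- cand[order(ratio[cand])][seq_len(cfg$prescreen)]

  acc_of <- function(ids) {
    core <- .fda_core(vals[, ids, drop = FALSE], yind, prop, ridge = ridge)
    if (core$degenerate) return(baseline)
    pred <- .fda_classify(core$eta, core$centroids, core$dim_weights,
                          class_labels)
    mean(pred == y)
  }

  selected <- character(0)
  acc_hist <- numeric(0)
  cur_acc <- baseline
  repeat {
    pool <- setdiff(cand, selected)
    if (!length(pool)) break
    accs <- vapply(pool, function(id) acc_of(c(selected, id)), numeric(1))
    best_acc <- max(accs)
    tied <- pool[accs >= best_acc - 1e-12]
    if (length(tied) > 1) {
      r <- ratio[tied]
      tied <- tied[r <= min(r) + 1e-12]
      if (length(tied) > 1) tied <- sort(tied)
    }
    pick <- tied[1L]
    increment <- best_acc - cur_acc
    if (length(selected) > 0 && increment < cfg$min_increment) break
    selected <- c(selected, pick)
    cur_acc <- best_acc
    acc_hist <- c(acc_hist, cur_acc)
    if (cur_acc >= cfg$target_accuracy) break
    if (length(selected) >= cfg$max_markers) break
  }
  steps <- data.frame(step = seq_along(selected), marker = selected,
                      type = unname(train$feature_type[selected]),
                      train_accuracy = acc_hist,
                      ssw_ssb = unname(ratio[selected]),
                      stringsAsFactors = FALSE)
  structure(list(steps = steps, markers = selected,
                 final_accuracy = cur_acc, baseline_accuracy = baseline),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: %d marker(s), training accuracy %.3f\n",
              length(x$markers), x$final_accuracy))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Run the cross-validated selection procedure
#'
#' For each fold: encode the training samples, run [forward_select()],
#' fit the final model, and score the held-out fold.  The result pools
#' the per-fold traces with marker selection counts and cross-validation
#' consistency, and designates the best model via [select_best_model()].
#'
#' @param g optional QC-filtered [genotype_matrix()]
#' @param e optional QC-filtered [expression_matrix()]
#' @param labels a [population_labels()]
#' @param cv a [make_cv_partition()]
#' @param cfg a [selection_config()]
#' @param ridge ridge passed to the FDA fits
#' @return a `candidate_model_set`: per-fold list `folds` (each with
#'   `trace`, `model`, `testing_accuracy`, `test_accuracy_by_step`,
#'   `train_result`, `test_result`), `selection_times`, `cvc`,
#'   `best_fold`, `best`, `selection_report`
#' @export
run_cross_validation <- function(g = NULL, e = NULL, labels, cv,
                                 cfg = selection_config(), ridge = 1e-8) {
  stopifnot(inherits(cv, "cv_partition"), inherits(labels, "population_labels"))
  sample_ids <- labels$sample_ids
  folds <- vector("list", cv$k)
  subset_g <- function(ids) if (is.null(g)) NULL else
    genotype_matrix(g$calls[ids, , drop = FALSE], chrom = g$chrom)
  subset_e <- function(ids) if (is.null(e)) NULL else {
    em <- expression_matrix(e$values[ids, , drop = FALSE])
    em$probe_annotation <- e$probe_annotation
    em
  }
  for (i in seq_len(cv$k)) {
    test_ids <- sample_ids[cv$fold[sample_ids] == i]
    train_ids <- setdiff(sample_ids, test_ids)
    train_x <- encode_features(subset_g(train_ids), subset_e(train_ids))
    trace <- forward_select(train_x, labels, cfg, ridge = ridge)
    sel <- trace$markers
    train_sel <- .subset_features(train_x, sel)
    model <- fit_fda(train_sel, labels, ridge = ridge)
    train_res <- predict(model, train_sel, labels = labels)
    test_res <- NULL; test_acc <- NA_real_; by_step <- numeric(0)
    if (length(test_ids)) {
      test_x <- encode_features(subset_g(test_ids), subset_e(test_ids),
                                impute_from = model)
      test_res <- predict(model, test_x, labels = labels)
      test_acc <- test_res$accuracy
      by_step <- vapply(seq_along(sel), function(s) {
        msub <- fit_fda(.subset_features(train_x, sel[seq_len(s)]), labels,
                        ridge = ridge)
        predict(msub, test_x, labels = labels)$accuracy
      }, numeric(1))
    }
    folds[[i]] <- list(fold = i, trace = trace, model = model,
                       train_ids = train_ids, test_ids = test_ids,
                       testing_accuracy = test_acc,
                       test_accuracy_by_step = by_step,
                       train_result = train_res, test_result = test_res)
  }
  all_sel <- lapply(folds, function(f) f$trace$markers)
  sel_tab <- table(unlist(all_sel))
  sets <- vapply(all_sel, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  cvc <- vapply(sets, function(s) sum(sets == s), integer(1))
  out <- structure(list(folds = folds, k = cv$k,
                        selection_times = sel_tab, cvc = unname(cvc)),
                   class = "candidate_model_set")
  best <- select_best_model(out)
  out$best_fold <- best$best_fold
  out$best <- out$folds[[best$best_fold]]
  out$model_cvc <- out$cvc[best$best_fold]
  out$selection_report <- best$report
  out
}

.subset_features <- function(x, ids) {
  structure(list(values = x$values[, ids, drop = FALSE],
                 feature_ids = ids,
                 feature_type = x$feature_type[ids],
                 sample_ids = x$sample_ids,
                 imputation_values = x$imputation_values[ids]),
            class = "feature_matrix")
}

#' @export
print.candidate_model_set <- function(x, ...) {
  cat(sprintf("candidate_model_set: %d folds, best fold %d (testing accuracy %.3f, %d markers, CVC %d)\n",
              x$k, x$best_fold, x$best$testing_accuracy,
              length(x$best$trace$markers), x$model_cvc))
  invisible(x)
}

#' Choose the best candidate model across folds
#'
#' Ranking: highest testing accuracy; then fewest markers; then highest
#' cross-validation consistency of the trace's marker set (number of
#' folds selecting exactly that set); then lowest fold index.
#'
#' @param c a `candidate_model_set`
#' @return list with `best_fold` and `report` (one row per fold with all
#'   ranking criteria)
#' @export
select_best_model <- function(c) {
  stopifnot(inherits(c, "candidate_model_set"))
  if (!length(c$folds)) stop("empty candidate model set")
  rep_df <- data.frame(
    fold = vapply(c$folds, `[[`, integer(1), "fold"),
    testing_accuracy = vapply(c$folds, `[[`, numeric(1), "testing_accuracy"),
    n_markers = vapply(c$folds, function(f) length(f$trace$markers), integer(1)),
    cvc = c$cvc,
    training_accuracy = vapply(c$folds, function(f) f$trace$final_accuracy,
                               numeric(1)),
    markers = vapply(c$folds, function(f) paste(f$trace$markers, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  ord <- order(-rep_df$testing_accuracy, rep_df$n_markers, -rep_df$cvc,
               rep_df$fold)
  list(best_fold = rep_df$fold[ord[1L]], report = rep_df)
}
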