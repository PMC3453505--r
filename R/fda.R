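## Flexible discriminant analysis by optimal scoring, linear basis.
##
## The class-indicator matrix Y (n x K) is regressed on the centered
## feature matrix (with a small ridge on the Gram matrix); the optimal
## scores are the eigenvectors of D^{-1/2} (Y'Yhat/n) D^{-1/2}, where D
## holds the class proportions.  With a linear basis this reproduces
## linear discriminant analysis: classifying by the weighted squared
## distance to class centroids in the discriminant space, with
## coordinate weights 1 / (a^2 (1 - a^2)) for eigenvalue a^2, equals the
## Mahalanobis nearest-mean rule up to a class-independent term.

#' Encode genotype and expression features into a numeric matrix
#'
#' SNP calls map additively to the count of the B allele
#' (`AA` -> 0, `AB` -> 1, `BB` -> 2); missing calls are imputed with the
#' per-feature training mean (taken from `impute_from` when encoding
#' test samples).  Expression intensities pass through unchanged, with
#' missing values mean-imputed the same way.
#'
#' @param g optional [genotype_matrix()] (already QC-filtered)
#' @param e optional [expression_matrix()] (already QC-filtered)
#' @param impute_from optional fitted [fit_fda()] model supplying
#'   imputation means (test-time encoding); the default imputes from the
#'   data itself (training-time encoding)
#' @return a `feature_matrix`: list with `values` (samples x features),
#'   `feature_ids`, `feature_type` (`"snp"`/`"ge"`), `sample_ids`,
#'   `imputation_values`
#' @export
encode_features <- function(g = NULL, e = NULL, impute_from = NULL) {
  if (is.null(g) && is.null(e)) stop("supply at least one of `g`, `e`")
  blocks <- list(); types <- character(0)
  if (!is.null(g)) {
    stopifnot(inherits(g, "genotype_matrix"))
    num <- matrix(NA_real_, nrow(g$calls), ncol(g$calls),
                  dimnames = dimnames(g$calls))
    num[g$calls == "AA"] <- 0
    num[g$calls == "AB"] <- 1
    num[g$calls == "BB"] <- 2
    blocks <- c(blocks, list(num))
    types <- c(types, rep("snp", ncol(num)))
  }
  if (!is.null(e)) {
    stopifnot(inherits(e, "expression_matrix"))
    if (!is.null(g) && !identical(g$sample_ids, e$sample_ids))
      stop("genotype and expression sample sets are not aligned")
    blocks <- c(blocks, list(e$values))
    types <- c(types, rep("ge", ncol(e$values)))
  }
  values <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids across inputs")
  names(types) <- colnames(values)
  if (is.null(impute_from)) {
    imp <- colMeans(values, na.rm = TRUE)
    if (anyNA(imp) || any(is.nan(imp)))
      stop("feature(s) entirely missing in training data: ",
           paste(utils::head(colnames(values)[is.nan(imp)], 5), collapse = ", "))
  } else {
    stopifnot(inherits(impute_from, "fda_model"))
    imp <- impute_from$imputation_values[colnames(values)]
    imp[is.na(imp)] <- colMeans(values, na.rm = TRUE)[is.na(imp)]
  }
  nas <- which(is.na(values), arr.ind = TRUE)
  if (nrow(nas)) values[nas] <- imp[nas[, 2L]]
  structure(list(values = values, feature_ids = colnames(values),
                 feature_type = types, sample_ids = rownames(values),
                 imputation_values = imp),
            class = "feature_matrix")
}

## Lean fitting core shared by fit_fda() and the forward-selection scan.
## x: n x p numeric matrix; yind: n x K indicator; prop: class proportions.
## Returns NULL-free list or a degenerate marker.
.fda_core <- function(x, yind, prop, ridge = 1e-8, dim_tol = 1e-9) {
  n <- nrow(x); p <- ncol(x); k <- ncol(yind)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = n)
  g <- crossprod(xc)
  diag(g) <- diag(g) + ridge
  b <- tryCatch(solve(g, crossprod(xc, yind)), error = function(e) NULL)
  if (is.null(b)) return(list(degenerate = TRUE, feature_means = mu))
  m <- crossprod(yind, xc %*% b) / n
  dsi <- 1 / sqrt(prop)
  msc <- m * tcrossprod(dsi)
  ev <- eigen((msc + t(msc)) / 2, symmetric = TRUE)
  a2 <- pmin(pmax(ev$values, 0), 1)
  keep <- which(a2 > dim_tol)
  keep <- keep[seq_len(min(length(keep), k - 1L))]
  if (!length(keep)) return(list(degenerate = TRUE, feature_means = mu))
  theta <- (ev$vectors[, keep, drop = FALSE]) * dsi     # D^{-1/2} u
  beta <- b %*% theta                                   # p x L
  eta <- xc %*% beta                                    # n x L
  a2 <- a2[keep]
  w <- 1 / pmax(a2 * (1 - a2), 1e-12)
  cent <- crossprod(yind, eta) / (prop * n)             # K x L class means
  list(degenerate = FALSE, feature_means = mu, coefficients = beta,
       optimal_scores = theta, eigenvalues = a2, dim_weights = w,
       centroids = cent, eta = eta)
}

## Weighted nearest-centroid labels for discriminant coordinates.
## Ties (within a relative floating-point tolerance) go to the earliest
## class in sorted label order, so discrete data that land exactly
## between centroids classify deterministically across platforms.
.fda_classify <- function(eta, centroids, w, class_labels) {
  n <- nrow(eta); k <- nrow(centroids)
  d <- matrix(0, n, k)
  for (j in seq_len(k)) {
    diff <- eta - rep(centroids[j, ], each = n)
    d[, j] <- (diff * diff) %*% w
  }
  dmin <- do.call(pmin, as.data.frame(d))
  tol <- 1e-8 * (1 + abs(dmin))
  first_tied <- max.col(d <= dmin + tol, ties.method = "first")
  class_labels[first_tied]
}

#' Fit flexible discriminant analysis by optimal scoring
#'
#' Linear regression basis; see the package vignette for the model.  A
#' feature set with no usable variation yields a degenerate model that
#' predicts the majority class (earliest sorted label on ties) rather
#' than an error.
#'
#' @param x a `feature_matrix` from [encode_features()]
#' @param labels a [population_labels()] covering `x`'s samples
#' @param ridge ridge added to the diagonal of the centered Gram matrix
#'   to absorb rank deficiency (default `1e-8`)
#' @return an object of class `fda_model`
#' @export
fit_fda <- function(x, labels, ridge = 1e-8) {
  stopifnot(inherits(x, "feature_matrix"), inherits(labels, "population_labels"))
  y <- labels$label[x$sample_ids]
  if (anyNA(y)) stop("unlabeled sample(s) in feature matrix")
  class_labels <- sort(unique(y))
  k <- length(class_labels)
  n <- nrow(x$values)
  if (n < k) stop("fewer samples than classes")
  if (ncol(x$values) < 1) stop("at least one feature required")
  yind <- matrix(0, n, k)
  yind[cbind(seq_len(n), match(y, class_labels))] <- 1
  prop <- colMeans(yind)
  core <- .fda_core(x$values, yind, prop, ridge = ridge)
  majority <- class_labels[which.max(prop)]
  if (core$degenerate) {
    pred <- rep(majority, n)
  } else {
    pred <- .fda_classify(core$eta, core$centroids, core$dim_weights,
                          class_labels)
  }
  structure(list(feature_ids = x$feature_ids,
                 feature_type = x$feature_type,
                 class_labels = class_labels,
                 degenerate = core$degenerate,
                 majority_class = majority,
                 feature_means = core$feature_means,
                 coefficient_matrix = core$coefficients,
                 optimal_scores = core$optimal_scores,
                 eigenvalues = core$eigenvalues,
                 dim_weights = core$dim_weights,
                 class_centroids = core$centroids,
                 training_accuracy = mean(pred == y),
                 imputation_values = x$imputation_values,
                 ridge = ridge),
            class = "fda_model")
}

#' @export
print.fda_model <- function(x, ...) {
  cat(sprintf("fda_model: %d feature(s), %d classes, training accuracy %.3f%s\n",
              length(x$feature_ids), length(x$class_labels),
              x$training_accuracy,
              if (x$degenerate) " (degenerate: majority rule)" else ""))
  invisible(x)
}

#' Classify samples with a fitted FDA model
#'
#' @param object an `fda_model`
#' @param x a `feature_matrix` containing at least the model's features
#'   (extra features are ignored); encode test data with
#'   `encode_features(..., impute_from = object)` so missing values use
#'   the training means
#' @param labels optional [population_labels()] with true labels; when
#'   given, the result carries an accuracy
#' @param ... unused
#' @return a `classification_result`: list with `sample_ids`,
#'   `predicted_label`, `true_label` (or `NA`), `accuracy` (or `NA`)
#' @export
predict.fda_model <- function(object, x, labels = NULL, ...) {
  stopifnot(inherits(x, "feature_matrix"))
  missing_feats <- setdiff(object$feature_ids, x$feature_ids)
  if (length(missing_feats))
    stop("feature(s) unknown to the data: ",
         paste(utils::head(missing_feats, 5), collapse = ", "))
  vals <- x$values[, object$feature_ids, drop = FALSE]
  n <- nrow(vals)
  if (object$degenerate) {
    pred <- rep(object$majority_class, n)
  } else {
    xc <- vals - rep(object$feature_means, each = n)
    eta <- xc %*% object$coefficient_matrix
    pred <- .fda_classify(eta, object$class_centroids, object$dim_weights,
                          object$class_labels)
  }
  truth <- rep(NA_character_, n)
  acc <- NA_real_
  if (!is.null(labels)) {
    truth <- unname(labels$label[x$sample_ids])
    acc <- mean(pred == truth)
  }
  structure(list(sample_ids = x$sample_ids, predicted_label = pred,
                 true_label = truth, accuracy = acc),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("classification_result: %d samples, accuracy %s\n",
              length(x$sample_ids),
              if (is.na(x$accuracy)) "NA" else sprintf("%.3f", x$accuracy)))
  invisible(x)
}

#' Within/between sum-of-squares ratio of one feature
#'
#' `SSW = sum_k sum_{i in k} (x_i - mean_k)^2` and
#' `SSB = sum_k n_k (mean_k - mean)^2`; smaller ratios indicate stronger
#' population differentiation.  Returns `Inf` when `SSB = 0` (a feature
#' with identical class means carries no between-group signal).
#'
#' @param values numeric vector (encoded genotype values or expression
#'   intensities)
#' @param labels character/factor vector of class labels, same length
#' @return the ratio `SSW / SSB`
#' @export
ssw_ssb <- function(values, labels) {
  if (length(values) == 0) stop("empty input")
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("at least two classes required")
  gm <- mean(values)
  means <- tapply(values, labels, mean)
  nk <- tapply(values, labels, length)
  ssb <- sum(nk * (means - gm)^2)
  ssw <- sum((values - means[labels])^2)
  if (ssb <= 0) return(Inf)
  ssw / ssb
}

## ---- plain-text model serialization ----------------------------------

#' Write an FDA model to a plain-text file
#'
#' Key-value header lines (`# key: value`) followed by tab-separated
#' matrix blocks, so selected panels are portable and diffable.
#'
#' @param model an `fda_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fda_model <- function(model, path) {
  stopifnot(inherits(model, "fda_model"))
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(format(x, digits = 17), collapse = "\t")
  wr("# aimsel_fda_model: 1")
  wr("# classes: %s", paste(model$class_labels, collapse = "\t"))
  wr("# features: %s", paste(model$feature_ids, collapse = "\t"))
  wr("# feature_type: %s", paste(model$feature_type, collapse = "\t"))
  wr("# degenerate: %s", model$degenerate)
  wr("# majority_class: %s", model$majority_class)
  wr("# training_accuracy: %s", format(model$training_accuracy, digits = 17))
  wr("# ridge: %s", format(model$ridge, digits = 17))
  wr("# feature_means: %s", num(model$feature_means))
  wr("# imputation_values: %s", num(model$imputation_values))
  if (!model$degenerate) {
    wr("# eigenvalues: %s", num(model$eigenvalues))
    wr("# dim_weights: %s", num(model$dim_weights))
    wr("[coefficients]")
    write.table(model$coefficient_matrix, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    wr("[optimal_scores]")
    write.table(model$optimal_scores, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    wr("[centroids]")
    write.table(model$class_centroids, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an FDA model written by [write_fda_model()]
#'
#' @param path path to the model file
#' @return an `fda_model`
#' @export
read_fda_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "# aimsel_fda_model"))
    stop("not an aimsel model file: ", path)
  kv <- list()
  for (l in grep("^# ", lines, value = TRUE)) {
    key <- sub("^# ([^:]+):.*$", "\\1", l)
    val <- sub("^# [^:]+: ?", "", l)
    kv[[key]] <- strsplit(val, "\t", fixed = TRUE)[[1L]]
  }
  block <- function(name, nrow) {
    at <- which(lines == sprintf("[%s]", name))
    if (!length(at)) return(NULL)
    body <- lines[(at + 1L):(at + nrow)]
    do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  }
  feats <- kv$features
  classes <- kv$classes
  degenerate <- identical(kv$degenerate, "TRUE")
  model <- list(feature_ids = feats,
                feature_type = setNames(kv$feature_type, feats),
                class_labels = classes,
                degenerate = degenerate,
                majority_class = kv$majority_class,
                feature_means = setNames(as.numeric(kv$feature_means), feats),
                coefficient_matrix = NULL, optimal_scores = NULL,
                eigenvalues = NULL, dim_weights = NULL,
                class_centroids = NULL,
                training_accuracy = as.numeric(kv$training_accuracy),
                imputation_values = setNames(as.numeric(kv$imputation_values),
                                             feats),
                ridge = as.numeric(kv$ridge))
  if (!degenerate) {
    model$eigenvalues <- as.numeric(kv$eigenvalues)
    model$dim_weights <- as.numeric(kv$dim_weights)
    model$coefficient_matrix <- block("coefficients", length(feats))
    model$optimal_scores <- block("optimal_scores", length(classes))
    model$class_centroids <- block("centroids", length(classes))
    rownames(model$coefficient_matrix) <- feats
  }
  structure(model, class = "fda_model")
}
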