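# Small programmatic fixtures shared across test files.

# Bare feature_matrix from a plain numeric matrix (all features tagged
# as expression so no recoding applies).
fm <- function(values, type = "ge") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  structure(list(values = values, feature_ids = colnames(values),
                 feature_type = setNames(rep(type, ncol(values)),
                                         colnames(values)),
                 sample_ids = rownames(values),
                 imputation_values = colMeans(values)),
            class = "feature_matrix")
}

labs <- function(y, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(y))
  population_labels(ids, y)
}

# Gaussian K-class problem with class-mean spread `sep`.
gaussian_problem <- function(seed, K = 2, p = 2, n = 60, n_test = 40,
                             sep = 1.2) {
  set.seed(seed)
  cls <- letters[1:K]
  y <- sample(rep(cls, length.out = n))
  mu <- matrix(rnorm(K * p, sd = sep), K, p)
  x <- mu[match(y, cls), , drop = FALSE] + matrix(rnorm(n * p), n, p)
  dimnames(x) <- list(sprintf("s%03d", 1:n), sprintf("f%03d", 1:p))
  yte <- sample(cls, n_test, replace = TRUE)
  xte <- mu[match(yte, cls), , drop = FALSE] +
    matrix(rnorm(n_test * p), n_test, p)
  dimnames(xte) <- list(sprintf("t%03d", 1:n_test), colnames(x))
  list(x = x, y = y, xte = xte, yte = yte)
}

# Genotype matrix built from a samples x markers character matrix given
# as row-wise vectors.
gm <- function(..., chrom = NULL, ids = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(m)))
  rownames(m) <- ids
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%03d", seq_len(ncol(m)))
  genotype_matrix(m, chrom = chrom)
}

# Random marker pool: n samples, m SNP-like {0,1,2} markers with one
# optional perfectly separating marker, as encoded numeric features.
random_marker_pool <- function(seed, n = 60, m = 8, K = 2) {
  set.seed(seed)
  cls <- letters[1:K]
  y <- sort(rep_len(cls, n))
  vals <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  dimnames(vals) <- list(sprintf("s%03d", 1:n), sprintf("mk%02d", 1:m))
  list(vals = vals, y = y)
}
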