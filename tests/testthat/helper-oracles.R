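# Independent oracles used to validate the package's implementations.
# These deliberately re-derive each quantity from first principles and
# never call the code path they check.

# Linear discriminant analysis: Mahalanobis nearest class mean with the
# pooled within-class covariance (no prior term); ties go to the
# earliest sorted class.
oracle_lda <- function(xtr, ytr, xte) {
  cls <- sort(unique(ytr))
  n <- nrow(xtr); K <- length(cls); p <- ncol(xtr)
  mus <- do.call(rbind, lapply(cls, function(c)
    colMeans(xtr[ytr == c, , drop = FALSE])))
  S <- matrix(0, p, p)
  for (c in cls) {
    xc <- scale(xtr[ytr == c, , drop = FALSE], scale = FALSE)
    S <- S + crossprod(xc)
  }
  Si <- solve(S / (n - K))
  d <- vapply(seq_len(K), function(j) {
    v <- sweep(xte, 2, mus[j, ])
    rowSums((v %*% Si) * v)
  }, numeric(nrow(xte)))
  d <- matrix(d, nrow(xte), K)
  # same tolerance-based tie rule as the package: earliest sorted class
  # among centroids within a relative distance tolerance
  dmin <- do.call(pmin, as.data.frame(d))
  cls[max.col(d <= dmin + 1e-8 * (1 + abs(dmin)), ties.method = "first")]
}

# Exact p-value of the heterozygote-count statistic under random
# pairing of the 2N alleles, from the combinatorial distribution
#   P(het = h) = C(N, b) C(N - b, h) 2^h / C(2N, nB),  b = (nB - h) / 2.
oracle_hwe_exact <- function(n_AA, n_AB, n_BB) {
  n_a <- 2 * n_AA + n_AB; n_b <- n_AB + 2 * n_BB
  N <- n_AA + n_AB + n_BB
  if (n_a == 0 || n_b == 0) return(1.0)
  hs <- seq(n_b %% 2, min(n_a, n_b), by = 2)
  pmf <- vapply(hs, function(h) {
    b <- (n_b - h) / 2
    exp(lchoose(N, b) + lchoose(N - b, h) + h * log(2) - lchoose(2 * N, n_b))
  }, numeric(1))
  e <- n_a * n_b / (2 * N - 1)
  min(1, sum(pmf[abs(hs - e) >= abs(n_AB - e) - 1e-9]))
}

# Brute-force enumeration of every distinct pairing outcome for tiny
# allele pools: shuffles all permutations of the pool explicitly.
# Validates oracle_hwe_exact itself on very small tables.
oracle_hwe_enumerate <- function(n_AA, n_AB, n_BB) {
  n_a <- 2 * n_AA + n_AB; n_b <- n_AB + 2 * n_BB
  N <- n_AA + n_AB + n_BB
  if (n_a == 0 || n_b == 0) return(1.0)
  pool_size <- n_a + n_b
  # enumerate which slots carry the B alleles
  slots <- utils::combn(pool_size, n_b)
  pair_of <- ceiling(seq_len(pool_size) / 2)
  hets <- apply(slots, 2, function(s) {
    cnt <- tabulate(pair_of[s], nbins = N)
    sum(cnt == 1)
  })
  e <- n_a * n_b / (2 * N - 1)
  mean(abs(hets - e) >= abs(n_AB - e) - 1e-9)
}

# Univariate within/between sum-of-squares ratio, written independently.
oracle_ssw_ssb <- function(v, y) {
  gm <- mean(v)
  ssb <- 0; ssw <- 0
  for (c in unique(y)) {
    vi <- v[y == c]
    ssb <- ssb + length(vi) * (mean(vi) - gm)^2
    ssw <- ssw + sum((vi - mean(vi))^2)
  }
  if (ssb <= 0) Inf else ssw / ssb
}

# One step of exhaustive forward selection: evaluates the training
# accuracy of every candidate joined to the current set with the LDA
# oracle, then applies the documented tie-break chain (max accuracy,
# min univariate SSW/SSB, lexicographic id).  Returns the winner and
# its accuracy.
oracle_forward_step <- function(vals, y, selected, pool) {
  baseline <- max(table(y)) / length(y)
  accs <- vapply(pool, function(id) {
    x <- vals[, c(selected, id), drop = FALSE]
    pred <- tryCatch(oracle_lda(x, y, x), error = function(e) NULL)
    if (is.null(pred)) baseline else mean(pred == y)
  }, numeric(1))
  best <- max(accs)
  tied <- pool[accs >= best - 1e-12]
  if (length(tied) > 1) {
    r <- vapply(tied, function(id) oracle_ssw_ssb(vals[, id], y), numeric(1))
    tied <- tied[r <= min(r) + 1e-12]
    if (length(tied) > 1) tied <- sort(tied)
  }
  list(marker = tied[1L], accuracy = best)
}

# Full exhaustive forward selection with the same stopping rules as
# selection_config().
oracle_forward_select <- function(vals, y, target = 1.0, min_inc = 0.001,
                                  max_markers = Inf) {
  selected <- character(0)
  cur <- max(table(y)) / length(y)
  repeat {
    pool <- setdiff(colnames(vals), selected)
    if (!length(pool)) break
    st <- oracle_forward_step(vals, y, selected, pool)
    if (length(selected) > 0 && st$accuracy - cur < min_inc) break
    selected <- c(selected, st$marker)
    cur <- st$accuracy
    if (cur >= target || length(selected) >= max_markers) break
  }
  selected
}

# Same per-table seed derivation the QC chain uses.
oracle_table_seed <- function(base, id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 2147483587
  as.integer((h + base) %% 2147483587)
}
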