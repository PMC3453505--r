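## Marker quality control.
##
## SNPs are removed when the genotype call rate is below threshold, the
## minor allele frequency is zero (configurable), a permutation-based
## Hardy-Weinberg test rejects after FDR adjustment, or the marker sits
## on a sex chromosome.  Expression probes are removed when they are not
## RefSeq-derived, sit on a sex chromosome, or lack gene information.
## Removal reasons are a union, not a cascade, so reports are auditable.

#' Genotype call rate of one marker
#'
#' @param calls character vector of calls (`AA`/`AB`/`BB`/`NA`)
#' @return fraction of non-missing calls, in `[0, 1]`
#' @export
call_rate <- function(calls) {
  if (length(calls) == 0) stop("empty call vector")
  mean(!is.na(calls))
}

#' Minor allele frequency of one marker
#'
#' Counts B alleles as `2*#BB + #AB` over `2 * (non-missing calls)` and
#' returns the smaller of the two allele frequencies.
#'
#' @param calls character vector of calls (`AA`/`AB`/`BB`/`NA`)
#' @return minor allele frequency, in `[0, 0.5]`
#' @export
minor_allele_frequency <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("all calls missing: MAF undefined")
  n_b <- 2 * sum(calls == "BB") + sum(calls == "AB")
  f <- n_b / (2 * length(calls))
  min(f, 1 - f)
}

#' Permutation test of Hardy-Weinberg equilibrium
#'
#' Monte-Carlo test of the observed heterozygote count under random
#' re-pairing of the allele pool: the `2N` alleles implied by the
#' genotype counts are shuffled and paired consecutively in each
#' permutation, and the statistic is the absolute deviation of the
#' heterozygote count from its exact expectation under random pairing,
#' `n_A * n_B / (2N - 1)`.  The p-value uses the add-one correction
#' `(1 + #{extreme}) / (1 + n_perm)` and is therefore always positive.
#' Monomorphic markers return `p = 1` (the statistic is degenerate).
#'
#' @param n_AA,n_AB,n_BB genotype counts
#' @param n_perm number of permutations (default 1000)
#' @param seed optional integer seed; when supplied the global RNG state
#'   is left untouched
#' @return the permutation p-value
#' @export
hwe_permutation_test <- function(n_AA, n_AB, n_BB, n_perm = 1000, seed = NULL) {
  counts <- c(n_AA, n_AB, n_BB)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  if (sum(counts) < 1) stop("at least one genotype required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_a <- 2 * n_AA + n_AB
  n_b <- n_AB + 2 * n_BB
  if (n_a == 0 || n_b == 0) return(1.0)          # monomorphic
  run <- function() {
    e_het <- n_a * n_b / (n_a + n_b - 1)
    obs <- abs(n_AB - e_het)
    het <- hwe_perm_het(n_a, n_b, as.integer(n_perm))
    (1 + sum(abs(het - e_het) >= obs - 1e-9)) / (1 + n_perm)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

## Evaluate `expr` under a local seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; values are capped
#' at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @export
fdr_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / seq(n, 1) * p[o]))
  adj[order(o)]
}

#' SNP quality-control configuration
#'
#' @param min_call_rate markers below this call rate are removed
#'   (default 0.9)
#' @param min_maf_exclusive markers with MAF less than or equal to this
#'   are removed; the default 0 removes exactly the monomorphic markers
#' @param hwe_alpha significance level applied to the FDR-adjusted HWE
#'   p-value (default 0.05)
#' @param hwe_permutations permutations per marker for the HWE test
#'   (default 1000)
#' @param drop_sex_chromosomes remove markers on X/Y/XY (default `TRUE`)
#' @param seed integer seed for the permutation tests
#' @return a `snp_qc_config` list
#' @export
snp_qc_config <- function(min_call_rate = 0.9, min_maf_exclusive = 0,
                          hwe_alpha = 0.05, hwe_permutations = 1000,
                          drop_sex_chromosomes = TRUE, seed = 1L) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf_exclusive >= 0, min_maf_exclusive <= 0.5,
            hwe_alpha > 0, hwe_alpha <= 1, hwe_permutations >= 1)
  structure(list(min_call_rate = min_call_rate,
                 min_maf_exclusive = min_maf_exclusive,
                 hwe_alpha = hwe_alpha,
                 hwe_permutations = as.integer(hwe_permutations),
                 drop_sex_chromosomes = isTRUE(drop_sex_chromosomes),
                 seed = as.integer(seed)),
            class = "snp_qc_config")
}

#' Filter SNP markers by the quality-control chain
#'
#' Applies, per marker, the call-rate rule, the minor-allele-frequency
#' rule, the permutation Hardy-Weinberg test (rejecting when the
#' FDR-adjusted p-value falls below `hwe_alpha`) and the sex-chromosome
#' rule.  Reasons are recorded as a union; a marker survives iff its
#' reason set is empty.  HWE is computed on the pooled samples of the
#' matrix as given (restrict to the population combination of interest
#' beforehand, e.g. with [align_samples()]).
#'
#' @param g a [genotype_matrix()] already restricted to the samples of
#'   the current analysis
#' @param cfg a [snp_qc_config()]
#' @return list with elements `genotypes` (filtered matrix, original
#'   marker order preserved) and `report` (a `qc_report`)
#' @export
filter_snps <- function(g, cfg = snp_qc_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "snp_qc_config"))
  m <- length(g$marker_ids)
  cr <- maf <- hwe_raw <- rep(NA_real_, m)
  reasons <- vector("list", m)
  counts <- matrix(0L, 3L, m,
                   dimnames = list(c("AA", "AB", "BB"), g$marker_ids))
  for (j in seq_len(m)) {
    v <- g$calls[, j]
    cr[j] <- call_rate(v)
    tab <- table(factor(v, levels = c("AA", "AB", "BB")))
    counts[, j] <- as.integer(tab)
    if (cr[j] > 0) maf[j] <- minor_allele_frequency(v)
  }
  ## Each marker gets a seed derived from the run seed and its own id, so
  ## its p-value does not depend on which other markers are in the run
  ## (this is what makes filtering idempotent for a fixed seed).
  for (j in seq_len(m)) {
    if (cr[j] == 0) next
    hwe_raw[j] <- hwe_permutation_test(counts[1L, j], counts[2L, j],
                                       counts[3L, j],
                                       n_perm = cfg$hwe_permutations,
                                       seed = .marker_seed(cfg$seed,
                                                           g$marker_ids[j]))
  }
  hwe_adj <- rep(NA_real_, m)
  tested <- !is.na(hwe_raw)
  hwe_adj[tested] <- fdr_adjust(hwe_raw[tested])
  for (j in seq_len(m)) {
    r <- character(0)
    if (cr[j] < cfg$min_call_rate) r <- c(r, "CALL_RATE")
    if (!is.na(maf[j]) && maf[j] <= cfg$min_maf_exclusive) r <- c(r, "MAF_ZERO")
    if (!is.na(hwe_adj[j]) && hwe_adj[j] < cfg$hwe_alpha) r <- c(r, "HWE")
    if (cfg$drop_sex_chromosomes && !is.na(g$chrom[j]) &&
        g$chrom[j] %in% SEX_CHROMS) r <- c(r, "SEX_CHROM")
    reasons[[j]] <- r
  }
  removed <- lengths(reasons) > 0
  rep_df <- data.frame(marker_id = g$marker_ids, call_rate = cr, maf = maf,
                       hwe_p_raw = hwe_raw, hwe_p_adjusted = hwe_adj,
                       removal_reasons = vapply(reasons, paste,
                                                character(1), collapse = ","),
                       stringsAsFactors = FALSE)
  keep <- g$marker_ids[!removed]
  g2 <- genotype_matrix(g$calls[, keep, drop = FALSE], chrom = g$chrom[keep])
  list(genotypes = g2,
       report = .qc_report(rep_df, c("CALL_RATE", "MAF_ZERO", "HWE", "SEX_CHROM")))
}

#' Filter expression probes by annotation
#'
#' Removes probes whose source is not RefSeq, that sit on a sex
#' chromosome, or that carry no gene symbol.  Probes with no annotation
#' record are treated as lacking gene information (with a warning).
#'
#' @param e an [expression_matrix()] with probe annotation attached
#' @return list with elements `expression` (filtered matrix) and
#'   `report` (a `qc_report`)
#' @export
filter_probes <- function(e) {
  stopifnot(inherits(e, "expression_matrix"))
  if (is.null(e$probe_annotation)) stop("probe annotation required for probe QC")
  ann <- e$probe_annotation
  idx <- match(e$probe_ids, ann$probe_id)
  if (anyNA(idx))
    warning(sprintf("%d probe(s) lack an annotation record; treated as NO_GENE_INFO",
                    sum(is.na(idx))))
  reasons <- lapply(seq_along(e$probe_ids), function(j) {
    i <- idx[j]
    if (is.na(i)) return("NO_GENE_INFO")
    r <- character(0)
    if (!identical(ann$source[i], "RefSeq")) r <- c(r, "NON_REFSEQ")
    if (!is.na(ann$chrom[i]) && ann$chrom[i] %in% SEX_CHROMS) r <- c(r, "SEX_CHROM")
    if (is.na(ann$gene_symbol[i]) || ann$gene_symbol[i] == "")
      r <- c(r, "NO_GENE_INFO")
    r
  })
  removed <- lengths(reasons) > 0
  rep_df <- data.frame(probe_id = e$probe_ids,
                       removal_reasons = vapply(reasons, paste,
                                                character(1), collapse = ","),
                       stringsAsFactors = FALSE)
  keep <- e$probe_ids[!removed]
  e2 <- expression_matrix(e$values[, keep, drop = FALSE])
  e2$probe_annotation <- ann[match(keep, ann$probe_id), , drop = FALSE]
  list(expression = e2,
       report = .qc_report(rep_df, c("NON_REFSEQ", "SEX_CHROM", "NO_GENE_INFO")))
}

## Deterministic per-marker seed: polynomial hash of the marker id folded
## with the run seed, kept below 2^31.
.marker_seed <- function(base, id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 2147483587
  as.integer((h + as.numeric(base)) %% 2147483587)
}

.qc_report <- function(records, reason_levels) {
  all_reasons <- strsplit(records$removal_reasons, ",", fixed = TRUE)
  counts <- vapply(reason_levels,
                   function(r) sum(vapply(all_reasons, function(x) r %in% x,
                                          logical(1))),
                   integer(1))
  structure(list(records = records, reason_counts = counts,
                 n_input = nrow(records),
                 n_removed = sum(records$removal_reasons != ""),
                 n_survivors = sum(records$removal_reasons == "")),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d markers in, %d removed, %d surviving\n",
              x$n_input, x$n_removed, x$n_survivors))
  for (r in names(x$reason_counts))
    cat(sprintf("  %-12s %d\n", r, x$reason_counts[[r]]))
  invisible(x)
}

#' Write a QC report to TSV
#' @param report a `qc_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  write.table(report$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
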