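## Population-structured SNP + gene-expression simulator with known
## ground truth.
##
## Noise SNPs share one allele frequency across populations (drawn
## uniformly from a configurable range) so they carry no ancestry
## signal and sit in Hardy-Weinberg equilibrium; informative SNPs take
## population-differentiated frequencies, either given explicitly or
## drawn under the Balding-Nichols model.  Expression is Gaussian on a
## log-intensity-like scale; informative probes shift their mean by a
## fixed number of standard deviations between consecutive populations.
## Informative markers are always autosomal and RefSeq so the QC chain
## never removes planted signal.

#' Simulation configuration
#'
#' @param populations named integer vector of per-population sample
#'   counts, e.g. `c(CHB = 45, JPT = 45)`
#' @param n_noise_snps number of no-signal SNPs (default 200)
#' @param n_info_snps number of ancestry-informative SNPs (default 1)
#' @param info_freq optional matrix (`n_info_snps` x K) of per-population
#'   B-allele frequencies for the informative SNPs; when `NULL` they are
#'   drawn by [draw_population_frequencies()] with `fst`
#' @param fst Balding-Nichols differentiation for informative SNPs when
#'   `info_freq` is `NULL` (default 0.15, a typical inter-continental
#'   human value)
#' @param base_freq_range range the shared/ancestral allele frequencies
#'   are drawn from (default `c(0.2, 0.8)`)
#' @param n_noise_ge number of no-signal expression probes (default 100)
#' @param n_info_ge number of informative probes (default 0)
#' @param ge_shift standardized mean difference between consecutive
#'   populations for informative probes (default 2)
#' @param ge_sd residual standard deviation of expression (default 1)
#' @param ge_baseline_mean grand mean of the log-intensity scale
#'   (default 7, a mid-range value for normalized bead arrays)
#' @param missing_rate per-call genotype missingness probability
#'   (default 0.01)
#' @param sex_chrom_fraction fraction of noise markers/probes annotated
#'   to chromosome X, to exercise QC (default 0.05)
#' @param non_refseq_fraction fraction of noise probes annotated
#'   UniGene/Gnomon (default 0.1)
#' @param no_gene_fraction fraction of noise probes with no gene symbol
#'   (default 0.05)
#' @param seed integer seed; the whole dataset is reproducible from it
#' @return a `sim_config`
#' @export
sim_config <- function(populations, n_noise_snps = 200, n_info_snps = 1,
                       info_freq = NULL, fst = 0.15,
                       base_freq_range = c(0.2, 0.8),
                       n_noise_ge = 100, n_info_ge = 0, ge_shift = 2,
                       ge_sd = 1, ge_baseline_mean = 7, missing_rate = 0.01,
                       sex_chrom_fraction = 0.05, non_refseq_fraction = 0.1,
                       no_gene_fraction = 0.05, seed = 1L) {
  if (is.null(names(populations)) || any(names(populations) == ""))
    stop("`populations` must be a named vector of sample counts")
  if (length(populations) < 2 || length(populations) > 4)
    stop("2 to 4 populations supported")
  if (any(populations < 1)) stop("each population needs at least one sample")
  fracs <- c(missing_rate, sex_chrom_fraction, non_refseq_fraction,
             no_gene_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (!is.null(info_freq)) {
    info_freq <- as.matrix(info_freq)
    if (nrow(info_freq) != n_info_snps ||
        ncol(info_freq) != length(populations))
      stop("`info_freq` must be n_info_snps x n_populations")
    if (any(info_freq < 0 | info_freq > 1)) stop("frequencies must lie in [0, 1]")
  } else if (n_info_snps > 0 && (fst <= 0 || fst >= 1)) {
    stop("fst must lie in (0, 1)")
  }
  stopifnot(length(base_freq_range) == 2, base_freq_range[1] > 0,
            base_freq_range[2] < 1, base_freq_range[1] <= base_freq_range[2],
            ge_sd > 0)
  structure(list(populations = populations, n_noise_snps = n_noise_snps,
                 n_info_snps = n_info_snps, info_freq = info_freq, fst = fst,
                 base_freq_range = base_freq_range, n_noise_ge = n_noise_ge,
                 n_info_ge = n_info_ge, ge_shift = ge_shift, ge_sd = ge_sd,
                 ge_baseline_mean = ge_baseline_mean,
                 missing_rate = missing_rate,
                 sex_chrom_fraction = sex_chrom_fraction,
                 non_refseq_fraction = non_refseq_fraction,
                 no_gene_fraction = no_gene_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' HapMap-like preset configuration
#'
#' Four populations sized like the HapMap II panel (CHB 45, JPT 45,
#' CEU 60, YRI 60) at reduced marker scale, or any subset of them.
#'
#' @param populations named sample counts (default the four-population
#'   panel)
#' @param n_snps total SNPs (default 5000)
#' @param n_probes total expression probes (default 2000)
#' @param n_info_snps informative SNPs among `n_snps` (default 10)
#' @param n_info_ge informative probes among `n_probes` (default 5)
#' @param ... further arguments passed to [sim_config()]
#' @return a `sim_config`
#' @export
hapmap_preset <- function(populations = c(CHB = 45, JPT = 45,
                                          CEU = 60, YRI = 60),
                          n_snps = 5000, n_probes = 2000,
                          n_info_snps = 10, n_info_ge = 5, ...) {
  sim_config(populations = populations,
             n_noise_snps = n_snps - n_info_snps,
             n_info_snps = n_info_snps,
             n_noise_ge = n_probes - n_info_ge,
             n_info_ge = n_info_ge, ...)
}

#' Balding-Nichols per-population allele frequencies
#'
#' Each population's frequency is an independent draw from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with ancestral frequency
#' `p` and differentiation `F`; the draws have mean `p` and variance
#' `F p (1 - p)`.
#'
#' @param base_freq ancestral allele frequency, in (0, 1)
#' @param fst differentiation parameter, in (0, 1)
#' @param n_pops number of populations
#' @param seed optional seed (global RNG state is preserved)
#' @return numeric vector of `n_pops` frequencies
#' @export
draw_population_frequencies <- function(base_freq, fst, n_pops, seed = NULL) {
  if (base_freq <= 0 || base_freq >= 1) stop("base_freq must lie in (0, 1)")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (n_pops < 1) stop("n_pops must be >= 1")
  draw <- function() rbeta(n_pops, base_freq * (1 - fst) / fst,
                           (1 - base_freq) * (1 - fst) / fst)
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Simulate a population-structured SNP + expression dataset
#'
#' @param cfg a [sim_config()]
#' @return a `sim_dataset`: list with `genotypes`, `expression`,
#'   `labels`, `marker_annotation`, `probe_annotation`, `truth`
#'   (informative ids, per-population allele frequencies and expression
#'   means)
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, .simulate_dataset_impl(cfg))
}

.simulate_dataset_impl <- function(cfg) {
  pops <- names(cfg$populations)
  k <- length(pops)
  n_by_pop <- as.integer(cfg$populations)
  n <- sum(n_by_pop)
  pop_of <- rep(pops, n_by_pop)
  sample_ids <- unlist(lapply(seq_len(k), function(i)
    sprintf("%s_%03d", pops[i], seq_len(n_by_pop[i]))))
  labels <- population_labels(sample_ids, pop_of)

  ## --- SNPs ------------------------------------------------------------
  m_noise <- cfg$n_noise_snps
  m_info <- cfg$n_info_snps
  m <- m_noise + m_info
  freq <- matrix(0, m, k)            # per-population B-allele frequency
  info_flag <- c(rep(FALSE, m_noise), rep(TRUE, m_info))
  if (m_noise > 0)
    freq[!info_flag, ] <- runif(m_noise, cfg$base_freq_range[1],
                                cfg$base_freq_range[2])  # shared across pops
  if (m_info > 0) {
    freq[info_flag, ] <- if (!is.null(cfg$info_freq)) cfg$info_freq else {
      base <- runif(m_info, cfg$base_freq_range[1], cfg$base_freq_range[2])
      t(vapply(base, function(p)
        draw_population_frequencies(p, cfg$fst, k), numeric(k)))
    }
  }
  ord <- sample.int(m)               # informative SNPs sit anywhere
  freq <- freq[ord, , drop = FALSE]
  info_flag <- info_flag[ord]
  marker_ids <- sprintf("rs%06d", seq_len(m))
  calls <- matrix(NA_character_, n, m, dimnames = list(sample_ids, marker_ids))
  for (i in seq_len(k)) {
    rows <- which(pop_of == pops[i])
    dosage <- matrix(rbinom(length(rows) * m, 2L, rep(freq[, i],
                                                      each = length(rows))),
                     length(rows), m)
    calls[rows, ] <- c("AA", "AB", "BB")[dosage + 1L]
  }
  if (cfg$missing_rate > 0)
    calls[runif(length(calls)) < cfg$missing_rate] <- NA_character_
  chrom <- as.character(sample.int(22L, m, replace = TRUE))
  n_sex <- round(cfg$sex_chrom_fraction * sum(!info_flag))
  if (n_sex > 0) chrom[sample(which(!info_flag), n_sex)] <- "X"
  genotypes <- genotype_matrix(calls, chrom = chrom)

  ## --- expression ------------------------------------------------------
  p_noise <- cfg$n_noise_ge
  p_info <- cfg$n_info_ge
  p <- p_noise + p_info
  expression <- NULL; probe_annotation <- NULL
  ge_means <- NULL; info_probe_flag <- logical(0); probe_ids <- character(0)
  if (p > 0) {
    info_probe_flag <- c(rep(FALSE, p_noise), rep(TRUE, p_info))
    pord <- sample.int(p)
    info_probe_flag <- info_probe_flag[pord]
    probe_ids <- sprintf("GI_%06d-S", seq_len(p))
    base_mean <- rnorm(p, cfg$ge_baseline_mean, 1)
    ge_means <- matrix(base_mean, p, k)   # probe x population means
    shift <- cfg$ge_shift * cfg$ge_sd
    ge_means[info_probe_flag, ] <- base_mean[info_probe_flag] +
      outer(rep(1, sum(info_probe_flag)), (seq_len(k) - 1) * shift)
    vals <- matrix(NA_real_, n, p, dimnames = list(sample_ids, probe_ids))
    for (i in seq_len(k)) {
      rows <- which(pop_of == pops[i])
      vals[rows, ] <- rep(ge_means[, i], each = length(rows)) +
        rnorm(length(rows) * p, 0, cfg$ge_sd)
    }
    src <- rep("RefSeq", p)
    n_nonref <- round(cfg$non_refseq_fraction * sum(!info_probe_flag))
    if (n_nonref > 0) {
      pick <- sample(which(!info_probe_flag), n_nonref)
      src[pick] <- rep_len(c("UniGene", "Gnomon"), n_nonref)
    }
    pchrom <- as.character(sample.int(22L, p, replace = TRUE))
    n_psex <- round(cfg$sex_chrom_fraction * sum(!info_probe_flag))
    if (n_psex > 0) pchrom[sample(which(!info_probe_flag), n_psex)] <- "X"
    gene <- sprintf("GENE%05d", seq_len(p))
    n_nogene <- round(cfg$no_gene_fraction * sum(!info_probe_flag))
    if (n_nogene > 0) gene[sample(which(!info_probe_flag), n_nogene)] <- NA
    probe_annotation <- data.frame(probe_id = probe_ids, source = src,
                                   chrom = pchrom, gene_symbol = gene,
                                   stringsAsFactors = FALSE)
    expression <- expression_matrix(vals, probe_annotation = probe_annotation)
    colnames(ge_means) <- pops
    rownames(ge_means) <- probe_ids
  }

  colnames(freq) <- pops
  rownames(freq) <- marker_ids
  truth <- list(informative_snp_ids = marker_ids[info_flag],
                informative_ge_ids = probe_ids[info_probe_flag],
                snp_freq = freq,
                ge_means = ge_means)
  marker_annotation <- data.frame(marker_id = marker_ids, chrom = chrom,
                                  stringsAsFactors = FALSE)
  structure(list(genotypes = genotypes, expression = expression,
                 labels = labels, marker_annotation = marker_annotation,
                 probe_annotation = probe_annotation, truth = truth,
                 config = cfg),
            class = "sim_dataset")
}

#' Write a simulated dataset to a directory
#'
#' Emits `genotypes.tsv`, `expression.tsv`, `labels.tsv`,
#' `marker_annotation.tsv`, `probe_annotation.tsv`, `ground_truth.tsv`
#' and optionally `genotypes.vcf`; all round-trip through the package
#' readers.
#'
#' @param ds a `sim_dataset`
#' @param out_dir output directory (created if needed)
#' @param vcf also write a VCF copy of the genotypes (default `FALSE`)
#' @return `out_dir`, invisibly
#' @export
write_dataset <- function(ds, out_dir, vcf = FALSE) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  write_genotypes_tabular(ds$genotypes, pth("genotypes.tsv"))
  if (vcf) write_genotypes_vcf(ds$genotypes, pth("genotypes.vcf"))
  if (!is.null(ds$expression)) write_expression(ds$expression, pth("expression.tsv"))
  write_labels(ds$labels, pth("labels.tsv"))
  write.table(ds$marker_annotation, pth("marker_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$probe_annotation))
    write.table(ds$probe_annotation, pth("probe_annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- data.frame(id = c(ds$truth$informative_snp_ids,
                          ds$truth$informative_ge_ids),
                   type = c(rep("snp", length(ds$truth$informative_snp_ids)),
                            rep("ge", length(ds$truth$informative_ge_ids))),
                   stringsAsFactors = FALSE)
  write.table(gt, pth("ground_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(out_dir)
}
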