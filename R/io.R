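## I/O and core containers: genotype calls, expression intensities,
## population labels, annotation tables.  Genotype calls are kept
## categorical ("AA"/"AB"/"BB", NA for missing); numeric coding happens
## only in encode_features().

GENOTYPE_LEVELS <- c("AA", "AB", "BB")
SEX_CHROMS <- c("X", "Y", "XY")

#' Construct a genotype matrix
#'
#' @param calls character matrix, samples in rows and SNP markers in
#'   columns, with entries `"AA"`, `"AB"`, `"BB"` or `NA` (missing call).
#'   Row and column names supply the sample and marker identifiers.
#' @param chrom optional character vector of per-marker chromosome labels
#'   (`1`--`22`, `X`, `Y`, `XY`, `MT`); `NA` when unknown.
#' @return an object of class `genotype_matrix` with elements
#'   `sample_ids`, `marker_ids`, `calls` and `chrom`.
#' @export
genotype_matrix <- function(calls, chrom = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  calls <- matrix(as.character(calls), nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
  sample_ids <- rownames(calls)
  marker_ids <- colnames(calls)
  if (is.null(sample_ids) || is.null(marker_ids))
    stop("`calls` must have row names (samples) and column names (markers)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in genotype matrix")
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids in genotype matrix")
  bad <- !is.na(calls) & !(calls %in% GENOTYPE_LEVELS)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("illegal genotype call '%s' for sample '%s', marker '%s'",
                 calls[bad][1L], sample_ids[idx[1L]], marker_ids[idx[2L]]))
  }
  if (is.null(chrom)) chrom <- rep(NA_character_, length(marker_ids))
  if (length(chrom) != length(marker_ids))
    stop("`chrom` must have one entry per marker")
  chrom <- as.character(chrom)
  names(chrom) <- marker_ids
  structure(list(sample_ids = sample_ids, marker_ids = marker_ids,
                 calls = calls, chrom = chrom),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.1f%% missing)\n",
              length(x$sample_ids), length(x$marker_ids),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Construct an expression matrix
#'
#' @param values numeric matrix, samples in rows and probes in columns
#'   (`NA` for missing intensities).  Dimnames supply identifiers.
#' @param probe_annotation optional data frame with columns `probe_id`,
#'   `source` (`RefSeq`, `UniGene` or `Gnomon`), `chrom`, `gene_symbol`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_annotation = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (samples) and column names (probes)")
  if (anyDuplicated(colnames(values))) stop("duplicate probe ids")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (any(is.infinite(values))) stop("expression values must be finite")
  e <- structure(list(sample_ids = rownames(values),
                      probe_ids = colnames(values),
                      values = values,
                      probe_annotation = NULL),
                 class = "expression_matrix")
  if (!is.null(probe_annotation)) e <- set_probe_annotation(e, probe_annotation)
  e
}

#' Attach probe annotation to an expression matrix
#'
#' @param e an `expression_matrix`
#' @param annotation data frame with columns `probe_id`, `source`,
#'   `chrom`, `gene_symbol`
#' @return `e` with annotation attached (rows matched by `probe_id`)
#' @export
set_probe_annotation <- function(e, annotation) {
  stopifnot(inherits(e, "expression_matrix"))
  req <- c("probe_id", "source", "chrom", "gene_symbol")
  if (!all(req %in% names(annotation)))
    stop("probe annotation needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(annotation$probe_id)) stop("duplicate probe_id in annotation")
  e$probe_annotation <- as.data.frame(annotation)[, req]
  e
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d probes%s\n",
              length(x$sample_ids), length(x$probe_ids),
              if (is.null(x$probe_annotation)) " (no annotation)" else ""))
  invisible(x)
}

#' Construct population labels
#'
#' @param sample_ids character vector of sample identifiers
#' @param label character vector of population codes, one per sample
#' @return an object of class `population_labels` with elements
#'   `sample_ids`, `label` (named character vector) and `K`
#' @export
population_labels <- function(sample_ids, label) {
  sample_ids <- as.character(sample_ids)
  label <- as.character(label)
  if (length(sample_ids) != length(label))
    stop("`sample_ids` and `label` must have equal length")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in labels")
  if (anyNA(label)) stop("missing population label")
  k <- length(unique(label))
  if (k < 2) stop("K >= 2 required: need at least two distinct populations")
  names(label) <- sample_ids
  structure(list(sample_ids = sample_ids, label = label, K = k),
            class = "population_labels")
}

#' @export
print.population_labels <- function(x, ...) {
  cat(sprintf("population_labels: %d samples, K = %d (%s)\n",
              length(x$sample_ids), x$K,
              paste(names(table(x$label)), table(x$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

## ---- readers ----------------------------------------------------------

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(header))
    stop("malformed header: duplicate column id '",
         header[duplicated(header)][1L], "' in ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = "character",
                                        na.strings = NULL, ...),
                      check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Read a tabular genotype matrix
#'
#' Tab-separated file: header row of marker identifiers, first column of
#' sample identifiers, cells in `AA`/`AB`/`BB`/`NA` (`NA` = missing call).
#'
#' @param path path to the TSV file
#' @param annotation optional path to (or data frame of) marker annotation
#'   with columns `marker_id` and `chrom`
#' @return a [genotype_matrix()]
#' @export
read_genotypes_tabular <- function(path, annotation = NULL) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("malformed genotype file: need sample column plus markers")
  sample_ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m == "NA" | m == ""] <- NA_character_
  rownames(m) <- sample_ids
  chrom <- NULL
  if (!is.null(annotation)) {
    ann <- if (is.character(annotation)) read_marker_annotation(annotation) else annotation
    chrom <- ann$chrom[match(colnames(m), ann$marker_id)]
  }
  genotype_matrix(m, chrom = chrom)
}

#' Write a tabular genotype matrix
#'
#' @param g a [genotype_matrix()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_genotypes_tabular <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- g$calls
  m[is.na(m)] <- "NA"
  df <- data.frame(sample_id = g$sample_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Imports biallelic records only; multi-allelic records are skipped with
#' a warning.  `GT` values `0/0` map to `AA`, `0/1` and `1/0` to `AB`,
#' `1/1` to `BB`, and `./.` (or the phased equivalents) to missing.
#' The `CHROM` column becomes the per-marker chromosome label; VCF
#' coordinates are carried through unchanged (1-based, no arithmetic).
#'
#' @param path path to an uncompressed or bgzipped VCF 4.x file
#' @return a [genotype_matrix()]
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("package 'VariantAnnotation' is required to read VCF files")
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  gmat <- VariantAnnotation::geno(vcf)
  if (!("GT" %in% names(gmat))) stop("VCF has no GT genotype field")
  gt <- gmat$GT                      # markers x samples
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1L
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic VCF record(s)", sum(multi)))
    gt <- gt[!multi, , drop = FALSE]
    rr <- rr[!multi]
  }
  map <- c("0/0" = "AA", "0|0" = "AA",
           "0/1" = "AB", "1/0" = "AB", "0|1" = "AB", "1|0" = "AB",
           "1/1" = "BB", "1|1" = "BB",
           "./." = NA, ".|." = NA, "." = NA)
  known <- is.na(gt) | gt %in% names(map)
  if (!all(known))
    stop("unsupported GT value(s): ",
         paste(unique(gt[!known])[1:5], collapse = ", "))
  calls <- matrix(unname(map[gt]), nrow(gt), ncol(gt))
  calls[is.na(gt)] <- NA_character_
  rownames(calls) <- rownames(gt)
  colnames(calls) <- colnames(gt)
  genotype_matrix(t(calls),
                  chrom = as.character(GenomicRanges::seqnames(rr)))
}

#' Write genotypes to a minimal VCF 4.2 file
#'
#' Each marker becomes one biallelic record with REF `A`, ALT `B`
#' (placeholder alleles: the categorical calls, not nucleotides, are the
#' payload).  Positions are sequential within each chromosome unless
#' supplied.
#'
#' @param g a [genotype_matrix()]
#' @param path output path
#' @param pos optional integer vector of 1-based positions per marker
#' @return `path`, invisibly
#' @export
write_genotypes_vcf <- function(g, path, pos = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  chrom <- ifelse(is.na(g$chrom), "1", g$chrom)
  if (is.null(pos)) pos <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
  map <- c(AA = "0/0", AB = "0/1", BB = "1/1")
  gtm <- matrix("./.", length(g$marker_ids), length(g$sample_ids))
  filled <- !is.na(t(g$calls))
  gtm[filled] <- map[t(g$calls)[filled]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=aimsel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$sample_ids), collapse = "\t")), con)
  body <- cbind(chrom, pos, g$marker_ids, "A", "B", ".", ".", ".", "GT", gtm)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-separated, probes in rows (first column = probe identifier) and
#' samples in columns, as in GEO series-matrix files; the matrix is
#' transposed on load so samples are rows.  Empty cells are missing.
#'
#' @param path path to the TSV file
#' @param annotation optional path to (or data frame of) probe annotation
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path, annotation = NULL) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("malformed expression file: need probe column plus samples")
  probe_ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[raw == "" | raw == "NA"] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- is.na(num) & !is.na(raw)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value '%s' at probe '%s', sample '%s'",
                 raw[bad][1L], probe_ids[idx[1L]], colnames(raw)[idx[2L]]))
  }
  rownames(num) <- probe_ids
  colnames(num) <- colnames(raw)
  ann <- if (is.character(annotation)) read_probe_annotation(annotation) else annotation
  expression_matrix(t(num), probe_annotation = ann)
}

#' Write an expression matrix
#'
#' Probes x samples orientation on disk (the transpose of the in-memory
#' layout), matching [read_expression()].
#'
#' @param e an [expression_matrix()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_expression <- function(e, path) {
  stopifnot(inherits(e, "expression_matrix"))
  m <- t(e$values)
  ## 17 significant digits so write -> read is bit-exact for doubles
  txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m), dimnames = dimnames(m))
  txt[is.na(m)] <- "NA"
  df <- data.frame(probe_id = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read population labels
#'
#' Two-column TSV (`sample_id`, `label`).
#'
#' @param path path to the TSV file
#' @return a [population_labels()]
#' @export
read_labels <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("label file needs columns sample_id and label")
  population_labels(df[[1L]], df[[2L]])
}

#' Write population labels
#' @param labels a [population_labels()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "population_labels"))
  write.table(data.frame(sample_id = labels$sample_ids, label = labels$label),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe annotation
#'
#' TSV with columns `probe_id`, `source`, `chrom`, `gene_symbol` (an
#' empty `gene_symbol` means no gene information).
#'
#' @param path path to the TSV file
#' @return a data frame
#' @export
read_probe_annotation <- function(path) {
  df <- .read_tsv(path)
  req <- c("probe_id", "source", "chrom", "gene_symbol")
  if (!all(req %in% names(df)))
    stop("probe annotation needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  df$gene_symbol[df$gene_symbol == "" | df$gene_symbol == "NA"] <- NA_character_
  df[, req]
}

#' Read marker (SNP) annotation
#'
#' TSV with columns `marker_id` and `chrom`.
#'
#' @param path path to the TSV file
#' @return a data frame
#' @export
read_marker_annotation <- function(path) {
  df <- .read_tsv(path)
  req <- c("marker_id", "chrom")
  if (!all(req %in% names(df)))
    stop("marker annotation needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$marker_id)) stop("duplicate marker_id in annotation")
  df[, intersect(c("marker_id", "chrom", "position"), names(df))]
}

## ---- subsetting helpers ----------------------------------------------

#' Restrict a dataset to the samples carrying a label
#'
#' Samples present in a matrix but absent from the label file are dropped
#' with a warning (partially labeled cohorts are permitted); samples in
#' the label file but absent from every supplied matrix raise an error.
#'
#' @param labels a [population_labels()]
#' @param g optional [genotype_matrix()]
#' @param e optional [expression_matrix()]
#' @param populations optional character vector: keep only these labels
#' @return list with elements `genotypes`, `expression`, `labels`, all
#'   restricted to the common samples in a stable order
#' @export
align_samples <- function(labels, g = NULL, e = NULL, populations = NULL) {
  stopifnot(inherits(labels, "population_labels"))
  if (is.null(g) && is.null(e)) stop("supply at least one of `g`, `e`")
  keep <- labels$sample_ids
  if (!is.null(populations)) keep <- keep[labels$label[keep] %in% populations]
  present <- rep(TRUE, length(keep))
  for (m in list(g, e)) if (!is.null(m)) present <- present & keep %in% m$sample_ids
  if (!any(present)) stop("no labeled sample found in the supplied matrices")
  missing_lab <- keep[!present]
  if (length(missing_lab))
    stop("labeled sample(s) absent from a matrix: ",
         paste(utils::head(missing_lab, 5), collapse = ", "))
  keep <- keep[present]
  for (m in list(g, e)) {
    if (is.null(m)) next
    extra <- setdiff(m$sample_ids, keep)
    if (length(extra))
      warning(sprintf("dropping %d unlabeled/out-of-scope sample(s)", length(extra)))
  }
  lab2 <- population_labels(keep, labels$label[keep])
  g2 <- if (!is.null(g))
    genotype_matrix(g$calls[keep, , drop = FALSE], chrom = g$chrom) else NULL
  e2 <- if (!is.null(e)) {
    em <- expression_matrix(e$values[keep, , drop = FALSE])
    em$probe_annotation <- e$probe_annotation
    em
  } else NULL
  list(genotypes = g2, expression = e2, labels = lab2)
}
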