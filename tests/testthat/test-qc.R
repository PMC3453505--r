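test_that("call_rate counts non-missing calls", {
  expect_equal(call_rate(c("AA", "AB", NA, "BB")), 0.75)
  expect_equal(call_rate(c(NA_character_, NA_character_)), 0)
  expect_equal(call_rate(c("AA", "AB", "BB")), 1)
  expect_error(call_rate(character(0)), "empty")
})

test_that("minor_allele_frequency counts B alleles over non-missing calls", {
  expect_equal(minor_allele_frequency(c("AA", "AA", "AA")), 0)
  expect_equal(minor_allele_frequency(c("AA", "AB", "BB")), 0.5)
  expect_equal(minor_allele_frequency(c("AA", "AA", "AB")), 1 / 6)
  expect_equal(minor_allele_frequency(c("BB", "BB", NA)), 0)  # folded
  expect_error(minor_allele_frequency(c(NA_character_)), "missing")
})

test_that("fdr_adjust matches the Benjamini-Hochberg closed form", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.05), 0.05)
  expect_equal(fdr_adjust(c(0.001, 0.9)), c(0.002, 0.9))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # property: agrees with the reference BH implementation
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_adjust(p), stats::p.adjust(p, "BH"))
  }
})

test_that("hwe_permutation_test matches its worked examples", {
  # perfect HWE proportions: the observed het count sits at its expectation
  expect_gte(hwe_permutation_test(25, 50, 25, n_perm = 2000, seed = 1), 0.5)
  # extreme heterozygote deficit
  expect_lte(hwe_permutation_test(5, 0, 5, n_perm = 10000, seed = 1), 0.01)
  # monomorphic: statistic degenerate
  expect_equal(hwe_permutation_test(3, 0, 0, n_perm = 10), 1.0)
  expect_error(hwe_permutation_test(-1, 2, 3), "non-negative")
})

test_that("hwe permutation p converges to the exact enumeration p", {
  # oracle self-check: closed-form pairing pmf equals brute-force
  # enumeration on very small pools
  for (tab in list(c(2, 1, 1), c(3, 0, 2), c(1, 2, 0), c(2, 2, 2))) {
    expect_equal(oracle_hwe_exact(tab[1], tab[2], tab[3]),
                 oracle_hwe_enumerate(tab[1], tab[2], tab[3]),
                 tolerance = 1e-12)
  }
  # Monte-Carlo vs exact on a spread of tables at moderate n_perm
  tables <- list(c(5, 0, 5), c(4, 2, 4), c(1, 8, 1), c(6, 3, 1), c(2, 5, 3))
  n_perm <- 20000
  for (tab in tables) {
    pe <- oracle_hwe_exact(tab[1], tab[2], tab[3])
    pm <- hwe_permutation_test(tab[1], tab[2], tab[3], n_perm = n_perm,
                               seed = oracle_table_seed(1, paste(tab, collapse = "_")))
    tol <- max(3 * sqrt(pe * (1 - pe) / n_perm), 3 / (n_perm + 1))
    expect_lt(abs(pm - (1 + n_perm * pe) / (1 + n_perm)), tol + 1e-12)
  }
})

test_that("filter_snps assigns removal reasons as a union", {
  # marker 1: call rate 0.8 (< 0.9); marker 2: monomorphic; marker 3:
  # chrX but otherwise clean; marker 4: clean autosomal
  g <- gm(c("AA", "AA", "AA", "AB"),
          c("AA", "AA", "AA", "AB"),
          c("AB", "AA", "AA", "BB"),
          c("AB", "AA", "AB", "AB"),
          c(NA,   "AA", "BB", "AA"),
          chrom = c("1", "2", "X", "5"))
  res <- filter_snps(g, snp_qc_config(seed = 42))
  rec <- res$report$records
  expect_match(rec$removal_reasons[1], "CALL_RATE")
  expect_identical(rec$removal_reasons[2], "MAF_ZERO")
  expect_identical(rec$removal_reasons[3], "SEX_CHROM")
  expect_identical(rec$removal_reasons[4], "")
  expect_identical(res$genotypes$marker_ids, "m004")
  # reason counts match record tallies; survivor arithmetic holds
  expect_equal(res$report$n_survivors,
               res$report$n_input - sum(rec$removal_reasons != ""))
  expect_equal(unname(res$report$reason_counts["MAF_ZERO"]),
               sum(grepl("MAF_ZERO", rec$removal_reasons)))
})

test_that("the HWE rule triggers on FDR-adjusted p below alpha", {
  # 30 clean markers in HWE plus one with a gross het deficit
  set.seed(77)
  n <- 60
  clean <- replicate(30, {
    d <- rbinom(n, 2, 0.5)
    c("AA", "AB", "BB")[d + 1]
  })
  bad <- sample(c(rep("AA", 30), rep("BB", 30)))
  calls <- cbind(clean, bad)
  dimnames(calls) <- list(sprintf("s%03d", 1:n), sprintf("m%03d", 1:31))
  g <- genotype_matrix(calls, chrom = rep("1", 31))
  res <- filter_snps(g, snp_qc_config(hwe_permutations = 5000, seed = 3))
  rec <- res$report$records
  expect_match(rec$removal_reasons[31], "HWE")
  expect_false(any(grepl("HWE", rec$removal_reasons[1:30])))
})

test_that("filter_snps is idempotent for a fixed seed", {
  set.seed(11)
  n <- 50
  calls <- replicate(40, {
    p <- runif(1, 0.2, 0.8)
    v <- c("AA", "AB", "BB")[rbinom(n, 2, p) + 1]
    v[runif(n) < 0.05] <- NA
    v
  })
  dimnames(calls) <- list(sprintf("s%03d", 1:n), sprintf("m%03d", 1:40))
  g <- genotype_matrix(calls, chrom = sample(c(1:22, "X"), 40, replace = TRUE))
  cfg <- snp_qc_config(seed = 99)
  once <- filter_snps(g, cfg)
  twice <- filter_snps(once$genotypes, cfg)
  expect_identical(twice$genotypes$marker_ids, once$genotypes$marker_ids)
  expect_equal(twice$report$n_removed, 0)
})

test_that("filter_probes applies the annotation rules", {
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(sprintf("s%d", 1:3), sprintf("p%d", 1:4)))
  ann <- data.frame(probe_id = sprintf("p%d", 1:4),
                    source = c("UniGene", "RefSeq", "RefSeq", "RefSeq"),
                    chrom = c("1", "Y", "2", "3"),
                    gene_symbol = c("G1", "G2", NA, "G4"),
                    stringsAsFactors = FALSE)
  e <- expression_matrix(v, probe_annotation = ann)
  res <- filter_probes(e)
  rec <- res$report$records
  expect_match(rec$removal_reasons[1], "NON_REFSEQ")
  expect_identical(rec$removal_reasons[2], "SEX_CHROM")
  expect_identical(rec$removal_reasons[3], "NO_GENE_INFO")
  expect_identical(rec$removal_reasons[4], "")
  expect_identical(res$expression$probe_ids, "p4")
})

test_that("probes without an annotation record are NO_GENE_INFO", {
  v <- matrix(rnorm(6), 3, 2,
              dimnames = list(sprintf("s%d", 1:3), c("p1", "p2")))
  ann <- data.frame(probe_id = "p1", source = "RefSeq", chrom = "1",
                    gene_symbol = "G1", stringsAsFactors = FALSE)
  e <- expression_matrix(v, probe_annotation = ann)
  expect_warning(res <- filter_probes(e), "NO_GENE_INFO")
  expect_identical(res$report$records$removal_reasons[2], "NO_GENE_INFO")
  expect_identical(res$expression$probe_ids, "p1")
})
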