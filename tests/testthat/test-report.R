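# One modest cross-validated run shared by the report tests.
report_fixture <- local({
  out <- NULL
  function() {
    if (!is.null(out)) return(out)
    cfg <- sim_config(populations = c(A = 16, B = 16), n_noise_snps = 30,
                      n_info_snps = 1, info_freq = matrix(c(0.05, 0.95), 1, 2),
                      n_noise_ge = 20, n_info_ge = 1, ge_shift = 2,
                      missing_rate = 0.02, seed = 71)
    ds <- simulate_dataset(cfg)
    cv <- make_cv_partition(ds$labels, k = 4, seed = 71)
    cms <- run_cross_validation(ds$genotypes, ds$expression, ds$labels, cv)
    out <<- list(ds = ds, cms = cms)
    out
  }
})

test_that("misclassification report bookkeeping is consistent", {
  fx <- report_fixture()
  rep <- misclassification_report(fx$cms)
  # every sample is a test sample in exactly one fold of a full partition
  expect_true(all(rep$n_test == 1))
  expect_true(all(rep$n_train == fx$cms$k - 1))
  expect_true(all(rep$test_misclassification %in% c(0, 1)))
  # column sums equal total error counts across folds
  total_test_errors <- sum(vapply(fx$cms$folds, function(f)
    sum(f$test_result$predicted_label != f$test_result$true_label),
    numeric(1)))
  expect_equal(sum(rep$test_misclassification * rep$n_test), total_test_errors)
  per_step <- attr(rep, "per_step")
  expect_equal(per_step$train_misclassification,
               1 - do.call(rbind, lapply(fx$cms$folds, function(f)
                 f$trace$steps))$train_accuracy)
})

test_that("marker impact report counts selections per fold", {
  fx <- report_fixture()
  imp <- marker_impact_report(fx$cms)
  expect_true(all(imp$selection_times <= fx$cms$k))
  all_sel <- unlist(lapply(fx$cms$folds, function(f) f$trace$markers))
  expect_setequal(imp$marker, unique(all_sel))
  for (i in seq_len(nrow(imp)))
    expect_equal(imp$selection_times[i], sum(all_sel == imp$marker[i]))
  # never-selected markers are absent
  expect_false(any(!imp$marker %in% all_sel))
})

test_that("genotype frequency rows sum to one over non-missing calls", {
  g <- gm(c("AA", "AA"), c("AA", "AB"), c("AB", "BB"), c("BB", NA),
          ids = sprintf("s%d", 1:4))
  lab <- population_labels(sprintf("s%d", 1:4), c("P", "P", "Q", "Q"))
  tab <- genotype_frequency_report("m001", g, lab)
  expect_equal(unname(unlist(tab[tab$population == "P", c("AA", "AB", "BB")])),
               c(1, 0, 0))
  expect_equal(rowSums(tab[, c("AA", "AB", "BB")]), c(1, 1),
               ignore_attr = TRUE)
  # worked example: {AA, AA, AB, BB} -> (0.5, 0.25, 0.25)
  lab2 <- population_labels(c(sprintf("t%d", 1:4), "u1"),
                            c(rep("P", 4), "Q"))
  g2b <- gm(c("AA"), c("AA"), c("AB"), c("BB"), c("AB"),
            ids = c(sprintf("t%d", 1:4), "u1"))
  tab2 <- genotype_frequency_report("m001", g2b, lab2)
  expect_equal(unname(unlist(tab2[tab2$population == "P",
                                  c("AA", "AB", "BB")])),
               c(0.5, 0.25, 0.25))
  # pair mode has nine combination columns summing to one
  gp <- gm(c("AA", "AA"), c("AA", "AB"), c("AB", "BB"), c("BB", "BB"),
           ids = sprintf("s%d", 1:4))
  tabp <- genotype_frequency_report(c("m001", "m002"), gp, lab)
  expect_equal(ncol(tabp), 10)   # population + 9 combinations
  expect_equal(unname(rowSums(tabp[, -1])), c(1, 1))
})

test_that("classical MDS has its closed-form behaviors", {
  # two samples: +/- d/2 on the first axis, first coordinate positive
  x <- fm(matrix(c(0, 3), 2, 1))
  co <- mds_coordinates(x)
  d <- dist(scale(x$values))[1]
  expect_equal(unname(co[, 1]), c(d / 2, -d / 2))
  expect_equal(unname(co[, 2]), c(0, 0))
  # planar configurations are reproduced exactly (up to rotation):
  # pairwise distances preserved to 1e-8
  set.seed(99)
  pts <- matrix(rnorm(20), 10, 2)
  xf <- fm(pts)
  co2 <- mds_coordinates(xf)
  expect_equal(as.numeric(dist(co2)), as.numeric(dist(scale(pts))),
               tolerance = 1e-8)
  # duplicated samples land on identical coordinates
  dup <- fm(rbind(pts, pts[1, , drop = FALSE]))
  co3 <- mds_coordinates(dup)
  expect_equal(unname(co3[11, ]), unname(co3[1, ]), tolerance = 1e-9)
  # constant features: zero coordinates with a warning
  expect_warning(z <- mds_coordinates(fm(matrix(5, 4, 2))), "constant")
  expect_true(all(z == 0))
})

test_that("run_pipeline is deterministic and reproducible from disk", {
  cfg <- sim_config(populations = c(A = 12, B = 12), n_noise_snps = 25,
                    n_info_snps = 1, info_freq = matrix(c(0, 1), 1, 2),
                    n_noise_ge = 15, n_info_ge = 1, missing_rate = 0.02,
                    seed = 81)
  ds <- simulate_dataset(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  rc <- function(out) run_config(mode = "snp+ge", genotypes = ds$genotypes,
                                 expression = ds$expression,
                                 labels = ds$labels, folds = 4, seed = 9,
                                 out_dir = out)
  b1 <- run_pipeline(rc(d1))
  b2 <- run_pipeline(rc(d2))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_identical(b1$manifest$best_markers, b2$manifest$best_markers)
  # rerunning from the files on disk reproduces the tables byte-identically
  d3 <- tempfile(); dir.create(d3)
  write_dataset(ds, d3)
  d4 <- tempfile()
  b3 <- run_pipeline(run_config(
    mode = "snp+ge", genotypes = file.path(d3, "genotypes.tsv"),
    expression = file.path(d3, "expression.tsv"),
    labels = file.path(d3, "labels.tsv"),
    marker_annotation = file.path(d3, "marker_annotation.tsv"),
    probe_annotation = file.path(d3, "probe_annotation.tsv"),
    folds = 4, seed = 9, out_dir = d4))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d4, f)), readLines(file.path(d1, f)),
                     label = f)
  unlink(c(d1, d2, d3, d4), recursive = TRUE)
})

test_that("mode-required inputs are validated before any computation", {
  expect_error(run_config(mode = "ge", labels = "labs.tsv"), "expression")
  expect_error(run_config(mode = "snp", labels = "labs.tsv"), "genotype")
})
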