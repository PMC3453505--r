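test_that("make_cv_partition stratifies within populations", {
  lab <- labs(rep(c("CHB", "JPT"), each = 45),
              ids = sprintf("s%03d", 1:90))
  cv <- make_cv_partition(lab, k = 10, seed = 4)
  for (pop in c("CHB", "JPT")) {
    sizes <- table(cv$fold[lab$sample_ids[lab$label == pop]])
    expect_true(all(sizes %in% 4:5))
  }
  expect_equal(sort(unique(cv$fold)), 1:10)
  # determinism
  cv2 <- make_cv_partition(lab, k = 10, seed = 4)
  expect_identical(cv2$fold, cv$fold)
  expect_false(identical(make_cv_partition(lab, k = 10, seed = 5)$fold,
                         cv$fold))
  expect_error(make_cv_partition(lab, k = 1), "k >= 2")
})

test_that("small populations spread over distinct folds", {
  lab <- labs(c(rep("A", 4), rep("B", 4)), ids = sprintf("s%03d", 1:8))
  cv <- make_cv_partition(lab, k = 2, seed = 1)
  expect_equal(as.integer(table(cv$fold)), c(4L, 4L))
  cv6 <- make_cv_partition(labs(c(rep("A", 3), rep("B", 12)),
                                ids = sprintf("s%03d", 1:15)), k = 6, seed = 2)
  a_folds <- cv6$fold[sprintf("s%03d", 1:3)]
  expect_equal(length(unique(a_folds)), 3)
})

test_that("forward_select picks the separating marker and stops", {
  set.seed(10)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  sep <- c(rep(0, n / 2), rep(2, n / 2))
  noise <- sample(0:2, n, replace = TRUE)
  vals <- cbind(M1 = sep, M2 = noise)
  rownames(vals) <- sprintf("s%03d", 1:n)
  tr <- forward_select(fm(vals), labs(y))
  expect_identical(tr$markers, "M1")
  expect_equal(tr$final_accuracy, 1.0)
})

test_that("accuracy ties break by minimum SSW/SSB then marker id", {
  n <- 20
  y <- rep(c("a", "b"), each = n / 2)
  tight <- c(rep(0, n / 2), rep(2, n / 2))              # SSW/SSB = 0
  loose <- tight + rep(c(-0.3, 0.3), n / 2)             # separates, SSW > 0
  vals <- cbind(M_loose = loose, M_tight = tight)
  rownames(vals) <- sprintf("s%03d", 1:n)
  tr <- forward_select(fm(vals), labs(y))
  expect_identical(tr$markers[1], "M_tight")
  # exact duplicates: lexicographically smallest id wins
  vals2 <- cbind(Mb = tight, Ma = tight)
  rownames(vals2) <- sprintf("s%03d", 1:n)
  tr2 <- forward_select(fm(vals2), labs(y))
  expect_identical(tr2$markers[1], "Ma")
})

test_that("an uninformative pool still returns one marker", {
  n <- 12
  vals <- matrix(1, n, 3, dimnames = list(sprintf("s%03d", 1:n),
                                          c("c1", "c2", "c3")))
  y <- c(rep("a", 8), rep("b", 4))
  tr <- forward_select(fm(vals), labs(y))
  expect_equal(length(tr$markers), 1)
  expect_equal(tr$final_accuracy, 8 / 12)
})

test_that("forward_select equals exhaustive oracle selection", {
  for (seed in c(101, 102, 103)) {
    pool <- random_marker_pool(seed, n = 40, m = 8)
    got <- forward_select(fm(pool$vals), labs(pool$y))$markers
    want <- oracle_forward_select(pool$vals, pool$y)
    expect_identical(got, want)
  }
})

test_that("max_markers and min_increment stopping modes work", {
  pool <- random_marker_pool(7, n = 40, m = 10)
  capped <- forward_select(fm(pool$vals), labs(pool$y),
                           selection_config(max_markers = 2))
  expect_lte(length(capped$markers), 2)
  # a huge min_increment stops after the mandatory first marker
  one <- forward_select(fm(pool$vals), labs(pool$y),
                        selection_config(min_increment = 0.9))
  expect_equal(length(one$markers), 1)
})

test_that("run_cross_validation returns k consistent traces", {
  set.seed(61)
  cfg <- sim_config(populations = c(A = 20, B = 20), n_noise_snps = 30,
                    n_info_snps = 1, info_freq = matrix(c(0, 1), 1, 2),
                    n_noise_ge = 0, missing_rate = 0, seed = 61)
  ds <- simulate_dataset(cfg)
  cv <- make_cv_partition(ds$labels, k = 10, seed = 61)
  cms <- run_cross_validation(ds$genotypes, NULL, ds$labels, cv)
  expect_length(cms$folds, 10)
  accs <- vapply(cms$folds, `[[`, numeric(1), "testing_accuracy")
  expect_true(all(accs >= 0 & accs <= 1))
  # the fixed-difference SNP is selected first everywhere
  planted <- ds$truth$informative_snp_ids
  first <- vapply(cms$folds, function(f) f$trace$markers[1], character(1))
  expect_identical(unique(first), planted)
  expect_equal(unname(cms$selection_times[planted]), 10L)
  expect_equal(cms$best$testing_accuracy, 1.0)
  # training accuracy is monotone within traces
  for (f in cms$folds)
    expect_true(all(diff(f$trace$steps$train_accuracy) >= 0))
})

test_that("sample order does not change fold selections", {
  set.seed(62)
  cfg <- sim_config(populations = c(A = 15, B = 15), n_noise_snps = 20,
                    n_info_snps = 1, info_freq = matrix(c(0.1, 0.9), 1, 2),
                    n_noise_ge = 0, missing_rate = 0, seed = 62)
  ds <- simulate_dataset(cfg)
  cv <- make_cv_partition(ds$labels, k = 5, seed = 62)
  cms1 <- run_cross_validation(ds$genotypes, NULL, ds$labels, cv)
  perm <- sample(ds$labels$sample_ids)
  g2 <- genotype_matrix(ds$genotypes$calls[perm, , drop = FALSE],
                        chrom = ds$genotypes$chrom)
  lab2 <- population_labels(perm, ds$labels$label[perm])
  cms2 <- run_cross_validation(g2, NULL, lab2, cv)
  for (i in 1:5)
    expect_identical(cms2$folds[[i]]$trace$markers,
                     cms1$folds[[i]]$trace$markers)
})

test_that("select_best_model applies the documented tie-break chain", {
  mk <- function(fold, acc, markers) {
    list(fold = fold, testing_accuracy = acc,
         trace = list(markers = markers, final_accuracy = 1,
                      steps = data.frame()))
  }
  build <- function(folds) {
    sets <- vapply(folds, function(f) paste(sort(f$trace$markers),
                                            collapse = "|"), character(1))
    structure(list(folds = folds, k = length(folds),
                   cvc = vapply(sets, function(s) sum(sets == s), integer(1))),
              class = "candidate_model_set")
  }
  # highest testing accuracy wins
  c1 <- build(list(mk(1L, 0.8, "a"), mk(2L, 1.0, c("a", "b")), mk(3L, 0.9, "c")))
  expect_equal(select_best_model(c1)$best_fold, 2L)
  # tie: fewest markers
  c2 <- build(list(mk(1L, 1.0, c("a", "b", "c", "d", "e")),
                   mk(2L, 1.0, c("a", "b", "c"))))
  expect_equal(select_best_model(c2)$best_fold, 2L)
  # tie on size: highest set consistency
  c3 <- build(list(mk(1L, 1.0, c("x", "y", "z")),
                   mk(2L, 1.0, c("a", "b", "c")), mk(3L, 1.0, c("a", "b", "c")),
                   mk(4L, 1.0, c("b", "a", "c")), mk(5L, 1.0, c("a", "c", "b")),
                   mk(6L, 0.5, "q")))
  expect_equal(select_best_model(c3)$best_fold, 2L)
  # full tie: lowest fold index
  c4 <- build(list(mk(1L, 0.9, "a"), mk(2L, 0.9, "a")))
  expect_equal(select_best_model(c4)$best_fold, 1L)
})
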