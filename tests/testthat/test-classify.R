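binormal_data <- function(n_per_class, d, seed) {
  withr::with_seed(seed, {
    list(x = c(rnorm(n_per_class, 0), rnorm(n_per_class, d)),
         y = factor(rep(c("A", "B"), each = n_per_class), levels = c("A", "B")))
  })
}

test_that("perfectly separated classes reach AUC 1", {
  x <- c(seq(0, 1, length.out = 50), seq(2, 3, length.out = 50))
  y <- factor(rep(c("A", "B"), each = 50), levels = c("A", "B"))
  res <- classify_groups(x, y, n_folds = 5, seed = 1)
  expect_equal(res$auc_mean, 1)
  expect_equal(res$fold_aucs, rep(1, 5))
})

test_that("stratification preserves test folds and undersampling equalizes
           training classes", {
  dat <- binormal_data(200, 1, seed = 31)
  # imbalance: drop 120 of class B
  keep <- c(1:200, 201:280)
  x <- dat$x[keep]; y <- droplevels(dat$y[keep])
  folds <- make_stratified_folds(y, 5, seed = 3)
  for (f in 1:5) {
    tab <- table(y[folds == f])
    expect_equal(unname(tab["A"]), 40) # 200 / 5: class ratio preserved
    expect_equal(unname(tab["B"]), 16)
  }
  res <- classify_groups(x, y, n_folds = 5, seed = 3, folds = folds)
  # training folds balanced to the minority count after undersampling
  expect_true(all(res$n_per_class_used["A", ] == res$n_per_class_used["B", ]))
  expect_true(all(res$n_per_class_used["B", ] == 64)) # 80 - 16 held out
})

test_that("AUC is invariant under strictly increasing transforms of 1-D input", {
  dat <- binormal_data(300, 1, seed = 32)
  r1 <- classify_groups(dat$x, dat$y, seed = 5)
  r2 <- classify_groups(exp(dat$x), dat$y, seed = 5)
  expect_equal(r2$fold_aucs, r1$fold_aucs, tolerance = 1e-10)
})

test_that("classification is bit-reproducible under a fixed seed", {
  dat <- binormal_data(150, 0.8, seed = 33)
  r1 <- classify_groups(dat$x, dat$y, seed = 17)
  r2 <- classify_groups(dat$x, dat$y, seed = 17)
  expect_identical(r1$fold_aucs, r2$fold_aucs)
  expect_identical(r1$n_per_class_used, r2$n_per_class_used)
})

test_that("AUC grows with class separation", {
  seps <- c(0, 0.5, 1, 2)
  mean_auc <- vapply(seps, function(d) {
    mean(vapply(1:8, function(s) {
      dat <- binormal_data(300, d, seed = 40 + s)
      classify_groups(dat$x, dat$y, seed = s)$auc_mean
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) > -0.02)) # non-decreasing within noise
  expect_lt(mean_auc[1], 0.55)
  expect_gt(mean_auc[4], 0.9)
})

test_that("degenerate constant inputs give chance AUC with a warning", {
  y <- factor(rep(c("A", "B"), each = 30))
  expect_warning(res <- classify_groups(rep(1, 60), y, seed = 1),
                 "single unique value")
  expect_equal(res$auc_mean, 0.5)
})

test_that("classify_groups validates classes and fold counts", {
  y3 <- factor(rep(c("A", "B", "C"), each = 20))
  expect_error(classify_groups(rnorm(60), y3), "exactly 2 levels")
  y <- factor(rep(c("A", "B"), c(50, 3)))
  expect_error(classify_groups(rnorm(53), y, n_folds = 5), "at least n_folds")
})

test_that("repeat-seed mode separates split noise from fold variance", {
  dat <- binormal_data(500, 1, seed = 35)
  rep5 <- classify_groups_repeated(dat$x, dat$y, seed = 9, n_repeats = 5)
  expect_equal(nrow(rep5$per_seed), 5)
  expect_gt(length(unique(rep5$per_seed$auc_mean)), 1) # seeds really differ
  expect_lt(rep5$auc_sd_across_seeds, rep5$auc_sd_across_folds)
  expect_equal(rep5$auc_mean, stats::pnorm(1 / sqrt(2)), tolerance = 0.05)
})

test_that("augmentation comparison produces four paired rows and flags
           missing deltas", {
  co <- generate_cohort(toy_spec(n_cn = 80, n_ad = 60, offset_ad = 0,
                                 seed = 51), seed = 51)
  pair <- group_pair("CN", "AD")
  # label signal lives only in "score"; deltas are pure noise by design
  deltas <- data.frame(subject_id = co$subject_id,
                       delta = withr::with_seed(52, rnorm(n_subjects(co))))
  out <- augmentation_comparison(co, pair, deltas, feature_set = "score",
                                 n_folds = 5, seed = 2)
  expect_equal(out$input_set,
               c("features", "features+age", "delta", "features+delta"))
  res <- attr(out, "results")
  expect_true(all(vapply(res, function(r) length(r$fold_aucs), numeric(1)) == 5))
  # a noise delta adds nothing to the informative feature (paired folds)
  expect_equal(out$auc_mean[out$input_set == "features+delta"],
               out$auc_mean[out$input_set == "features"], tolerance = 0.05)
  expect_gt(out$auc_mean[out$input_set == "features"], 0.8)

  expect_error(
    augmentation_comparison(co, pair, deltas[-1, ], "score", seed = 2),
    "missing delta.*S00001"
  )
})
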