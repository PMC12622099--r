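# one default synthetic cohort shared by the heavier pipeline tests
influence_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(default_adni_like_spec(1), seed = 301)
      run <- run_feature_influence(coh, group_pair("CN", "AD"),
                                   run_config(seed = 77))
      cache <<- list(cohort = coh, run = run)
    }
    cache
  }
})

test_that("feature influence yields two complete progression curves", {
  fx <- influence_fixture()
  curves <- fx$run$curves
  expect_named(curves, c("age", "discrimination"))
  for (cv in curves) {
    expect_equal(cv$k, 1:16) # one point per nested set, strictly increasing
    expect_false(anyNA(cv$mae))
    expect_false(anyNA(cv$auc))
  }
  expect_equal(curves$age$criterion[1], "age")
  expect_equal(curves$discrimination$criterion[1], "CN vs AD")
})

test_that("both orderings coincide exactly at the full feature set", {
  fx <- influence_fixture()
  a <- fx$run$curves$age
  d <- fx$run$curves$discrimination
  expect_identical(a$mae[a$k == 16], d$mae[d$k == 16])
  expect_identical(a$auc[a$k == 16], d$auc[d$k == 16])
})

test_that("a pure-noise extra feature does not displace the top-ranked
           feature", {
  fx <- influence_fixture()
  coh <- fx$cohort
  top1 <- function(cohort, seed) {
    rank_features(mi_with_age(cohort, seed = seed))$order[1]
  }
  for (s in 1:10) {
    noisy <- cohort_table(
      coh$subject_id, coh$age, coh$label,
      cbind(coh$features,
            pure_noise = withr::with_seed(600 + s, rnorm(n_subjects(coh)))),
      label_levels = coh$label_levels
    )
    expect_equal(top1(noisy, seed = s), top1(coh, seed = s))
  }
})

test_that("model comparison produces four aligned curves and the ridge/linear
           pair overlaps at small penalty", {
  fx <- influence_fixture()
  cfg <- run_config(seed = 88, ks = c(1, 3),
                    model_hyperparams = list(ridge = list(lambda = 1e-6)))
  run <- run_model_vs_logistic(fx$cohort, group_pair("CN", "AD"), cfg)
  kinds <- c("delta-linear", "delta-ridge", "delta-svr", "direct-logistic")
  for (ord in c("age", "discrimination")) {
    sub <- run$curves[run$curves$ordering == ord, ]
    expect_setequal(unique(sub$model_kind), kinds)
    for (kind in kinds) {
      expect_equal(sub$k[sub$model_kind == kind], c(1, 3)) # same k grid
    }
  }
  lin <- run$curves[run$curves$model_kind == "delta-linear", "auc_mean"]
  rid <- run$curves[run$curves$model_kind == "delta-ridge", "auc_mean"]
  expect_equal(rid, lin, tolerance = 0.005)
  expect_equal(run$augmentation$input_set,
               c("features", "features+age", "delta", "features+delta"))
})

test_that("deltas discard label signal orthogonal to age, direct logistic
           keeps it", {
  spec <- synthetic_spec(
    c(CN = 150, AD = 100),
    features = list(
      feature_spec("tracker", age_slope = 1, noise_sd = 1),
      feature_spec("marker", age_slope = 0, group_offsets = c(AD = 2),
                   noise_sd = 1)
    ),
    seed = 71
  )
  coh <- generate_cohort(spec, seed = 71)
  run <- run_model_vs_logistic(coh, group_pair("CN", "AD"),
                               run_config(seed = 5, ks = 2))
  full <- run$curves[run$curves$ordering == "age", ]
  direct <- full$auc_mean[full$model_kind == "direct-logistic"]
  deltas <- full$auc_mean[full$model_kind != "direct-logistic"]
  expect_gt(direct, max(deltas))
  expect_gt(direct, 0.85)
})

test_that("write_report emits CSVs, figure, config and a traceable manifest,
           byte-identically on rerun", {
  fx <- influence_fixture()
  d1 <- file.path(withr::local_tempdir(), "r1")
  files <- write_report(fx$run, d1)
  expect_true(all(file.exists(files)))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$master_seed, 77)
  expect_equal(man$mi_k_neighbors, 3)
  expect_match(man$config_md5, "^[0-9a-f]{32}$")
  expect_true(all(c("rankings.csv", "influence_curves.csv", "config.json") %in%
                    unlist(man$files)))

  # rerunning the same configuration reproduces the CSVs byte for byte
  coh2 <- generate_cohort(default_adni_like_spec(1), seed = 301)
  run2 <- run_feature_influence(coh2, group_pair("CN", "AD"),
                                run_config(seed = 77))
  d2 <- file.path(withr::local_tempdir(), "r2")
  write_report(run2, d2, plots = FALSE)
  for (f in c("rankings.csv", "influence_curves.csv")) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
  }
})

test_that("stage errors are annotated with criterion and set size", {
  coh <- generate_cohort(toy_spec(n_cn = 6, n_ad = 8), seed = 1)
  expect_error(
    run_feature_influence(coh, group_pair("CN", "AD"),
                          run_config(seed = 1, n_folds = 7)),
    "\\[criterion=.*k=1\\] fewer controls"
  )
})
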