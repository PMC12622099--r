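test_that("a perfect single-feature predictor yields near-zero MAE for all
           three regressors", {
  co <- age_feature_cohort(n = 100, noise_sd = 0, seed = 7)
  mae <- function(reg, hp = list()) {
    fit_age_model(co, age_model_spec("f", regressor = reg, hyperparams = hp,
                                     seed = 3))$mae_uncorrected
  }
  expect_lte(mae("linear"), 0.01)
  expect_lte(mae("ridge", list(lambda = 1e-8)), 0.01)
  # RBF SVR needs a laxer budget than the default cost to track a 35-year
  # span through the epsilon tube
  expect_lte(mae("svr", list(cost = 100)), 0.5)
})

test_that("fold models never see their held-out subjects (leakage guard)", {
  co <- age_feature_cohort(n = 20, noise_sd = 2, seed = 8)
  m <- fit_age_model(co, age_model_spec("f", n_folds = 2, seed = 5))
  for (f in 1:2) {
    tr <- m$fold_assignment != f
    expect_equal(unname(m$fold_pipelines[[f]]$scaler$center["f"]),
                 mean(co$features[tr, "f"]))
    expect_equal(unname(m$fold_pipelines[[f]]$scaler$scale["f"]),
                 sd(co$features[tr, "f"]))
  }
  # every control has exactly one out-of-fold prediction
  expect_setequal(names(m$oof_predictions), co$subject_id)
})

test_that("refitting with the same seed is bit-identical", {
  co <- age_feature_cohort(n = 200, noise_sd = 3, seed = 9)
  m1 <- fit_age_model(co, age_model_spec("f", seed = 11))
  m2 <- fit_age_model(co, age_model_spec("f", seed = 11))
  expect_identical(m1$oof_predictions, m2$oof_predictions)
  expect_identical(m1$bias_coefficients, m2$bias_coefficients)
  m3 <- fit_age_model(co, age_model_spec("f", seed = 12))
  expect_false(identical(m1$fold_assignment, m3$fold_assignment))
})

test_that("feature order in the spec does not change the fit", {
  spec2 <- synthetic_spec(
    c(CN = 150),
    features = list(
      feature_spec("b", age_slope = -0.05, noise_sd = 0.3),
      feature_spec("a", age_slope = 0.03, noise_sd = 0.3)
    ),
    seed = 2
  )
  co <- generate_cohort(spec2)
  m_ab <- fit_age_model(co, age_model_spec(c("a", "b"), seed = 4))
  m_ba <- fit_age_model(co, age_model_spec(c("b", "a"), seed = 4))
  expect_identical(m_ab$oof_predictions, m_ba$oof_predictions)
})

test_that("training-cohort preconditions are enforced", {
  co_mixed <- generate_cohort(toy_spec(), seed = 1)
  expect_error(fit_age_model(co_mixed, age_model_spec("vol")),
               "single \\(control\\) label")
  co_small <- age_feature_cohort(n = 3)
  expect_error(fit_age_model(co_small, age_model_spec("f", n_folds = 5)),
               "fewer controls")
  co <- age_feature_cohort(n = 50)
  expect_error(fit_age_model(co, age_model_spec("nope")), "not in cohort")
})

test_that("bias correction recovers exact and noisy linear prediction bias", {
  age <- seq(60, 80, length.out = 50)
  expect_equal(fit_bias_correction(age, age), c(a = 1, b = 0))
  expect_equal(fit_bias_correction(0.5 * age + 30, age), c(a = 0.5, b = 30),
               tolerance = 1e-9)
  withr::local_seed(21)
  age2 <- runif(2000, 55, 90)
  pred <- 0.7 * age2 + 20 + rnorm(2000, 0, 2)
  ab <- fit_bias_correction(pred, age2)
  expect_equal(unname(ab["a"]), 0.7, tolerance = 0.02)
  expect_equal(unname(ab["b"]), 20, tolerance = 1.5)
  expect_error(fit_bias_correction(c(1, 2, 3), c(70, 70, 70)), "variance")
})

test_that("compute_deltas applies the correction arithmetic exactly", {
  # yhat = 75 at y = 72 with identity correction: delta = 3
  m_id <- fake_linear_model(slope = 1, intercept = 5, a = 1, b = 0)
  g <- cohort_table("p1", 72, "AD", cbind(f = 70)) # yhat = 5 + 70 = 75
  expect_equal(compute_deltas(m_id, g)$delta, 3)

  # yhat = 65 at y = 70 under (a, b) = (0.5, 30): corrected 70, delta 0
  m_bias <- fake_linear_model(slope = 1, intercept = -5, a = 0.5, b = 30)
  g2 <- cohort_table("p2", 70, "AD", cbind(f = 70)) # yhat = 65
  expect_equal(compute_deltas(m_bias, g2)$delta, 0)

  # residual-style correction removes the same age trend
  m_res <- fake_linear_model(slope = 1, intercept = -5, a = 0.5, b = 30,
                             bias_method = "residual")
  expect_equal(compute_deltas(m_res, g2)$delta, 65 - (0.5 * 70 + 30))

  m_deg <- fake_linear_model(slope = 1, intercept = 0, a = 0, b = 0)
  expect_error(compute_deltas(m_deg, g), "degenerate")
})

test_that("out-of-fold deltas demand training controls and mae precedes
           correction", {
  co <- age_feature_cohort(n = 120, noise_sd = 3, seed = 13)
  m <- fit_age_model(co, age_model_spec("f", seed = 6))
  d <- compute_deltas(m, co, use_oof = TRUE)
  expect_setequal(d$subject_id, co$subject_id)
  # mae_uncorrected is computed from raw out-of-fold predictions
  expect_equal(m$mae_uncorrected,
               mean(abs(m$oof_predictions[co$subject_id] - co$age)))
  stranger <- cohort_table("zz", 70, "AD", cbind(f = 70))
  expect_error(compute_deltas(m, stranger, use_oof = TRUE),
               "non-control subject.*zz")
})

test_that("model summaries serialize to valid JSON", {
  co <- age_feature_cohort(n = 40, noise_sd = 2, seed = 14)
  m <- fit_age_model(co, age_model_spec("f", seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_age_model_summary(m, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$regressor, "linear")
  expect_equal(j$mae_uncorrected, m$mae_uncorrected, tolerance = 1e-9)
  expect_length(j$fold_assignment, 40)
})
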