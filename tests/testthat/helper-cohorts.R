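# small in-code fixtures shared across test files

# two-group cohort with one age-tracking feature and one purely diagnostic
# feature; offsets/slopes chosen per test via arguments
toy_spec <- function(n_cn = 60, n_ad = 40, age_slope = -0.05,
                     offset_ad = -0.5, noise_sd = 0.3, seed = 1) {
  synthetic_spec(
    n_per_group = c(CN = n_cn, AD = n_ad),
    age_range = c(55, 90),
    features = list(
      feature_spec("vol", age_slope = age_slope,
                   group_offsets = c(AD = offset_ad), noise_sd = noise_sd),
      feature_spec("score", age_slope = 0,
                   group_offsets = c(AD = 1.5), noise_sd = 0.8)
    ),
    seed = seed
  )
}

# control-only cohort whose single feature is age plus optional noise
age_feature_cohort <- function(n = 100, noise_sd = 0, seed = 1, label = "CN") {
  withr::with_seed(seed, {
    age <- runif(n, 55, 90)
    f <- age + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    cohort_table(sprintf("c%04d", seq_len(n)), age, rep(label, n),
                 cbind(f = f))
  })
}

# hand-built age_model with known linear pipeline and bias coefficients,
# for arithmetic checks of compute_deltas()
fake_linear_model <- function(slope, intercept, a, b,
                              bias_method = "invert") {
  spec <- age_model_spec("f", regressor = "linear", n_folds = 2, seed = 1,
                         bias_method = bias_method)
  structure(
    list(
      spec = spec, control_label = "CN",
      full_pipeline = list(
        scaler = list(center = c(f = 0), scale = c(f = 1)),
        model = list(kind = "linear",
                     coef = c(`(Intercept)` = intercept, f = slope))
      ),
      oof_predictions = numeric(), ages = numeric(),
      fold_mae = c(0, 0), mae_uncorrected = 0,
      bias_coefficients = c(a = a, b = b)
    ),
    class = "age_model"
  )
}

write_toy_csv <- function(path, rows) {
  writeLines(c("id,age,dx,GM,MMSE", rows), path)
}
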