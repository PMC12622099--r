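#' Specify a brain-age regression pipeline
#'
#' The pipeline is a feature standardizer (zero mean, unit variance,
#' statistics taken from the training subjects only) followed by a
#' regressor of chronological age: ordinary least squares (`"linear"`),
#' ridge regression (`"ridge"`, penalty `lambda`, default 1), or epsilon
#' support vector regression with an RBF kernel (`"svr"`, `cost` 1,
#' `epsilon` 0.1 by default). Models are trained on healthy controls with
#' shuffled k-fold cross-validation.
#'
#' @param feature_set character vector of feature names used as predictors.
#' @param regressor `"linear"`, `"ridge"` or `"svr"`.
#' @param hyperparams named list of regressor hyperparameters overriding
#'   the defaults above.
#' @param n_folds number of cross-validation folds (>= 2; default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param bias_method age-bias-correction flavour, see
#'   [fit_bias_correction()]: `"invert"` (default) rescales predictions by
#'   the inverse of the prediction-on-age regression; `"residual"`
#'   subtracts the age-explained component of the prediction.
#' @return an `age_model_spec`.
#' @export
age_model_spec <- function(feature_set, regressor = c("linear", "ridge", "svr"),
                           hyperparams = list(), n_folds = 5, seed = 1,
                           bias_method = c("invert", "residual")) {
  regressor <- match.arg(regressor)
  bias_method <- match.arg(bias_method)
  if (!length(feature_set)) stop("feature_set must be non-empty")
  if (n_folds < 2) stop("n_folds must be >= 2")
  defaults <- switch(regressor,
    linear = list(),
    ridge = list(lambda = 1),
    svr = list(cost = 1, epsilon = 0.1, gamma = NULL)
  )
  structure(
    list(feature_set = as.character(feature_set), regressor = regressor,
         hyperparams = utils::modifyList(defaults, hyperparams),
         n_folds = as.integer(n_folds), seed = as.integer(seed),
         bias_method = bias_method),
    class = "age_model_spec"
  )
}

# --- scaler + regressor primitives -------------------------------------

fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0] <- 1 # constant feature: centre only
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

fit_regressor <- function(Xs, y, regressor, hp) {
  switch(regressor,
    linear = {
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0 # aliased (collinear) columns contribute nothing
      list(kind = "linear", coef = cf)
    },
    ridge = {
      # penalized normal equations on the standardized design; columns of
      # Xs are centred (training-fold scaler), so the intercept is mean(y)
      # and stays unpenalized -- the standard ridge convention
      p <- ncol(Xs)
      beta <- solve(crossprod(Xs) + diag(hp$lambda, p, p),
                    crossprod(Xs, y - mean(y)))
      cf <- c(`(Intercept)` = mean(y), setNames(drop(beta), colnames(Xs)))
      list(kind = "linear", coef = cf)
    },
    svr = {
      args <- list(x = Xs, y = y, type = "eps-regression", kernel = "radial",
                   cost = hp$cost, epsilon = hp$epsilon, scale = FALSE)
      if (!is.null(hp$gamma)) args$gamma <- hp$gamma
      list(kind = "svr", fit = do.call(e1071::svm, args))
    }
  )
}

predict_regressor <- function(model, Xs) {
  if (model$kind == "linear") {
    drop(cbind(1, Xs) %*% model$coef)
  } else {
    unname(predict(model$fit, Xs))
  }
}

predict_pipeline <- function(pipeline, X) {
  predict_regressor(pipeline$model, apply_scaler(pipeline$scaler, X))
}

# --- cross-validated fit ------------------------------------------------

#' Fit a brain-age model on healthy controls
#'
#' Fits the pipeline of an [age_model_spec()] on a control-only cohort with
#' shuffled k-fold cross-validation. Within each fold the scaler and the
#' regressor see only the training subjects, and each control receives
#' exactly one out-of-fold predicted age. The uncorrected mean absolute
#' error is computed from these out-of-fold predictions, strictly before
#' any bias correction. A full-cohort refit (`full_pipeline`) is kept for
#' scoring external clinical groups, and the age-bias-correction
#' coefficients are fitted on the pooled out-of-fold predictions.
#'
#' Internally the predictor columns are ordered canonically (sorted by
#' name), so two specs declaring the same feature set in different orders
#' produce identical fits; the declared order is kept in the spec for
#' reporting.
#'
#' @param controls a [cohort_table()] containing only control subjects (one
#'   unique label); any other label is an error.
#' @param spec an [age_model_spec()].
#' @return an `age_model` with components `spec`, `fold_assignment`,
#'   `fold_pipelines`, `full_pipeline`, `oof_predictions` (named by
#'   subject), `fold_mae`, `mae_uncorrected` and `bias_coefficients`
#'   `(a, b)` from [fit_bias_correction()].
#' @export
fit_age_model <- function(controls, spec) {
  validate_cohort(controls)
  stopifnot(inherits(spec, "age_model_spec"))
  if (length(unique(controls$label)) != 1) {
    stop("training cohort must contain a single (control) label; found: ",
         paste(unique(controls$label), collapse = ", "))
  }
  absent <- setdiff(spec$feature_set, feature_names(controls))
  if (length(absent)) {
    stop("feature(s) not in cohort: ", paste(absent, collapse = ", "))
  }
  n <- n_subjects(controls)
  if (n < spec$n_folds) stop("fewer controls (", n, ") than folds")

  feats <- sort(spec$feature_set) # canonical column order
  X <- controls$features[, feats, drop = FALSE]
  y <- controls$age

  fold_of <- with_seed(spec$seed, sample(rep(seq_len(spec$n_folds), length.out = n)))
  oof <- numeric(n)
  fold_pipelines <- vector("list", spec$n_folds)
  fold_mae <- numeric(spec$n_folds)
  for (f in seq_len(spec$n_folds)) {
    tr <- fold_of != f
    scaler <- fit_scaler(X[tr, , drop = FALSE])
    model <- fit_regressor(apply_scaler(scaler, X[tr, , drop = FALSE]),
                           y[tr], spec$regressor, spec$hyperparams)
    pipeline <- list(scaler = scaler, model = model)
    fold_pipelines[[f]] <- pipeline
    oof[!tr] <- predict_pipeline(pipeline, X[!tr, , drop = FALSE])
    fold_mae[f] <- mean(abs(oof[!tr] - y[!tr]))
  }
  names(oof) <- controls$subject_id

  scaler <- fit_scaler(X)
  full_pipeline <- list(
    scaler = scaler,
    model = fit_regressor(apply_scaler(scaler, X), y, spec$regressor,
                          spec$hyperparams)
  )
  structure(
    list(spec = spec, control_label = controls$label[1],
         fold_assignment = setNames(fold_of, controls$subject_id),
         fold_pipelines = fold_pipelines, full_pipeline = full_pipeline,
         oof_predictions = oof, ages = setNames(y, controls$subject_id),
         fold_mae = fold_mae, mae_uncorrected = mean(abs(oof - y)),
         bias_coefficients = fit_bias_correction(oof, y)),
    class = "age_model"
  )
}

#' @export
print.age_model <- function(x, ...) {
  cat("<age_model> ", x$spec$regressor, " regressor, ",
      length(x$spec$feature_set), " features, ",
      x$spec$n_folds, "-fold CV on ", length(x$oof_predictions),
      " controls ('", x$control_label, "')\n", sep = "")
  cat(sprintf("  uncorrected MAE: %.2f years\n", x$mae_uncorrected))
  cat(sprintf("  bias fit: predicted ~ %.3f * age + %.1f\n",
              x$bias_coefficients["a"], x$bias_coefficients["b"]))
  invisible(x)
}

#' Fit the age-bias correction
#'
#' Brain-age predictions regress toward the training mean, so prediction
#' errors correlate with age. The correction fits ordinary least squares of
#' predicted age on chronological age, `yhat ~ a * y + b`, on (out-of-fold)
#' control predictions; downstream, either the prediction is rescaled by
#' the inverse map (`(yhat - b) / a`) or the age-explained component is
#' subtracted. Either way the corrected deltas of the fitting sample are
#' uncorrelated with age.
#'
#' @param predictions numeric vector of predicted ages (years).
#' @param ages numeric vector of chronological ages, same length (>= 3,
#'   with positive variance).
#' @return named numeric vector `c(a = slope, b = intercept)`.
#' @export
#' @examples
#' fit_bias_correction(0.5 * c(60, 70, 80) + 30, c(60, 70, 80))
fit_bias_correction <- function(predictions, ages) {
  if (length(predictions) != length(ages)) stop("length mismatch")
  if (length(ages) < 3) stop("need at least 3 subjects")
  if (var(ages) == 0) stop("zero age variance; correction is undefined")
  cf <- coef(lm(predictions ~ ages))
  c(a = unname(cf[2]), b = unname(cf[1]))
}

#' Compute bias-corrected brain-age deltas
#'
#' Applies a fitted [fit_age_model()] pipeline to a group of subjects and
#' returns the delta, the bias-corrected predicted age minus chronological
#' age (positive = older-appearing brain). When the group *is* the training
#' control group, set `use_oof = TRUE` so each control is scored with the
#' prediction from the fold that held it out, avoiding optimistic
#' in-sample deltas; any other group is scored with the full-cohort refit.
#'
#' @param model an `age_model`.
#' @param group a [cohort_table()] of subjects to score.
#' @param use_oof use stored out-of-fold predictions; every subject must
#'   then be a training control.
#' @return a `data.frame` (`delta_table`) with columns `subject_id`, `age`,
#'   `label`, `prediction` (raw), `prediction_corrected` and `delta`.
#' @export
compute_deltas <- function(model, group, use_oof = FALSE) {
  stopifnot(inherits(model, "age_model"))
  validate_cohort(group)
  ab <- model$bias_coefficients
  if (abs(ab["a"]) < 1e-12) stop("degenerate bias correction: slope a = 0")
  if (use_oof) {
    missing <- setdiff(group$subject_id, names(model$oof_predictions))
    if (length(missing)) {
      stop("no out-of-fold prediction for non-control subject(s): ",
           paste(missing, collapse = ", "))
    }
    yhat <- unname(model$oof_predictions[group$subject_id])
  } else {
    absent <- setdiff(model$spec$feature_set, feature_names(group))
    if (length(absent)) {
      stop("feature(s) not in group cohort: ", paste(absent, collapse = ", "))
    }
    feats <- sort(model$spec$feature_set)
    yhat <- predict_pipeline(model$full_pipeline,
                             group$features[, feats, drop = FALSE])
  }
  y <- group$age
  yc <- if (model$spec$bias_method == "invert") {
    (yhat - ab["b"]) / ab["a"]
  } else {
    y + (yhat - (ab["a"] * y + ab["b"]))
  }
  structure(
    data.frame(subject_id = group$subject_id, age = y, label = group$label,
               prediction = yhat, prediction_corrected = unname(yc),
               delta = unname(yc) - y, stringsAsFactors = FALSE),
    class = c("delta_table", "data.frame")
  )
}

#' Serialize an age model's audit trail to JSON
#'
#' Writes fold assignments, out-of-fold predictions, uncorrected MAE and
#' bias-correction coefficients as a JSON sidecar for reproducibility
#' audits; fitted pipeline objects themselves are not serialized.
#'
#' @param model an `age_model`.
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_age_model_summary <- function(model, path) {
  stopifnot(inherits(model, "age_model"))
  jsonlite::write_json(
    list(
      regressor = model$spec$regressor,
      hyperparams = model$spec$hyperparams,
      feature_set = model$spec$feature_set,
      n_folds = model$spec$n_folds,
      seed = model$spec$seed,
      bias_method = model$spec$bias_method,
      control_label = model$control_label,
      fold_assignment = as.list(model$fold_assignment),
      oof_predictions = as.list(round(model$oof_predictions, 6)),
      fold_mae = model$fold_mae,
      mae_uncorrected = model$mae_uncorrected,
      bias_coefficients = as.list(model$bias_coefficients)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
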