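#' Configuration for the experiment pipelines
#'
#' Bundles the tunable parameters shared by [run_feature_influence()] and
#' [run_model_vs_logistic()]. Every stochastic stage derives its own seed
#' from `seed` via [stage_seed()].
#'
#' @param n_folds cross-validation folds for both the age models and the
#'   classifiers (default 5).
#' @param seed master seed of the run.
#' @param mi_k nearest-neighbour count of the mutual-information estimator.
#' @param regressor age-model regressor for the feature-influence pipeline.
#' @param hyperparams hyperparameters for that regressor.
#' @param model_hyperparams named list (`linear`, `ridge`, `svr`) of
#'   hyperparameter overrides for the model-comparison pipeline.
#' @param bias_method age-bias-correction flavour, see [age_model_spec()].
#' @param ks integer vector of nested-set sizes to evaluate; `NULL`
#'   (default) evaluates every size `1..p`.
#' @param age_ranking_population population used for the MI-with-age
#'   ranking: `"all"` subjects (default) or `"controls"` only.
#' @return a `run_config` list.
#' @export
run_config <- function(n_folds = 5, seed = 42, mi_k = 3,
                       regressor = "linear", hyperparams = list(),
                       model_hyperparams = list(), bias_method = "invert",
                       ks = NULL,
                       age_ranking_population = c("all", "controls")) {
  age_ranking_population <- match.arg(age_ranking_population)
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(
    list(n_folds = as.integer(n_folds), seed = as.integer(seed),
         mi_k = as.integer(mi_k), regressor = regressor,
         hyperparams = hyperparams, model_hyperparams = model_hyperparams,
         bias_method = bias_method, ks = ks,
         age_ranking_population = age_ranking_population),
    class = "run_config"
  )
}

# the two rankings every pipeline starts from; the discrimination ranking
# is computed on the two clinical groups only, the age ranking on the
# configured population
compute_rankings <- function(cohort, pair, config) {
  pop <- if (config$age_ranking_population == "controls") {
    subset_by_labels(cohort, pair$control_label)
  } else {
    cohort
  }
  list(
    age = rank_features(
      mi_with_age(pop, config$mi_k, stage_seed(config$seed, "mi", "age")),
      criterion = "age"
    ),
    discrimination = rank_features(
      mi_with_labels(cohort, pair, config$mi_k,
                     stage_seed(config$seed, "mi", "labels")),
      criterion = paste(pair$group_a, "vs", pair$group_b)
    )
  )
}

# deltas for both groups of the pair: out-of-fold predictions whenever the
# group is the training control group, full-model scoring otherwise
pair_deltas <- function(model, cohort, pair) {
  one <- function(g) {
    compute_deltas(model, subset_by_labels(cohort, g),
                   use_oof = identical(g, pair$control_label))
  }
  rbind(one(pair$group_a), one(pair$group_b))
}

annotate_stage <- function(expr, criterion, k) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[criterion=%s, k=%d] %s", criterion, k,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Feature-influence progression curves
#'
#' The first headline pipeline: features are ranked by mutual information
#' with age and, separately, by their power to discriminate the two
#' clinical groups; for each ranking, brain-age models are trained on
#' healthy controls over the nested top-k feature sets, and for every k the
#' uncorrected age-prediction MAE and the AUC of the resulting deltas as a
#' two-group classifier are recorded. Plotting MAE and AUC against k
#' exposes the trade-off between age-prediction accuracy and diagnostic
#' usefulness of the deltas.
#'
#' @param cohort a [cohort_table()] containing controls and both groups.
#' @param pair a [group_pair()].
#' @param config a [run_config()].
#' @return an `influence_run`: list with `curves` (named list of
#'   `progression_curve` data frames for the `age` and `discrimination`
#'   orderings), `rankings`, `pair` and `config`. Each curve has columns
#'   `ordering`, `criterion`, `k`, `feature_added`, `mae`, `mae_sd`,
#'   `mae_lo`, `mae_hi`, `auc`, `auc_sd`, `auc_lo`, `auc_hi` (95% normal
#'   approximation across folds).
#' @export
run_feature_influence <- function(cohort, pair, config = run_config()) {
  validate_cohort(cohort)
  check_pair_in_cohort(cohort, pair)
  if (!pair$control_label %in% cohort$label_levels) {
    stop("control label '", pair$control_label, "' not in cohort")
  }
  controls <- subset_by_labels(cohort, pair$control_label)
  rankings <- compute_rankings(cohort, pair, config)

  curves <- lapply(names(rankings), function(ordering) {
    ranking <- rankings[[ordering]]
    sets <- nested_feature_sets(ranking)
    ks <- if (is.null(config$ks)) seq_along(sets) else intersect(config$ks, seq_along(sets))
    rows <- lapply(ks, function(k) {
      annotate_stage({
        fs <- sets[[k]]
        spec <- age_model_spec(
          fs, regressor = config$regressor, hyperparams = config$hyperparams,
          n_folds = config$n_folds, seed = stage_seed(config$seed, "agemodel", k),
          bias_method = config$bias_method
        )
        model <- fit_age_model(controls, spec)
        deltas <- pair_deltas(model, cohort, pair)
        labels <- factor(deltas$label, levels = c(pair$group_a, pair$group_b))
        res <- classify_groups(deltas$delta, labels, n_folds = config$n_folds,
                               seed = stage_seed(config$seed, "classify", k))
        half_mae <- 1.96 * sd(model$fold_mae) / sqrt(config$n_folds)
        half_auc <- 1.96 * res$auc_sd / sqrt(config$n_folds)
        data.frame(
          ordering = ordering, criterion = ranking$criterion, k = k,
          feature_added = fs[k],
          mae = model$mae_uncorrected, mae_sd = sd(model$fold_mae),
          mae_lo = model$mae_uncorrected - half_mae,
          mae_hi = model$mae_uncorrected + half_mae,
          auc = res$auc_mean, auc_sd = res$auc_sd,
          auc_lo = res$auc_mean - half_auc, auc_hi = res$auc_mean + half_auc,
          stringsAsFactors = FALSE
        )
      }, ranking$criterion, k)
    })
    structure(do.call(rbind, rows), class = c("progression_curve", "data.frame"))
  })
  names(curves) <- names(rankings)
  structure(
    list(curves = curves, rankings = rankings, pair = pair, config = config),
    class = "influence_run"
  )
}

#' Brain-age deltas versus direct logistic regression
#'
#' The second headline pipeline: at every nested-set size k (for both
#' feature orderings) four classifiers of the group pair are compared with
#' identical fold assignments -- logistic models on the 1-D deltas of
#' linear, ridge and SVR brain-age models, and a logistic model fitted
#' directly on the k raw features. A four-row augmentation table (features,
#' features + age, delta alone, features + delta, all at the full feature
#' set with the linear-model delta) is attached as the summary-table
#' analogue.
#'
#' @inheritParams run_feature_influence
#' @return a `comparison_run`: list with `curves` (data frame: `ordering`,
#'   `model_kind` in `delta-linear`, `delta-ridge`, `delta-svr`,
#'   `direct-logistic`; `k`, `feature_added`, `auc_mean`, `auc_sd`),
#'   `augmentation` (see [augmentation_comparison()]), `rankings`, `pair`,
#'   `config`.
#' @export
run_model_vs_logistic <- function(cohort, pair, config = run_config()) {
  validate_cohort(cohort)
  check_pair_in_cohort(cohort, pair)
  controls <- subset_by_labels(cohort, pair$control_label)
  rankings <- compute_rankings(cohort, pair, config)
  regressors <- c("linear", "ridge", "svr")

  sub <- subset_by_labels(cohort, c(pair$group_a, pair$group_b))
  labels_all <- factor(sub$label, levels = c(pair$group_a, pair$group_b))

  rows <- list()
  for (ordering in names(rankings)) {
    ranking <- rankings[[ordering]]
    sets <- nested_feature_sets(ranking)
    ks <- if (is.null(config$ks)) seq_along(sets) else intersect(config$ks, seq_along(sets))
    for (k in ks) {
      fs <- sets[[k]]
      cls_seed <- stage_seed(config$seed, "classify", k)
      folds <- make_stratified_folds(labels_all, config$n_folds,
                                     stage_seed(cls_seed, "folds"))
      for (reg in regressors) {
        rows[[length(rows) + 1]] <- annotate_stage({
          spec <- age_model_spec(
            fs, regressor = reg,
            hyperparams = config$model_hyperparams[[reg]] %||% list(),
            n_folds = config$n_folds,
            seed = stage_seed(config$seed, "agemodel", k),
            bias_method = config$bias_method
          )
          model <- fit_age_model(controls, spec)
          deltas <- pair_deltas(model, cohort, pair)
          d <- deltas$delta[match(sub$subject_id, deltas$subject_id)]
          res <- classify_groups(d, labels_all, n_folds = config$n_folds,
                                 seed = cls_seed, folds = folds)
          data.frame(ordering = ordering, model_kind = paste0("delta-", reg),
                     k = k, feature_added = fs[k], auc_mean = res$auc_mean,
                     auc_sd = res$auc_sd, stringsAsFactors = FALSE)
        }, ranking$criterion, k)
      }
      rows[[length(rows) + 1]] <- annotate_stage({
        res <- classify_groups(sub$features[, fs, drop = FALSE], labels_all,
                               n_folds = config$n_folds, seed = cls_seed,
                               folds = folds)
        data.frame(ordering = ordering, model_kind = "direct-logistic",
                   k = k, feature_added = fs[k], auc_mean = res$auc_mean,
                   auc_sd = res$auc_sd, stringsAsFactors = FALSE)
      }, ranking$criterion, k)
    }
  }
  curves <- do.call(rbind, rows)

  # summary table: augmentation comparison at the full feature panel with
  # the linear-model delta
  full_fs <- rankings$age$order
  aug <- annotate_stage({
    spec <- age_model_spec(
      full_fs, regressor = "linear",
      n_folds = config$n_folds,
      seed = stage_seed(config$seed, "agemodel", length(full_fs)),
      bias_method = config$bias_method
    )
    model <- fit_age_model(controls, spec)
    augmentation_comparison(cohort, pair, pair_deltas(model, cohort, pair),
                            full_fs, n_folds = config$n_folds,
                            seed = stage_seed(config$seed, "augmentation"))
  }, "augmentation", length(full_fs))

  structure(
    list(curves = curves, augmentation = aug, rankings = rankings,
         pair = pair, config = config),
    class = "comparison_run"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
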