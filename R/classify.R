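#' Stratified cross-validation folds
#'
#' Assigns each subject to one of `n_folds` folds, shuffling within each
#' class so that every fold preserves the original class ratio as closely
#' as integer counts allow. Deterministic given the seed.
#'
#' @param labels factor (or coercible) of class labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
make_stratified_folds <- function(labels, n_folds, seed) {
  labels <- as.factor(labels)
  if (any(table(labels) < n_folds)) {
    stop("every class needs at least n_folds = ", n_folds, " subjects")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  })
  folds
}

#' Evaluate an input representation as a two-group classifier
#'
#' Scores any per-subject numeric representation (a 1-D brain-age delta,
#' raw features, or an augmented feature set) as a classifier of two
#' clinical groups. The protocol guards against both class imbalance and
#' leakage: folds are stratified to preserve class ratios; within each
#' training fold the majority class is randomly undersampled to the
#' minority count (test folds are never touched, so they stay
#' representative); inputs are standardized with statistics from the
#' undersampled training fold only; an unpenalized logistic model is
#' fitted and the held-out fold is scored. The AUC is computed per fold
#' from predicted class probabilities with the standard rank (trapezoidal)
#' convention, and summarized as mean and standard deviation across folds.
#'
#' @param inputs numeric matrix (subjects x dimensions) or vector.
#' @param labels two-level factor (or coercible); the second level is
#'   treated as the positive class.
#' @param n_folds number of CV folds (default 5); each class needs at
#'   least `n_folds` subjects.
#' @param seed integer seed driving fold assignment and undersampling.
#' @param folds optional precomputed fold assignment (integer vector), used
#'   to pair comparisons across input sets; overrides the internal
#'   stratified split.
#' @return a `classification_result`: `fold_aucs`, `auc_mean`, `auc_sd`,
#'   `n_per_class_used` (training counts after undersampling, per fold),
#'   `n_folds`, `seed`.
#' @export
classify_groups <- function(inputs, labels, n_folds = 5, seed = 1,
                            folds = NULL) {
  if (is.vector(inputs)) inputs <- matrix(inputs, ncol = 1)
  if (is.data.frame(inputs)) inputs <- as.matrix(inputs)
  storage.mode(inputs) <- "double"
  # internal column names: the logistic fit is agnostic to feature names
  # and this keeps non-syntactic names (e.g. "Grey Matter") out of formulas
  colnames(inputs) <- paste0("x", seq_len(ncol(inputs)))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
  if (anyNA(inputs) || any(!is.finite(inputs))) stop("inputs must be finite")
  if (nrow(inputs) != length(labels)) stop("inputs/labels length mismatch")

  if (nrow(unique(inputs)) == 1) {
    warning("inputs take a single unique value; AUC is chance level")
    return(new_classification_result(rep(0.5, n_folds),
                                     matrix(NA_integer_, 2, n_folds),
                                     n_folds, seed, levels(labels)))
  }

  if (is.null(folds)) {
    folds <- make_stratified_folds(labels, n_folds, stage_seed(seed, "folds"))
  }
  if (length(folds) != length(labels)) stop("folds length mismatch")

  pos <- levels(labels)[2]
  fold_aucs <- numeric(n_folds)
  n_used <- matrix(0L, nrow = 2, ncol = n_folds,
                   dimnames = list(levels(labels), NULL))
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(labels[te])) < 2 || length(unique(labels[tr])) < 2) {
      stop("class absent from fold ", f, "; stratification failed")
    }
    tr <- undersample_majority(tr, labels, stage_seed(seed, "undersample", f))
    n_used[, f] <- table(labels[tr])

    scaler <- fit_scaler(inputs[tr, , drop = FALSE])
    dtr <- as.data.frame(apply_scaler(scaler, inputs[tr, , drop = FALSE]))
    dte <- as.data.frame(apply_scaler(scaler, inputs[te, , drop = FALSE]))
    dtr$.y <- as.integer(labels[tr] == pos)
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dtr, family = stats::binomial())
    )
    prob <- suppressWarnings(unname(predict(fit, newdata = dte, type = "response")))
    fold_aucs[f] <- auc_rank(labels[te], prob, positive = pos)
  }
  new_classification_result(fold_aucs, n_used, n_folds, seed, levels(labels))
}

# training-fold indices after undersampling the majority class to the
# minority count; seeded, test folds untouched by construction
undersample_majority <- function(train_idx, labels, seed) {
  tab <- table(labels[train_idx])
  n_min <- min(tab)
  with_seed(seed, {
    keep <- unlist(lapply(names(tab), function(cl) {
      idx <- train_idx[labels[train_idx] == cl]
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }), use.names = FALSE)
  })
  sort(keep)
}

# trapezoidal AUC from probability scores via pROC; direction fixed so an
# anti-learning model scores below 0.5 rather than being flipped
auc_rank <- function(truth, score, positive) {
  truth <- as.factor(truth)
  lv <- c(setdiff(levels(truth), positive), positive)
  as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score, levels = lv,
    direction = "<", quiet = TRUE
  )))
}

new_classification_result <- function(fold_aucs, n_used, n_folds, seed, levels) {
  structure(
    list(fold_aucs = fold_aucs, auc_mean = mean(fold_aucs),
         auc_sd = sd(fold_aucs), n_per_class_used = n_used,
         n_folds = n_folds, seed = seed, class_levels = levels),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> AUC %.3f +/- %.3f (%d folds; %s vs %s)\n",
              x$auc_mean, x$auc_sd, x$n_folds,
              x$class_levels[1], x$class_levels[2]))
  invisible(x)
}

#' Repeat a classification over several seeds
#'
#' Cross-validated AUCs fluctuate with the fold split; repeating
#' [classify_groups()] under several derived seeds (default 5) separates
#' that split noise from the fold-to-fold variance. Reports the per-seed
#' summary plus the mean and standard deviation of `auc_mean` across
#' seeds.
#'
#' @inheritParams classify_groups
#' @param n_repeats number of repeated runs (default 5).
#' @return a list with `per_seed` (data frame: `repeat_id`, `auc_mean`,
#'   `auc_sd`), `auc_mean` (grand mean), `auc_sd_across_seeds` and
#'   `auc_sd_across_folds` (mean of the per-run fold sds).
#' @export
classify_groups_repeated <- function(inputs, labels, n_folds = 5, seed = 1,
                                     n_repeats = 5) {
  runs <- lapply(seq_len(n_repeats), function(r) {
    classify_groups(inputs, labels, n_folds = n_folds,
                    seed = stage_seed(seed, "repeat", r))
  })
  per_seed <- data.frame(
    repeat_id = seq_len(n_repeats),
    auc_mean = vapply(runs, `[[`, numeric(1), "auc_mean"),
    auc_sd = vapply(runs, `[[`, numeric(1), "auc_sd")
  )
  list(per_seed = per_seed, auc_mean = mean(per_seed$auc_mean),
       auc_sd_across_seeds = sd(per_seed$auc_mean),
       auc_sd_across_folds = mean(per_seed$auc_sd))
}

#' Compare delta-augmented input sets for classification
#'
#' Evaluates four logistic classifiers of a clinical group pair with
#' identical (paired) fold assignments: the declared features alone, the
#' features plus chronological age, the brain-age delta alone, and the
#' features plus the delta. Pairing the folds ensures that differences
#' between rows reflect the inputs, not split noise.
#'
#' @param cohort a [cohort_table()].
#' @param pair a [group_pair()].
#' @param deltas a `delta_table` (from [compute_deltas()], typically
#'   stacked over both groups) covering every subject of the pair.
#' @param feature_set feature names to use (e.g. the volumetric panel).
#' @param n_folds number of CV folds.
#' @param seed integer seed shared by all four evaluations.
#' @return a `data.frame` with one row per input set (`input_set`,
#'   `auc_mean`, `auc_sd`, `n_folds`, `seed`); the full
#'   `classification_result` objects are attached as attribute `results`.
#' @export
augmentation_comparison <- function(cohort, pair, deltas, feature_set,
                                    n_folds = 5, seed = 1) {
  validate_cohort(cohort)
  check_pair_in_cohort(cohort, pair)
  sub <- subset_by_labels(cohort, c(pair$group_a, pair$group_b))
  absent <- setdiff(feature_set, feature_names(sub))
  if (length(absent)) {
    stop("feature(s) not in cohort: ", paste(absent, collapse = ", "))
  }
  missing <- setdiff(sub$subject_id, deltas$subject_id)
  if (length(missing)) {
    stop("missing delta for subject(s): ", paste(missing, collapse = ", "))
  }
  delta <- deltas$delta[match(sub$subject_id, deltas$subject_id)]
  labels <- factor(sub$label, levels = c(pair$group_a, pair$group_b))
  folds <- make_stratified_folds(labels, n_folds, stage_seed(seed, "folds"))

  X <- sub$features[, feature_set, drop = FALSE]
  input_sets <- list(
    features = X,
    `features+age` = cbind(X, age = sub$age),
    delta = matrix(delta, ncol = 1, dimnames = list(NULL, "delta")),
    `features+delta` = cbind(X, delta = delta)
  )
  results <- lapply(input_sets, classify_groups, labels = labels,
                    n_folds = n_folds, seed = seed, folds = folds)
  out <- data.frame(
    input_set = names(results),
    auc_mean = vapply(results, `[[`, numeric(1), "auc_mean"),
    auc_sd = vapply(results, `[[`, numeric(1), "auc_sd"),
    n_folds = n_folds, seed = seed,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "results") <- results
  out
}
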