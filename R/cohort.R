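#' Construct a cohort table
#'
#' A `cohort_table` is the central data container of the package: one row
#' per subject with a unique identifier, chronological age in years, a
#' clinical label drawn from a declared label set, and a fixed panel of
#' numeric features (the same features for every subject). Missing feature
#' values are rejected outright -- the methods here assume complete cases
#' and never impute.
#'
#' @param subject_id character vector of unique subject identifiers.
#' @param age numeric vector of ages in years; strictly positive and finite.
#' @param label character vector of clinical labels (e.g. `"CN"`, `"AD"`).
#' @param features numeric matrix or data frame, one named column per
#'   feature; row order matches `subject_id`.
#' @param label_levels declared label set; defaults to the labels present,
#'   in order of first appearance.
#' @return an object of class `cohort_table` with components `subject_id`,
#'   `age`, `label`, `features` (numeric matrix) and `label_levels`.
#' @seealso [read_cohort()], [write_cohort()], [subset_by_labels()]
#' @export
cohort_table <- function(subject_id, age, label, features, label_levels = NULL) {
  subject_id <- as.character(subject_id)
  label <- as.character(label)
  if (is.data.frame(features)) {
    features <- as.matrix(features)
  }
  if (!is.matrix(features)) stop("`features` must be a matrix or data frame")
  storage.mode(features) <- "double"
  rownames(features) <- subject_id
  if (is.null(label_levels)) label_levels <- unique(label)
  x <- structure(
    list(
      subject_id = subject_id,
      age = as.numeric(age),
      label = label,
      features = features,
      label_levels = as.character(label_levels)
    ),
    class = "cohort_table"
  )
  validate_cohort(x)
}

#' Validate a cohort table
#'
#' Checks the invariants of the data model: unique subject identifiers,
#' strictly positive finite ages, complete numeric features shared by all
#' subjects, at least one feature, and labels drawn from the declared set.
#'
#' @param x a `cohort_table`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  n <- length(x$subject_id)
  if (length(x$age) != n || length(x$label) != n || nrow(x$features) != n) {
    stop("cohort components have inconsistent lengths")
  }
  dup <- x$subject_id[duplicated(x$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  }
  if (anyNA(x$age) || any(!is.finite(x$age)) || any(x$age <= 0)) {
    bad <- x$subject_id[is.na(x$age) | !is.finite(x$age) | x$age <= 0]
    stop("ages must be strictly positive and finite; offending subjects: ",
         paste(bad, collapse = ", "))
  }
  if (ncol(x$features) < 1) stop("cohort must declare at least one feature")
  if (is.null(colnames(x$features)) || anyNA(colnames(x$features)) ||
      any(colnames(x$features) == "")) {
    stop("all features must be named")
  }
  if (anyDuplicated(colnames(x$features))) stop("duplicate feature names")
  bad_cells <- which(is.na(x$features) | !is.finite(x$features), arr.ind = TRUE)
  if (nrow(bad_cells)) {
    stop("missing or non-finite feature values for subject(s): ",
         paste(unique(x$subject_id[bad_cells[, 1]]), collapse = ", "),
         " (missing values are rejected, not imputed)")
  }
  if (length(x$label_levels) < 1) stop("label set must have at least one level")
  unknown <- setdiff(unique(x$label), x$label_levels)
  if (length(unknown)) {
    stop("labels outside the declared label set: ",
         paste(unknown, collapse = ", "))
  }
  invisible(x)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", length(x$subject_id), " subjects, ",
      ncol(x$features), " features\n", sep = "")
  cat("  age: ", sprintf("%.1f-%.1f years", min(x$age), max(x$age)), "\n", sep = "")
  tab <- table(factor(x$label, levels = x$label_levels))
  cat("  labels: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  cat("  features: ", paste(utils::head(colnames(x$features), 8), collapse = ", "),
      if (ncol(x$features) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of subjects and feature names
#'
#' Small accessors for `cohort_table` objects.
#' @param cohort a `cohort_table`.
#' @return `n_subjects()` the number of rows; `feature_names()` the feature
#'   panel in declared order.
#' @export
n_subjects <- function(cohort) length(cohort$subject_id)

#' @rdname n_subjects
#' @export
feature_names <- function(cohort) colnames(cohort$features)

#' Describe a clinical group comparison
#'
#' A `group_pair` names the two clinical groups to be compared and the
#' label of the healthy-control group used to train brain-age models.
#'
#' @param group_a,group_b the two (distinct) clinical labels to compare.
#' @param control_label label of the control group used for model training;
#'   default `"CN"` (cognitively normal).
#' @return an object of class `group_pair`.
#' @export
#' @examples
#' group_pair("CN", "AD")
group_pair <- function(group_a, group_b, control_label = "CN") {
  stopifnot(is.character(group_a), is.character(group_b),
            length(group_a) == 1, length(group_b) == 1)
  if (group_a == group_b) stop("group_a and group_b must differ")
  structure(
    list(group_a = group_a, group_b = group_b, control_label = control_label),
    class = "group_pair"
  )
}

#' @export
print.group_pair <- function(x, ...) {
  cat("<group_pair> ", x$group_a, " vs ", x$group_b,
      " (controls: ", x$control_label, ")\n", sep = "")
  invisible(x)
}

check_pair_in_cohort <- function(cohort, pair) {
  missing <- setdiff(c(pair$group_a, pair$group_b), cohort$label_levels)
  if (length(missing)) {
    stop("group label(s) not in cohort label set: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Column schema for cohort CSV files
#'
#' Declares how the columns of a subject-level CSV map onto the cohort data
#' model. Exports from different studies name their columns differently, so
#' the mapping is configuration, not convention.
#'
#' @param id_column,age_column,label_column column names holding the subject
#'   identifier, age in years, and clinical label.
#' @param features character vector of feature column names, in the order
#'   they should be kept; `NULL` (default) takes every remaining column.
#' @param labels declared label set; `NULL` uses the labels present.
#' @return a `cohort_schema` list.
#' @export
cohort_schema <- function(id_column = "subject_id", age_column = "age",
                          label_column = "diagnosis", features = NULL,
                          labels = NULL) {
  structure(
    list(id_column = id_column, age_column = age_column,
         label_column = label_column, features = features, labels = labels),
    class = "cohort_schema"
  )
}

#' Read a cohort from a CSV file
#'
#' Reads a comma-separated, UTF-8, header-first subject table and validates
#' it into a [cohort_table()]. Feature column order is preserved as declared
#' in the schema (or as found in the file). Any missing or non-numeric
#' feature cell is an error naming the subject: complete cases are required.
#'
#' @param path path to a CSV file.
#' @param schema a [cohort_schema()] mapping column names.
#' @return a validated `cohort_table`.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  needed <- c(schema$id_column, schema$age_column, schema$label_column)
  absent <- setdiff(needed, names(raw))
  if (length(absent)) {
    stop("schema error: missing column(s): ", paste(absent, collapse = ", "))
  }
  feat_cols <- schema$features
  if (is.null(feat_cols)) {
    feat_cols <- setdiff(names(raw), needed)
  } else {
    absent <- setdiff(feat_cols, names(raw))
    if (length(absent)) {
      stop("schema error: missing feature column(s): ",
           paste(absent, collapse = ", "))
    }
  }
  if (!length(feat_cols)) stop("schema declares no feature columns")

  ids <- raw[[schema$id_column]]
  parse_num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) | raw[[col]] == ""
    if (any(bad)) {
      stop("non-numeric or missing ", what, " in column '", col,
           "' for subject(s): ", paste(ids[bad], collapse = ", "))
    }
    v
  }
  age <- parse_num(schema$age_column, "age")
  feats <- vapply(feat_cols, parse_num, numeric(nrow(raw)), what = "value")
  if (nrow(raw) == 1) feats <- matrix(feats, nrow = 1, dimnames = list(NULL, feat_cols))
  cohort_table(ids, age, raw[[schema$label_column]], feats,
               label_levels = schema$labels)
}

#' Write a cohort to a CSV file
#'
#' Writes one header row plus one row per subject, with columns
#' `subject_id`, `age`, `diagnosis` and the features in declared order.
#' The file round-trips through [read_cohort()] up to double precision.
#'
#' @param cohort a valid `cohort_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  df <- data.frame(subject_id = cohort$subject_id, age = cohort$age,
                   diagnosis = cohort$label, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cohort$features, check.names = FALSE))
  ok <- tryCatch({
    # suppress the connection warning that accompanies the error on an
    # unwritable path; the informative error below replaces both
    suppressWarnings(utils::write.csv(df, path, row.names = FALSE,
                                      fileEncoding = "UTF-8"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write cohort to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Subset a cohort by clinical labels
#'
#' Keeps the subjects whose label belongs to `labels`; ages and feature
#' values are untouched and the feature panel is unchanged. The result's
#' declared label set becomes `labels`.
#'
#' @param cohort a `cohort_table`.
#' @param labels character vector of labels to keep; must all belong to the
#'   cohort's declared label set.
#' @return a `cohort_table` with the selected subjects.
#' @export
subset_by_labels <- function(cohort, labels) {
  validate_cohort(cohort)
  unknown <- setdiff(labels, cohort$label_levels)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  keep <- cohort$label %in% labels
  cohort_table(cohort$subject_id[keep], cohort$age[keep], cohort$label[keep],
               cohort$features[keep, , drop = FALSE], label_levels = labels)
}
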