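#' Mutual information of each feature with age
#'
#' Estimates, per feature, the mutual information (in nats) between the
#' feature and chronological age with the Kraskov-Stoegbauer-Grassberger
#' k-nearest-neighbour estimator for two continuous variables. Each
#' variable is standardized to unit variance before the joint-space
#' neighbour search (the estimator's Chebyshev metric needs both variables
#' on a common scale), and a tiny seeded uniform jitter at the square root
#' of machine precision breaks ties so the neighbour counts are well
#' defined; negative raw estimates, which occur by chance under
#' independence, are clamped to zero. Estimates are therefore independent
#' of each feature's measurement units.
#'
#' @param cohort a [cohort_table()].
#' @param k_neighbors number of nearest neighbours (default 3).
#' @param seed integer seed for the tie-breaking jitter.
#' @return named numeric vector of MI estimates, one per feature, in the
#'   cohort's feature order.
#' @references Kraskov, Stoegbauer & Grassberger (2004) Phys Rev E 69,
#'   066138.
#' @export
mi_with_age <- function(cohort, k_neighbors = 3, seed = 1) {
  validate_cohort(cohort)
  n <- n_subjects(cohort)
  if (n < k_neighbors + 2) {
    stop("need at least k_neighbors + 2 = ", k_neighbors + 2, " subjects")
  }
  with_seed(seed, {
    age_j <- jitter_ties(cohort$age)
    vapply(feature_names(cohort), function(f) {
      x <- cohort$features[, f]
      if (var(x) == 0) return(0)
      max(0, ksg_mi_cc(jitter_ties(x), age_j, as.integer(k_neighbors)))
    }, numeric(1))
  })
}

#' Mutual information of each feature with a binary clinical label
#'
#' Restricts the cohort to the two groups of a [group_pair()] and
#' estimates, per feature, the mutual information between the continuous
#' feature and the binary group membership with the k-nearest-neighbour
#' continuous-discrete estimator of Ross (2014). Jitter and clamping as in
#' [mi_with_age()].
#'
#' @param cohort a [cohort_table()].
#' @param pair a [group_pair()]; both groups must be present.
#' @param k_neighbors number of nearest neighbours (default 3).
#' @param seed integer seed for the tie-breaking jitter.
#' @return named numeric vector of MI estimates in nats.
#' @references Ross (2014) PLoS ONE 9(2): e87357.
#' @export
mi_with_labels <- function(cohort, pair, k_neighbors = 3, seed = 1) {
  validate_cohort(cohort)
  check_pair_in_cohort(cohort, pair)
  sub <- subset_by_labels(cohort, c(pair$group_a, pair$group_b))
  counts <- table(factor(sub$label, levels = c(pair$group_a, pair$group_b)))
  if (any(counts == 0)) {
    stop("group(s) with zero subjects: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  if (any(counts < k_neighbors + 2)) {
    stop("each group needs at least k_neighbors + 2 subjects")
  }
  lab <- as.integer(sub$label == pair$group_b)
  with_seed(seed, {
    vapply(feature_names(sub), function(f) {
      x <- sub$features[, f]
      if (var(x) == 0) return(0)
      max(0, ksg_mi_cd(jitter_ties(x), lab, as.integer(k_neighbors)))
    }, numeric(1))
  })
}

# standardize to unit variance, then add uniform jitter at the square root
# of machine precision. The Chebyshev ball of the KSG estimator compares
# distances across the two variables, so they must be on a common scale:
# without this the larger-scale variable dominates the neighbour search and
# dependence is underestimated. The jitter breaks exact ties without moving
# real neighbour structure.
jitter_ties <- function(x) {
  s <- sd(x)
  if (s > 0) x <- x / s
  x + runif(length(x), -sqrt(.Machine$double.eps), sqrt(.Machine$double.eps))
}

#' Rank features by mutual information
#'
#' Orders features by descending MI score; exact ties are broken by
#' ascending feature name so the ranking does not depend on column order.
#'
#' @param scores named numeric vector of MI estimates (e.g. from
#'   [mi_with_age()] or [mi_with_labels()]).
#' @param criterion label recorded with the ranking, e.g. `"age"` or
#'   `"CN vs AD"`.
#' @return a `feature_ranking` with components `criterion`, `scores`
#'   (input order preserved) and `order` (feature names, best first).
#' @export
#' @examples
#' rank_features(c(A = 0.5, B = 0.9, C = 0.1))$order
rank_features <- function(scores, criterion = "age") {
  if (!length(scores) || is.null(names(scores))) {
    stop("scores must be a non-empty named vector")
  }
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  ord <- names(scores)[order(-scores, names(scores), method = "radix")]
  structure(
    list(criterion = criterion, scores = scores, order = ord),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("<feature_ranking> criterion:", x$criterion, "\n")
  df <- as.data.frame(x)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("  ... ", nrow(df) - 10, " more\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.feature_ranking <- function(x, ...) {
  data.frame(rank = seq_along(x$order), feature = x$order,
             criterion = x$criterion, mi_nats = unname(x$scores[x$order]),
             stringsAsFactors = FALSE)
}

#' Nested feature sets from a ranking
#'
#' Builds the sequence of top-k feature sets: set k holds the k highest
#' ranked features, so consecutive sets are nested and the last set is the
#' full panel.
#'
#' @param ranking a `feature_ranking`.
#' @return a list of character vectors of lengths 1..p.
#' @export
#' @examples
#' nested_feature_sets(rank_features(c(A = 0.5, B = 0.9, C = 0.1)))
nested_feature_sets <- function(ranking) {
  stopifnot(inherits(ranking, "feature_ranking"))
  lapply(seq_along(ranking$order), function(k) ranking$order[seq_len(k)])
}

#' Write a feature ranking as CSV
#'
#' Columns: `rank`, `feature`, `criterion`, `mi_nats`.
#'
#' @param ranking a `feature_ranking` (or list of them; rows are stacked).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  if (inherits(ranking, "feature_ranking")) ranking <- list(ranking)
  df <- do.call(rbind, lapply(ranking, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
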