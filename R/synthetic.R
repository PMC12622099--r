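#' Declare one synthetic feature
#'
#' A feature is generated per subject as
#' `intercept + age_slope * age + group_offset[label] + loading * z + noise`,
#' where `z` is a subject-level standard-normal latent shared by all
#' features with `shares_latent = TRUE` (inducing the collinearity typical
#' of volumetric measures), `loading` is the cohort-level `latent_loading`,
#' and `noise` is Gaussian with standard deviation `noise_sd`.
#'
#' @param name feature name.
#' @param age_slope change per year of age, in feature units.
#' @param group_offsets named numeric vector of additive shifts per clinical
#'   label; labels not named get offset 0.
#' @param noise_sd standard deviation of the independent Gaussian noise
#'   (must be > 0).
#' @param shares_latent does this feature load on the shared latent?
#' @param intercept feature value at age 0 for an offset-free subject.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(name, age_slope = 0, group_offsets = numeric(),
                         noise_sd = 1, shares_latent = FALSE, intercept = 0) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd <= 0) {
    stop("noise_sd must be a single positive number")
  }
  if (length(group_offsets) && is.null(names(group_offsets))) {
    stop("group_offsets must be named by label")
  }
  structure(
    list(name = name, age_slope = age_slope, group_offsets = group_offsets,
         noise_sd = noise_sd, shares_latent = isTRUE(shares_latent),
         intercept = intercept),
    class = "feature_spec"
  )
}

#' Declare a synthetic cohort
#'
#' @param n_per_group named integer vector: subjects per clinical label.
#' @param age_range `c(min, max)` age span in years; ages are drawn
#'   uniformly on this interval (set `age_distribution = "gaussian"` for a
#'   normal draw centred on the midpoint with sd = span/4, truncated to the
#'   range).
#' @param features list of [feature_spec()] objects.
#' @param latent_loading nonnegative scalar loading of the shared latent on
#'   every feature with `shares_latent = TRUE`.
#' @param seed integer default seed for [generate_cohort()].
#' @param age_distribution `"uniform"` (default) or `"gaussian"`.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_group, age_range = c(55, 90), features,
                           latent_loading = 0, seed = 1,
                           age_distribution = c("uniform", "gaussian")) {
  age_distribution <- match.arg(age_distribution)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("n_per_group must be named by label")
  }
  if (any(n_per_group < 0)) stop("group counts must be >= 0")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("age_range must be (min, max) with min < max")
  }
  if (!length(features)) stop("at least one feature_spec is required")
  if (!all(vapply(features, inherits, logical(1), "feature_spec"))) {
    stop("features must be a list of feature_spec objects")
  }
  if (latent_loading < 0) stop("latent_loading must be >= 0")
  structure(
    list(n_per_group = n_per_group, age_range = age_range,
         features = features, latent_loading = latent_loading,
         seed = as.integer(seed), age_distribution = age_distribution),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [synthetic_spec()]: ages are sampled per subject,
#' one standard-normal latent per subject induces collinearity among the
#' latent-sharing features, and each feature follows its linear
#' age-plus-offset model with independent Gaussian noise. The draw is fully
#' deterministic given the seed.
#'
#' @param spec a `synthetic_spec`.
#' @param seed integer seed; defaults to the seed stored in the spec.
#' @return a validated [cohort_table()].
#' @export
#' @examples
#' spec <- synthetic_spec(
#'   c(CN = 20, AD = 10),
#'   features = list(feature_spec("vol", age_slope = -0.05, noise_sd = 0.5))
#' )
#' generate_cohort(spec, seed = 7)
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- rep(names(spec$n_per_group), times = spec$n_per_group)
  n <- length(labels)
  if (n == 0) stop("spec generates zero subjects")
  lo <- spec$age_range[1]; hi <- spec$age_range[2]
  with_seed(seed, {
    age <- if (spec$age_distribution == "uniform") {
      runif(n, lo, hi)
    } else {
      mu <- (lo + hi) / 2; s <- (hi - lo) / 4
      pmin(pmax(rnorm(n, mu, s), lo), hi)
    }
    z <- rnorm(n)
    feats <- vapply(spec$features, function(fs) {
      off <- rep(0, n)
      hit <- labels %in% names(fs$group_offsets)
      if (any(hit)) off[hit] <- fs$group_offsets[labels[hit]]
      fs$intercept + fs$age_slope * age + off +
        (if (fs$shares_latent) spec$latent_loading * z else 0) +
        rnorm(n, 0, fs$noise_sd)
    }, numeric(n))
    colnames(feats) <- vapply(spec$features, `[[`, character(1), "name")
    cohort_table(sprintf("S%05d", seq_len(n)), age, labels, feats,
                 label_levels = names(spec$n_per_group))
  })
}

# Planted effect sizes for the default aging-cohort simulation.  Feature
# values are on a standardized scale (z-score units relative to a reference
# population); slopes are per year of age, offsets per clinical label.
# These are synthetic stand-ins chosen to reproduce the qualitative
# structure of an Alzheimer's cohort -- volumetric measures carry strong
# age signal and modest diagnostic shifts, cognitive scores the reverse --
# not estimates from any real data set.
default_feature_table <- function() {
  vol <- function(name, slope, mci, ad) {
    feature_spec(
      name, age_slope = slope,
      group_offsets = c(MCI = mci, AD = ad, sMCI = 0.85 * mci,
                        pMCI = 0.4 * mci + 0.6 * ad),
      noise_sd = 0.45, shares_latent = TRUE, intercept = -70 * slope
    )
  }
  cog <- function(name, slope, mci, ad) {
    feature_spec(
      name, age_slope = slope,
      group_offsets = c(MCI = mci, AD = ad, sMCI = 0.95 * mci,
                        pMCI = 1.25 * mci),
      noise_sd = 0.9, shares_latent = FALSE, intercept = -70 * slope
    )
  }
  list(
    vol("Grey Matter",         -0.085, -0.25, -0.55),
    vol("White Matter",        -0.018, -0.05, -0.12),
    vol("Cerebrospinal Fluid",  0.070,  0.20,  0.45),
    vol("Thalamus",            -0.075, -0.10, -0.25),
    vol("Caudate",             -0.035, -0.04, -0.10),
    vol("Putamen",             -0.052, -0.08, -0.18),
    vol("Pallidum",            -0.042, -0.05, -0.12),
    vol("Hippocampus",         -0.065, -0.35, -0.80),
    vol("Amygdala",            -0.048, -0.25, -0.55),
    vol("Accumbens",           -0.058, -0.10, -0.25),
    cog("MMSE",                -0.008, -0.70, -1.80),
    cog("ADAS",                 0.012,  0.70,  1.60),
    cog("FAQ",                  0.006,  0.60,  1.70),
    cog("MoCA",                -0.015, -0.60, -1.40),
    cog("ADNI Memory",         -0.022, -0.90, -2.00),
    cog("ADNI Executive Function", -0.025, -0.50, -1.20)
  )
}

#' Default Alzheimer's-cohort-like synthetic specification
#'
#' Returns a ready-made [synthetic_spec()] emulating a baseline-visit
#' Alzheimer's study cohort: 10 normalized volumetric measures (grey
#' matter, white matter, cerebrospinal fluid and seven subcortical
#' structures) with strong age slopes, shared-latent collinearity and
#' modest diagnostic offsets, plus 6 cognitive test scores (MMSE, ADAS,
#' FAQ, MoCA and composite memory / executive-function scores) with weak
#' age slopes and strong, stage-ordered diagnostic offsets. Stable and
#' progressive MCI get nearly equal cognitive offsets, reflecting their
#' shared cognitive profile at baseline. Group sizes are CN 300, MCI 300,
#' AD 100, sMCI 120, pMCI 50 over ages 55-90. All effect sizes are
#' synthetic stand-ins, not estimates from restricted data.
#'
#' @param seed integer seed stored in the spec.
#' @return a `synthetic_spec` with 16 features.
#' @export
default_adni_like_spec <- function(seed = 1) {
  synthetic_spec(
    n_per_group = c(CN = 300, MCI = 300, AD = 100, sMCI = 120, pMCI = 50),
    age_range = c(55, 90),
    features = default_feature_table(),
    latent_loading = 0.55,
    seed = seed
  )
}
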