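#' Write the outputs of a run to a directory
#'
#' Writes the machine-readable analogues of the study's tables and figures:
#' a ranking CSV (`rankings.csv`), the progression-curve CSVs, the four-row
#' augmentation summary where available, one figure per pipeline, the
#' configuration as JSON, and a JSON run manifest tying every output file
#' to the master seed and the MD5 of the configuration. Rerunning with the
#' same inputs and seed reproduces the CSVs byte for byte.
#'
#' @param run an `influence_run` or `comparison_run`.
#' @param out_dir output directory (created if needed).
#' @param plots write figures as well (default `TRUE`); PNG when the
#'   graphics device supports it, PDF otherwise.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(run, out_dir, plots = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  files <- character()
  add <- function(path) files <<- c(files, path)

  rk_path <- file.path(out_dir, "rankings.csv")
  write_ranking(run$rankings, rk_path); add(rk_path)

  if (inherits(run, "influence_run")) {
    cv_path <- file.path(out_dir, "influence_curves.csv")
    utils::write.csv(do.call(rbind, run$curves), cv_path, row.names = FALSE)
    add(cv_path)
    if (plots) add(save_plot(plot_influence(run),
                             file.path(out_dir, "influence_curves")))
  } else if (inherits(run, "comparison_run")) {
    cv_path <- file.path(out_dir, "model_comparison_curves.csv")
    utils::write.csv(run$curves, cv_path, row.names = FALSE); add(cv_path)
    aug_path <- file.path(out_dir, "augmentation_summary.csv")
    utils::write.csv(run$augmentation, aug_path, row.names = FALSE)
    add(aug_path)
    if (plots) add(save_plot(plot_model_comparison(run),
                             file.path(out_dir, "model_comparison_curves")))
  } else {
    stop("run must be an influence_run or comparison_run")
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(run$config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  add(cfg_path)

  manifest <- list(
    package = "agedelta",
    version = as.character(utils::packageVersion("agedelta")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = run$config$seed,
    mi_k_neighbors = run$config$mi_k,
    n_folds = run$config$n_folds,
    pair = unclass(run$pair),
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = basename(files)
  )
  mf_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf_path, auto_unbox = TRUE, digits = NA)
  add(mf_path)
  invisible(files)
}

#' Plot feature-influence progression curves
#'
#' MAE and AUC against the number of features, one line per ordering, with
#' shaded 95% confidence bands across folds.
#'
#' @param run an `influence_run`.
#' @return a ggplot object.
#' @export
plot_influence <- function(run) {
  df <- do.call(rbind, run$curves)
  long <- rbind(
    data.frame(ordering = df$ordering, k = df$k, metric = "MAE (years)",
               value = df$mae, lo = df$mae_lo, hi = df$mae_hi),
    data.frame(ordering = df$ordering, k = df$k, metric = "AUC",
               value = df$auc, lo = df$auc_lo, hi = df$auc_hi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$ordering,
                                     fill = .data$ordering)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "number of features (nested sets)", y = NULL,
      title = sprintf("%s vs %s: age-prediction error and delta AUC",
                      run$pair$group_a, run$pair$group_b),
      colour = "ordering", fill = "ordering"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the model-comparison curves
#'
#' AUC against the number of features for the three delta-based classifiers
#' and the direct logistic model, faceted by feature ordering, with error
#' bars showing the across-fold standard deviation.
#'
#' @param run a `comparison_run`.
#' @return a ggplot object.
#' @export
plot_model_comparison <- function(run) {
  df <- run$curves
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$auc_mean,
                                   colour = .data$model_kind)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$auc_mean - .data$auc_sd,
                                        ymax = .data$auc_mean + .data$auc_sd),
                           width = 0.2, alpha = 0.5) +
    ggplot2::facet_wrap(~ordering) +
    ggplot2::labs(
      x = "number of features (nested sets)", y = "AUC",
      title = sprintf("%s vs %s: delta-based vs direct classification",
                      run$pair$group_a, run$pair$group_b),
      colour = "model"
    ) +
    ggplot2::theme_minimal()
}

# save a ggplot as PNG when the device is available, PDF otherwise;
# returns the path written
save_plot <- function(p, stem, width = 8, height = 4.5) {
  if (isTRUE(capabilities("png"))) {
    path <- paste0(stem, ".png")
    try_save <- tryCatch({
      ggplot2::ggsave(path, p, width = width, height = height, dpi = 110)
      TRUE
    }, error = function(e) FALSE)
    if (try_save) return(path)
  }
  path <- paste0(stem, ".pdf")
  ggplot2::ggsave(path, p, width = width, height = height)
  path
}

#' @importFrom ggplot2 .data
NULL
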