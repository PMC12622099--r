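default_config_tree <- function() {
  list(
    data = list(
      id_column = "subject_id", age_column = "age",
      label_column = "diagnosis", features = NULL, labels = NULL,
      control_label = "CN"
    ),
    model = list(
      regressor = "linear", hyperparams = list(), n_folds = 5,
      bias_method = "invert"
    ),
    mi = list(k_neighbors = 3),
    seeds = list(master = 42, n_repeats = 5),
    output = list(directory = ".", plots = TRUE)
  )
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file with up to five blocks -- `data` (column schema,
#' feature list, label set, control label), `model` (regressor,
#' hyperparameters, fold count, bias-correction method), `mi`
#' (`k_neighbors`), `seeds` (`master`, `n_repeats`) and `output`
#' (`directory`, `plots`) -- fills in the documented defaults for every
#' omitted key, and fails fast on unknown keys or invalid values before
#' any computation starts. An empty or missing argument yields the pure
#' defaults.
#'
#' @param path path to a YAML file, or `NULL` for defaults only.
#' @return a validated `run_config_file` list with all defaults applied.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  defaults <- default_config_tree()

  unknown_top <- setdiff(names(user), names(defaults))
  if (length(unknown_top)) {
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  }
  cfg <- defaults
  for (block in names(user)) {
    unknown <- setdiff(names(user[[block]]), names(defaults[[block]]))
    if (length(unknown)) {
      stop("unknown config key(s) in '", block, "': ",
           paste(unknown, collapse = ", "))
    }
    cfg[[block]] <- utils::modifyList(defaults[[block]], user[[block]],
                                      keep.null = TRUE)
  }

  if (!cfg$model$regressor %in% c("linear", "ridge", "svr")) {
    stop("model.regressor must be one of linear, ridge, svr")
  }
  if (!cfg$model$bias_method %in% c("invert", "residual")) {
    stop("model.bias_method must be 'invert' or 'residual'")
  }
  if (!is.numeric(cfg$model$n_folds) || cfg$model$n_folds < 2) {
    stop("model.n_folds must be an integer >= 2")
  }
  if (!is.numeric(cfg$mi$k_neighbors) || cfg$mi$k_neighbors < 1) {
    stop("mi.k_neighbors must be an integer >= 1")
  }
  if (!is.numeric(cfg$seeds$master)) stop("seeds.master must be an integer")
  structure(cfg, class = "run_config_file")
}

# translate the validated file config into the in-memory run_config used
# by the experiment pipelines
as_run_config <- function(cfg, seed = NULL) {
  run_config(
    n_folds = cfg$model$n_folds,
    seed = seed %||% cfg$seeds$master,
    mi_k = cfg$mi$k_neighbors,
    regressor = cfg$model$regressor,
    hyperparams = cfg$model$hyperparams,
    bias_method = cfg$model$bias_method
  )
}

config_schema_of <- function(cfg) {
  cohort_schema(
    id_column = cfg$data$id_column, age_column = cfg$data$age_column,
    label_column = cfg$data$label_column, features = cfg$data$features,
    labels = cfg$data$labels
  )
}
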