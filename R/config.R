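#' Default run configuration
#'
#' Every defaulted field equals the published value where one exists: FDR
#' cutoff 0.01, log fold-change threshold 0, 80:20 splits, 5 folds, the
#' two-level training hyperparameters, and the seven noise levels.
#'
#' @return Nested named list with blocks `labeling`, `split`, `model`,
#'   `train`, `noise`, `baselines` and the master `seed`.
#' @export
run_config_defaults <- function() {
  list(seed = 1L,
       labeling = list(fdr_cutoff = 0.01, logfc_threshold = 0,
                       feature_transform = "log2_centered_scaled", feature_scale = 100,
                       pseudocount = 1),
       split = list(ratios = c(0.8, 0.2)),
       model = list(conv_channels = c(8L, 8L, 16L, 16L, 32L, 32L, 64L, 64L),
                    linear_widths = NULL, head_arity = 3L),
       train = list(level1 = list(), finetune = list(), folds = 5L),
       noise = list(levels = c(1, 10, 50, 100, 500, 1000, 1500)),
       baselines = BASELINE_IDS,
       synthetic = unclass(synthetic_spec()))
}

#' Read a run configuration file
#'
#' A YAML document whose keys override [run_config_defaults()]; unknown
#' keys are an error. Flags on the command line override file values.
#'
#' @param path Path to a YAML configuration file, or `NULL` for pure
#'   defaults.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop2("reading configuration files needs the 'yaml' package")
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop2("unknown configuration key: '", unknown[[1L]], "'")
  utils::modifyList(cfg, user)
}

config_model <- function(cfg) {
  model_config(conv_channels = cfg$model$conv_channels,
               linear_widths = cfg$model$linear_widths,
               head_arity = cfg$model$head_arity)
}

config_train <- function(cfg) {
  train_config(level1 = cfg$train$level1, finetune = cfg$train$finetune,
               folds = cfg$train$folds)
}
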