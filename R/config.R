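# Flat declarative config files (YAML) for cohort specs and experiments.
# Unknown keys are an error, so typos fail loudly rather than silently
# falling back to defaults.

check_keys <- function(x, allowed, what) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stop_("unknown ", what, " key(s): ", paste(extra, collapse = ", "),
          "; allowed: ", paste(allowed, collapse = ", "))
}

#' Read a cohort spec from a YAML config file
#'
#' Flat keys mirroring [cohort_spec()] arguments; `markers` and
#' `interactions` are lists of per-marker mappings.
#'
#' @param path config file path
#' @return a `cohort_spec`
#' @export
read_cohort_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("n_patients", "n_background_features", "class_priors",
                    "markers", "interactions", "background_prevalence",
                    "gender_distribution", "seed"), "cohort")
  to_df <- function(x) if (is.null(x)) NULL else do.call(rbind, lapply(x, as.data.frame))
  args <- cfg
  args$class_priors <- if (is.null(cfg$class_priors)) DEFAULT_PRIORS else unlist(cfg$class_priors)
  args$markers <- if (is.null(cfg$markers)) default_markers() else to_df(cfg$markers)
  args$interactions <- to_df(cfg$interactions)
  if (!is.null(cfg$gender_distribution))
    args$gender_distribution <- unlist(cfg$gender_distribution)
  do.call(cohort_spec, args)
}

#' Read an experiment config from a YAML config file
#'
#' Keys: `data` (EMR file path) or `cohort` (path to a cohort-spec YAML),
#' `k`, `validation_fraction`, `missing_rate`, `protect_demographics`,
#' `hidden_dims`, `activation`, `dropout_rate`, `learning_rate`,
#' `batch_size`, `max_epochs`, `patience`, `baselines`, `target_layer`,
#' `master_seed`, `out_dir`. The network spec is finalized once the
#' vocabulary size is known.
#'
#' @param path config file path
#' @return an `experiment_config`
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("data", "cohort", "k", "validation_fraction", "missing_rate",
                    "protect_demographics", "hidden_dims", "activation",
                    "dropout_rate", "learning_rate", "batch_size", "max_epochs",
                    "patience", "baselines", "target_layer", "master_seed",
                    "out_dir", "verbose"), "experiment")
  if (is.null(cfg$data) && is.null(cfg$cohort))
    stop_("experiment config needs either 'data' (EMR file) or 'cohort' (cohort spec file)")
  data <- if (!is.null(cfg$cohort)) read_cohort_spec(cfg$cohort) else cfg$data
  tc <- train_config(learning_rate = cfg$learning_rate %||% 0.001,
                     batch_size = cfg$batch_size %||% 128,
                     max_epochs = cfg$max_epochs %||% 100,
                     patience = cfg$patience %||% 5)
  ec <- experiment_config(data,
                          k = cfg$k %||% 10,
                          validation_fraction = cfg$validation_fraction %||% 0.1,
                          missing_rate = cfg$missing_rate %||% 0,
                          protect_demographics = isTRUE(cfg$protect_demographics),
                          config = tc,
                          baselines = unlist(cfg$baselines) %||% character(),
                          target_layer = cfg$target_layer %||% "logits",
                          master_seed = cfg$master_seed %||% 1,
                          out_dir = cfg$out_dir,
                          verbose = isTRUE(cfg$verbose))
  # architecture knobs are deferred until the vocabulary size is known
  attr(ec, "arch") <- list(hidden_dims = unlist(cfg$hidden_dims),
                           activation = cfg$activation,
                           dropout_rate = cfg$dropout_rate)
  ec
}
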