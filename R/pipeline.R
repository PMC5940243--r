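# End-to-end k-fold experiment orchestration: encode, partition, optionally
# mask, tune, train, evaluate and interpret from a single declarative
# config, with all randomness derived from one master seed.

#' Configure an end-to-end k-fold experiment
#'
#' @param data an `emr_records` data frame, a path to an EMR text file, or a
#'   `cohort_spec` (the cohort is then generated as the first stage)
#' @param k number of cross-validation folds
#' @param validation_fraction training-split fraction held out for early
#'   stopping and tuning
#' @param missing_rate MCAR masking rate in [0, 1); 0 disables masking
#' @param protect_demographics exclude age/gender columns from masking
#' @param spec a `network_spec`, or NULL to use the default architecture
#'   scaled to the vocabulary (two hidden layers of 64 at desk scale)
#' @param config a `train_config` (its seed is overridden per fold)
#' @param hyper optional `hyper_space`; when given, a randomized grid search
#'   runs once on the first fold's validation subsample and the winning
#'   configuration is reused across folds
#' @param baselines character vector of baseline methods to run alongside
#'   the MLP (see [baseline_harness()])
#' @param target_layer DeepLIFT target, `"logits"` or `"probabilities"`
#' @param master_seed single integer seed from which all stage seeds derive
#' @param out_dir optional output directory; per-fold metrics, aggregate
#'   orderings and a summary table are written under it
#' @param verbose print stage progress lines
#' @return an `experiment_config`
#' @export
experiment_config <- function(data, k = 10, validation_fraction = 0.1,
                              missing_rate = 0, protect_demographics = FALSE,
                              spec = NULL, config = train_config(),
                              hyper = NULL, baselines = character(),
                              target_layer = "logits", master_seed = 1,
                              out_dir = NULL, verbose = FALSE) {
  if (missing_rate < 0 || missing_rate >= 1) stop_("missing_rate must be in [0, 1)")
  if (k < 2) stop_("k must be >= 2")
  structure(list(data = data, k = as.integer(k),
                 validation_fraction = validation_fraction,
                 missing_rate = missing_rate,
                 protect_demographics = protect_demographics,
                 spec = spec, config = config, hyper = hyper,
                 baselines = baselines, target_layer = target_layer,
                 master_seed = as.integer(master_seed),
                 out_dir = out_dir, verbose = verbose),
            class = "experiment_config")
}

log_stage <- function(ec, fold, stage, ...) {
  if (isTRUE(ec$verbose))
    message(sprintf("[fold %s] %s %s", fold, stage, paste0(...)))
}

#' Run a k-fold imputation experiment
#'
#' For each fold: (optionally) mask observations, train the MLP with early
#' stopping on the fold's validation holdout, evaluate on the held-out test
#' fold, and compute DeepLIFT scores on the test samples. Contribution
#' matrices are summed across the k experiments so that every patient
#' contributes exactly once; metrics are reported per fold and as cross-fold
#' means. Fully reproducible from `master_seed`.
#'
#' @param ec an `experiment_config`
#' @return an experiment bundle: `records`, `vocab`, `plan`, `fold_metrics`
#'   (list of `metrics_report`), `metrics` (per-fold data frame),
#'   `mean_metrics`, `contribs` (aggregate `contribution_matrix`),
#'   `orderings` (data frame), `models`, `baseline_metrics`, `comparisons`,
#'   and `markers` (ground truth, for synthetic cohorts)
#' @export
run_experiment <- function(ec) {
  stopifnot(inherits(ec, "experiment_config"))
  markers <- NULL
  data <- ec$data
  if (is.character(data)) data <- parse_emr_file(data)
  if (inherits(data, "cohort_spec")) {
    log_stage(ec, "-", "generate", paste("cohort of", data$n_patients))
    g <- generate_cohort(data)
    records <- g$records; markers <- g$markers
  } else {
    records <- data
  }
  stopifnot(inherits(records, "emr_records"))
  n <- nrow(records)

  vocab <- build_vocabulary(records)
  batch <- encode_batch(records, vocab, quiet = !ec$verbose)
  if (ec$missing_rate > 0) {
    log_stage(ec, "-", "mask", paste("rate", ec$missing_rate))
    batch <- mask_observations(batch, ec$missing_rate,
                               seed = derive_seed(ec$master_seed, "mask"),
                               protect_demographics = ec$protect_demographics)
  }
  if (any(is.na(batch$labels)))
    stop_("run_experiment requires labeled records (no 'unknown' class)")
  plan <- make_fold_plan(n, ec$k, ec$validation_fraction,
                         seed = derive_seed(ec$master_seed, "folds"))
  X <- as.matrix(batch$matrix)
  y <- batch$labels

  spec <- ec$spec %||% network_spec(ncol(X), hidden_dims = c(64, 64),
                                    activation = "prelu", dropout_rate = 0.2)
  if (spec$input_dim != ncol(X)) stop_("network_spec input_dim != vocabulary size")
  cfg <- ec$config

  if (!is.null(ec$hyper)) {
    sp1 <- fold_split(plan, 1)
    log_stage(ec, 1, "tune", paste(ec$hyper$n_draws, "draws"))
    tuned <- random_grid_search(ec$hyper, X[sp1$val, , drop = FALSE], y[sp1$val],
                                base_spec = spec,
                                seed = derive_seed(ec$master_seed, "tune"))
    spec <- tuned$spec
    cfg <- train_config(tuned$config$learning_rate, tuned$config$batch_size,
                        max_epochs = cfg$max_epochs, patience = cfg$patience,
                        seed = cfg$seed)
  }

  fold_metrics <- vector("list", ec$k)
  models <- vector("list", ec$k)
  contribs <- NULL
  base_rows <- list()
  for (f in seq_len(ec$k)) {
    sp <- fold_split(plan, f)
    fold_cfg <- train_config(cfg$learning_rate, cfg$batch_size, cfg$max_epochs,
                             cfg$patience, seed = derive_seed(ec$master_seed, "train", f))
    log_stage(ec, f, "train", paste(length(sp$train), "train /",
                                    length(sp$val), "val /", length(sp$test), "test"))
    model <- train_mlp(build_mlp(spec, derive_seed(ec$master_seed, "init", f)),
                       X[sp$train, , drop = FALSE], y[sp$train],
                       X[sp$val, , drop = FALSE], y[sp$val], fold_cfg)
    probs <- predict_proba(model, X[sp$test, , drop = FALSE])
    fold_metrics[[f]] <- compute_metrics(probs, y[sp$test])
    log_stage(ec, f, "evaluate",
              sprintf("accuracy %.3f", fold_metrics[[f]]$accuracy))
    sc <- deeplift_scores(model, X[sp$test, , drop = FALSE],
                          target_layer = ec$target_layer)
    if (is.null(contribs)) {
      contribs <- sc
    } else {
      contribs <- aggregate_contributions(list(sc$scores), previous = contribs)
      contribs$sample_count <- contribs$sample_count - 1L + sc$sample_count
    }
    models[[f]] <- model
    for (bm in ec$baselines) {
      log_stage(ec, f, "baseline", bm)
      br <- baseline_harness(bm, X[sp$train, , drop = FALSE], y[sp$train],
                             X[sp$test, , drop = FALSE], y[sp$test],
                             seed = derive_seed(ec$master_seed, "baseline", bm, f))
      base_rows[[length(base_rows) + 1]] <-
        cbind(method = bm, fold = f, metrics_row(br$metrics))
    }
  }

  metrics_df <- cbind(fold = seq_len(ec$k),
                      do.call(rbind, lapply(fold_metrics, metrics_row)))
  mean_metrics <- colMeans(metrics_df[, -1, drop = FALSE])
  orderings <- orderings_table(contribs)
  baseline_metrics <- if (length(base_rows)) do.call(rbind, base_rows) else NULL

  comparisons <- list()
  if (length(ec$baselines) > 0) {
    comp_metrics <- c("accuracy", "loss", "micro_auc")
    n_comp <- length(comp_metrics) * length(ec$baselines)
    for (bm in ec$baselines) {
      bdf <- baseline_metrics[baseline_metrics$method == bm, ]
      bdf <- bdf[order(bdf$fold), ]
      for (m in comp_metrics) {
        comparisons[[paste(bm, m, sep = ".")]] <-
          compare_methods(metrics_df[[m]], bdf[[m]], n_comparisons = n_comp,
                          metric = paste0("mlp vs ", bm, ": ", m))
      }
    }
  }

  bundle <- list(records = records, vocab = vocab, plan = plan,
                 fold_metrics = fold_metrics, metrics = metrics_df,
                 mean_metrics = mean_metrics, contribs = contribs,
                 orderings = orderings, models = models,
                 baseline_metrics = baseline_metrics,
                 comparisons = comparisons, markers = markers,
                 spec = spec, config = cfg)
  if (!is.null(ec$out_dir)) write_experiment(bundle, ec)
  bundle
}

write_experiment <- function(bundle, ec) {
  dir.create(file.path(ec$out_dir, "aggregate"), recursive = TRUE, showWarnings = FALSE)
  for (f in seq_len(ec$k)) {
    fd <- file.path(ec$out_dir, "folds", f)
    dir.create(fd, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(metrics_row(bundle$fold_metrics[[f]]),
                       file.path(fd, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(bundle$metrics, file.path(ec$out_dir, "aggregate", "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_vocabulary(bundle$vocab, file.path(ec$out_dir, "aggregate", "vocabulary.tsv"))
  utils::write.table(orderings_table(bundle$contribs),
                     file.path(ec$out_dir, "aggregate", "orderings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(bundle$markers))
    write_marker_table(bundle$markers, file.path(ec$out_dir, "aggregate", "markers.tsv"))
  invisible(ec$out_dir)
}

#' Fraction of planted markers whose true class ranks first
#'
#' Convenience check for synthetic cohorts: for each ground-truth marker,
#' does the aggregate DeepLIFT class ordering place the marker's target
#' class first?
#'
#' @param bundle a [run_experiment()] bundle for a synthetic cohort
#' @return list with `rate`, `n_markers` and the per-marker logical `hits`
#' @export
marker_recovery <- function(bundle) {
  mk <- bundle$markers
  if (is.null(mk)) stop_("bundle has no ground-truth marker table")
  mk <- mk[mk$feature %in% rownames(bundle$contribs$scores), , drop = FALSE]
  hits <- vapply(seq_len(nrow(mk)), function(i) {
    o <- class_ordering(mk$feature[i], bundle$contribs$scores[mk$feature[i], ])
    o$classes[1] == mk$target_class[i]
  }, TRUE)
  list(rate = mean(hits), n_markers = nrow(mk),
       hits = stats::setNames(hits, mk$feature))
}
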