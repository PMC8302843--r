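#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations: synthetic acquisition, feature
#' scaling scope, network training budgets for the expression (k = 7) and
#' intensity (k = 5) classifiers, optional evaluation experiments, and one
#' global seed that propagates deterministically to every stage.
#'
#' @param generator A [generator_config()].
#' @param scaler_scope `"per_batch"` (default) or `"global"`.
#' @param epochs,batch_size Training budget for both classifiers.
#' @param run_robustness Run the cross-batch robustness experiment
#'   (requires at least two batches in the generator config).
#' @param ablation_subsets Optional list of channel subsets for
#'   [channel_ablation()].
#' @param run_baselines Also fit the classical baseline classifiers.
#' @param write_recordings Write every simulated recording as a delimited
#'   file plus a manifest CSV (off by default; the feature CSV is always
#'   written).
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            scaler_scope = "per_batch",
                            epochs = 30L, batch_size = 128L,
                            run_robustness = FALSE,
                            ablation_subsets = NULL,
                            run_baselines = FALSE,
                            write_recordings = FALSE,
                            seed = 1L) {
  cfg <- structure(
    list(generator = generator, scaler_scope = scaler_scope,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         run_robustness = isTRUE(run_robustness),
         ablation_subsets = ablation_subsets,
         run_baselines = isTRUE(run_baselines),
         write_recordings = isTRUE(write_recordings),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$generator, "generator_config"))
  if (cfg$run_robustness && length(cfg$generator$batch_gains) < 2L) {
    stop_feree("robustness experiment needs >= 2 batches in the generator",
               "feree_config_error")
  }
  if (!cfg$scaler_scope %in% c("per_batch", "global")) {
    stop_feree("scaler_scope must be per_batch or global",
               "feree_config_error")
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes simulate -> segment -> featurize -> scale -> train (expression
#' and intensity) -> evaluate, writing all artifacts under `out_dir`:
#' `features.csv`, `scaler.json`, `model_expression.json`,
#' `model_intensity.json`, `confusion_expression.csv`,
#' `confusion_intensity.csv`, `report.json`, plus optional experiment
#' tables. Re-running with the same configuration reproduces every metric.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the trained models, reports and the
#'   metric summary written to `report.json`.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("feree_run_")) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profile <- default_activation_matrix()

  recs <- generate_dataset(cfg$generator, profile, seed = cfg$seed)
  if (cfg$write_recordings) {
    rec_dir <- file.path(out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
    manifest <- do.call(rbind, lapply(seq_along(recs), function(i) {
      p <- file.path(rec_dir, sprintf("rec_%04d.csv", i))
      write_recording(recs[[i]], p)
      data.frame(path = p, expression = recs[[i]]$label$expression,
                 intensity = recs[[i]]$label$intensity,
                 subject = recs[[i]]$subject_id, batch = recs[[i]]$batch_id)
    }))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }

  fm <- featurize_recordings(recs)
  fms <- scale_features(fm, cfg$scaler_scope)
  meta <- attr(fm, "meta")
  utils::write.csv(cbind(meta, as.data.frame(unclass(fms))),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  scaler <- attr(fms, "scaler")
  jsonlite::write_json(
    lapply(scaler, function(p) lapply(p, unname)),
    file.path(out_dir, "scaler.json"), digits = NA, auto_unbox = TRUE)

  fit_task <- function(task) {
    k <- if (task == "expression") 7L else 5L
    labels <- if (task == "expression") meta$expression
              else as.character(meta$intensity)
    ncfg <- network_config(k, seed = derive_seed(cfg$seed, k),
                           epochs = cfg$epochs, batch_size = cfg$batch_size)
    fit <- train_network(fms, labels, ncfg)
    val <- fit$report$split$validation
    pred <- predict(fit$model, unclass(fms)[val, , drop = FALSE])
    cm <- confusion_matrix(labels[val], pred, fit$model$class_names)
    utils::write.csv(as.data.frame(unclass(cm)),
                     file.path(out_dir, sprintf("confusion_%s.csv", task)))
    save_model(fit$model,
               file.path(out_dir, sprintf("model_%s.json", task)))
    list(fit = fit, true = labels[val], predicted = pred, confusion = cm)
  }

  expr_res <- fit_task("expression")
  int_res <- fit_task("intensity")

  metrics <- list(
    expression_accuracy = exact_accuracy(expr_res$true, expr_res$predicted),
    intensity_accuracy = exact_accuracy(int_res$true, int_res$predicted),
    intensity_fuzzy_accuracy = fuzzy_intensity_accuracy(
      as.integer(int_res$true), as.integer(int_res$predicted)),
    n_recordings = length(recs),
    n_frames = nrow(fm),
    seed = cfg$seed
  )

  extras <- list()
  if (cfg$run_robustness) {
    rob <- batch_robustness_experiment(recs, seeds = cfg$seed + 0:2,
                                       epochs = cfg$epochs,
                                       batch_size = cfg$batch_size)
    utils::write.csv(rob$results, file.path(out_dir, "robustness.csv"),
                     row.names = FALSE)
    metrics$crossbatch_accuracy_scaled <-
      mean(rob$results$accuracy[rob$results$scaler])
    metrics$crossbatch_accuracy_raw <-
      mean(rob$results$accuracy[!rob$results$scaler])
    extras$robustness <- rob
  }
  if (!is.null(cfg$ablation_subsets)) {
    abl <- channel_ablation(recs, cfg$ablation_subsets,
                            seeds = cfg$seed + 0:2, epochs = cfg$epochs,
                            batch_size = cfg$batch_size)
    utils::write.csv(abl$results, file.path(out_dir, "ablation.csv"),
                     row.names = FALSE)
    extras$ablation <- abl
  }
  if (cfg$run_baselines) {
    bl <- compare_baselines(fms, meta$expression, seeds = cfg$seed,
                            epochs = cfg$epochs, batch_size = cfg$batch_size)
    utils::write.csv(bl$results, file.path(out_dir, "baselines.csv"),
                     row.names = FALSE)
    extras$baselines <- bl
  }

  jsonlite::write_json(metrics, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(c(list(out_dir = out_dir, metrics = metrics,
                   expression = expr_res, intensity = int_res), extras))
}
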