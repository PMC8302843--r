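#' Confusion matrix and accuracies
#'
#' `confusion_matrix()` counts frames per (true, predicted) class pair:
#' rows are true classes, columns predictions. `exact_accuracy()` is
#' `trace/total`. `fuzzy_intensity_accuracy()` scores an intensity
#' prediction as correct when it lands on the true level or an adjacent one
#' (`|pred - true| <= 1`) — equivalently, the diagonal of the 5 x 5
#' intensity confusion matrix plus its two neighbouring cells — reflecting
#' that posed intensity is a discretised continuum whose adjacent grades are
#' not reliably distinguishable even by the subject.
#'
#' @param true,predicted Equal-length label vectors.
#' @param class_names Ordered class vocabulary; labels outside it raise an
#'   error. Defaults to the sorted union of observed labels.
#' @return `confusion_matrix()`: an integer `k x k` matrix of class
#'   `confusion_matrix`; the accuracies: a scalar in `[0, 1]`.
#' @examples
#' fuzzy_intensity_accuracy(c(1, 2, 3), c(2, 3, 5))  # 2/3
#' @export
confusion_matrix <- function(true, predicted, class_names = NULL) {
  if (length(true) != length(predicted)) {
    stop_feree("label vectors must have equal length", "feree_label_error")
  }
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (is.null(class_names)) class_names <- sort(unique(c(true, predicted)))
  bad <- setdiff(unique(c(true, predicted)), as.character(class_names))
  if (length(bad)) {
    stop_feree(sprintf("labels outside class set: %s",
                       paste(bad, collapse = ", ")), "feree_label_error")
  }
  tab <- table(factor(true, levels = class_names),
               factor(predicted, levels = class_names))
  m <- matrix(as.integer(tab), nrow = length(class_names),
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @rdname confusion_matrix
#' @export
exact_accuracy <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    stop_feree("label vectors must have equal length", "feree_label_error")
  }
  mean(as.character(true) == as.character(predicted))
}

#' @rdname confusion_matrix
#' @export
fuzzy_intensity_accuracy <- function(true, predicted) {
  true <- as.integer(as.character(true))
  predicted <- as.integer(as.character(predicted))
  if (length(true) != length(predicted)) {
    stop_feree("label vectors must have equal length", "feree_label_error")
  }
  if (anyNA(true) || anyNA(predicted) ||
      any(true < 1L | true > 5L) || any(predicted < 1L | predicted > 5L)) {
    stop_feree("intensity levels must be integers in 1..5",
               "feree_label_error")
  }
  mean(abs(predicted - true) <= 1L)
}

# Shared experiment plumbing: featurize, scale per batch, train, and report
# validation accuracy on the model's own held-out third.
run_condition <- function(recordings, channels, task, seed, scope,
                          scale = TRUE, epochs = 30L, batch_size = 128L) {
  fm <- featurize_recordings(recordings, channels = channels)
  fms <- if (scale) scale_features(fm, scope) else fm
  meta <- attr(fm, "meta")
  labels <- if (task == "expression") meta$expression
            else as.character(meta$intensity)
  k <- if (task == "expression") 7L else 5L
  cfg <- network_config(k, input_dim = 2L * length(channels), seed = seed,
                        epochs = epochs, batch_size = batch_size)
  fit <- train_network(fms, labels, cfg)
  val <- fit$report$split$validation
  pred <- predict(fit$model, unclass(fms)[val, , drop = FALSE])
  list(model = fit$model, report = fit$report,
       true = labels[val], predicted = pred,
       accuracy = exact_accuracy(labels[val], pred),
       confusion = confusion_matrix(labels[val], pred,
                                    fit$model$class_names))
}

experiment_result <- function(results, conditions) {
  structure(list(results = results, conditions = conditions),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Channel-ablation experiment
#'
#' Retrains the full pipeline on each channel subset (features recomputed on
#' the subset, network input layer resized to `2 * |subset|`) and reports
#' held-out accuracy per subset averaged over seeds. This probes how many of
#' the ten electrodes the recognizer actually needs — i.e. its robustness to
#' the loss of one or more channels.
#'
#' @param recordings A list of [recording()] objects.
#' @param channel_subsets List of integer vectors (unique indices in 1..10).
#' @param task `"expression"` or `"intensity"`.
#' @param seeds Integer vector of pipeline seeds (default 1:3).
#' @param scope Scaler scope (default per-batch).
#' @param epochs,batch_size Training budget per condition.
#' @return An `experiment_result`; `$results` has one row per
#'   (subset, seed) with the subset size and accuracy, `$conditions`
#'   records the call parameters.
#' @export
channel_ablation <- function(recordings, channel_subsets, task = "expression",
                             seeds = 1:3, scope = "per_batch",
                             epochs = 30L, batch_size = 128L) {
  if (!length(channel_subsets)) {
    stop_feree("channel_subsets must be non-empty", "feree_config_error")
  }
  for (s in channel_subsets) {
    if (!length(s) || anyDuplicated(s) || any(s < 1L | s > 10L)) {
      stop_feree("each subset must be a non-empty set of unique channels in 1..10",
                 "feree_config_error")
    }
  }
  rows <- list()
  for (si in seq_along(channel_subsets)) {
    subset <- sort(as.integer(channel_subsets[[si]]))
    for (seed in seeds) {
      res <- run_condition(recordings, subset, task, seed, scope,
                           epochs = epochs, batch_size = batch_size)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(subset, collapse = "+"),
        n_channels = length(subset), seed = seed, accuracy = res$accuracy)
    }
  }
  experiment_result(do.call(rbind, rows),
                    list(task = task, seeds = seeds, scope = scope))
}

#' Cross-batch robustness experiment
#'
#' Trains on the frames of one batch and tests on the frames of the
#' other(s), with and without robust scaling, using the same split and seed
#' in both arms. With per-batch scaling the test batch is scaled by
#' statistics fitted on its own (unlabeled) frames; without scaling, raw
#' features go straight to the network. When batches differ by a
#' multiplicative gain, scaling removes the shift exactly and cross-batch
#' accuracy should not fall below the unscaled arm.
#'
#' @param recordings A list of recordings spanning at least two batches.
#' @param train_batch Batch id to train on (default: first batch observed).
#' @param task `"expression"` or `"intensity"`.
#' @param seeds Pipeline seeds (default 1:3).
#' @param epochs,batch_size Training budget per condition.
#' @return An `experiment_result`; `$results` has one row per
#'   (scaler, seed) with cross-batch accuracy.
#' @export
batch_robustness_experiment <- function(recordings, train_batch = NULL,
                                        task = "expression", seeds = 1:3,
                                        epochs = 30L, batch_size = 128L) {
  batch_of <- vapply(recordings, function(r) r$batch_id, "")
  batches <- unique(batch_of)
  if (length(batches) < 2L) {
    stop_feree("cross-batch experiment needs >= 2 batches",
               "feree_config_error")
  }
  train_batch <- train_batch %||% batches[[1]]
  if (!train_batch %in% batches) {
    stop_feree(sprintf("train_batch '%s' not present", train_batch),
               "feree_config_error")
  }
  fm_all <- featurize_recordings(recordings)
  meta <- attr(fm_all, "meta")
  labels <- if (task == "expression") meta$expression
            else as.character(meta$intensity)
  k <- if (task == "expression") 7L else 5L
  tr_rows <- which(meta$batch_id == train_batch)
  te_rows <- which(meta$batch_id != train_batch)

  scaled <- scale_features(fm_all, "per_batch")
  rows <- list()
  for (use_scaler in c(TRUE, FALSE)) {
    x <- if (use_scaler) scaled else fm_all
    xtr <- feature_matrix(unclass(x)[tr_rows, , drop = FALSE],
                          meta[tr_rows, , drop = FALSE])
    for (seed in seeds) {
      cfg <- network_config(k, seed = seed, epochs = epochs,
                            batch_size = batch_size)
      fit <- train_network(xtr, labels[tr_rows], cfg)
      pred <- predict(fit$model, unclass(x)[te_rows, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        scaler = use_scaler, seed = seed,
        accuracy = exact_accuracy(labels[te_rows], pred))
    }
  }
  experiment_result(do.call(rbind, rows),
                    list(task = task, train_batch = train_batch,
                         test_batches = setdiff(batches, train_batch),
                         seeds = seeds))
}

#' Compare classical baselines with the FER-EE network
#'
#' Fits support vector machine, random forest, k-nearest-neighbour and
#' linear-discriminant classifiers (library implementations at fixed
#' defaults) on exactly the same stratified split as the network, so the
#' comparison is paired.
#'
#' @param features A scaled `feature_matrix`.
#' @param labels Class labels, length `nrow(features)`.
#' @param methods Subset of `c("svm", "random_forest", "knn", "lda")`.
#' @param seeds Split/training seeds (default 1:3).
#' @param include_network Also train the FER-EE network on the same splits
#'   (default TRUE).
#' @param epochs,batch_size Network training budget.
#' @return An `experiment_result`; `$results` has one row per
#'   (method, seed).
#' @export
compare_baselines <- function(features, labels,
                              methods = c("svm", "random_forest", "knn",
                                          "lda"),
                              seeds = 1:3, include_network = TRUE,
                              epochs = 30L, batch_size = 128L) {
  known <- c("svm", "random_forest", "knn", "lda")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop_feree(sprintf("unknown classifier(s): %s",
                       paste(bad, collapse = ", ")), "feree_config_error")
  }
  labels <- as.character(labels)
  x <- unclass(features)
  attr(x, "meta") <- NULL
  attr(x, "scaler") <- NULL
  class_names <- sort(unique(labels))
  rows <- list()
  for (seed in seeds) {
    split <- stratified_split(labels, 2 / 3, seed = derive_seed(seed, 7L))
    xtr <- x[split$train, , drop = FALSE]
    xte <- x[split$validation, , drop = FALSE]
    ytr <- factor(labels[split$train], levels = class_names)
    yte <- labels[split$validation]
    preds <- list()
    for (m in methods) {
      preds[[m]] <- with_seed(seed, switch(
        m,
        svm = as.character(stats::predict(
          e1071::svm(xtr, ytr, kernel = "radial"), xte)),
        random_forest = as.character(stats::predict(
          randomForest::randomForest(xtr, ytr, ntree = 200), xte)),
        knn = as.character(class::knn(xtr, xte, ytr, k = 5)),
        lda = as.character(stats::predict(
          MASS::lda(xtr, grouping = ytr), xte)$class)
      ))
    }
    if (include_network) {
      k <- length(class_names)
      if (k %in% c(5L, 7L)) {
        cfg <- network_config(k, input_dim = ncol(x), seed = seed,
                              epochs = epochs, batch_size = batch_size)
        fit <- train_network(features, labels, cfg, class_names = class_names)
        vsplit <- fit$report$split
        preds[["feree"]] <- predict(fit$model,
                                    x[vsplit$validation, , drop = FALSE])
        yte_net <- labels[vsplit$validation]
      }
    }
    for (m in names(preds)) {
      truth <- if (m == "feree") yte_net else yte
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, seed = seed, accuracy = exact_accuracy(truth, preds[[m]]))
    }
  }
  experiment_result(do.call(rbind, rows),
                    list(methods = methods, seeds = seeds,
                         include_network = include_network))
}

#' Stabilize a streaming label sequence
#'
#' Continuous recognition emits one label per frame; around expression
#' transitions the features fluctuate and single-frame outliers appear.
#' The smoother applies a centred sliding-window majority vote (ties broken
#' in favour of the earliest label inside the window), then merges any
#' remaining run shorter than `min_run` frames into its longer neighbouring
#' run. With the defaults (window 5 = 250 ms at 20 frames/s, `min_run` 3)
#' the operation is idempotent.
#'
#' @param frame_labels Character (or coercible) label sequence.
#' @param window_frames Odd window length in frames (default 5).
#' @param min_run Minimum surviving run length (default 3).
#' @return A list with `labels` (stabilized sequence, same length) and
#'   `transitions` (0-based frame indices where the stabilized label
#'   changes).
#' @export
smooth_stream <- function(frame_labels, window_frames = 5L, min_run = 3L) {
  labs <- as.character(frame_labels)
  n <- length(labs)
  if (n == 0L) return(list(labels = character(), transitions = integer()))
  window_frames <- as.integer(window_frames)
  if (window_frames < 1L || window_frames %% 2L == 0L) {
    stop_feree("window_frames must be odd and >= 1", "feree_config_error")
  }
  h <- window_frames %/% 2L
  voted <- vapply(seq_len(n), function(i) {
    win <- labs[max(1L, i - h):min(n, i + h)]
    counts <- table(win)
    modal <- names(counts)[counts == max(counts)]
    if (length(modal) == 1L) modal else win[win %in% modal][1L]
  }, "")
  # merge short runs into the longer adjacent run (previous wins ties)
  repeat {
    r <- rle(voted)
    if (length(r$lengths) <= 1L || all(r$lengths >= min_run)) break
    i <- which(r$lengths < min_run)[1L]
    if (i == 1L) {
      r$values[1L] <- r$values[2L]
    } else if (i == length(r$lengths)) {
      r$values[i] <- r$values[i - 1L]
    } else {
      r$values[i] <- if (r$lengths[i - 1L] >= r$lengths[i + 1L]) {
        r$values[i - 1L]
      } else {
        r$values[i + 1L]
      }
    }
    voted <- inverse.rle(r)
  }
  r <- rle(voted)
  transitions <- if (length(r$lengths) > 1L) {
    cumsum(r$lengths)[-length(r$lengths)]
  } else {
    integer()
  }
  list(labels = voted, transitions = as.integer(transitions))
}
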