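#' Time-domain sEMG features: root mean square and integrated EMG
#'
#' `rms()` is `sqrt(sum(x^2) / N)` — the average discharge level of a muscle
#' over the window. `iemg()` is `sum(|x|)` — the total muscle activity over
#' the window. Both are homogeneous of degree 1 in the signal amplitude,
#' which is what makes per-batch robust scaling cancel multiplicative batch
#' gains exactly.
#'
#' @param x Numeric vector, one channel of one analysis window.
#' @return A nonnegative scalar.
#' @examples
#' rms(c(0, 3, 4))   # sqrt(25/3)
#' iemg(c(1, -2, 3)) # 6
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop_feree("empty window", "feree_empty_input_error")
  sqrt(sum(x * x) / length(x))
}

#' @rdname rms
#' @export
iemg <- function(x) {
  if (length(x) == 0L) stop_feree("empty window", "feree_empty_input_error")
  sum(abs(x))
}

feature_names <- function(channels = 1:10) {
  c(paste0("RMS_CH", channels), paste0("IEMG_CH", channels))
}

#' Extract the 20-dimensional feature matrix from a list of frames
#'
#' One row per frame, columns ordered as the RMS block then the IEMG block:
#' `RMS_CH1..RMS_CH10, IEMG_CH1..IEMG_CH10`. Label and provenance columns
#' ride along as attributes of the returned object.
#'
#' @param frames A list of `emg_frame` objects from [segment_windows()]
#'   (possibly pooled over many recordings).
#' @return A `feature_matrix`: a numeric matrix `n_frames x 20` with
#'   attached data frame attribute `meta` holding `expression`, `intensity`,
#'   `subject_id`, `batch_id`, `frame_index` per row.
#' @export
extract_features <- function(frames) {
  if (inherits(frames, "emg_frame")) frames <- list(frames)
  n_ch <- unique(vapply(frames, function(f) nrow(f$window), 0L))
  if (length(n_ch) != 1L) {
    stop_feree("all frames must have the same channel count",
               "feree_shape_error")
  }
  vals <- t(vapply(frames, function(f) {
    w <- f$window
    c(sqrt(rowSums(w * w) / ncol(w)), rowSums(abs(w)))
  }, numeric(2L * n_ch)))
  colnames(vals) <- feature_names(seq_len(n_ch))
  meta <- data.frame(
    expression = vapply(frames, function(f) f$label$expression, ""),
    intensity = vapply(frames, function(f) f$label$intensity, 0L),
    subject_id = vapply(frames, function(f) f$subject_id, ""),
    batch_id = vapply(frames, function(f) f$batch_id, ""),
    frame_index = seq_along(frames) - 1L,
    stringsAsFactors = FALSE
  )
  feature_matrix(vals, meta)
}

feature_matrix <- function(values, meta) {
  stopifnot(nrow(values) == nrow(meta))
  structure(values, meta = meta, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d features (%d batches)\n",
              nrow(x), ncol(x), length(unique(attr(x, "meta")$batch_id))))
  invisible(x)
}

#' Segment and featurize a set of recordings in one step
#'
#' @param recordings A list of [recording()] objects.
#' @param window,hop Passed to [segment_windows()].
#' @param channels Optional integer subset of channels to keep (features are
#'   recomputed on the subset, giving `2 * length(channels)` columns).
#' @return A `feature_matrix` pooling all frames of all recordings.
#' @export
featurize_recordings <- function(recordings, window = 200L, hop = 50L,
                                 channels = 1:10) {
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  if (length(channels) == 0L || anyDuplicated(channels) ||
      any(channels < 1L | channels > 10L)) {
    stop_feree("channels must be a non-empty set of unique indices in 1..10",
               "feree_config_error")
  }
  frames <- unlist(lapply(recordings, function(rec) {
    fr <- segment_windows(rec, window, hop)
    if (length(channels) < 10L) {
      fr <- lapply(fr, function(f) {
        f$window <- f$window[channels, , drop = FALSE]
        f
      })
    }
    fr
  }), recursive = FALSE)
  fm <- extract_features(frames)
  colnames(fm) <- feature_names(channels)
  fm
}

#' Fit robust-scaler parameters (median and IQR per feature)
#'
#' The robust scaler centres each feature on its median and scales by its
#' interquartile range, so that the handful of extreme values that raw sEMG
#' inevitably contains cannot drag the normalization the way a mean/SD
#' standardization would. With `scope = "per_batch"` one parameter set is
#' fitted per batch, which removes per-batch multiplicative gain exactly
#' (RMS and IEMG are degree-1 homogeneous); fitting needs no labels, so new
#' sessions can be scaled before any prediction. Quartiles use the
#' linear-interpolation convention (`stats::quantile`, type 7).
#'
#' @param features A `feature_matrix`.
#' @param scope `"per_batch"` (default) or `"global"`.
#' @return A list of class `scaler_params`: one element per group, each with
#'   `medians`, `iqrs`, `fitted_on`.
#' @export
fit_robust_scaler <- function(features, scope = c("per_batch", "global")) {
  scope <- match.arg(scope)
  meta <- attr(features, "meta")
  groups <- if (scope == "per_batch") split(seq_len(nrow(features)),
                                            meta$batch_id)
            else list(global = seq_len(nrow(features)))
  params <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < 4L) {
      stop_feree(sprintf(
        "group '%s' has %d rows; >= 4 needed for quartiles", g, length(idx)),
        "feree_fit_error")
    }
    sub <- features[idx, , drop = FALSE]
    q <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
               names = FALSE, type = 7)
    list(medians = q[2, ], iqrs = q[3, ] - q[1, ], fitted_on = g)
  })
  names(params) <- names(groups)
  structure(params, scope = scope, class = "scaler_params")
}

#' Apply fitted robust-scaler parameters
#'
#' Each entry becomes `(f - median_j) / IQR_j` using the parameters of the
#' row's own group. Features with zero IQR (degenerate, e.g. constant
#' columns) are centred only: the divisor is replaced by 1.
#'
#' @param features A `feature_matrix`.
#' @param params A `scaler_params` from [fit_robust_scaler()].
#' @return A `feature_matrix` of scaled values, same shape and metadata.
#' @export
apply_robust_scaler <- function(features, params) {
  stopifnot(inherits(params, "scaler_params"))
  meta <- attr(features, "meta")
  out <- features
  scope <- attr(params, "scope")
  group_of <- if (scope == "per_batch") meta$batch_id
              else rep("global", nrow(features))
  for (g in unique(group_of)) {
    p <- params[[g]]
    if (is.null(p)) {
      stop_feree(sprintf("no scaler parameters fitted for group '%s'", g),
                 "feree_fit_error")
    }
    if (length(p$medians) != ncol(features)) {
      stop_feree("scaler dimension does not match feature count",
                 "feree_shape_error")
    }
    div <- ifelse(p$iqrs > 0, p$iqrs, 1)
    idx <- which(group_of == g)
    out[idx, ] <- sweep(sweep(features[idx, , drop = FALSE], 2, p$medians),
                        2, div, "/")
  }
  feature_matrix(unclass(out), meta)
}

#' Fit and apply the robust scaler in one step
#'
#' @inheritParams fit_robust_scaler
#' @return A scaled `feature_matrix` with the fitted `scaler_params`
#'   attached as attribute `"scaler"`.
#' @export
scale_features <- function(features, scope = c("per_batch", "global")) {
  params <- fit_robust_scaler(features, scope)
  out <- apply_robust_scaler(features, params)
  attr(out, "scaler") <- params
  out
}
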