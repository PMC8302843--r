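#' Default expression-to-channel activation profile
#'
#' A fixed 7 x 10 matrix of activation weights in `[0, 1]`: entry
#' `[e, c]` is the relative sEMG drive of channel `CH<c>` when expression
#' `e` is posed. Rows follow [feree_expressions]; columns follow the channel
#' layout in [feree_channel_aus] (brow channels CH1-CH3, nose/cheek CH4-CH5,
#' mouth and chin CH6-CH10). The weights encode standard FACS muscle
#' recruitment: brow-raiser channels dominate surprise and fear, the brow
#' lowerer dominates anger, the nose wrinkler disgust, and the mouth-corner
#' channels CH6, CH8 and CH10 are the three strongest for happiness.
#'
#' @return A matrix of class `activation_profile` with expression row names
#'   and CH1..CH10 column names.
#' @export
default_activation_matrix <- function() {
  a <- rbind(
    contempt  = c(0.05, 0.05, 0.10, 0.10, 0.35, 0.15, 0.30, 0.70, 0.45, 0.25),
    surprise  = c(0.80, 0.75, 0.10, 0.05, 0.10, 0.70, 0.15, 0.10, 0.20, 0.05),
    sadness   = c(0.60, 0.15, 0.40, 0.10, 0.10, 0.10, 0.05, 0.15, 0.55, 0.70),
    happiness = c(0.15, 0.20, 0.05, 0.10, 0.50, 0.75, 0.55, 0.85, 0.30, 0.80),
    anger     = c(0.10, 0.10, 0.85, 0.30, 0.20, 0.15, 0.10, 0.65, 0.50, 0.20),
    disgust   = c(0.10, 0.05, 0.35, 0.80, 0.65, 0.10, 0.15, 0.20, 0.55, 0.40),
    fear      = c(0.70, 0.60, 0.55, 0.10, 0.15, 0.55, 0.10, 0.25, 0.15, 0.30)
  )
  colnames(a) <- paste0("CH", 1:10)
  activation_profile(a)
}

#' Construct and validate an activation profile
#'
#' @param a Numeric 7 x 10 matrix, weights in `[0, 1]`, rows ordered as
#'   [feree_expressions]. Every expression must drive at least one channel
#'   with weight > 0.5, no two rows may be identical, and for happiness the
#'   mouth-corner channels CH6, CH8, CH10 must carry the three largest
#'   weights of the row.
#' @return The validated matrix with class `activation_profile`.
#' @export
activation_profile <- function(a) {
  a <- as.matrix(a)
  if (!all(dim(a) == c(7L, 10L))) {
    stop_feree("activation profile must be 7 x 10", "feree_config_error")
  }
  if (any(a < 0) || any(a > 1)) {
    stop_feree("activation weights must lie in [0, 1]", "feree_config_error")
  }
  if (any(apply(a, 1, max) <= 0.5)) {
    stop_feree("every expression needs one channel weight > 0.5",
               "feree_config_error")
  }
  if (anyDuplicated(as.data.frame(a))) {
    stop_feree("expression rows must be pairwise distinct",
               "feree_config_error")
  }
  hap <- a[4L, ]
  if (!setequal(order(hap, decreasing = TRUE)[1:3], c(6L, 8L, 10L)) ||
      sort(hap[c(6, 8, 10)])[1] <= max(hap[-c(6, 8, 10)])) {
    stop_feree(
      "happiness row must peak strictly on the mouth-corner channels CH6/CH8/CH10",
      "feree_config_error")
  }
  rownames(a) <- feree_expressions
  structure(a, class = c("activation_profile", "matrix", "array"))
}

#' Generator configuration
#'
#' Parameters of the synthetic sEMG generator. Each simulated recording is
#' amplitude-modulated band-limited Gaussian noise: channel `c` of a
#' recording with expression `e` and intensity level `v` has EMG-band RMS
#' amplitude `A[e, c] * intensity_curve(v) * amplitude_uV`, plus white
#' baseline noise, the sum multiplied by the per-channel gain of its batch.
#'
#' @param duration_s Recording length in seconds (default 1).
#' @param fs Sampling rate in Hz (default 1000).
#' @param amplitude_uV Full-activation EMG RMS amplitude in microvolts per
#'   unit of the intensity curve (default 5).
#' @param baseline_noise_sd Standard deviation of additive white baseline
#'   noise in microvolts (default 2).
#' @param burst_band EMG passband `(low, high)` in Hz (default 20-450, the
#'   conventional surface-EMG band).
#' @param intensity_curve Strictly increasing function mapping level 1-5 to
#'   an amplitude multiplier. Default `v^1.5`: monotone in the level but
#'   deliberately nonlinear, mimicking how recorded sEMG amplitude grows
#'   faster than the posed intensity grade.
#' @param batch_gains Named list: `batch_id` -> numeric vector of 10
#'   positive per-channel gains (a scalar is recycled). Defaults to a single
#'   unit-gain batch `"B1"`.
#' @param batch_offsets Optional named list of additive per-channel offsets
#'   (microvolts) for stress-testing; default none (batch effects are purely
#'   multiplicative).
#' @param recordings_per_class Recordings per (expression x intensity x
#'   batch) cell in [generate_dataset()] (default 3).
#' @param subject_id Subject identifier stamped on generated recordings.
#' @param seed Base RNG seed for [generate_dataset()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(duration_s = 1, fs = 1000, amplitude_uV = 5,
                             baseline_noise_sd = 2,
                             burst_band = c(20, 450),
                             intensity_curve = function(v) v^1.5,
                             batch_gains = list(B1 = 1),
                             batch_offsets = NULL,
                             recordings_per_class = 3L,
                             subject_id = "S1",
                             seed = 1L) {
  if (!(burst_band[1] > 0 && burst_band[1] < burst_band[2] &&
        burst_band[2] < fs / 2)) {
    stop_feree("burst_band must satisfy 0 < low < high < fs/2",
               "feree_config_error")
  }
  curve_vals <- vapply(1:5, intensity_curve, 0)
  if (any(diff(curve_vals) <= 0)) {
    stop_feree("intensity_curve must be strictly increasing on 1..5",
               "feree_config_error")
  }
  if (any(unlist(batch_gains) <= 0)) {
    stop_feree("batch gains must be positive", "feree_config_error")
  }
  structure(
    list(duration_s = duration_s, fs = fs, amplitude_uV = amplitude_uV,
         baseline_noise_sd = baseline_noise_sd, burst_band = burst_band,
         intensity_curve = intensity_curve, batch_gains = batch_gains,
         batch_offsets = batch_offsets,
         recordings_per_class = as.integer(recordings_per_class),
         subject_id = subject_id, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Simulate one EMG-like channel
#'
#' Zero-mean Gaussian white noise is band-limited with a zero-phase 4th
#' order Butterworth filter (edge transients generated on 0.25 s padding and
#' trimmed), then rescaled so the sample RMS equals `amplitude` exactly.
#' Deterministic given `seed`.
#'
#' @param duration_s Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param amplitude Target RMS amplitude (microvolts), `>= 0`.
#' @param band Passband `(low, high)` in Hz.
#' @param seed RNG seed.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
simulate_emg_channel <- function(duration_s, fs = 1000, amplitude = 1,
                                 band = c(20, 450), seed = 1L) {
  if (amplitude < 0) {
    stop_feree("amplitude must be nonnegative", "feree_config_error")
  }
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2)) {
    stop_feree("band must satisfy 0 < low < high < fs/2",
               "feree_config_error")
  }
  n <- as.integer(round(duration_s * fs))
  if (amplitude == 0) return(numeric(n))
  pad <- as.integer(round(0.25 * fs))
  x <- with_seed(seed, stats::rnorm(n + 2L * pad))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)[(pad + 1L):(pad + n)]
  y <- y - mean(y)
  y * (amplitude / sqrt(mean(y^2)))
}

#' Generate one synthetic labelled recording
#'
#' Channel `c` is
#' `gain[c] * (emg(A[e,c] * curve(v) * amplitude_uV) + baseline + offset[c])`
#' where `emg()` is [simulate_emg_channel()] and `baseline` is white noise
#' with SD `baseline_noise_sd`. Per-channel seeds derive deterministically
#' from `seed`, and the underlying noise streams do not depend on intensity
#' or batch, so the same `seed` across intensities or batches yields
#' comparable signals.
#'
#' @param expression,intensity Label (see [expression_label()]).
#' @param batch_id A key of `cfg$batch_gains`.
#' @param profile An [activation_profile()].
#' @param cfg A [generator_config()].
#' @param seed RNG seed for this recording.
#' @return An [recording()].
#' @export
generate_recording <- function(expression, intensity, batch_id,
                               profile = default_activation_matrix(),
                               cfg = generator_config(), seed = 1L) {
  label <- expression_label(expression, intensity)
  if (!batch_id %in% names(cfg$batch_gains)) {
    stop_feree(sprintf("unknown batch_id '%s'", batch_id),
               "feree_config_error")
  }
  gains <- rep_len(as.numeric(cfg$batch_gains[[batch_id]]), 10L)
  offsets <- if (is.null(cfg$batch_offsets)) {
    rep(0, 10L)
  } else {
    rep_len(as.numeric(cfg$batch_offsets[[batch_id]] %||% 0), 10L)
  }
  e <- match(label$expression, feree_expressions)
  lvl <- cfg$intensity_curve(label$intensity)
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  sig <- matrix(0, 10L, n)
  for (ch in 1:10) {
    amp <- profile[e, ch] * lvl * cfg$amplitude_uV
    emg <- simulate_emg_channel(cfg$duration_s, cfg$fs, amp, cfg$burst_band,
                                seed = derive_seed(seed, ch))
    base <- with_seed(derive_seed(seed, 100L + ch),
                      stats::rnorm(n, sd = cfg$baseline_noise_sd))
    sig[ch, ] <- gains[ch] * (emg + base + offsets[ch])
  }
  recording(sig, fs = cfg$fs, expression = label$expression,
            intensity = label$intensity, subject_id = cfg$subject_id,
            batch_id = batch_id)
}

#' Generate a balanced labelled dataset
#'
#' Produces `cfg$recordings_per_class` recordings for every
#' (expression x intensity x batch) cell, with per-recording seeds derived
#' deterministically from `seed`, so the dataset is a pure function of
#' `(cfg, profile, batches, seed)`.
#'
#' @param cfg A [generator_config()].
#' @param profile An [activation_profile()].
#' @param batches Character vector of batch ids (default: all batches named
#'   in `cfg$batch_gains`).
#' @param seed Base seed (default `cfg$seed`).
#' @return A list of [recording()] objects of length
#'   `7 * 5 * length(batches) * recordings_per_class`.
#' @export
generate_dataset <- function(cfg = generator_config(),
                             profile = default_activation_matrix(),
                             batches = names(cfg$batch_gains),
                             seed = cfg$seed) {
  if (cfg$recordings_per_class < 1L) {
    stop_feree("recordings_per_class must be >= 1", "feree_config_error")
  }
  grid <- expand.grid(rep = seq_len(cfg$recordings_per_class),
                      intensity = 1:5, expression = feree_expressions,
                      batch = batches, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    generate_recording(g$expression, g$intensity, g$batch, profile, cfg,
                       seed = derive_seed(seed, i))
  })
}
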