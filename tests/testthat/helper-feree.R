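# Shared fixtures, built in code. Heavier datasets are generated once per
# test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# A deterministic toy recording: 10 channels of structured sinusoid + noise.
toy_recording <- function(T = 1000L, fs = 1000, expression = "happiness",
                          intensity = 3L, batch_id = "B1", seed = 99L) {
  sig <- feree:::with_seed(seed, {
    t(sapply(1:10, function(ch) {
      sin(2 * pi * (20 + 5 * ch) * seq_len(T) / fs) * ch +
        stats::rnorm(T, sd = 0.5)
    }))
  })
  recording(sig, fs = fs, expression = expression, intensity = intensity,
            batch_id = batch_id)
}

# Small two-batch synthetic dataset (gains 1 and 2), 2 recordings per cell.
small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- generator_config(batch_gains = list(B1 = 1, B2 = 2),
                            recordings_per_class = 2L)
    .fixture_env$small <- list(cfg = cfg,
                               recs = generate_dataset(cfg, seed = 101L))
  }
  .fixture_env$small
}

# Independent scalar oracles for the feature definitions: per-sample loops
# over squaring / absolute value, deliberately not reusing rms()/iemg().
oracle_rms <- function(x) {
  sqrt(sum(vapply(x, function(v) v * v, 0)) / length(x))
}
oracle_iemg <- function(x) {
  sum(vapply(x, function(v) abs(v), 0))
}
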