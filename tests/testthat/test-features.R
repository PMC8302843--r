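test_that("rms and iemg match their closed-form examples", {
  expect_identical(rms(rep(3, 200)), 3)
  expect_identical(rms(rep(c(1, -1), 100)), 1)
  expect_equal(rms(c(0, 3, 4)), sqrt(25 / 3))
  expect_identical(iemg(numeric(10) + 0), 0)
  expect_identical(iemg(c(1, -2, 3)), 6)
  expect_error(rms(numeric(0)), class = "feree_empty_input_error")
  expect_error(iemg(numeric(0)), class = "feree_empty_input_error")
})

test_that("rms and iemg are homogeneous of degree 1", {
  set.seed(11)
  for (i in 1:20) {
    x <- stats::rnorm(50)
    a <- stats::runif(1, -5, 5)
    expect_equal(rms(a * x), abs(a) * rms(x))
    expect_equal(iemg(a * x), abs(a) * iemg(x))
  }
})

test_that("extract_features lays out RMS then IEMG per channel", {
  zero <- structure(list(window = matrix(0, 10, 200), start_index = 0L,
                         label = expression_label("fear", 1),
                         subject_id = "S1", batch_id = "B1"),
                    class = "emg_frame")
  fm <- extract_features(list(zero))
  expect_identical(dim(unclass(fm)), c(1L, 20L))
  expect_true(all(fm == 0))
  expect_identical(colnames(fm),
                   c(paste0("RMS_CH", 1:10), paste0("IEMG_CH", 1:10)))

  ch6 <- zero
  ch6$window[6, ] <- stats::rnorm(200)
  fm6 <- extract_features(list(ch6))
  expect_identical(which(fm6 != 0), c(6L, 16L))
})

test_that("extract_features agrees exactly with the scalar oracles", {
  frames <- segment_windows(toy_recording(T = 600L))
  fm <- extract_features(frames)
  for (i in seq_along(frames)) {
    for (ch in 1:10) {
      x <- frames[[i]]$window[ch, ]
      expect_identical(unname(fm[i, ch]), oracle_rms(x))
      expect_identical(unname(fm[i, 10 + ch]), oracle_iemg(x))
    }
  }
})

test_that("robust scaler fits linear-interpolation quartiles per group", {
  vals <- matrix(rep(1:5, 20), nrow = 5)
  colnames(vals) <- feree:::feature_names()
  meta <- data.frame(expression = "fear", intensity = 1L, subject_id = "S1",
                     batch_id = "B1", frame_index = 0:4)
  fm <- feree:::feature_matrix(vals, meta)
  p <- fit_robust_scaler(fm, "global")
  expect_equal(unname(p$global$medians), rep(3, 20))
  expect_equal(unname(p$global$iqrs), rep(2, 20))
  expect_identical(fit_robust_scaler(fm, "global"), p)

  scaled <- apply_robust_scaler(fm, p)
  expect_equal(unname(scaled[, 1]), c(-1, -0.5, 0, 0.5, 1))

  # constant column: IQR 0 triggers divisor substitution, centring only
  vals2 <- vals; vals2[, 3] <- 7
  fm2 <- feree:::feature_matrix(vals2, meta)
  p2 <- fit_robust_scaler(fm2, "global")
  expect_identical(unname(p2$global$iqrs[3]), 0)
  expect_equal(unname(apply_robust_scaler(fm2, p2)[, 3]), rep(0, 5))

  # groups below quartile size are rejected
  expect_error(fit_robust_scaler(feree:::feature_matrix(
    vals[1:3, ], meta[1:3, ]), "global"), class = "feree_fit_error")
})

test_that("scaled columns have median 0 and IQR 1", {
  fm <- featurize_recordings(small_dataset()$recs[1:40])
  sc <- scale_features(fm, "global")
  med <- apply(unclass(sc), 2, stats::median)
  iqr <- apply(unclass(sc), 2, stats::IQR)
  expect_equal(max(abs(med)), 0, tolerance = 1e-12)
  expect_equal(unname(iqr), rep(1, 20), tolerance = 1e-12)
})

test_that("per-batch scaling cancels multiplicative batch gain exactly", {
  base <- small_dataset()$recs[1:70]   # the B1 recordings
  gained <- lapply(base, function(r) {
    r$signals <- r$signals * 3.7
    r$batch_id <- "B2"
    r
  })
  fm <- featurize_recordings(c(base, gained))
  sc <- scale_features(fm, "per_batch")
  n <- length(base) * 17L
  a <- unclass(sc)[1:n, ]
  b <- unclass(sc)[(n + 1):(2 * n), ]
  # scaled features are O(1); relative error measured on that scale
  expect_lt(max(abs(a - b)) / max(1, max(abs(a))), 1e-9)
})

test_that("median and IQR resist 10% outlier corruption", {
  set.seed(7)
  vals <- matrix(stats::rnorm(200 * 20), 200)
  colnames(vals) <- feree:::feature_names()
  meta <- data.frame(expression = "fear", intensity = 1L, subject_id = "S1",
                     batch_id = "B1", frame_index = 0:199)
  fm <- feree:::feature_matrix(vals, meta)
  clean <- fit_robust_scaler(fm, "global")
  corrupt <- vals
  corrupt[1:20, 5] <- 1e9   # 10% of one column, arbitrarily large
  pc <- fit_robust_scaler(feree:::feature_matrix(corrupt, meta), "global")
  # bounded: the shift cannot exceed the spread of the clean order stats
  expect_lt(abs(pc$global$medians[5] - clean$global$medians[5]),
            stats::sd(vals[, 5]))
  expect_lt(abs(pc$global$iqrs[5] - clean$global$iqrs[5]),
            2 * stats::sd(vals[, 5]))
})
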