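test_that("intensity letter/level mapping is a bijection and validates", {
  expect_identical(intensity_level(c("A", "C", "E")), c(1L, 3L, 5L))
  expect_identical(intensity_letter(1:5), LETTERS[1:5])
  for (l in 1:5) expect_identical(intensity_level(intensity_letter(l)), l)
  expect_error(intensity_level("F"), class = "feree_label_error")
  expect_error(expression_label("happiness", 6), class = "feree_label_error")
  expect_error(expression_label("joy", 3), class = "feree_label_error")
})

test_that("recordings enforce the 10-channel contract", {
  expect_error(recording(matrix(0, 9, 100), expression = "fear",
                         intensity = 1),
               class = "feree_channel_error")
  expect_error(recording(matrix(0, 10, 100), fs = -1, expression = "fear",
                         intensity = 1),
               class = "feree_format_error")
  rec <- toy_recording()
  expect_identical(rec$channel_map, feree_channel_aus)
  expect_identical(rec$label$expression, "happiness")
})

test_that("segment_windows yields floor((T-window)/hop)+1 frames at i*hop", {
  rec <- toy_recording(T = 1000L)
  frames <- segment_windows(rec, window = 200, hop = 50)
  expect_length(frames, 17L)
  expect_identical(vapply(frames, function(f) f$start_index, 0L),
                   seq(0L, 800L, by = 50L))
  expect_true(all(vapply(frames, function(f) ncol(f$window), 0L) == 200L))
  expect_true(all(vapply(frames, function(f) f$label$expression, "") ==
                    "happiness"))

  expect_length(segment_windows(toy_recording(T = 200L)), 1L)
  expect_length(segment_windows(rec, window = 200, hop = 200), 5L)
  expect_error(segment_windows(toy_recording(T = 150L)),
               class = "feree_empty_input_error")
})

test_that("frame count formula holds across random sizes", {
  set.seed(42)
  for (i in 1:25) {
    T <- sample(200:1500, 1)
    window <- sample(50:200, 1)
    hop <- sample(1:window, 1)
    rec <- recording(matrix(stats::rnorm(10 * T), 10), expression = "anger",
                     intensity = 2)
    frames <- segment_windows(rec, window, hop)
    expect_length(frames, (T - window) %/% hop + 1L)
  }
})

test_that("non-overlapping frames concatenate back to the signal prefix", {
  rec <- toy_recording(T = 1030L)
  frames <- segment_windows(rec, window = 100, hop = 100)
  rebuilt <- do.call(cbind, lapply(frames, function(f) f$window))
  expect_identical(unname(rebuilt), unname(rec$signals[, 1:1000]))
})

test_that("delimited write/read round-trip is bit-exact with metadata", {
  rec <- toy_recording(batch_id = "B2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$signals, rec$signals)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$label, rec$label)
  expect_identical(back$batch_id, "B2")
  expect_identical(back$subject_id, rec$subject_id)
})

test_that("malformed delimited files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  # 9 columns only
  writeLines(c("#fs=1000", "#expression=fear", "#intensity=A",
               "#subject_id=S1", "#batch_id=B1",
               paste(paste0("CH", 1:9), collapse = ","),
               paste(rep("0", 9), collapse = ",")), path)
  expect_error(read_recording(path), class = "feree_channel_error")
  # missing metadata
  writeLines(c("#fs=1000",
               paste(paste0("CH", 1:10), collapse = ","),
               paste(rep("0", 10), collapse = ",")), path)
  expect_error(read_recording(path), class = "feree_format_error")
  expect_error(read_recording("no/such/file.csv"), class = "feree_io_error")
})

test_that("EDF round-trip preserves metadata and signals to quantization", {
  rec <- toy_recording(batch_id = "B3")
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path, format = "edf")
  back <- read_recording(path, format = "edf")
  expect_identical(back$fs, 1000)
  expect_identical(back$batch_id, "B3")
  expect_identical(back$label, rec$label)
  expect_identical(back$channel_map, rec$channel_map)
  # 16-bit quantization: error bounded by range / 2^16 per channel
  qtol <- (apply(rec$signals, 1, max) - apply(rec$signals, 1, min)) / 65535
  expect_true(all(abs(back$signals - rec$signals) <= qtol + 1e-12))
})
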