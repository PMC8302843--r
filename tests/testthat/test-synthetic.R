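test_that("default activation profile satisfies its invariants", {
  a <- default_activation_matrix()
  expect_identical(dim(unclass(a)), c(7L, 10L))
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(apply(a, 1, max) > 0.5))
  expect_identical(anyDuplicated(as.data.frame(unclass(a))), 0L)
  hap <- a["happiness", ]
  expect_true(which.max(hap) %in% c(6L, 8L, 10L))
  expect_setequal(order(hap, decreasing = TRUE)[1:3], c(6L, 8L, 10L))
})

test_that("invalid activation profiles are rejected", {
  a <- unclass(default_activation_matrix())
  bad <- a; bad["happiness", 8] <- 0.1   # CH8 no longer in top three
  expect_error(activation_profile(bad), class = "feree_config_error")
  bad <- a; bad[2, ] <- a[1, ]           # duplicate rows
  expect_error(activation_profile(bad), class = "feree_config_error")
  bad <- a; bad[1, ] <- bad[1, ] * 0.5   # no strong channel left
  expect_error(activation_profile(bad), class = "feree_config_error")
})

test_that("simulate_emg_channel hits the target RMS and is seeded", {
  x <- simulate_emg_channel(2, 1000, amplitude = 10, seed = 7)
  expect_length(x, 2000L)
  r <- sqrt(mean(x^2))
  expect_gte(r, 9.5)
  expect_lte(r, 10.5)
  expect_lt(abs(mean(x)), 1e-9)

  expect_identical(x, simulate_emg_channel(2, 1000, amplitude = 10, seed = 7))
  expect_false(identical(
    x, simulate_emg_channel(2, 1000, amplitude = 10, seed = 8)))

  expect_identical(simulate_emg_channel(1, 1000, amplitude = 0, seed = 1),
                   numeric(1000))
  expect_error(simulate_emg_channel(1, 1000, 1, band = c(450, 20)),
               class = "feree_config_error")
  expect_error(simulate_emg_channel(1, 1000, -1), class = "feree_config_error")
})

test_that("generated recordings reflect profile, intensity and batch gain", {
  cfg <- generator_config(batch_gains = list(B1 = 1, B2 = 2))
  ch_rms <- function(rec) apply(rec$signals, 1, function(v) sqrt(mean(v^2)))

  hap <- generate_recording("happiness", 4, "B1", cfg = cfg, seed = 3)
  expect_true(which.max(ch_rms(hap)) %in% c(6L, 8L, 10L))

  lo <- generate_recording("anger", 1, "B1", cfg = cfg, seed = 3)
  hi <- generate_recording("anger", 5, "B1", cfg = cfg, seed = 3)
  act <- which(default_activation_matrix()["anger", ] > 0)
  expect_true(all(ch_rms(hi)[act] > ch_rms(lo)[act]))

  b1 <- generate_recording("fear", 3, "B1", cfg = cfg, seed = 3)
  b2 <- generate_recording("fear", 3, "B2", cfg = cfg, seed = 3)
  expect_equal(b2$signals, 2 * b1$signals, tolerance = 1e-12)

  expect_error(generate_recording("fear", 3, "B9", cfg = cfg, seed = 1),
               class = "feree_config_error")
})

test_that("generate_dataset is balanced and a pure function of its seed", {
  fix <- small_dataset()
  recs <- fix$recs
  expect_length(recs, 7L * 5L * 2L * 2L)
  tab <- table(
    expression = vapply(recs, function(r) r$label$expression, ""),
    intensity = vapply(recs, function(r) r$label$intensity, 0L),
    batch = vapply(recs, function(r) r$batch_id, ""))
  expect_true(all(tab == 2L))

  again <- generate_dataset(fix$cfg, seed = 101L)
  expect_identical(lapply(again, function(r) r$signals),
                   lapply(recs, function(r) r$signals))
})

test_that("class separability grows as baseline noise shrinks", {
  ratio_for <- function(noise_sd) {
    cfg <- generator_config(baseline_noise_sd = noise_sd,
                            recordings_per_class = 1L)
    recs <- generate_dataset(cfg, seed = 5L)
    fm <- featurize_recordings(recs)
    meta <- attr(fm, "meta")
    centroids <- apply(unclass(fm), 2, tapply,
                       INDEX = meta$expression, mean)
    within <- mean(vapply(split(seq_len(nrow(fm)), meta$expression),
                          function(idx) {
      mean(sqrt(rowSums(sweep(unclass(fm)[idx, , drop = FALSE], 2,
                              colMeans(unclass(fm)[idx, , drop = FALSE]))^2)))
    }, 0))
    between <- mean(stats::dist(centroids))
    between / within
  }
  ratios <- vapply(c(8, 2, 0.25), ratio_for, 0)
  expect_true(all(diff(ratios) > 0))
})
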