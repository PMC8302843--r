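test_that("network configuration enforces the dimension chain", {
  cfg <- network_config(7L)
  expect_identical(cfg$conv_out, 5L)     # 8 - 4 + 1
  expect_identical(cfg$pool_out, 2L)     # (5 - 4)/1 + 1
  expect_identical(cfg$flatten_dim, 64L) # 2*2*16
  expect_error(network_config(4L), class = "feree_config_error")
  expect_error(network_config(7L, dense1_units = 60L),
               class = "feree_config_error")
  # the alternative small-kernel reading stays constructible
  alt <- network_config(7L, conv_kernel = 2L)
  expect_identical(alt$conv_out, 7L)
  expect_identical(alt$flatten_dim, 16L * 16L)
})

test_that("forward pass emits valid seeded probability vectors", {
  for (k in c(5L, 7L)) {
    model <- build_network(network_config(k, seed = 4L))
    p <- predict_proba(model, numeric(20))
    expect_identical(dim(p), c(1L, k))
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
  m1 <- build_network(network_config(7L, seed = 9L))
  m2 <- build_network(network_config(7L, seed = 9L))
  expect_identical(m1$weights, m2$weights)
  m3 <- build_network(network_config(7L, seed = 10L))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("prediction is the argmax with lowest-index tie-breaking", {
  model <- build_network(network_config(7L, seed = 1L))
  # zero all weights: logits identical -> exact tie -> first class
  model$weights <- lapply(model$weights, function(w) w * 0)
  x <- matrix(stats::rnorm(3 * 20), 3)
  expect_identical(predict(model, x), rep(model$class_names[1], 3))

  model2 <- build_network(network_config(7L, seed = 2L))
  x2 <- matrix(stats::rnorm(8 * 20), 8)
  probs <- predict_proba(model2, x2)
  expect_identical(predict(model2, x2),
                   model2$class_names[max.col(probs, "first")])
  # duplicated inputs give duplicated outputs (pure function)
  xx <- rbind(x2, x2)
  expect_identical(unname(predict_proba(model2, xx)[1:8, ]),
                   unname(predict_proba(model2, xx)[9:16, ]))
  expect_error(predict_proba(model2, matrix(0, 2, 19)),
               class = "feree_shape_error")
})

test_that("stratified split is disjoint, exhaustive and 2/3 proportional", {
  labels <- rep(letters[1:5], times = c(30, 33, 60, 9, 12))
  sp <- stratified_split(labels, seed = 3L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_identical(sort(c(sp$train, sp$validation)), seq_along(labels))
  for (cl in letters[1:5]) {
    n_cl <- sum(labels == cl)
    n_tr <- sum(labels[sp$train] == cl)
    expect_lte(abs(n_tr - 2 / 3 * n_cl), 1)
  }
})

test_that("the network overfits a small toy set (gradient flow)", {
  set.seed(21)
  x <- matrix(stats::rnorm(50 * 20), 50)
  y <- sample(feree_expressions[1:7], 50, replace = TRUE)
  # guarantee >= 3 per class
  y[1:21] <- rep(feree_expressions, each = 3)
  fm <- feree:::feature_matrix(x, data.frame(
    expression = y, intensity = 1L, subject_id = "S1", batch_id = "B1",
    frame_index = seq_len(50) - 1L))
  cfg <- network_config(7L, seed = 5L, epochs = 400L, batch_size = 16L,
                        patience = 400L)
  fit <- train_network(fm, y, cfg)
  expect_gte(max(fit$report$history$train_acc), 0.99)
})

test_that("training is reproducible and splits honour the contract", {
  fix <- small_dataset()
  fm <- scale_features(featurize_recordings(fix$recs[1:105]))
  labels <- attr(fm, "meta")$expression
  cfg <- network_config(7L, seed = 2L, epochs = 6L, batch_size = 128L)
  f1 <- train_network(fm, labels, cfg)
  f2 <- train_network(fm, labels, cfg)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_identical(f1$report$history, f2$report$history)
  sp <- f1$report$split
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_identical(f1$report$n_train + f1$report$n_validation, nrow(fm))
  expect_error(train_network(fm, rep("happiness", nrow(fm)), cfg),
               class = "feree_stratification_error")
})

test_that("near-noiseless synthetic features are learned almost perfectly", {
  cfg <- generator_config(baseline_noise_sd = 0.1, recordings_per_class = 2L)
  recs <- generate_dataset(cfg, seed = 31L)
  fm <- scale_features(featurize_recordings(recs))
  labels <- attr(fm, "meta")$expression
  fit <- train_network(fm, labels,
                       network_config(7L, seed = 1L, epochs = 25L,
                                      batch_size = 64L))
  best <- fit$report$history$val_acc[fit$report$best_epoch]
  expect_gte(best, 0.95)
})

test_that("label-randomized data trains to chance-level accuracy", {
  set.seed(77)
  x <- matrix(stats::rnorm(600 * 20), 600)
  y <- rep(as.character(1:5), each = 120)   # labels independent of x
  fm <- feree:::feature_matrix(x, data.frame(
    expression = "fear", intensity = 1L, subject_id = "S1", batch_id = "B1",
    frame_index = seq_len(600) - 1L))
  fit <- train_network(fm, y, network_config(5L, seed = 3L, epochs = 15L,
                                             batch_size = 64L))
  acc <- fit$report$history$val_acc[fit$report$best_epoch]
  expect_lt(abs(acc - 1 / 5), 0.1)
})

test_that("model checkpoints round-trip through JSON", {
  fix <- small_dataset()
  fm <- scale_features(featurize_recordings(fix$recs[1:105]))
  labels <- attr(fm, "meta")$expression
  fit <- train_network(fm, labels,
                       network_config(7L, seed = 8L, epochs = 3L,
                                      batch_size = 128L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  back <- load_model(path)
  x <- unclass(fm)[1:50, ]
  expect_identical(predict_proba(back, x), predict_proba(fit$model, x))
  expect_identical(back$class_names, fit$model$class_names)
})
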