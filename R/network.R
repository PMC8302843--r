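#' FER-EE network configuration
#'
#' The FER-EE classifier maps a scaled 20-dimensional feature vector to
#' class probabilities through: dense (input -> 64) with ReLU, reshape to an
#' 8 x 8 feature map, a 2-D convolution (default sixteen 4 x 4 filters,
#' stride 1, valid padding: 8 -> 5), ReLU, 4 x 4 max pooling with stride 1
#' (5 -> 2), flatten (2 x 2 x 16 = 64), and a dense softmax output layer
#' with `k` units (`k = 7` for expression type, `k = 5` for intensity
#' level). The full dimension chain is validated at construction time. The
#' alternative 2 x 2 convolution kernel reading (8 -> 7 -> pool 4 -> flatten
#' 256) is reachable by setting `conv_kernel = 2`.
#'
#' @param k Number of classes, 5 or 7.
#' @param input_dim Feature vector length (default 20; channel-ablation
#'   experiments use `2 * n_channels`).
#' @param dense1_units Width of the first dense layer; must equal
#'   `feature_map_side^2` (default 64).
#' @param feature_map_side Side of the square feature map (default 8).
#' @param conv_kernel,conv_filters Convolution kernel side and filter count
#'   (defaults 4 and 16).
#' @param pool_kernel,pool_stride Max-pool window side and stride (defaults
#'   4 and 1).
#' @param seed RNG seed for weight initialization and the training shuffle.
#' @param epochs,learning_rate,batch_size,patience Training hyperparameters:
#'   Adam with `learning_rate` (default 1e-3), up to `epochs` (default 200)
#'   passes in minibatches of `batch_size` (default 32), early stopping on
#'   validation loss with `patience` (default 20) epochs.
#' @return A list of class `network_config` with derived dimensions
#'   `conv_out`, `pool_out`, `flatten_dim`.
#' @export
network_config <- function(k, input_dim = 20L, dense1_units = 64L,
                           feature_map_side = 8L, conv_kernel = 4L,
                           conv_filters = 16L, pool_kernel = 4L,
                           pool_stride = 1L, seed = 1L, epochs = 200L,
                           learning_rate = 1e-3, batch_size = 32L,
                           patience = 20L) {
  if (!k %in% c(5L, 7L)) {
    stop_feree("k must be 5 (intensity) or 7 (expression)",
               "feree_config_error")
  }
  if (dense1_units != feature_map_side^2) {
    stop_feree("dense1_units must equal feature_map_side^2",
               "feree_config_error")
  }
  conv_out <- feature_map_side - conv_kernel + 1L
  if (conv_out < 1L) stop_feree("conv kernel larger than feature map",
                                "feree_config_error")
  if (conv_out < pool_kernel) stop_feree("pool kernel larger than conv map",
                                         "feree_config_error")
  pool_out <- (conv_out - pool_kernel) %/% pool_stride + 1L
  structure(
    list(k = as.integer(k), input_dim = as.integer(input_dim),
         dense1_units = as.integer(dense1_units),
         feature_map_side = as.integer(feature_map_side),
         conv_kernel = as.integer(conv_kernel),
         conv_filters = as.integer(conv_filters),
         pool_kernel = as.integer(pool_kernel),
         pool_stride = as.integer(pool_stride),
         conv_out = conv_out, pool_out = pool_out,
         flatten_dim = as.integer(pool_out^2 * conv_filters),
         seed = as.integer(seed), epochs = as.integer(epochs),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         patience = as.integer(patience)),
    class = "network_config"
  )
}

# Patch-index matrix: row p lists the feature-map vector indices covered by
# convolution output position p (row-major over the side x side map).
conv_patch_index <- function(side, kernel) {
  out <- side - kernel + 1L
  idx <- matrix(0L, out * out, kernel * kernel)
  p <- 0L
  for (r in seq_len(out)) {
    for (c in seq_len(out)) {
      p <- p + 1L
      cell <- 0L
      for (rr in r:(r + kernel - 1L)) {
        for (cc in c:(c + kernel - 1L)) {
          cell <- cell + 1L
          idx[p, cell] <- (rr - 1L) * side + cc
        }
      }
    }
  }
  idx
}

# Pool-set matrix: row q lists the conv-position indices inside pooled cell q.
pool_set_index <- function(conv_out, kernel, stride) {
  pool_out <- (conv_out - kernel) %/% stride + 1L
  sets <- matrix(0L, pool_out * pool_out, kernel * kernel)
  q <- 0L
  for (pr in seq_len(pool_out)) {
    for (pc in seq_len(pool_out)) {
      q <- q + 1L
      r0 <- (pr - 1L) * stride
      c0 <- (pc - 1L) * stride
      cell <- 0L
      for (rr in (r0 + 1L):(r0 + kernel)) {
        for (cc in (c0 + 1L):(c0 + kernel)) {
          cell <- cell + 1L
          sets[q, cell] <- (rr - 1L) * conv_out + cc
        }
      }
    }
  }
  sets
}

#' Build an untrained FER-EE network
#'
#' Weights are He-initialized from `cfg$seed`, so two builds with the same
#' configuration are identical.
#'
#' @param cfg A [network_config()].
#' @param class_names Ordered class labels of length `cfg$k` (defaults to
#'   [feree_expressions] for k = 7, `"1".."5"` for k = 5).
#' @return A list of class `feree_model` with fields `config`, `weights`,
#'   `class_names`, `trained` and precomputed index matrices.
#' @export
build_network <- function(cfg, class_names = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (is.null(class_names)) {
    class_names <- if (cfg$k == 7L) feree_expressions else as.character(1:5)
  }
  if (length(class_names) != cfg$k) {
    stop_feree("class_names length must equal k", "feree_config_error")
  }
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc,
                                                     sd = sqrt(2 / fan_in)),
                                        nr, nc)
  w <- with_seed(cfg$seed, list(
    W1 = he(cfg$input_dim, cfg$dense1_units, cfg$input_dim),
    b1 = numeric(cfg$dense1_units),
    Wc = he(cfg$conv_kernel^2, cfg$conv_filters, cfg$conv_kernel^2),
    bc = numeric(cfg$conv_filters),
    W2 = he(cfg$flatten_dim, cfg$k, cfg$flatten_dim),
    b2 = numeric(cfg$k)
  ))
  # dimension-chain assertion: input -> dense1 -> side^2 map -> conv -> pool
  # -> flatten -> k
  stopifnot(
    nrow(w$W1) == cfg$input_dim,
    ncol(w$W1) == cfg$feature_map_side^2,
    nrow(w$Wc) == cfg$conv_kernel^2,
    cfg$conv_out == cfg$feature_map_side - cfg$conv_kernel + 1L,
    cfg$pool_out == (cfg$conv_out - cfg$pool_kernel) %/% cfg$pool_stride + 1L,
    nrow(w$W2) == cfg$pool_out^2 * cfg$conv_filters,
    ncol(w$W2) == cfg$k
  )
  structure(
    list(config = cfg, weights = w, class_names = class_names,
         trained = FALSE, scaler_scope = NULL,
         patch_idx = conv_patch_index(cfg$feature_map_side, cfg$conv_kernel),
         pool_idx = pool_set_index(cfg$conv_out, cfg$pool_kernel,
                                   cfg$pool_stride)),
    class = "feree_model"
  ) -> model
  model$exp_idx <- conv_expansion(model$patch_idx, cfg$dense1_units,
                                  cfg$conv_filters)
  model
}

#' @export
print.feree_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<feree_model> %s | %d -> %d -> %dx%d -> conv %dx%d(x%d) -> pool %dx%d -> %d -> %d classes\n",
    if (x$trained) "trained" else "untrained",
    cfg$input_dim, cfg$dense1_units, cfg$feature_map_side,
    cfg$feature_map_side, cfg$conv_kernel, cfg$conv_kernel, cfg$conv_filters,
    cfg$pool_out, cfg$pool_out, cfg$flatten_dim, cfg$k))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# The convolution is evaluated as one dense matrix product: the shared
# kernel Wc (kernel^2 x filters) is scattered into an expanded weight matrix
# Wexp (dense1_units x positions*filters) whose column (p-1)*nf + f holds
# filter f's weights at the indices of patch p. conv_expansion precomputes
# the scatter indices; assemble_conv_weights fills Wexp from Wc each step.
conv_expansion <- function(patch_idx, dense1_units, nf) {
  np <- nrow(patch_idx)
  k2 <- ncol(patch_idx)
  p <- rep(seq_len(np), each = k2 * nf)
  cell <- rep(rep(seq_len(k2), each = nf), times = np)
  f <- rep(seq_len(nf), times = np * k2)
  row <- patch_idx[cbind(p, cell)]
  col <- (p - 1L) * nf + f
  list(dest = row + (col - 1L) * dense1_units,  # linear index into Wexp
       src = cell + (f - 1L) * k2,              # linear index into Wc
       dim = c(dense1_units, np * nf), nf = nf, np = np, k2 = k2)
}

assemble_conv_weights <- function(exp_idx, wc) {
  wexp <- matrix(0, exp_idx$dim[1], exp_idx$dim[2])
  wexp[exp_idx$dest] <- wc[exp_idx$src]
  wexp
}

# Forward pass. Returns the softmax probabilities plus, if keep = TRUE, the
# intermediates needed for backpropagation. Activations for conv position p,
# filter f live in column (p-1)*nf + f of the conv matrix.
network_forward <- function(model, x, keep = FALSE) {
  cfg <- model$config
  w <- model$weights
  n <- nrow(x)
  nf <- cfg$conv_filters
  z1 <- x %*% w$W1 + rep(w$b1, each = n)
  a1 <- z1 * (z1 > 0)
  wexp <- assemble_conv_weights(model$exp_idx, w$Wc)
  conv <- a1 %*% wexp + rep(rep(w$bc, times = model$exp_idx$np), each = n)
  a2 <- conv * (conv > 0)
  nq <- nrow(model$pool_idx)
  flat <- matrix(0, n, nq * nf)
  amax <- if (keep) vector("list", nq) else NULL
  for (q in seq_len(nq)) {
    set <- model$pool_idx[q, ]
    cols <- (set[1] - 1L) * nf + seq_len(nf)
    m <- a2[, cols, drop = FALSE]
    am <- matrix(set[1], n, nf)
    for (s in set[-1]) {
      cand <- a2[, (s - 1L) * nf + seq_len(nf), drop = FALSE]
      upd <- cand > m
      m[upd] <- cand[upd]
      am[upd] <- s
    }
    flat[, ((q - 1L) * nf + 1L):(q * nf)] <- m
    if (keep) amax[[q]] <- am
  }
  z3 <- flat %*% w$W2 + rep(w$b2, each = n)
  probs <- softmax_rows(z3)
  if (!keep) return(probs)
  list(probs = probs, x = x, z1 = z1, a1 = a1, conv = conv, flat = flat,
       amax = amax, wexp = wexp)
}

# Backward pass: gradients of mean cross-entropy w.r.t. all weights.
network_backward <- function(model, fwd, y_onehot) {
  cfg <- model$config
  w <- model$weights
  n <- nrow(fwd$x)
  nf <- cfg$conv_filters
  nq <- nrow(model$pool_idx)
  ei <- model$exp_idx
  dz3 <- (fwd$probs - y_onehot) / n
  dW2 <- crossprod(fwd$flat, dz3)
  db2 <- colSums(dz3)
  dflat <- tcrossprod(dz3, w$W2)
  dconv <- matrix(0, n, ei$np * nf)
  for (q in seq_len(nq)) {
    dm <- dflat[, ((q - 1L) * nf + 1L):(q * nf), drop = FALSE]
    am <- fwd$amax[[q]]
    for (s in model$pool_idx[q, ]) {
      hit <- am == s
      if (any(hit)) {
        cols <- (s - 1L) * nf + seq_len(nf)
        slice <- dconv[, cols, drop = FALSE]
        slice[hit] <- slice[hit] + dm[hit]
        dconv[, cols] <- slice
      }
    }
  }
  dconv <- dconv * (fwd$conv > 0)
  dwexp <- crossprod(fwd$a1, dconv)
  dwc_flat <- rowsum(matrix(dwexp[ei$dest], ncol = 1), group = ei$src)
  dWc <- matrix(0, ei$k2, nf)
  dWc[as.integer(rownames(dwc_flat))] <- dwc_flat[, 1]
  dbc <- rowSums(matrix(colSums(dconv), nf, ei$np))
  da1 <- tcrossprod(dconv, fwd$wexp)
  dz1 <- da1 * (fwd$z1 > 0)
  list(W1 = crossprod(fwd$x, dz1), b1 = colSums(dz1),
       Wc = dWc, bc = dbc, W2 = dW2, b2 = db2)
}

cross_entropy <- function(probs, y_onehot) {
  p <- rowSums(probs * y_onehot)
  -mean(log(pmax(p, 1e-12)))
}

#' Stratified train/validation split
#'
#' Splits sample indices into mutually exclusive train and validation sets
#' by stratified sampling within each class, with the training set holding
#' 2/3 of every stratum (rounded; +/- 1 sample per stratum).
#'
#' @param labels Vector of class labels.
#' @param train_frac Training fraction (default 2/3).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, train_frac = 2 / 3, seed = 1L) {
  idx_by_class <- split(seq_along(labels), labels)
  with_seed(seed, {
    train <- unlist(lapply(idx_by_class, function(idx) {
      n_tr <- round(length(idx) * train_frac)
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      sample(idx, n_tr)
    }), use.names = FALSE)
    list(train = sort(train),
         validation = sort(setdiff(seq_along(labels), train)))
  })
}

#' Train the FER-EE network
#'
#' Minimizes cross-entropy with Adam over minibatches, using a seeded
#' stratified 2/3 train / 1/3 validation split of the supplied frames and
#' early stopping on validation loss (weights restored from the best
#' epoch). Training is reproducible given `cfg$seed`.
#'
#' @param features A scaled `feature_matrix` (see [scale_features()]).
#' @param labels Vector of class labels, length `nrow(features)`; every
#'   class in `class_names` must appear at least 3 times.
#' @param cfg A [network_config()].
#' @param class_names Ordered class labels (see [build_network()]).
#' @return A list with `model` (trained `feree_model`) and `report` (class
#'   `training_report`: per-epoch train/validation accuracy and loss, split
#'   sizes, seed, epochs run).
#' @export
train_network <- function(features, labels, cfg, class_names = NULL) {
  model <- build_network(cfg, class_names)
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), model$class_names)
  if (length(unknown)) {
    stop_feree(sprintf("labels outside class set: %s",
                       paste(unknown, collapse = ", ")),
               "feree_label_error")
  }
  counts <- table(factor(labels, levels = model$class_names))
  if (any(counts < 3L)) {
    stop_feree(sprintf("every class needs >= 3 samples; missing/rare: %s",
                       paste(names(counts)[counts < 3L], collapse = ", ")),
               "feree_stratification_error")
  }
  x <- unclass(features)
  attr(x, "meta") <- NULL
  attr(x, "scaler") <- NULL
  if (ncol(x) != cfg$input_dim) {
    stop_feree(sprintf("feature dim %d != configured input_dim %d",
                       ncol(x), cfg$input_dim), "feree_shape_error")
  }
  y <- match(labels, model$class_names)
  onehot <- function(idx) {
    m <- matrix(0, length(idx), cfg$k)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  split <- stratified_split(labels, 2 / 3, seed = derive_seed(cfg$seed, 7L))
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]
  xva <- x[split$validation, , drop = FALSE]
  yva <- y[split$validation]
  ytr_oh <- onehot(ytr)
  yva_oh <- onehot(yva)

  w <- model$weights
  adam_m <- lapply(w, function(p) p * 0)
  adam_v <- lapply(w, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  best <- list(loss = Inf, weights = w, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  n_tr <- nrow(xtr)
  wait <- 0L
  with_seed(derive_seed(cfg$seed, 13L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq.int(1L, n_tr, by = cfg$batch_size)
      ep_loss <- 0; ep_hits <- 0L
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, n_tr)]
        model$weights <- w
        fwd <- network_forward(model, xtr[bi, , drop = FALSE], keep = TRUE)
        grads <- network_backward(model, fwd, ytr_oh[bi, , drop = FALSE])
        ep_loss <- ep_loss + cross_entropy(fwd$probs,
                                           ytr_oh[bi, , drop = FALSE]) *
          length(bi)
        ep_hits <- ep_hits + sum(max.col(fwd$probs, "first") == ytr[bi])
        t_step <- t_step + 1L
        for (nm in names(w)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mh <- adam_m[[nm]] / (1 - beta1^t_step)
          vh <- adam_v[[nm]] / (1 - beta2^t_step)
          w[[nm]] <- w[[nm]] - cfg$learning_rate * mh / (sqrt(vh) + eps)
        }
      }
      model$weights <- w
      pva <- predict_proba_matrix(model, xva)
      # train metrics are running minibatch averages (one pass, pre-update)
      row <- data.frame(
        epoch = epoch,
        train_loss = ep_loss / n_tr,
        train_acc = ep_hits / n_tr,
        val_loss = cross_entropy(pva, yva_oh),
        val_acc = mean(max.col(pva, "first") == yva)
      )
      hist <- rbind(hist, row)
      if (row$val_loss < best$loss - 1e-6) {
        best <- list(loss = row$val_loss, weights = w, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$weights <- best$weights
  model$trained <- TRUE
  report <- structure(
    list(history = hist, best_epoch = best$epoch,
         final_train_loss = utils::tail(hist$train_loss, 1),
         final_val_loss = best$loss,
         n_train = length(split$train), n_validation = length(split$validation),
         split = split, seed = cfg$seed),
    class = "training_report"
  )
  list(model = model, report = report)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf(
    "<training_report> %d epochs (best %d) | train %d / val %d | val acc %.3f\n",
    nrow(x$history), x$best_epoch, x$n_train, x$n_validation,
    x$history$val_acc[x$best_epoch]))
  invisible(x)
}

# Chunked forward pass on a plain matrix (keeps peak memory bounded).
predict_proba_matrix <- function(model, x, chunk = 4096L) {
  n <- nrow(x)
  out <- matrix(0, n, model$config$k)
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- network_forward(model, x[s:e, , drop = FALSE])
  }
  colnames(out) <- model$class_names
  out
}

#' Class probabilities and hard predictions
#'
#' `predict_proba()` returns the softmax probability matrix (one row per
#' frame, columns in `model$class_names` order; rows sum to 1).
#' `predict.feree_model()` returns the argmax label per row, ties broken by
#' the lowest class index.
#'
#' @param model A `feree_model`.
#' @param features A `feature_matrix` or plain numeric matrix, scaled with
#'   the same scaler scope used at training time.
#' @param object,... S3 `predict` method arguments (`newdata` =
#'   `features`).
#' @return `predict_proba()`: numeric matrix `n x k`; `predict()`:
#'   character vector of class labels.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "feree_model"))
  x <- unclass(features)
  attr(x, "meta") <- NULL
  attr(x, "scaler") <- NULL
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$config$input_dim) {
    stop_feree(sprintf("feature length %d != model input_dim %d",
                       ncol(x), model$config$input_dim), "feree_shape_error")
  }
  predict_proba_matrix(model, x)
}

#' @rdname predict_proba
#' @export
predict.feree_model <- function(object, newdata, ...) {
  probs <- predict_proba(object, newdata)
  object$class_names[max.col(probs, ties.method = "first")]
}

#' Save and load a trained model as JSON
#'
#' Checkpoints hold the configuration, weights and class names; reloaded
#' models give bit-identical predictions.
#'
#' @param model A `feree_model`.
#' @param path JSON file path.
#' @return `load_model()` returns the restored `feree_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "feree_model"))
  payload <- list(
    config = unclass(model$config),
    class_names = model$class_names,
    trained = model$trained,
    # weights stored as 17-significant-digit strings: exact double round-trip
    weights = lapply(model$weights, function(wm) {
      list(dim = if (is.matrix(wm)) dim(wm),
           data = sprintf("%.17g", as.vector(wm)))
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, payload$config[c(
    "k", "input_dim", "dense1_units", "feature_map_side", "conv_kernel",
    "conv_filters", "pool_kernel", "pool_stride", "seed", "epochs",
    "learning_rate", "batch_size", "patience")])
  model <- build_network(cfg, payload$class_names)
  model$weights <- lapply(payload$weights, function(wm) {
    v <- as.numeric(wm$data)
    if (length(wm$dim) == 2L) matrix(v, wm$dim[[1]], wm$dim[[2]]) else v
  })
  model$trained <- isTRUE(payload$trained)
  model
}
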