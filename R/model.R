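# The Siamese verifier: twin copies of one 1-D convolutional encoder with
# shared parameters, compared by cosine similarity in the embedding space,
# trained with a contrastive cosine loss
#   L = (1/B) * sum_i (1 - y_i) * c_i  -  lambda * y_i * (b + c_i)
# which pushes impostor-pair similarities down and genuine-pair
# similarities up; lambda weights the genuine term and b offsets it.

#' Siamese encoder configuration
#'
#' Three convolution blocks (convolution, batch normalization, max pooling
#' of width 2, ReLU) followed by three dense layers; the first two dense
#' layers use batch normalization, ReLU and dropout, the last is purely
#' linear and emits the embedding. All convolutions share one kernel size,
#' one tenth of the window length by default.
#'
#' @param n_beats Input window length in beats; must survive three
#'   halvings (>= 8).
#' @param conv_channels Output channels of the three convolution blocks.
#' @param kernel_size Shared convolution kernel size; default
#'   `max(1, floor(n_beats / 10))`.
#' @param pool_size Pooling width; fixed at 2 in this architecture.
#' @param linear_dims Widths of the three dense layers; the third is the
#'   embedding dimension.
#' @param embedding_dim Embedding dimension; must equal `linear_dims[3]`.
#' @param dropout_rate Dropout probability on the first two dense layers.
#' @return A list of class `"siamese_config"`.
#' @export
siamese_config <- function(n_beats,
                           conv_channels = c(16L, 32L, 64L),
                           kernel_size = max(1L, n_beats %/% 10L),
                           pool_size = 2L,
                           linear_dims = c(128L, 64L, 32L),
                           embedding_dim = linear_dims[3],
                           dropout_rate = 0.2) {
  abort_if(!is_count(n_beats, 2L), "n_beats must be a count >= 2")
  abort_if(length(conv_channels) != 3, "conv_channels must have length 3")
  abort_if(length(linear_dims) != 3, "linear_dims must have length 3")
  abort_if(!is_count(kernel_size, 1L), "kernel_size must be >= 1")
  abort_if(pool_size != 2L, "this architecture pools by 2")
  abort_if(embedding_dim < 2, "embedding_dim must be >= 2")
  abort_if(linear_dims[3] != embedding_dim,
           "linear_dims[3] is the embedding layer and must equal embedding_dim")
  abort_if(!(dropout_rate >= 0 && dropout_rate < 1),
           "dropout_rate must lie in [0, 1)")
  l_out <- n_beats %/% 2L %/% 2L %/% 2L
  abort_if(l_out < 1,
           "n_beats too small: three pool-by-2 stages leave no positions")
  structure(list(
    n_beats = as.integer(n_beats),
    conv_channels = as.integer(conv_channels),
    kernel_size = as.integer(kernel_size),
    pool_size = 2L,
    linear_dims = as.integer(linear_dims),
    embedding_dim = as.integer(embedding_dim),
    dropout_rate = dropout_rate,
    flat_dim = as.integer(conv_channels[3] * l_out)
  ), class = "siamese_config")
}

#' Loss hyperparameters of the contrastive cosine loss
#'
#' `lambda > 0` weights the genuine-pair term against the impostor term;
#' `b` in \[-1, 1\] offsets the genuine-pair similarity inside the loss,
#' expressing whether false rejections (b > 0) or false acceptances
#' (b < 0) are considered costlier.
#'
#' @param lambda Positive weight of the genuine-pair term.
#' @param b Offset in \[-1, 1\].
#' @return A list of class `"loss_params"`.
#' @export
loss_params <- function(lambda = 1, b = 0) {
  abort_if(!(is_scalar_number(lambda) && lambda > 0), "lambda must be > 0")
  abort_if(!(is_scalar_number(b) && b >= -1 && b <= 1),
           "b must lie in [-1, 1]")
  structure(list(lambda = lambda, b = b), class = "loss_params")
}

#' Initialize an untrained Siamese model
#'
#' Both branches share the single parameter set created here.
#'
#' @param config A [siamese_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `"siamese_model"`.
#' @export
build_encoder <- function(config, seed = 1) {
  stopifnot(inherits(config, "siamese_config"))
  withr::with_seed(as.integer(seed), {
    ch <- config$conv_channels
    ld <- config$linear_dims
    params <- list(
      conv1 = conv1d_init(1L, ch[1], config$kernel_size),
      bn1 = bn_init(ch[1]),
      conv2 = conv1d_init(ch[1], ch[2], config$kernel_size),
      bn2 = bn_init(ch[2]),
      conv3 = conv1d_init(ch[2], ch[3], config$kernel_size),
      bn3 = bn_init(ch[3]),
      fc1 = linear_init(config$flat_dim, ld[1]),
      bnf1 = bn_init(ld[1]),
      fc2 = linear_init(ld[1], ld[2]),
      bnf2 = bn_init(ld[2]),
      fc3 = linear_init(ld[2], ld[3])
    )
    structure(list(config = config, params = params,
                   meta = list(seed = as.integer(seed), epochs = 0L,
                               final_loss = NA_real_,
                               loss_history = numeric(0))),
              class = "siamese_model")
  })
}

#' @export
print.siamese_model <- function(x, ...) {
  cat(sprintf(
    "<siamese_model> n_beats %d, kernel %d, channels %s, embedding %d, %d epoch(s) trained\n",
    x$config$n_beats, x$config$kernel_size,
    paste(x$config$conv_channels, collapse = "-"),
    x$config$embedding_dim, x$meta$epochs))
  invisible(x)
}

BN_PARAM_NAMES <- c("bn1", "bn2", "bn3", "bnf1", "bnf2")

# Forward pass through the encoder. `x` is a (n_beats, batch) matrix;
# returns embeddings (embedding_dim, batch) and, when `keep_cache`, the
# per-layer caches needed for the backward pass.
encoder_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  abort_if(nrow(x) != cfg$n_beats,
           sprintf("window length %d does not match model n_beats %d",
                   nrow(x), cfg$n_beats))
  caches <- list()
  states <- list()
  a <- as_clb(x)
  for (blk in 1:3) {
    cv <- conv1d_forward(p[[paste0("conv", blk)]], a)
    bn <- bn_forward(p[[paste0("bn", blk)]], cv$out, training)
    mp <- maxpool2_forward(bn$out)
    rl <- relu_forward(mp$out)
    a <- rl$out
    if (keep_cache) {
      caches[[paste0("conv", blk)]] <- cv$cache
      caches[[paste0("bn", blk)]] <- bn$cache
      caches[[paste0("mp", blk)]] <- mp$cache
      caches[[paste0("relu", blk)]] <- rl$cache
    }
    if (training) states[[paste0("bn", blk)]] <- bn$new_state
  }
  a <- flat_cl(a)
  for (j in 1:2) {
    fc <- linear_forward(p[[paste0("fc", j)]], a)
    bn <- bn_forward(p[[paste0("bnf", j)]], fc$out, training)
    rl <- relu_forward(bn$out)
    dp <- dropout_forward(rl$out, cfg$dropout_rate, training)
    a <- dp$out
    if (keep_cache) {
      caches[[paste0("fc", j)]] <- fc$cache
      caches[[paste0("bnf", j)]] <- bn$cache
      caches[[paste0("reluf", j)]] <- rl$cache
      caches[[paste0("drop", j)]] <- dp$cache
    }
    if (training) states[[paste0("bnf", j)]] <- bn$new_state
  }
  fc <- linear_forward(p$fc3, a)
  if (keep_cache) caches$fc3 <- fc$cache
  list(emb = fc$out, caches = caches, states = states)
}

# Backward pass: `demb` is the gradient of the loss w.r.t. the embeddings
# (embedding_dim, batch). Returns gradients for every learnable parameter.
encoder_backward <- function(model, caches, demb, training = TRUE) {
  p <- model$params
  grads <- list()
  lb <- linear_backward(p$fc3, caches$fc3, demb)
  grads$fc3 <- lb$grads
  da <- lb$dx
  for (j in 2:1) {
    da <- dropout_backward(caches[[paste0("drop", j)]], da)
    da <- relu_backward(caches[[paste0("reluf", j)]], da)
    bb <- bn_backward(p[[paste0("bnf", j)]], caches[[paste0("bnf", j)]], da)
    grads[[paste0("bnf", j)]] <- bb$grads
    lb <- linear_backward(p[[paste0("fc", j)]], caches[[paste0("fc", j)]],
                          bb$dx)
    grads[[paste0("fc", j)]] <- lb$grads
    da <- lb$dx
  }
  # unflatten to the conv stack's output shape
  cfg <- model$config
  l3 <- cfg$n_beats %/% 2L %/% 2L %/% 2L
  dim(da) <- c(cfg$conv_channels[3], l3, ncol(demb))
  for (blk in 3:1) {
    da <- relu_backward(caches[[paste0("relu", blk)]], da)
    da <- maxpool2_backward(caches[[paste0("mp", blk)]], da)
    bb <- bn_backward(p[[paste0("bn", blk)]], caches[[paste0("bn", blk)]], da)
    grads[[paste0("bn", blk)]] <- bb$grads
    cb <- conv1d_backward(p[[paste0("conv", blk)]],
                          caches[[paste0("conv", blk)]], bb$dx)
    grads[[paste0("conv", blk)]] <- cb$grads
    da <- cb$dx
  }
  grads
}

#' Embed heartbeat windows
#'
#' Deterministic evaluation-mode forward pass (batch-norm running
#' statistics, no dropout).
#'
#' @param model A [build_encoder()] or [train_siamese()] result.
#' @param windows A window tibble, a list of interval vectors, or a
#'   `(n_beats, batch)` matrix.
#' @return An `(embedding_dim, batch)` matrix.
#' @export
embed_windows <- function(model, windows) {
  x <- windows_to_matrix(windows, model$config$n_beats)
  encoder_forward(model, x, training = FALSE)$emb
}

windows_to_matrix <- function(windows, n_beats) {
  if (is.matrix(windows)) {
    x <- windows
  } else if (is.data.frame(windows)) {
    x <- do.call(cbind, windows$intervals)
  } else if (is.list(windows)) {
    x <- do.call(cbind, windows)
  } else {
    x <- matrix(windows, ncol = 1)
  }
  abort_if(nrow(x) != n_beats,
           sprintf("window length %d does not match model n_beats %d",
                   nrow(x), n_beats))
  x
}

#' Cosine similarity between two embeddings
#'
#' The normalized inner product `t(e1) e2 / (||e1|| ||e2||)`, the cosine of
#' the angle between the embedded vectors; symmetric and scale-invariant,
#' in \[-1, 1\].
#'
#' @param e1,e2 Non-zero numeric vectors of equal length.
#' @return A similarity score in \[-1, 1\].
#' @export
cosine_similarity <- function(e1, e2) {
  abort_if(length(e1) != length(e2), "embeddings must have equal length")
  n1 <- sqrt(sum(e1^2)); n2 <- sqrt(sum(e2^2))
  abort_if(n1 == 0 || n2 == 0, "degenerate (zero-norm) embedding")
  s <- sum(e1 * e2) / (n1 * n2)
  min(max(s, -1), 1)
}

# Column-wise cosine for embedding matrices, plus the quantities needed by
# the backward pass.
cosine_cols <- function(E1, E2) {
  n1 <- sqrt(colSums(E1^2)); n2 <- sqrt(colSums(E2^2))
  abort_if(any(n1 == 0) || any(n2 == 0), "degenerate (zero-norm) embedding")
  c_val <- colSums(E1 * E2) / (n1 * n2)
  list(c = pmin(pmax(c_val, -1), 1), n1 = n1, n2 = n2)
}

# d c / d e1 = e2/(n1 n2) - c e1 / n1^2 (and symmetrically for e2)
cosine_cols_backward <- function(E1, E2, cc, dc) {
  dE1 <- sweep(E2, 2, cc$n1 * cc$n2, "/") -
    sweep(E1, 2, cc$c / cc$n1^2, "*")
  dE2 <- sweep(E1, 2, cc$n1 * cc$n2, "/") -
    sweep(E2, 2, cc$c / cc$n2^2, "*")
  list(dE1 = sweep(dE1, 2, dc, "*"), dE2 = sweep(dE2, 2, dc, "*"))
}

#' Contrastive cosine loss
#'
#' Mean over the batch of `(1 - y) * c - lambda * y * (b + c)` where `c` is
#' the cosine similarity of the pair's embeddings: genuine pairs (y = 1)
#' are rewarded for high similarity, impostor pairs (y = 0) penalized
#' for it.
#'
#' @param e1,e2 Embedding matrices `(dim, batch)` or single vectors.
#' @param y Labels, 1 genuine / 0 impostor.
#' @param params A [loss_params()].
#' @return The scalar batch loss.
#' @export
contrastive_cosine_loss <- function(e1, e2, y, params = loss_params()) {
  stopifnot(inherits(params, "loss_params"))
  if (!is.matrix(e1)) e1 <- matrix(e1, ncol = 1)
  if (!is.matrix(e2)) e2 <- matrix(e2, ncol = 1)
  abort_if(length(y) != ncol(e1), "one label per pair required")
  cc <- cosine_cols(e1, e2)
  mean((1 - y) * cc$c - params$lambda * y * (params$b + cc$c))
}

# Loss gradient with respect to each pair's cosine similarity.
loss_dc <- function(y, params, B) {
  ((1 - y) - params$lambda * y) / B
}

#' Score a pair of heartbeat windows
#'
#' Cosine similarity between the evaluation-mode embeddings of the two
#' windows; symmetric in argument order.
#'
#' @param model A Siamese model.
#' @param w1,w2 Interval vectors of length `model$config$n_beats`.
#' @return A similarity score in \[-1, 1\].
#' @export
score_pair <- function(model, w1, w2) {
  E <- embed_windows(model, list(as.numeric(w1), as.numeric(w2)))
  cosine_similarity(E[, 1], E[, 2])
}

#' Score every pair in a pair table
#'
#' @param model A Siamese model.
#' @param pairs A pair tibble from [enumerate_pairs()].
#' @param batch_size Windows embedded per forward pass.
#' @return A tibble `score`, `y` of class `"scored_pairs"`.
#' @export
score_pairs <- function(model, pairs, batch_size = 256L) {
  n <- nrow(pairs)
  scores <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    E1 <- embed_windows(model, pairs$first[idx])
    E2 <- embed_windows(model, pairs$second[idx])
    scores[idx] <- cosine_cols(E1, E2)$c
  }
  out <- tibble::tibble(score = scores, y = pairs$y)
  class(out) <- c("scored_pairs", class(out))
  out
}

# ---- SGD with momentum and weight decay ------------------------------------

sgd_update <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (layer in names(grads)) {
    decay_ok <- !(layer %in% BN_PARAM_NAMES)  # no decay on BN params
    for (slot in names(grads[[layer]])) {
      g <- grads[[layer]][[slot]]
      if (decay_ok && slot == "W") {
        g <- g + weight_decay * params[[layer]][[slot]]
      }
      v_old <- velocity[[layer]][[slot]]
      v <- if (is.null(v_old)) g else momentum * v_old + g
      velocity[[layer]][[slot]] <- v
      params[[layer]][[slot]] <- params[[layer]][[slot]] - lr * v
    }
  }
  list(params = params, velocity = velocity)
}

#' Train the Siamese verifier
#'
#' Minimizes the contrastive cosine loss by stochastic gradient descent
#' with momentum and weight decay, over class-balanced minibatches (every
#' batch half genuine, half impostor). The two branch inputs of each batch
#' are stacked into one forward pass, so batch normalization sees both.
#'
#' @param config A [siamese_config()] (or an existing `"siamese_model"` to
#'   continue training).
#' @param pairs Training pairs from [enumerate_pairs()].
#' @param loss A [loss_params()].
#' @param batch_size Even minibatch size.
#' @param learning_rate,momentum,weight_decay SGD hyperparameters.
#' @param epochs Number of passes over the genuine pairs; 0 returns the
#'   initialized model unchanged.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param verbose Print the per-epoch mean loss.
#' @return A trained `"siamese_model"` with `meta$loss_history`.
#' @export
train_siamese <- function(config, pairs, loss = loss_params(),
                          batch_size = 32L, learning_rate = 0.02,
                          momentum = 0.9, weight_decay = 1e-4,
                          epochs = 30L, seed = 1, verbose = FALSE) {
  stopifnot(inherits(loss, "loss_params"))
  model <- if (inherits(config, "siamese_model")) config else
    build_encoder(config, seed = seed)
  abort_if(epochs < 0, "epochs must be non-negative")
  if (epochs == 0) return(model)
  velocity <- list()
  history <- model$meta$loss_history
  withr::with_seed(as.integer(seed) + 1L, {
    for (ep in seq_len(epochs)) {
      batches <- balanced_minibatches(
        pairs, batch_size,
        seed = sample.int(.Machine$integer.max, 1L))
      ep_losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        bt <- batches[[bi]]
        nb <- nrow(bt)
        x1 <- windows_to_matrix(bt$first, model$config$n_beats)
        x2 <- windows_to_matrix(bt$second, model$config$n_beats)
        fw <- encoder_forward(model, cbind(x1, x2), training = TRUE,
                              keep_cache = TRUE)
        E1 <- fw$emb[, seq_len(nb), drop = FALSE]
        E2 <- fw$emb[, nb + seq_len(nb), drop = FALSE]
        cc <- cosine_cols(E1, E2)
        l_val <- mean((1 - bt$y) * cc$c - loss$lambda * bt$y * (loss$b + cc$c))
        abort_if(!is.finite(l_val),
                 "training diverged: non-finite loss; lower the learning rate")
        ep_losses[bi] <- l_val
        dE <- cosine_cols_backward(E1, E2, cc, loss_dc(bt$y, loss, nb))
        grads <- encoder_backward(model, fw$caches, cbind(dE$dE1, dE$dE2))
        upd <- sgd_update(model$params, grads, velocity, learning_rate,
                          momentum, weight_decay)
        model$params <- upd$params
        velocity <- upd$velocity
        for (nm in names(fw$states)) {
          model$params[[nm]]$run_mean <- fw$states[[nm]]$run_mean
          model$params[[nm]]$run_var <- fw$states[[nm]]$run_var
        }
      }
      history <- c(history, mean(ep_losses))
      if (verbose) {
        message(sprintf("epoch %d/%d: mean loss %.5f", ep, epochs,
                        mean(ep_losses)))
      }
    }
  })
  model$meta$epochs <- model$meta$epochs + as.integer(epochs)
  model$meta$loss_history <- history
  model$meta$final_loss <- history[length(history)]
  model$meta$loss_params <- loss
  model
}

#' Save / load a model checkpoint
#'
#' Stores configuration, learned parameters and training metadata.
#'
#' @param model A `"siamese_model"`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "siamese_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  abort_if(!inherits(model, "siamese_model"),
           "file does not contain a siamese_model checkpoint")
  model
}

#' Seeded random hyperparameter search
#'
#' Draws hyperparameter settings uniformly from the given ranges, trains a
#' model per trial, and keeps the one with the lowest equal error rate on
#' the validation pairs.
#'
#' @param config A [siamese_config()].
#' @param train_pairs,val_pairs Pair tibbles for training and validation.
#' @param n_trials Number of random draws.
#' @param space Named list of ranges: `learning_rate`, `batch_size`
#'   (choices), `momentum`, `weight_decay`, `epochs` (choices), `lambda`,
#'   `b`, `dropout`.
#' @param seed Integer seed.
#' @return A list with `best_model`, `best_eer`, and the `trials` tibble.
#' @export
tune_random_search <- function(config, train_pairs, val_pairs, n_trials = 5,
                               space = list(
                                 learning_rate = c(0.005, 0.05),
                                 batch_size = c(16L, 32L, 64L),
                                 momentum = c(0.5, 0.95),
                                 weight_decay = c(0, 1e-3),
                                 epochs = c(5L, 10L),
                                 lambda = c(0.5, 2),
                                 b = c(-1, 1),
                                 dropout = c(0, 0.4)),
                               seed = 1) {
  trials <- list()
  best <- NULL
  best_eer <- Inf
  withr::with_seed(as.integer(seed), {
    draws <- lapply(seq_len(n_trials), function(i) list(
      learning_rate = stats::runif(1, space$learning_rate[1],
                                   space$learning_rate[2]),
      batch_size = sample(space$batch_size, 1),
      momentum = stats::runif(1, space$momentum[1], space$momentum[2]),
      weight_decay = stats::runif(1, space$weight_decay[1],
                                  space$weight_decay[2]),
      epochs = sample(space$epochs, 1),
      lambda = stats::runif(1, space$lambda[1], space$lambda[2]),
      b = stats::runif(1, space$b[1], space$b[2]),
      dropout = stats::runif(1, space$dropout[1], space$dropout[2]),
      seed = sample.int(1e6, 1)
    ))
  })
  for (i in seq_len(n_trials)) {
    d <- draws[[i]]
    cfg_i <- config
    cfg_i$dropout_rate <- d$dropout
    fit <- train_siamese(cfg_i, train_pairs,
                         loss = loss_params(d$lambda, d$b),
                         batch_size = d$batch_size,
                         learning_rate = d$learning_rate,
                         momentum = d$momentum,
                         weight_decay = d$weight_decay,
                         epochs = d$epochs, seed = d$seed)
    sc <- score_pairs(fit, val_pairs)
    curves <- far_frr_curves(sc$score, sc$y)
    eer <- compute_eer(curves$far, curves$frr, curves$threshold)$eer
    trials[[i]] <- tibble::tibble(
      trial = i, eer = eer, learning_rate = d$learning_rate,
      batch_size = d$batch_size, momentum = d$momentum,
      weight_decay = d$weight_decay, epochs = d$epochs,
      lambda = d$lambda, b = d$b, dropout = d$dropout, seed = d$seed)
    if (eer < best_eer) {
      best_eer <- eer
      best <- fit
    }
  }
  list(best_model = best, best_eer = best_eer,
       trials = dplyr::bind_rows(trials))
}
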