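test_that("kernel size defaults to one tenth of the window length", {
  expect_equal(siamese_config(250)$kernel_size, 25)
  expect_equal(siamese_config(50)$kernel_size, 5)
  expect_equal(siamese_config(12)$kernel_size, 1)  # floor, min 1
  expect_error(siamese_config(6), "n_beats too small")
})

test_that("cosine similarity matches direct arithmetic and is symmetric", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / (sqrt(14) * sqrt(77)), tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 2), c(1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  withr::with_seed(1, {
    for (k in 1:20) {
      u <- rnorm(8); v <- rnorm(8)
      brute <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      expect_equal(cosine_similarity(u, v), brute, tolerance = 1e-6)
      expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
      expect_equal(cosine_similarity(3.7 * u, 0.2 * v),
                   cosine_similarity(u, v), tolerance = 1e-12)
    }
  })
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "degenerate")
})

test_that("the contrastive cosine loss reproduces hand-computed batches", {
  lp <- loss_params(lambda = 1, b = 0)
  # single genuine pair with c = 1 -> loss -1
  expect_equal(contrastive_cosine_loss(c(1, 0), c(1, 0), 1, lp), -1)
  # single impostor pair with c = 0 -> both terms vanish
  expect_equal(contrastive_cosine_loss(c(1, 0), c(0, 1), 0, lp), 0)
  # one genuine (c = 1) and one impostor (c = -1): (-1 + -1) / 2
  e1 <- cbind(c(1, 0), c(1, 0))
  e2 <- cbind(c(1, 0), c(-1, 0))
  expect_equal(contrastive_cosine_loss(e1, e2, c(1, 0), lp), -1)
  # lambda weights the genuine term; b offsets it additively
  expect_equal(contrastive_cosine_loss(c(1, 0), c(1, 0), 1,
                                       loss_params(lambda = 2, b = 0)), -2)
  expect_equal(contrastive_cosine_loss(c(1, 0), c(1, 0), 1,
                                       loss_params(lambda = 1, b = 0.5)),
               -1.5)
  expect_error(loss_params(lambda = 0), "lambda")
  expect_error(loss_params(b = 1.5), "b must")
})

test_that("eval-mode embeddings are deterministic and shared across branches", {
  cfg <- tiny_config()
  model <- build_encoder(cfg, seed = 3)
  withr::with_seed(4, w <- runif(8, 0.1, 0.2))
  E1 <- embed_windows(model, list(w))
  E2 <- embed_windows(model, list(w))
  expect_identical(E1, E2)
  # identical windows in either slot of a pair give score 1
  expect_equal(score_pair(model, w, w), 1)
  withr::with_seed(5, w2 <- runif(8, 0.1, 0.2))
  expect_equal(score_pair(model, w, w2), score_pair(model, w2, w))
  expect_true(abs(score_pair(model, w, w2)) <= 1)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_config()
  model <- build_encoder(cfg, seed = 11)
  withr::with_seed(12, {
    x1 <- matrix(runif(8 * 4, 0.1, 0.2), 8, 4)
    x2 <- matrix(runif(8 * 4, 0.1, 0.2), 8, 4)
  })
  y <- c(1, 0, 1, 0)
  lp <- loss_params(lambda = 1.3, b = 0.2)

  fw <- rrverify:::encoder_forward(model, cbind(x1, x2), training = TRUE,
                                   keep_cache = TRUE)
  E1 <- fw$emb[, 1:4]; E2 <- fw$emb[, 5:8]
  cc <- rrverify:::cosine_cols(E1, E2)
  dE <- rrverify:::cosine_cols_backward(E1, E2, cc,
                                        rrverify:::loss_dc(y, lp, 4))
  grads <- rrverify:::encoder_backward(model, fw$caches,
                                       cbind(dE$dE1, dE$dE2))
  h <- 1e-5
  for (layer in c("conv1", "bn2", "fc1", "bnf1", "fc3", "conv3")) {
    for (slot in names(grads[[layer]])) {
      v <- model$params[[layer]][[slot]]
      picks <- unique(pmin(length(v), c(1L, length(v) %/% 2 + 1L,
                                        length(v))))
      for (idx in picks) {
        mp <- model; mp$params[[layer]][[slot]][idx] <- v[idx] + h
        mm <- model; mm$params[[layer]][[slot]][idx] <- v[idx] - h
        num <- (tiny_batch_loss(mp, x1, x2, y, lp) -
                  tiny_batch_loss(mm, x1, x2, y, lp)) / (2 * h)
        expect_equal(grads[[layer]][[slot]][idx], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("a gradient step raises genuine-pair similarity and lowers impostor similarity", {
  # two-dimensional toy encoder f(x) = W x, trained by hand on one pair
  withr::with_seed(21, {
    W <- matrix(rnorm(4), 2, 2)
    x1 <- c(0.5, 1.2); x2 <- c(1.1, -0.3)
  })
  step_c <- function(y, lp) {
    c_of <- function(Wm) cosine_similarity(Wm %*% x1, Wm %*% x2)
    loss_of <- function(Wm) {
      cv <- c_of(Wm)
      (1 - y) * cv - lp$lambda * y * (lp$b + cv)
    }
    g <- matrix(0, 2, 2)
    h <- 1e-6
    for (i in 1:4) {
      Wp <- W; Wp[i] <- Wp[i] + h
      Wm2 <- W; Wm2[i] <- Wm2[i] - h
      g[i] <- (loss_of(Wp) - loss_of(Wm2)) / (2 * h)
    }
    c_of(W - 0.01 * g) - c_of(W)
  }
  expect_gt(step_c(1, loss_params()), 0)   # genuine: similarity increases
  expect_lt(step_c(0, loss_params()), 0)   # impostor: similarity decreases
  # lambda scales the genuine-pair pull
  expect_gt(step_c(1, loss_params(lambda = 3)), step_c(1, loss_params()))
})

test_that("the offset b shifts the loss value but not the learned parameters", {
  # In L = (1/B) sum (1-y)c - lambda y (b + c) the b term is constant in
  # the parameters, so training with different b from the same seed must
  # give identical weights while the loss differs by lambda * b * mean(y).
  w <- small_windows(n_beats = 25, n_subjects = 4, duration = 60)
  pairs <- enumerate_pairs(w, seed = 1)
  cfg <- siamese_config(25, conv_channels = c(4L, 6L, 8L),
                        linear_dims = c(16L, 8L, 4L), embedding_dim = 4L,
                        dropout_rate = 0)
  m_neg <- train_siamese(cfg, pairs, loss = loss_params(b = -1),
                         epochs = 2, batch_size = 8, seed = 5)
  m_pos <- train_siamese(cfg, pairs, loss = loss_params(b = 1),
                         epochs = 2, batch_size = 8, seed = 5)
  expect_equal(m_neg$params$fc3$W, m_pos$params$fc3$W, tolerance = 1e-12)
  # per-batch labels are balanced, so the epoch losses differ by
  # lambda * (b1 - b2) * 1/2
  expect_equal(m_neg$meta$final_loss - m_pos$meta$final_loss, 1,
               tolerance = 1e-10)
})

test_that("training with zero epochs returns the initialized model unchanged", {
  w <- small_windows(n_beats = 25, n_subjects = 3, duration = 40)
  pairs <- enumerate_pairs(w, seed = 1)
  cfg <- tiny_config(25)
  m0 <- train_siamese(cfg, pairs, epochs = 0, seed = 9)
  expect_identical(m0$params, build_encoder(cfg, seed = 9)$params)
  expect_equal(m0$meta$epochs, 0L)
})

test_that("training reduces the loss and improves verification on separable data", {
  w <- small_windows(n_beats = 25, n_subjects = 5, duration = 120, seed = 3)
  parts <- split_cd(w, split_spec("CD", seed = 1))
  tp <- enumerate_pairs(parts$train, max_positive_per_subject = 30, seed = 1)
  te <- enumerate_pairs(parts$test, seed = 2)
  cfg <- siamese_config(25, dropout_rate = 0.1)
  m <- train_siamese(cfg, tp, epochs = 6, seed = 1)
  expect_lt(m$meta$final_loss, m$meta$loss_history[1])
  eer_trained <- eer_from_scores(score_pairs(m, te))$eer
  eer_init <- eer_from_scores(score_pairs(build_encoder(cfg, 1), te))$eer
  expect_lt(eer_trained, 0.35)
  expect_lte(eer_trained, eer_init + 0.05)
})

test_that("checkpoints round-trip through save and load", {
  cfg <- tiny_config()
  m <- build_encoder(cfg, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$config, m$config)
})
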