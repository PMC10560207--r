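# Shared fixtures, built in code at test time.

# A small cohort with clearly separable subjects; fast to simulate.
small_cohort <- function(n_subjects = 6, seed = 7, duration = 150,
                         preset = "high_separability",
                         conditions = "basal", ages = 6,
                         artifact_rate = 0) {
  simulate_cohort(cohort_spec(
    n_subjects = n_subjects, ages_months = ages, conditions = conditions,
    segment_duration = stats::setNames(rep(duration, length(conditions)),
                                       conditions),
    artifact_rate = artifact_rate, seed = seed,
    hyper = cohort_preset(preset)))
}

small_windows <- function(n_beats = 25, ...) {
  balance_window_counts(preprocess_cohort(small_cohort(...), n_beats))
}

# A window tibble built directly (no simulation), for pairing unit tests.
toy_windows <- function(counts, condition = "basal", n_beats = 4) {
  rows <- list()
  for (sid in names(counts)) {
    for (k in seq_len(counts[[sid]])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, condition = condition, age_months = 6,
        window_index = k - 1L, n_beats = as.integer(n_beats),
        intervals = list(stats::runif(n_beats, 0.1, 0.2)))
    }
  }
  dplyr::bind_rows(rows)
}

# Independent brute-force FAR/FRR/EER oracle: direct proportions at every
# candidate threshold, then the first sign-change crossing found by a
# plain loop with linear interpolation.
brute_force_eer <- function(scores, y) {
  ts <- sort(unique(c(-1, scores, 1)))
  far <- vapply(ts, function(t) mean(scores[y == 0] >= t), numeric(1))
  frr <- vapply(ts, function(t) mean(scores[y == 1] < t), numeric(1))
  d <- far - frr
  for (i in seq_along(d)) {
    if (d[i] == 0) return(far[i])
    if (i < length(d) && d[i] * d[i + 1] < 0) {
      w <- d[i] / (d[i] - d[i + 1])
      return(far[i] + w * (far[i + 1] - far[i]))
    }
  }
  stop("no crossing found")
}

# Tiny encoder configuration for gradient checks: no dropout so the
# forward pass is deterministic.
tiny_config <- function(n_beats = 8) {
  siamese_config(n_beats, conv_channels = c(2L, 3L, 4L), kernel_size = 3L,
                 linear_dims = c(5L, 4L, 3L), embedding_dim = 3L,
                 dropout_rate = 0)
}

# Loss of a tiny Siamese batch as a pure function of the parameter list,
# for finite-difference gradient verification.
tiny_batch_loss <- function(model, x1, x2, y, loss) {
  fw <- rrverify:::encoder_forward(model, cbind(x1, x2), training = TRUE,
                                   keep_cache = FALSE)
  nb <- ncol(x1)
  E1 <- fw$emb[, seq_len(nb), drop = FALSE]
  E2 <- fw$emb[, nb + seq_len(nb), drop = FALSE]
  contrastive_cosine_loss(E1, E2, y, loss)
}
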