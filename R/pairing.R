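# Window balancing, CD/PD splits, labelled pair construction, and the
# class-balanced minibatch sampler.

#' Balance window counts across subjects
#'
#' The subject with the fewest basal windows defines the common count N;
#' every subject then keeps only its first N windows (by `window_index`)
#' in each condition present. This prevents long recordings from dominating
#' the pair pool.
#'
#' @param windows A window tibble (see [segment_windows()]).
#' @return The balanced window tibble.
#' @export
balance_window_counts <- function(windows) {
  abort_if(nrow(windows) == 0, "no windows to balance")
  basal_counts <- dplyr::count(
    dplyr::filter(windows, .data$condition == "basal"), .data$subject_id)
  subjects <- unique(windows$subject_id)
  missing <- setdiff(subjects, basal_counts$subject_id)
  abort_if(length(missing) > 0,
           paste0("subjects without basal windows: ",
                  paste(missing, collapse = ", ")))
  n_keep <- min(basal_counts$n)
  windows |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::arrange(.data$window_index, .by_group = TRUE) |>
    dplyr::slice_head(n = n_keep) |>
    dplyr::ungroup()
}

#' Split specification for CD/PD protocols
#'
#' @param protocol `"CD"` (complete dataset: every subject contributes to
#'   both sides, split over windows) or `"PD"` (partial dataset: disjoint
#'   subject sets).
#' @param train_fraction Fraction of windows (CD) or subjects (PD) assigned
#'   to training; strictly between 0 and 1.
#' @param seed Integer seed controlling split randomness.
#' @return A list of class `"split_spec"`.
#' @export
split_spec <- function(protocol = c("CD", "PD"), train_fraction = 0.8,
                       seed = 1) {
  protocol <- match.arg(protocol)
  abort_if(!(train_fraction > 0 && train_fraction < 1),
           "train_fraction must lie strictly between 0 and 1")
  structure(list(protocol = protocol, train_fraction = train_fraction,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Complete-dataset (CD) split: per-subject window partition
#'
#' Within every subject, windows are split into train and test at
#' `train_fraction`. The test share is rounded up so that a subject with at
#' least one window always has at least one test window (a subject with a
#' single window contributes it to the test side; its genuine pair is then
#' the window paired with itself downstream).
#'
#' @param windows A window tibble.
#' @param spec A [split_spec()] with `protocol = "CD"`.
#' @return A list with window tibbles `train` and `test`.
#' @export
split_cd <- function(windows, spec = split_spec("CD")) {
  stopifnot(inherits(spec, "split_spec"))
  abort_if(spec$protocol != "CD", "split_cd requires protocol = CD")
  abort_if(nrow(windows) == 0, "no windows to split")
  withr::with_seed(spec$seed, {
    groups <- split(seq_len(nrow(windows)), windows$subject_id)
    test_idx <- integer(0)
    for (g in groups) {
      n <- length(g)
      n_test <- max(1L, ceiling((1 - spec$train_fraction) * n))
      n_test <- min(n_test, n)
      test_idx <- c(test_idx, sample(g, n_test))
    }
    list(train = windows[setdiff(seq_len(nrow(windows)), test_idx), ],
         test = windows[sort(test_idx), ])
  })
}

#' Partial-dataset (PD) split: disjoint subject sets
#'
#' Subjects are partitioned so no individual appears on both sides; the
#' test side generalization to unseen individuals is what PD measures.
#' Optionally carves a subject-disjoint validation slice out of the
#' training subjects.
#'
#' @param subjects Character vector of subject ids (or a window tibble,
#'   from which ids are taken).
#' @param spec A [split_spec()] with `protocol = "PD"`.
#' @param validation_fraction Fraction of training subjects moved to a
#'   validation set; 0 disables it.
#' @return A list of character vectors `train`, `test` and (when requested)
#'   `validation`.
#' @export
split_pd <- function(subjects, spec = split_spec("PD"),
                     validation_fraction = 0) {
  stopifnot(inherits(spec, "split_spec"))
  abort_if(spec$protocol != "PD", "split_pd requires protocol = PD")
  if (is.data.frame(subjects)) subjects <- unique(subjects$subject_id)
  subjects <- unique(as.character(subjects))
  n <- length(subjects)
  abort_if(n < 2, "PD split needs at least two subjects")
  n_train <- round(spec$train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  withr::with_seed(spec$seed, {
    train <- sample(subjects, n_train)
    test <- setdiff(subjects, train)
    out <- list(train = train, test = test)
    if (validation_fraction > 0) {
      n_val <- max(1L, round(validation_fraction * length(train)))
      abort_if(n_val >= length(train),
               "validation slice would empty the training set")
      out$validation <- sample(train, n_val)
      out$train <- setdiff(train, out$validation)
    }
    out
  })
}

# All unordered index pairs {i < j} between two index sets (or within one).
cross_index_pairs <- function(idx_by_subject) {
  subj <- rep(seq_along(idx_by_subject), lengths(idx_by_subject))
  all_idx <- unlist(idx_by_subject, use.names = FALSE)
  n <- length(all_idx)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  keep <- subj[i] != subj[j]
  cbind(all_idx[i][keep], all_idx[j][keep])
}

#' Build labelled window pairs
#'
#' Positive (genuine) pairs are all distinct same-subject window
#' combinations; a subject represented by a single window contributes the
#' window paired with itself. Negative (impostor) pairs are sampled
#' uniformly over cross-subject combinations — without replacement until
#' the space is exhausted, then with replacement — to match the positive
#' count. Under `condition_policy = "same"` both members of every pair
#' (positive and negative) share the recording condition.
#'
#' @param windows A window tibble.
#' @param condition_policy `"same"` (members share condition) or
#'   `"mixed"`.
#' @param max_positive_per_subject Optional cap on genuine pairs drawn per
#'   subject (and condition, under `"same"`); `Inf` keeps all combinations.
#' @param seed Integer seed for negative sampling and subsampling.
#' @return A tibble of class `"window_pairs"` with list-columns `first`
#'   and `second` (interval vectors), label `y` (1 genuine / 0 impostor),
#'   and provenance columns.
#' @export
enumerate_pairs <- function(windows, condition_policy = c("same", "mixed"),
                            max_positive_per_subject = Inf, seed = 1) {
  condition_policy <- match.arg(condition_policy)
  abort_if(nrow(windows) < 2 && length(unique(windows$subject_id)) > 1,
           "need at least two windows")
  abort_if(nrow(windows) == 0, "no windows given")
  withr::with_seed(as.integer(seed), {
    pool_key <- if (condition_policy == "same") {
      paste(windows$subject_id, windows$condition)
    } else {
      windows$subject_id
    }
    # --- positives ---
    pos <- list()
    for (key in unique(pool_key)) {
      idx <- which(pool_key == key)
      if (length(idx) == 1L) {
        pairs_ij <- cbind(idx, idx)  # duplicated-window fallback
      } else {
        pairs_ij <- t(utils::combn(idx, 2))
      }
      if (is.finite(max_positive_per_subject) &&
          nrow(pairs_ij) > max_positive_per_subject) {
        pairs_ij <- pairs_ij[sample(nrow(pairs_ij),
                                    max_positive_per_subject), ,
                             drop = FALSE]
      }
      pos[[key]] <- pairs_ij
    }
    pos <- do.call(rbind, pos)
    n_pos <- nrow(pos)
    # --- negatives: uniform over cross-subject pairs ---
    if (condition_policy == "same") {
      neg_parts <- lapply(unique(windows$condition), function(cc) {
        idx <- which(windows$condition == cc)
        cross_index_pairs(split(idx, windows$subject_id[idx]))
      })
      neg_space <- do.call(rbind, neg_parts)
    } else {
      neg_space <- cross_index_pairs(
        split(seq_len(nrow(windows)), windows$subject_id))
    }
    abort_if(nrow(neg_space) == 0,
             "no cross-subject pair exists to serve as a negative")
    if (n_pos <= nrow(neg_space)) {
      neg <- neg_space[sample(nrow(neg_space), n_pos), , drop = FALSE]
    } else {
      extra <- neg_space[sample(nrow(neg_space), n_pos - nrow(neg_space),
                                replace = TRUE), , drop = FALSE]
      neg <- rbind(neg_space, extra)
    }
    pair_tbl <- function(ij, y) {
      tibble::tibble(
        first = windows$intervals[ij[, 1]],
        second = windows$intervals[ij[, 2]],
        y = y,
        subject_first = windows$subject_id[ij[, 1]],
        subject_second = windows$subject_id[ij[, 2]],
        condition_first = windows$condition[ij[, 1]],
        condition_second = windows$condition[ij[, 2]],
        first_ref = paste0(windows$subject_id[ij[, 1]], "/",
                           windows$condition[ij[, 1]], "/",
                           windows$window_index[ij[, 1]]),
        second_ref = paste0(windows$subject_id[ij[, 2]], "/",
                            windows$condition[ij[, 2]], "/",
                            windows$window_index[ij[, 2]])
      )
    }
    out <- dplyr::bind_rows(pair_tbl(pos, 1L), pair_tbl(neg, 0L))
    # the label must follow subject identity, nothing else
    stopifnot(all((out$subject_first == out$subject_second) == (out$y == 1L)))
    class(out) <- c("window_pairs", class(out))
    out
  })
}

#' Serve class-balanced minibatches
#'
#' One epoch is a single shuffled pass over all genuine pairs. Every full
#' batch holds exactly `batch_size / 2` genuine and `batch_size / 2`
#' impostor pairs; the minority class is resampled with replacement within
#' the epoch when it runs short.
#'
#' @param pairs A pair tibble from [enumerate_pairs()].
#' @param batch_size Even batch size.
#' @param seed Integer seed for shuffling/resampling.
#' @return A list of batches; each batch is a row-subset of `pairs` with
#'   exactly half genuine pairs.
#' @export
balanced_minibatches <- function(pairs, batch_size, seed = 1) {
  abort_if(!is_count(batch_size, 2L) || batch_size %% 2 != 0,
           "batch_size must be a positive even count")
  pos_idx <- which(pairs$y == 1L)
  neg_idx <- which(pairs$y == 0L)
  abort_if(length(pos_idx) == 0 || length(neg_idx) == 0,
           "need both genuine and impostor pairs")
  half <- batch_size %/% 2L
  withr::with_seed(as.integer(seed), {
    pos_idx <- sample(pos_idx)
    n_batches <- length(pos_idx) %/% half
    abort_if(n_batches == 0,
             "fewer genuine pairs than half a batch; reduce batch_size")
    need_neg <- n_batches * half
    neg_perm <- sample(neg_idx)
    if (need_neg > length(neg_perm)) {
      neg_perm <- c(neg_perm,
                    sample(neg_idx, need_neg - length(neg_perm),
                           replace = TRUE))
    }
    lapply(seq_len(n_batches), function(bi) {
      sel <- c(pos_idx[((bi - 1L) * half + 1L):(bi * half)],
               neg_perm[((bi - 1L) * half + 1L):(bi * half)])
      pairs[sel, ]
    })
  })
}

#' Write a pair table to CSV for audit
#'
#' Serializes window references and labels (not the raw intervals).
#'
#' @param pairs A pair tibble from [enumerate_pairs()].
#' @param path Output CSV path.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(
    data.frame(first_window_ref = pairs$first_ref,
               second_window_ref = pairs$second_ref,
               y = pairs$y),
    path, row.names = FALSE)
  invisible(path)
}
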