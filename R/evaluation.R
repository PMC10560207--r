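# Verification evaluation: threshold decisions, FAR/FRR curves, equal
# error rate, fold-wise repeatability (mean, SD, CV), confusion matrix,
# score-distribution reporting, and TOST equivalence across ages.

#' Threshold decision for one similarity score
#'
#' Accept (same subject) iff `score >= threshold`; a score exactly at the
#' threshold is accepted. Equivalent to accepting when the angle between
#' the embeddings is at most the angle corresponding to the threshold.
#'
#' @param score Similarity score(s) in \[-1, 1\].
#' @param threshold Acceptance threshold in \[-1, 1\].
#' @return `"accept"` or `"reject"` per score.
#' @export
classify_pair <- function(score, threshold) {
  abort_if(!(is_scalar_number(threshold) && threshold >= -1 &&
               threshold <= 1), "threshold must lie in [-1, 1]")
  abort_if(any(score < -1 | score > 1), "scores must lie in [-1, 1]")
  ifelse(score >= threshold, "accept", "reject")
}

#' FAR and FRR as functions of the acceptance threshold
#'
#' At each candidate threshold, FAR is the fraction of impostor pairs
#' (y = 0) accepted and FRR the fraction of genuine pairs (y = 1)
#' rejected. Candidate thresholds are the sorted unique scores plus the
#' sentinels -1 and +1.
#'
#' @param scores Similarity scores.
#' @param y Labels, 1 genuine / 0 impostor; both classes must be present.
#' @return A tibble `threshold`, `far`, `frr` (FAR non-increasing, FRR
#'   non-decreasing in the threshold).
#' @export
far_frr_curves <- function(scores, y) {
  if (is.data.frame(scores)) {
    y <- scores$y
    scores <- scores$score
  }
  abort_if(length(scores) != length(y), "scores and labels differ in length")
  abort_if(!all(y %in% c(0, 1)), "labels must be 0 or 1")
  abort_if(!any(y == 1) || !any(y == 0),
           "both genuine and impostor pairs are required")
  thresholds <- sort(unique(c(-1, scores, 1)))
  pos <- sort(scores[y == 1])
  neg <- sort(scores[y == 0])
  n_pos <- length(pos); n_neg <- length(neg)
  # accepted iff score >= t: use binary search counts on the sorted scores
  far <- (n_neg - findInterval(thresholds, neg, left.open = TRUE)) / n_neg
  frr <- findInterval(thresholds, pos, left.open = TRUE) / n_pos
  tibble::tibble(threshold = thresholds, far = far, frr = frr)
}

#' Equal error rate from FAR/FRR curves
#'
#' The common value of FAR and FRR where the curves cross. When no grid
#' threshold gives an exact tie, the crossing is located by linear
#' interpolation between the two thresholds bracketing the sign change of
#' FAR - FRR.
#'
#' @param far,frr Curves from [far_frr_curves()].
#' @param thresholds The matching threshold grid.
#' @return A list `eer`, `eer_threshold`.
#' @export
compute_eer <- function(far, frr, thresholds) {
  abort_if(length(far) != length(frr) || length(far) != length(thresholds),
           "far, frr and thresholds must have equal length")
  d <- far - frr
  exact <- which(d == 0)
  if (length(exact) > 0) {
    i <- exact[1]
    return(list(eer = far[i], eer_threshold = thresholds[i]))
  }
  sign_change <- which(d[-length(d)] * d[-1] < 0)
  abort_if(length(sign_change) == 0, "FAR and FRR curves do not cross")
  i <- sign_change[1]
  w <- d[i] / (d[i] - d[i + 1])
  eer <- far[i] + w * (far[i + 1] - far[i])
  list(eer = eer,
       eer_threshold = thresholds[i] + w * (thresholds[i + 1] - thresholds[i]))
}

#' Equal error rate straight from scored pairs
#'
#' Convenience wrapper chaining [far_frr_curves()] and [compute_eer()].
#'
#' @param scores Similarity scores (or a `"scored_pairs"` tibble).
#' @param y Labels, 1 genuine / 0 impostor.
#' @return A list `eer`, `eer_threshold`.
#' @export
eer_from_scores <- function(scores, y = NULL) {
  if (is.data.frame(scores)) {
    y <- scores$y
    scores <- scores$score
  }
  cur <- far_frr_curves(scores, y)
  compute_eer(cur$far, cur$frr, cur$threshold)
}

#' Confusion matrix at a threshold
#'
#' Rows are the ground truth (genuine, impostor), columns the prediction
#' (accept, reject).
#'
#' @param scores Similarity scores.
#' @param y Labels, 1 genuine / 0 impostor.
#' @param threshold Acceptance threshold.
#' @return A 2x2 integer matrix.
#' @export
confusion_at <- function(scores, y, threshold) {
  acc <- scores >= threshold
  matrix(c(sum(y == 1 & acc), sum(y == 1 & !acc),
           sum(y == 0 & acc), sum(y == 0 & !acc)),
         nrow = 2, byrow = TRUE,
         dimnames = list(truth = c("genuine", "impostor"),
                         prediction = c("accept", "reject")))
}

#' Fold-wise evaluation report
#'
#' Splits the scored pairs into `n_folds` disjoint random folds, computes
#' the EER inside each fold, and reports the mean, standard deviation and
#' coefficient of variation (CV = sd/mean) across folds, alongside the
#' pooled FAR/FRR curves, pooled EER and the confusion matrix at the
#' pooled-EER threshold. Folds that land with a single class are redrawn a
#' bounded number of times.
#'
#' @param scores Similarity scores (or a `"scored_pairs"` tibble).
#' @param y Labels, 1 genuine / 0 impostor.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param max_retries Redraws allowed when a fold lacks a class.
#' @return A list of class `"eval_report"`.
#' @export
folded_eval <- function(scores, y = NULL, n_folds = 5, seed = 1,
                        max_retries = 25L) {
  if (is.data.frame(scores)) {
    y <- scores$y
    scores <- scores$score
  }
  abort_if(!is_count(n_folds, 2L), "n_folds must be a count >= 2")
  n <- length(scores)
  abort_if(n < 2 * n_folds, "not enough pairs for the requested folds")
  fold_of <- NULL
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(max_retries)) {
      cand <- sample(rep_len(seq_len(n_folds), n))
      ok <- all(vapply(seq_len(n_folds), function(f) {
        yy <- y[cand == f]
        any(yy == 1) && any(yy == 0)
      }, logical(1)))
      if (ok) {
        fold_of <- cand
        break
      }
    }
  })
  abort_if(is.null(fold_of),
           "could not form folds containing both classes; use fewer folds")
  fold_eers <- vapply(seq_len(n_folds), function(f) {
    eer_from_scores(scores[fold_of == f], y[fold_of == f])$eer
  }, numeric(1))
  mean_eer <- mean(fold_eers)
  std_eer <- stats::sd(fold_eers)
  pooled <- far_frr_curves(scores, y)
  pooled_eer <- compute_eer(pooled$far, pooled$frr, pooled$threshold)
  structure(list(
    thresholds = pooled$threshold,
    far_curve = pooled$far,
    frr_curve = pooled$frr,
    eer = pooled_eer$eer,
    eer_threshold = pooled_eer$eer_threshold,
    fold_eers = fold_eers,
    mean_eer = mean_eer,
    std_eer = std_eer,
    cv = if (mean_eer > 0) std_eer / mean_eer else NA_real_,
    confusion = confusion_at(scores, y, pooled_eer$eer_threshold),
    n_pairs = n,
    n_folds = n_folds
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d pairs, pooled EER %.4f @ threshold %.4f\n",
    x$n_pairs, x$eer, x$eer_threshold))
  cat(sprintf("  %d-fold EER: mean %.4f, sd %.4f, CV %.4f\n",
              x$n_folds, x$mean_eer, x$std_eer, x$cv))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' `eval_report_json()` writes the full report (curves, EER, folds, CV,
#' confusion) as JSON; `eval_report_csv()` writes the threshold/FAR/FRR
#' rows as CSV.
#'
#' @param report An [folded_eval()] result.
#' @param path Output file path.
#' @export
eval_report_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- unclass(report)
  out$confusion <- as.data.frame(as.table(report$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname eval_report_json
#' @export
eval_report_csv <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  utils::write.csv(
    data.frame(threshold = report$thresholds, far = report$far_curve,
               frr = report$frr_curve),
    path, row.names = FALSE)
  invisible(path)
}

# One-sided Welch t-test p-value for H1: mean(x) - mean(y) > mu
# (alternative "greater") or < mu ("less"), unequal variances.
welch_one_sided <- function(x, y, mu, alternative) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  abort_if(vx + vy == 0, "degenerate test: zero variance in both groups")
  tstat <- (mean(x) - mean(y) - mu) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  if (alternative == "greater") {
    stats::pt(tstat, df, lower.tail = FALSE)
  } else {
    stats::pt(tstat, df, lower.tail = TRUE)
  }
}

#' TOST equivalence of EER between two ages
#'
#' Two one-sided unpaired Welch t-tests of the fold-EER difference against
#' an equivalence margin, by default three standard deviations of the
#' reference-age fold EERs. `p_lower` tests that the difference exceeds
#' `-margin`, `p_upper` that it falls below `+margin`. Equivalence is
#' declared when `p_lower + p_upper < alpha` (the `"sum"` rule); the
#' conventional `max(p_lower, p_upper) < alpha` rule is available as
#' `rule = "max"`.
#'
#' @param eer_ref Fold EERs at the reference age (>= 2 values).
#' @param eer_test Fold EERs at the test age (>= 2 values).
#' @param alpha Significance level in (0, 1).
#' @param margin Equivalence margin in EER units; default `3 * sd(eer_ref)`.
#' @param rule `"sum"` or `"max"` decision rule.
#' @return A list `p_lower`, `p_upper`, `equivalent`, `margin`, `diff`,
#'   `rule`.
#' @export
tost_equivalence <- function(eer_ref, eer_test, alpha = 0.05, margin = NULL,
                             rule = c("sum", "max")) {
  rule <- match.arg(rule)
  abort_if(!(alpha > 0 && alpha < 1), "alpha must lie in (0, 1)")
  abort_if(length(eer_ref) < 2 || length(eer_test) < 2,
           "need at least two fold EERs per group")
  if (is.null(margin)) margin <- 3 * stats::sd(eer_ref)
  abort_if(!(is_scalar_number(margin) && margin > 0),
           "margin must be positive (reference fold EERs may have zero sd)")
  # H0_lower: diff <= -margin  vs  H1: diff > -margin
  p_lower <- welch_one_sided(eer_test, eer_ref, -margin, "greater")
  # H0_upper: diff >= +margin  vs  H1: diff < +margin
  p_upper <- welch_one_sided(eer_test, eer_ref, margin, "less")
  equivalent <- if (rule == "sum") {
    (p_lower + p_upper) < alpha
  } else {
    max(p_lower, p_upper) < alpha
  }
  list(p_lower = p_lower, p_upper = p_upper, equivalent = equivalent,
       margin = margin, diff = mean(eer_test) - mean(eer_ref), rule = rule)
}

#' Score-distribution report
#'
#' Per-class similarity-score table with the decision boundary attached —
#' the data behind the classic two-histogram verification figure. A
#' perfect verifier has all genuine scores right of the threshold and all
#' impostor scores left of it. Pure reporting; nothing is mutated.
#'
#' @param scores Similarity scores (or a `"scored_pairs"` tibble).
#' @param y Labels, 1 genuine / 0 impostor.
#' @param threshold Decision boundary; default the EER threshold.
#' @return A tibble `score`, `y`, `class`, `side` with attribute
#'   `"threshold"`, of class `"score_report"`.
#' @export
score_distribution_report <- function(scores, y = NULL, threshold = NULL) {
  if (is.data.frame(scores)) {
    y <- scores$y
    scores <- scores$score
  }
  if (is.null(threshold)) threshold <- eer_from_scores(scores, y)$eer_threshold
  out <- tibble::tibble(
    score = scores, y = y,
    class = ifelse(y == 1, "genuine", "impostor"),
    side = ifelse(scores >= threshold, "accept", "reject"))
  attr(out, "threshold") <- threshold
  class(out) <- c("score_report", class(out))
  out
}

#' Plot a score-distribution report
#'
#' @param report A [score_distribution_report()] result.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(report, bins = 40) {
  stopifnot(inherits(report, "score_report"))
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_histogram(alpha = 0.6, bins = bins,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = attr(report, "threshold"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "cosine similarity", y = "pairs",
                  fill = "ground truth") +
    ggplot2::theme_minimal()
}
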