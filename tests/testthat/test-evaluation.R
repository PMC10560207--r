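test_that("threshold decisions accept at or above the threshold", {
  expect_identical(classify_pair(0.9, 0.5), "accept")
  expect_identical(classify_pair(-0.2, 0.5), "reject")
  expect_identical(classify_pair(0.5, 0.5), "accept")  # tie accepts
  expect_error(classify_pair(0.2, 1.5), "threshold")
})

test_that("FAR/FRR curves count acceptance errors per class", {
  cur <- far_frr_curves(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  at <- function(t) cur[which.min(abs(cur$threshold - t)), ]
  expect_equal(at(0.8)$far, 0)
  expect_equal(at(0.8)$frr, 0)
  cur2 <- far_frr_curves(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0))
  # at threshold 0.5: impostor 0.5 accepted, genuine 0.3 rejected
  i <- which(cur2$threshold == 0.5)
  expect_equal(cur2$far[i], 0.5)
  expect_equal(cur2$frr[i], 0.5)
  expect_error(far_frr_curves(c(0.1, 0.2), c(1, 1)), "both")
})

test_that("FAR is non-increasing and FRR non-decreasing in the threshold", {
  withr::with_seed(31, {
    for (k in 1:10) {
      n <- sample(20:200, 1)
      scores <- pmin(pmax(rnorm(n, 0, 0.5), -1), 1)
      y <- rbinom(n, 1, 0.5)
      if (!any(y == 1) || !any(y == 0)) next
      cur <- far_frr_curves(scores, y)
      expect_true(all(diff(cur$far) <= 0))
      expect_true(all(diff(cur$frr) >= 0))
    }
  })
})

test_that("EER handles perfect, naive and crossing cases", {
  perfect <- eer_from_scores(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$eer, 0)
  # one constant score for every pair: the naive-classifier law
  naive <- eer_from_scores(rep(0.3, 40), rep(c(1, 0), 20))
  expect_equal(naive$eer, 0.5)
  crossing <- eer_from_scores(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(crossing$eer, 0.5)
})

test_that("EER agrees with a brute-force threshold scan", {
  withr::with_seed(32, {
    for (k in 1:12) {
      n <- sample(50:500, 1)
      y <- rbinom(n, 1, 0.5)
      if (!any(y == 1) || !any(y == 0)) next
      scores <- pmin(pmax(rnorm(n, ifelse(y == 1, 0.3, -0.1), 0.4), -1), 1)
      expect_equal(eer_from_scores(scores, y)$eer,
                   brute_force_eer(scores, y), tolerance = 1e-9)
    }
  })
})

test_that("EER is invariant under strictly increasing score transforms", {
  withr::with_seed(33, {
    y <- rbinom(300, 1, 0.5)
    scores <- pmin(pmax(rnorm(300, ifelse(y == 1, 0.4, -0.2), 0.3), -1), 1)
  })
  base <- eer_from_scores(scores, y)$eer
  for (f in list(function(s) s / 2, function(s) tanh(2 * s),
                 function(s) s^3)) {
    expect_equal(eer_from_scores(f(scores), y)$eer, base, tolerance = 1e-9)
  }
})

test_that("fold-wise evaluation reports mean, sd and CV = sd/mean", {
  withr::with_seed(34, {
    y <- rbinom(500, 1, 0.5)
    scores <- pmin(pmax(rnorm(500, ifelse(y == 1, 0.5, -0.3), 0.4), -1), 1)
  })
  rep5 <- folded_eval(scores, y, n_folds = 5, seed = 1)
  expect_length(rep5$fold_eers, 5)
  expect_equal(rep5$mean_eer, mean(rep5$fold_eers))
  expect_equal(rep5$std_eer, sd(rep5$fold_eers))
  expect_equal(rep5$cv, rep5$std_eer / rep5$mean_eer)
  expect_equal(sum(rep5$confusion), 500)
  # identical fold EERs give zero spread; CV definition check
  expect_equal(0.02 / 0.2, 0.1)
  expect_identical(folded_eval(scores, y, n_folds = 5, seed = 1)$fold_eers,
                   rep5$fold_eers)
})

test_that("the confusion matrix is truth-by-prediction", {
  cm <- confusion_at(c(0.9, 0.2, 0.6, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(cm["genuine", "accept"], 1)
  expect_equal(cm["genuine", "reject"], 1)
  expect_equal(cm["impostor", "accept"], 1)
  expect_equal(cm["impostor", "reject"], 1)
})

test_that("TOST p-values match the Welch t-test oracle", {
  withr::with_seed(35, {
    ref <- rnorm(8, 0.15, 0.02)
    test <- rnorm(8, 0.16, 0.03)
  })
  margin <- 3 * sd(ref)
  res <- tost_equivalence(ref, test, alpha = 0.05, margin = margin)
  p_lower_oracle <- t.test(test, ref, mu = -margin,
                           alternative = "greater")$p.value
  p_upper_oracle <- t.test(test, ref, mu = margin,
                           alternative = "less")$p.value
  expect_equal(res$p_lower, p_lower_oracle, tolerance = 1e-9)
  expect_equal(res$p_upper, p_upper_oracle, tolerance = 1e-9)
  expect_identical(res$equivalent,
                   (p_lower_oracle + p_upper_oracle) < 0.05)
})

test_that("TOST declares equivalence for same-distribution groups and not for distant ones", {
  withr::with_seed(36, {
    a <- rnorm(10, 0.2, 0.01)
    b <- rnorm(10, 0.2, 0.01)
  })
  expect_true(tost_equivalence(a, b, margin = 0.1)$equivalent)
  expect_false(tost_equivalence(a, b + 0.5, margin = 0.1)$equivalent)
  # enormous margin: both p-values collapse toward zero
  huge <- tost_equivalence(a, b + 0.5, margin = 100)
  expect_lt(huge$p_lower + huge$p_upper, 1e-6)
  expect_true(huge$equivalent)
  # the conventional max rule is available
  expect_true(tost_equivalence(a, b, margin = 0.1, rule = "max")$equivalent)
  expect_error(tost_equivalence(rep(0.1, 3), rep(0.1, 3), margin = 0.1),
               "zero variance")
})

test_that("the score-distribution report separates classes around the boundary", {
  scores <- c(0.9, 0.8, 0.7, -0.5, -0.6, -0.7)
  y <- c(1, 1, 1, 0, 0, 0)
  rep1 <- score_distribution_report(scores, y)
  expect_true(all(rep1$side[rep1$y == 1] == "accept"))
  expect_true(all(rep1$side[rep1$y == 0] == "reject"))
  # regenerating from the same scores yields the identical artifact
  expect_identical(score_distribution_report(scores, y), rep1)
  p <- plot_score_distribution(rep1)
  expect_s3_class(p, "ggplot")
})
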