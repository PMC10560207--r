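test_that("window balancing keeps the first N windows, N set by the smallest basal count", {
  withr::with_seed(1, w <- toy_windows(c(A = 5, B = 3, C = 7)))
  b <- balance_window_counts(w)
  counts <- table(b$subject_id)
  expect_true(all(counts == 3))
  for (sid in c("A", "B", "C")) {
    expect_equal(sort(b$window_index[b$subject_id == sid]), 0:2)
  }
  # already balanced input is untouched
  withr::with_seed(2, w2 <- toy_windows(c(A = 4, B = 4)))
  expect_equal(nrow(balance_window_counts(w2)), 8)
  # a single subject keeps all its basal windows
  withr::with_seed(3, w3 <- toy_windows(c(A = 6)))
  expect_equal(nrow(balance_window_counts(w3)), 6)
  # drug windows are capped at the basal N too
  withr::with_seed(4, {
    w4 <- dplyr::bind_rows(toy_windows(c(A = 2, B = 5)),
                           toy_windows(c(A = 9, B = 9), condition = "drug"))
  })
  b4 <- balance_window_counts(w4)
  expect_true(all(table(b4$subject_id, b4$condition) == 2))
})

test_that("CD split is per-subject 80/20 with guaranteed test coverage", {
  withr::with_seed(5, w <- toy_windows(c(A = 10, B = 10)))
  parts <- split_cd(w, split_spec("CD", seed = 3))
  expect_equal(sum(parts$train$subject_id == "A"), 8)
  expect_equal(sum(parts$test$subject_id == "A"), 2)
  # 30 subjects x 5 windows -> 120 train, 30 test
  withr::with_seed(6, {
    counts <- stats::setNames(rep(5, 30), sprintf("S%02d", 1:30))
    w30 <- toy_windows(as.list(counts))
  })
  p30 <- split_cd(w30, split_spec("CD", seed = 1))
  expect_equal(nrow(p30$train), 120)
  expect_equal(nrow(p30$test), 30)
  # every test subject also appears in training (CD invariant)
  expect_true(all(p30$test$subject_id %in% p30$train$subject_id))
  # a single-window subject lands in test
  withr::with_seed(7, w1 <- toy_windows(c(A = 1, B = 5)))
  p1 <- split_cd(w1, split_spec("CD", seed = 2))
  expect_equal(sum(p1$test$subject_id == "A"), 1)
})

test_that("PD split is subject-disjoint and reproducible", {
  subjects <- sprintf("M%02d", 1:30)
  parts <- split_pd(subjects, split_spec("PD", seed = 4))
  expect_length(parts$train, 24)
  expect_length(parts$test, 6)
  expect_length(intersect(parts$train, parts$test), 0)
  expect_identical(parts, split_pd(subjects, split_spec("PD", seed = 4)))
  expect_false(identical(parts$test,
                         split_pd(subjects, split_spec("PD", seed = 5))$test))
  two <- split_pd(c("A", "B"), split_spec("PD", 0.5, seed = 1))
  expect_length(two$train, 1)
  expect_length(two$test, 1)
  # optional subject-disjoint validation slice
  pv <- split_pd(subjects, split_spec("PD", seed = 4),
                 validation_fraction = 0.2)
  expect_length(intersect(pv$validation, pv$train), 0)
  expect_length(intersect(pv$validation, pv$test), 0)
})

test_that("pair enumeration labels by subject identity and balances classes", {
  withr::with_seed(8, w <- toy_windows(c(A = 2, B = 2)))
  pairs <- enumerate_pairs(w, seed = 1)
  expect_equal(sum(pairs$y == 1), 2)   # one genuine combination per subject
  expect_equal(sum(pairs$y == 0), 2)   # negatives sampled to match
  expect_true(all((pairs$subject_first == pairs$subject_second) ==
                    (pairs$y == 1)))
  # single-window subject: genuine pair duplicates the window
  withr::with_seed(9, w1 <- toy_windows(c(A = 1, B = 3)))
  p1 <- enumerate_pairs(w1, seed = 1)
  dup <- p1[p1$y == 1 & p1$subject_first == "A", ]
  expect_equal(nrow(dup), 1)
  expect_identical(dup$first[[1]], dup$second[[1]])
})

test_that("condition policy `same` keeps both members in one condition", {
  withr::with_seed(10, {
    w <- dplyr::bind_rows(toy_windows(c(A = 3, B = 3)),
                          toy_windows(c(A = 3, B = 3), condition = "drug"))
  })
  pairs <- enumerate_pairs(w, condition_policy = "same", seed = 2)
  expect_true(all(pairs$condition_first == pairs$condition_second))
  mixed <- enumerate_pairs(w, condition_policy = "mixed", seed = 2)
  expect_true(any(mixed$condition_first != mixed$condition_second))
})

test_that("negative sampling matches the positive count even beyond the pair space", {
  withr::with_seed(11, w <- toy_windows(c(A = 6, B = 1)))
  # positives: C(6,2) + 1 = 16 > cross-subject space of 6
  pairs <- enumerate_pairs(w, seed = 3)
  expect_equal(sum(pairs$y == 0), sum(pairs$y == 1))
})

test_that("balanced minibatches are exactly half genuine in every full batch", {
  withr::with_seed(12, w <- toy_windows(c(A = 8, B = 8, C = 8)))
  pairs <- enumerate_pairs(w, seed = 4)
  for (bs in c(2L, 8L, 20L)) {
    batches <- balanced_minibatches(pairs, bs, seed = 1)
    for (bt in batches) {
      expect_equal(nrow(bt), bs)
      expect_equal(sum(bt$y == 1), bs / 2)
    }
  }
  # one epoch = one pass over genuine pairs
  n_pos <- sum(pairs$y == 1)
  batches <- balanced_minibatches(pairs, 20L, seed = 2)
  expect_equal(length(batches), n_pos %/% 10)
  expect_error(balanced_minibatches(pairs, 7L), "even")
})

test_that("pair lists serialize to an auditable CSV", {
  withr::with_seed(13, w <- toy_windows(c(A = 2, B = 2)))
  pairs <- enumerate_pairs(w, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairs_csv(pairs, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(pairs))
  expect_identical(names(back), c("first_window_ref", "second_window_ref",
                                  "y"))
})
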