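# Experiment runner reproducing the three study designs on synthetic
# cohorts: window-length sweep, train-young/test-older age sweep with TOST
# verdicts, and the drug-condition comparison with a shared drug test set.

#' Experiment specification
#'
#' @param design `"window_sweep"` (EER vs window length),
#'   `"age_sweep"` (train at one age, test across ages, TOST verdicts), or
#'   `"drug_conditions"` (train on basal / drug / combined pairs, always
#'   test on the drug test set).
#' @param protocol `"CD"` or `"PD"`.
#' @param n_beats_grid Window lengths swept (window_sweep); default the
#'   full 25-to-600-beat grid in steps of 25.
#' @param train_age Training age in months.
#' @param test_ages Ages evaluated (age_sweep).
#' @param train_condition `"basal"`, `"drug"` or `"combined"`
#'   (drug_conditions trains each requested condition).
#' @param test_condition Condition of the test pairs.
#' @param n_folds Folds for the EER repeatability statistics.
#' @param seeds One result row per grid cell and seed.
#' @param n_beats Window length for designs that fix it.
#' @return A list of class `"experiment_spec"`.
#' @export
experiment_spec <- function(design = c("window_sweep", "age_sweep",
                                       "drug_conditions"),
                            protocol = c("CD", "PD"),
                            n_beats_grid = seq(25, 600, by = 25),
                            train_age = 6,
                            test_ages = c(6, 9, 12, 15, 18, 21, 24),
                            train_condition = "basal",
                            test_condition = "basal",
                            n_folds = 5,
                            seeds = 1,
                            n_beats = 50) {
  design <- match.arg(design)
  protocol <- match.arg(protocol)
  abort_if(length(n_beats_grid) == 0, "n_beats_grid must be non-empty")
  abort_if(length(test_ages) == 0, "test_ages must be non-empty")
  structure(list(design = design, protocol = protocol,
                 n_beats_grid = n_beats_grid, train_age = train_age,
                 test_ages = test_ages, train_condition = train_condition,
                 test_condition = test_condition, n_folds = n_folds,
                 seeds = seeds, n_beats = n_beats),
            class = "experiment_spec")
}

# Fit-and-evaluate for one cell: returns the eval_report of the test pairs.
fit_eval_cell <- function(train_windows, test_windows, n_beats, seed,
                          n_folds, train_opts) {
  train_pairs <- enumerate_pairs(
    train_windows, condition_policy = "same",
    max_positive_per_subject = train_opts$max_positive_per_subject,
    seed = seed)
  test_pairs <- enumerate_pairs(
    test_windows, condition_policy = "same",
    max_positive_per_subject = train_opts$max_positive_per_subject,
    seed = seed + 1L)
  cfg <- siamese_config(n_beats, dropout_rate = train_opts$dropout_rate)
  model <- train_siamese(
    cfg, train_pairs, loss = train_opts$loss,
    batch_size = train_opts$batch_size,
    learning_rate = train_opts$learning_rate,
    momentum = train_opts$momentum,
    weight_decay = train_opts$weight_decay,
    epochs = train_opts$epochs, seed = seed)
  scored <- score_pairs(model, test_pairs)
  list(report = folded_eval(scored, n_folds = n_folds, seed = seed),
       model = model)
}

default_train_opts <- function(...) {
  opts <- list(batch_size = 32L, learning_rate = 0.02, momentum = 0.9,
               weight_decay = 1e-4, epochs = 15L, dropout_rate = 0.2,
               loss = loss_params(), max_positive_per_subject = 40L)
  override <- list(...)
  opts[names(override)] <- override
  opts
}

#' Run a study design over a synthetic cohort
#'
#' Every grid cell (window length, test age, or training condition,
#' depending on the design) is trained and evaluated once per seed; each
#' row reports the fold-wise mean EER, its standard deviation and the
#' coefficient of variation. For `age_sweep`, each non-reference age also
#' carries the TOST equivalence verdict against the reference-age fold
#' EERs. For `drug_conditions`, training uses basal, drug or
#' combined pairs while the test set is always the drug windows, so the
#' three training regimes are compared on identical test data.
#'
#' @param spec An [experiment_spec()].
#' @param cohort An [simulate_cohort()] result (or list of [rr_series()])
#'   covering the required ages and conditions.
#' @param train_opts Training options from [default_train_opts()].
#' @param alpha TOST significance level (age_sweep).
#' @return A tibble with one row per grid cell and seed.
#' @export
run_experiment <- function(spec, cohort, train_opts = default_train_opts(),
                           alpha = 0.05) {
  stopifnot(inherits(spec, "experiment_spec"))
  rows <- list()
  for (seed in spec$seeds) {
    seed <- as.integer(seed)
    if (spec$design == "window_sweep") {
      for (nb in spec$n_beats_grid) {
        w <- cohort_windows(cohort, nb, ages = spec$train_age,
                            conditions = spec$train_condition)
        parts <- protocol_split(w, spec$protocol, seed)
        cell <- fit_eval_cell(parts$train, parts$test, nb, seed,
                              spec$n_folds, train_opts)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          design = spec$design, protocol = spec$protocol, seed = seed,
          n_beats = nb, age_months = spec$train_age,
          train_condition = spec$train_condition,
          mean_eer = cell$report$mean_eer, std_eer = cell$report$std_eer,
          cv = cell$report$cv)
      }
    } else if (spec$design == "age_sweep") {
      nb <- spec$n_beats
      train_w <- cohort_windows(cohort, nb, ages = spec$train_age,
                                conditions = spec$train_condition)
      parts <- protocol_split(train_w, spec$protocol, seed)
      cell <- fit_eval_cell(parts$train, parts$test, nb, seed,
                            spec$n_folds, train_opts)
      ref_folds <- cell$report$fold_eers
      for (age in spec$test_ages) {
        if (age == spec$train_age) {
          rep_a <- cell$report
          tost <- list(p_lower = NA_real_, p_upper = NA_real_,
                       equivalent = NA)
        } else {
          test_w <- cohort_windows(cohort, nb, ages = age,
                                   conditions = spec$test_condition)
          test_w <- keep_subjects(test_w, unique(parts$test$subject_id))
          test_pairs <- enumerate_pairs(
            test_w, condition_policy = "same",
            max_positive_per_subject = train_opts$max_positive_per_subject,
            seed = seed + 1L)
          scored <- score_pairs(cell$model, test_pairs)
          rep_a <- folded_eval(scored, n_folds = spec$n_folds, seed = seed)
          tost <- tryCatch(
            tost_equivalence(ref_folds, rep_a$fold_eers, alpha = alpha),
            error = function(e) list(p_lower = NA_real_, p_upper = NA_real_,
                                     equivalent = NA))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          design = spec$design, protocol = spec$protocol, seed = seed,
          n_beats = nb, age_months = age,
          train_condition = spec$train_condition,
          mean_eer = rep_a$mean_eer, std_eer = rep_a$std_eer, cv = rep_a$cv,
          tost_p_lower = tost$p_lower, tost_p_upper = tost$p_upper,
          tost_equivalent = tost$equivalent)
      }
    } else { # drug_conditions
      nb <- spec$n_beats
      train_conds <- if (identical(spec$train_condition, "combined")) {
        list("basal", "drug", "combined")
      } else {
        as.list(spec$train_condition)
      }
      # shared drug test set across all training regimes
      all_w <- cohort_windows(cohort, nb, ages = spec$train_age,
                              conditions = c("basal", "drug"))
      parts <- protocol_split(all_w, spec$protocol, seed)
      test_w <- parts$test[parts$test$condition == "drug", ]
      abort_if(nrow(test_w) == 0, "no drug windows available for testing")
      test_pairs <- enumerate_pairs(
        test_w, condition_policy = "same",
        max_positive_per_subject = train_opts$max_positive_per_subject,
        seed = seed + 1L)
      for (tc in train_conds) {
        train_w <- if (tc == "combined") parts$train else
          parts$train[parts$train$condition == tc, ]
        train_pairs <- enumerate_pairs(
          train_w, condition_policy = "same",
          max_positive_per_subject = train_opts$max_positive_per_subject,
          seed = seed)
        cfg <- siamese_config(nb, dropout_rate = train_opts$dropout_rate)
        model <- train_siamese(
          cfg, train_pairs, loss = train_opts$loss,
          batch_size = train_opts$batch_size,
          learning_rate = train_opts$learning_rate,
          momentum = train_opts$momentum,
          weight_decay = train_opts$weight_decay,
          epochs = train_opts$epochs, seed = seed)
        scored <- score_pairs(model, test_pairs)
        rep_c <- folded_eval(scored, n_folds = spec$n_folds, seed = seed)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          design = spec$design, protocol = spec$protocol, seed = seed,
          n_beats = nb, age_months = spec$train_age, train_condition = tc,
          test_condition = "drug",
          mean_eer = rep_c$mean_eer, std_eer = rep_c$std_eer, cv = rep_c$cv)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Windows for the requested ages/conditions, balanced across subjects.
cohort_windows <- function(cohort, n_beats, ages, conditions) {
  series <- if (inherits(cohort, "rr_cohort")) cohort$series else cohort
  keep <- vapply(series, function(s) {
    s$age_months %in% ages && s$condition %in% conditions
  }, logical(1))
  abort_if(!any(keep),
           "cohort lacks coverage for the requested ages/conditions")
  w <- preprocess_cohort(series[keep], n_beats)
  abort_if(nrow(w) == 0, "no windows after preprocessing; series too short")
  if ("basal" %in% w$condition) balance_window_counts(w) else w
}

protocol_split <- function(windows, protocol, seed) {
  if (protocol == "CD") {
    split_cd(windows, split_spec("CD", seed = seed))
  } else {
    subj <- split_pd(windows, split_spec("PD", seed = seed))
    list(train = keep_subjects(windows, subj$train),
         test = keep_subjects(windows, subj$test))
  }
}

keep_subjects <- function(windows, subjects) {
  windows[windows$subject_id %in% subjects, ]
}
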