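# Synthetic mouse-like RR cohort generator.
#
# Each subject carries a persistent dynamical signature: a mean RR level, an
# AR(2) short-range correlation structure, a respiratory-like sinusoidal
# modulation, and subject-specific responses to aging and to dual autonomic
# blockade ("drug"). Distinct subjects draw independent signatures, which is
# what gives downstream verification something to learn.

#' Hyperparameters of the cohort signature distribution
#'
#' Defines the population distributions from which per-subject biometric
#' signatures are drawn. Scale parameters are standard deviations of normal
#' draws (truncated where a sign constraint applies); `*_range` parameters
#' are uniform bounds. Setting every `*_sd` to zero and collapsing every
#' range to a point makes all subjects identical (the degenerate preset).
#'
#' The default mean RR of 0.132 s is calibrated so that a 250-beat window
#' spans about 33 s, the time scale typical of anesthetized mice.
#'
#' @param mean_rr Population mean of the subject baseline RR (seconds).
#' @param mean_rr_sd Between-subject SD of the baseline RR (seconds).
#' @param sd_rr Population centre of within-subject RR variability (seconds).
#' @param sd_rr_sd Between-subject spread of `sd_rr` (seconds).
#' @param ar1_range,ar2_range Uniform bounds for the two AR coefficients;
#'   defaults lie inside the stationarity triangle.
#' @param osc_amp,osc_amp_sd Amplitude (seconds) of the respiratory-like
#'   sinusoid and its between-subject spread.
#' @param osc_freq_range Uniform bounds on oscillation frequency, in cycles
#'   per beat.
#' @param drug_var_scale,drug_var_scale_sd Multiplicative shrinkage of RR
#'   variability under autonomic blockade (dimensionless, in (0, 1]).
#' @param drug_mean_shift,drug_mean_shift_sd Additive RR shift under drug
#'   (seconds).
#' @param aging_mean_drift,aging_mean_drift_sd Linear drift of the mean RR
#'   per month of age beyond the 6-month baseline (seconds/month).
#' @param aging_var_drift,aging_var_drift_sd Fractional growth of RR
#'   variability per month beyond baseline (1/month).
#' @return A list of class `"signature_hyper"`.
#' @seealso [cohort_preset()] for ready-made separability regimes.
#' @export
signature_hyper <- function(mean_rr = 0.132, mean_rr_sd = 0.012,
                            sd_rr = 0.010, sd_rr_sd = 0.003,
                            ar1_range = c(0.15, 0.6),
                            ar2_range = c(-0.3, 0.2),
                            osc_amp = 0.004, osc_amp_sd = 0.0015,
                            osc_freq_range = c(0.05, 0.2),
                            drug_var_scale = 0.4, drug_var_scale_sd = 0.1,
                            drug_mean_shift = 0.005, drug_mean_shift_sd = 0.003,
                            aging_mean_drift = 5e-4, aging_mean_drift_sd = 2e-4,
                            aging_var_drift = 0.01, aging_var_drift_sd = 0.005) {
  hyper <- list(
    mean_rr = mean_rr, mean_rr_sd = mean_rr_sd,
    sd_rr = sd_rr, sd_rr_sd = sd_rr_sd,
    ar1_range = ar1_range, ar2_range = ar2_range,
    osc_amp = osc_amp, osc_amp_sd = osc_amp_sd,
    osc_freq_range = osc_freq_range,
    drug_var_scale = drug_var_scale, drug_var_scale_sd = drug_var_scale_sd,
    drug_mean_shift = drug_mean_shift, drug_mean_shift_sd = drug_mean_shift_sd,
    aging_mean_drift = aging_mean_drift,
    aging_mean_drift_sd = aging_mean_drift_sd,
    aging_var_drift = aging_var_drift, aging_var_drift_sd = aging_var_drift_sd
  )
  abort_if(hyper$mean_rr <= 0, "mean_rr hyperparameter must be positive")
  abort_if(hyper$sd_rr < 0, "sd_rr hyperparameter must be non-negative")
  structure(hyper, class = "signature_hyper")
}

#' Cohort presets with known separability
#'
#' `"default"` mimics a realistic mixed cohort. `"high_separability"` widens
#' the between-subject spread of every signature field while shrinking
#' within-subject noise, so that a working verifier must reach a low equal
#' error rate on it. `"degenerate"` collapses all distributions to a point:
#' every subject has the identical signature and no verifier can beat
#' chance (EER 0.5).
#'
#' @param name One of `"default"`, `"high_separability"`, `"degenerate"`.
#' @return A `"signature_hyper"` object.
#' @export
cohort_preset <- function(name = c("default", "high_separability",
                                   "degenerate")) {
  name <- match.arg(name)
  switch(name,
    default = signature_hyper(),
    high_separability = signature_hyper(
      mean_rr_sd = 0.025, sd_rr = 0.006, sd_rr_sd = 0.004,
      ar1_range = c(0.0, 0.8), ar2_range = c(-0.45, 0.25),
      osc_amp = 0.005, osc_amp_sd = 0.003, osc_freq_range = c(0.03, 0.3)
    ),
    degenerate = signature_hyper(
      mean_rr_sd = 0, sd_rr_sd = 0,
      ar1_range = c(0.4, 0.4), ar2_range = c(-0.1, -0.1),
      # no oscillation: its per-segment phase would persist across a
      # subject's windows and act as a subject signature on its own
      osc_amp = 0, osc_amp_sd = 0, osc_freq_range = c(0.1, 0.1),
      drug_var_scale_sd = 0, drug_mean_shift_sd = 0,
      aging_mean_drift_sd = 0, aging_var_drift_sd = 0
    )
  )
}

ar2_stationary <- function(phi1, phi2) {
  # stationarity triangle for AR(2)
  (phi2 > -1) && (phi2 < 1) && (phi1 + phi2 < 1) && (phi2 - phi1 < 1)
}

#' Draw one subject signature
#'
#' Samples a per-subject biometric signature from the cohort distributions.
#' Draws whose AR coefficients fall outside the stationarity triangle are
#' rejected and redrawn a bounded number of times.
#'
#' @param hyper A [signature_hyper()] object.
#' @param subject_id Identifier attached to the signature.
#' @param seed Optional integer seed for a self-contained draw.
#' @param max_tries Redraw budget for the stationarity rejection step.
#' @return A list of class `"subject_signature"`.
#' @export
draw_signature <- function(hyper = signature_hyper(), subject_id = "S1",
                           seed = NULL, max_tries = 100L) {
  stopifnot(inherits(hyper, "signature_hyper"))
  with_seed_if(seed, {
    for (try in seq_len(max_tries)) {
      phi1 <- stats::runif(1, hyper$ar1_range[1], hyper$ar1_range[2])
      phi2 <- stats::runif(1, hyper$ar2_range[1], hyper$ar2_range[2])
      mean_rr <- stats::rnorm(1, hyper$mean_rr, hyper$mean_rr_sd)
      sd_rr <- abs(stats::rnorm(1, hyper$sd_rr, hyper$sd_rr_sd))
      osc_amp <- abs(stats::rnorm(1, hyper$osc_amp, hyper$osc_amp_sd))
      osc_freq <- stats::runif(1, hyper$osc_freq_range[1],
                               hyper$osc_freq_range[2])
      dvs <- stats::rnorm(1, hyper$drug_var_scale, hyper$drug_var_scale_sd)
      dvs <- min(max(dvs, 1e-3), 1)
      dms <- stats::rnorm(1, hyper$drug_mean_shift, hyper$drug_mean_shift_sd)
      amd <- stats::rnorm(1, hyper$aging_mean_drift, hyper$aging_mean_drift_sd)
      avd <- stats::rnorm(1, hyper$aging_var_drift, hyper$aging_var_drift_sd)
      if (ar2_stationary(phi1, phi2) && mean_rr > 0) {
        return(structure(list(
          subject_id = subject_id, mean_rr = mean_rr, sd_rr = sd_rr,
          ar_coeffs = c(phi1, phi2), osc_amp = osc_amp, osc_freq = osc_freq,
          drug_var_scale = dvs, drug_mean_shift = dms,
          aging_mean_drift = amd, aging_var_drift = avd
        ), class = "subject_signature"))
      }
    }
    stop("could not draw a stationary signature within ", max_tries,
         " tries; check AR coefficient ranges", call. = FALSE)
  })
}

#' @export
print.subject_signature <- function(x, ...) {
  cat(sprintf(
    "<subject_signature %s> mean RR %.4f s, SD %.4f s, AR(%.2f, %.2f)\n",
    x$subject_id, x$mean_rr, x$sd_rr, x$ar_coeffs[1], x$ar_coeffs[2]))
  invisible(x)
}

# Innovation SD giving a stationary AR(2) process the target SD.
ar2_innovation_sd <- function(target_sd, phi1, phi2) {
  if (target_sd == 0) return(0)
  v <- (1 + phi2) * ((1 - phi2)^2 - phi1^2) / (1 - phi2)
  abort_if(v <= 0, "AR coefficients do not define a stationary process")
  target_sd * sqrt(v)
}

REFERENCE_AGE_MONTHS <- 6

#' Simulate one RR segment for a subject
#'
#' Generates beat-to-beat intervals for one (subject, age, condition) cell.
#' The generating mean is the signature baseline plus linear aging drift
#' (relative to the 6-month reference) plus, under `"drug"`, the subject's
#' mean shift. The generating SD is the signature SD scaled by the aging
#' variance drift and, under `"drug"`, shrunk by the subject's
#' `drug_var_scale` (autonomic blockade suppresses variability). Beats are
#' generated until their cumulative duration reaches `duration`.
#' Out-of-range artifacts are injected at `artifact_rate` as uniform draws
#' from \[0.26, 0.40\] s or \[0.01, 0.045\] s, so they always violate the
#' 0.05–0.24 s physiological filter.
#'
#' @param sig A [draw_signature()] result.
#' @param age_months Age in months.
#' @param condition `"basal"` or `"drug"`.
#' @param duration Segment duration in seconds (> 0).
#' @param artifact_rate Fraction of beats replaced by artifacts, in \[0, 1).
#' @param seed Optional integer seed.
#' @return An [rr_series()] object.
#' @export
simulate_rr_segment <- function(sig, age_months, condition = c("basal", "drug"),
                                duration, artifact_rate = 0, seed = NULL) {
  stopifnot(inherits(sig, "subject_signature"))
  condition <- match.arg(condition)
  abort_if(!is_scalar_number(duration) || duration <= 0,
           "duration must be a positive number of seconds")
  abort_if(artifact_rate < 0 || artifact_rate >= 1,
           "artifact_rate must lie in [0, 1)")
  months_past <- age_months - REFERENCE_AGE_MONTHS
  mu <- sig$mean_rr + sig$aging_mean_drift * months_past
  sd_eff <- sig$sd_rr * max(0, 1 + sig$aging_var_drift * months_past)
  if (condition == "drug") {
    mu <- mu + sig$drug_mean_shift
    sd_eff <- sd_eff * sig$drug_var_scale
  }
  abort_if(mu <= 0, "age/drug-adjusted mean RR is non-positive")
  abort_if(duration < 2 * mu,
           "duration too short to hold at least two beats at this mean RR")

  with_seed_if(seed, {
    phi1 <- sig$ar_coeffs[1]; phi2 <- sig$ar_coeffs[2]
    eps_sd <- ar2_innovation_sd(sd_eff, phi1, phi2)
    phase <- stats::runif(1, 0, 2 * pi)
    n_guess <- max(4L, ceiling(duration / mu * 1.2) + 8L)
    x <- numeric(0)
    x1 <- 0; x2 <- 0
    repeat {
      innov <- if (eps_sd > 0) stats::rnorm(n_guess, 0, eps_sd) else
        numeric(n_guess)
      chunk <- numeric(n_guess)
      for (i in seq_len(n_guess)) {
        xi <- phi1 * x1 + phi2 * x2 + innov[i]
        chunk[i] <- xi
        x2 <- x1; x1 <- xi
      }
      x <- c(x, chunk)
      idx <- seq_along(x)
      rr <- mu + x + sig$osc_amp * sin(2 * pi * sig$osc_freq * idx + phase)
      rr <- pmax(rr, 0.005)  # physiological floor, guards rare deep excursions
      cum <- cumsum(rr)
      if (cum[length(cum)] >= duration) {
        n_keep <- which(cum >= duration)[1]
        rr <- rr[seq_len(n_keep)]
        break
      }
      n_guess <- max(4L, ceiling((duration - cum[length(cum)]) / mu * 1.2) + 8L)
    }
    if (artifact_rate > 0) {
      hit <- stats::runif(length(rr)) < artifact_rate
      n_hit <- sum(hit)
      if (n_hit > 0) {
        high <- stats::runif(n_hit) < 0.5
        art <- ifelse(high,
                      stats::runif(n_hit, 0.26, 0.40),
                      stats::runif(n_hit, 0.01, 0.045))
        rr[hit] <- art
      }
    }
    rr_series(rr, subject_id = sig$subject_id, condition = condition,
              age_months = age_months)
  })
}

#' Cohort specification
#'
#' Defaults mirror a longitudinal anesthetized-mouse study design: 30
#' subjects recorded from 6 to 24 months at 3-month intervals, 10 min under
#' basal conditions and 40 min after autonomic blockade per visit.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param ages_months Ages at which each subject is recorded.
#' @param conditions Subset of `c("basal", "drug")`.
#' @param segment_duration Seconds of recording per condition; either one
#'   number for all conditions or a named vector like
#'   `c(basal = 600, drug = 2400)`.
#' @param artifact_rate Fraction of beats replaced by out-of-range values.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param hyper A [signature_hyper()] object.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 30, ages_months = seq(6, 24, by = 3),
                        conditions = c("basal", "drug"),
                        segment_duration = c(basal = 600, drug = 2400),
                        artifact_rate = 0.01, seed = 1,
                        hyper = signature_hyper()) {
  abort_if(!is_count(n_subjects, 2L), "n_subjects must be a count >= 2")
  abort_if(length(ages_months) == 0, "ages_months must be non-empty")
  conditions <- match.arg(conditions, c("basal", "drug"), several.ok = TRUE)
  abort_if(length(conditions) == 0, "conditions must be non-empty")
  abort_if(any(segment_duration <= 0), "segment_duration must be positive")
  abort_if(artifact_rate < 0 || artifact_rate >= 1,
           "artifact_rate must lie in [0, 1)")
  if (is.null(names(segment_duration))) {
    segment_duration <- stats::setNames(
      rep(segment_duration[1], length(conditions)), conditions)
  }
  abort_if(!all(conditions %in% names(segment_duration)),
           "segment_duration must name every condition")
  structure(list(
    n_subjects = as.integer(n_subjects),
    ages_months = sort(unique(ages_months)),
    conditions = conditions,
    segment_duration = segment_duration,
    artifact_rate = artifact_rate,
    seed = as.integer(seed),
    hyper = hyper
  ), class = "cohort_spec")
}

#' Simulate a full cohort
#'
#' Draws one signature per subject, then one RR segment per
#' (subject, age, condition) cell. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `"rr_cohort"` with elements `signatures` (list),
#'   `series` (list of [rr_series()]) and `manifest` (a tibble with one row
#'   per series: `subject_id`, `age_months`, `condition`, `series_index`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    ids <- sprintf("M%02d", seq_len(spec$n_subjects))
    sigs <- lapply(ids, function(id) draw_signature(spec$hyper, id))
    names(sigs) <- ids
    series <- list()
    rows <- list()
    k <- 0L
    for (id in ids) {
      for (age in spec$ages_months) {
        for (cond in spec$conditions) {
          k <- k + 1L
          series[[k]] <- simulate_rr_segment(
            sigs[[id]], age_months = age, condition = cond,
            duration = spec$segment_duration[[cond]],
            artifact_rate = spec$artifact_rate)
          rows[[k]] <- tibble::tibble(
            subject_id = id, age_months = age, condition = cond,
            series_index = k)
        }
      }
    }
    structure(list(
      signatures = sigs,
      series = series,
      manifest = dplyr::bind_rows(rows),
      spec = spec
    ), class = "rr_cohort")
  })
}

#' @export
print.rr_cohort <- function(x, ...) {
  cat(sprintf("<rr_cohort> %d subjects, %d series (ages: %s; conditions: %s)\n",
              x$spec$n_subjects, length(x$series),
              paste(x$spec$ages_months, collapse = ", "),
              paste(x$spec$conditions, collapse = ", ")))
  invisible(x)
}

#' Write a cohort to plain-text RR files plus a manifest CSV
#'
#' Each segment becomes one text file with `#`-prefixed header comments and
#' one interval (seconds) per line; `manifest.csv` lists
#' `subject_id, age_months, condition, file_path`.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble with absolute `file_path`s.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  paths <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    s <- cohort$series[[man$series_index[i]]]
    fname <- sprintf("%s_age%02d_%s.rr.txt", man$subject_id[i],
                     man$age_months[i], man$condition[i])
    path <- file.path(dir, fname)
    con <- file(path, "w")
    writeLines(c(
      sprintf("# subject_id: %s", s$subject_id),
      sprintf("# condition: %s", s$condition),
      sprintf("# age_months: %s", s$age_months),
      "# units: seconds, one RR interval per line",
      format(s$intervals, digits = 17, scientific = FALSE, trim = TRUE)
    ), con)
    close(con)
    paths[i] <- path
  }
  out <- tibble::tibble(subject_id = man$subject_id,
                        age_months = man$age_months,
                        condition = man$condition,
                        file_path = paths)
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}
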