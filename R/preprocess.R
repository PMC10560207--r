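# Preprocessing: RR derivation, range-based artifact filtering with linear
# interpolation, drug-transient exclusion, and non-overlapping windowing.

DEFAULT_FILTER_LO <- 0.05
DEFAULT_FILTER_HI <- 0.24
DEFAULT_DRUG_EXCLUSION_S <- 120

#' RR interval series
#'
#' Container for the beat-to-beat intervals of one subject under one
#' condition at one age. `times` holds the beat timestamps (the series
#' origin plus the cumulative intervals), so `diff(times)` always equals
#' `intervals` exactly.
#'
#' @param intervals Positive RR intervals in seconds.
#' @param subject_id Subject identifier.
#' @param condition `"basal"` or `"drug"`.
#' @param age_months Age in months.
#' @param origin Timestamp of the first beat (seconds).
#' @return A list of class `"rr_series"`.
#' @export
rr_series <- function(intervals, subject_id = NA_character_,
                      condition = c("basal", "drug"), age_months = NA_real_,
                      origin = 0) {
  condition <- match.arg(condition)
  intervals <- as.numeric(intervals)
  abort_if(length(intervals) < 1, "need at least one RR interval")
  abort_if(any(!is.finite(intervals)) || any(intervals <= 0),
           "all RR intervals must be finite and positive")
  structure(list(
    subject_id = subject_id, condition = condition, age_months = age_months,
    origin = origin,
    times = origin + c(0, cumsum(intervals)),
    intervals = intervals
  ), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series %s/%s age %s> %d intervals, mean RR %.4f s, span %.1f s\n",
    x$subject_id, x$condition, format(x$age_months), length(x$intervals),
    mean(x$intervals), sum(x$intervals)))
  invisible(x)
}

replace_intervals <- function(series, intervals) {
  rr_series(intervals, subject_id = series$subject_id,
            condition = series$condition, age_months = series$age_months,
            origin = series$origin)
}

#' Derive RR intervals from R-peak times
#'
#' `RR(t_i) = t_{i+1} - t_i` for strictly increasing peak timestamps.
#'
#' @param peak_times Strictly increasing beat timestamps in seconds (>= 2).
#' @inheritParams rr_series
#' @return An [rr_series()] whose origin is the first peak time.
#' @export
rr_from_peaks <- function(peak_times, subject_id = NA_character_,
                          condition = "basal", age_months = NA_real_) {
  peak_times <- as.numeric(peak_times)
  abort_if(length(peak_times) < 2, "need at least two peak times")
  d <- diff(peak_times)
  abort_if(any(d <= 0), "peak times must be strictly increasing")
  rr_series(d, subject_id = subject_id, condition = condition,
            age_months = age_months, origin = peak_times[1])
}

#' Range-based artifact filter
#'
#' Intervals outside `[lo, hi]` (bounds inclusive: a value exactly at a
#' bound is physiological) are treated as artifacts and replaced by linear
#' interpolation, in beat index, between the nearest in-range neighbours.
#' Runs of artifacts at either end, which have an in-range neighbour on one
#' side only, are filled flat with that neighbour's value. Output length
#' equals input length and the filter is idempotent.
#'
#' @param x An [rr_series()] or a numeric interval vector.
#' @param lo,hi Filter bounds in seconds; defaults 0.05 and 0.24 s
#'   (1200 and 250 bpm).
#' @return Filtered object of the same type as `x`.
#' @export
range_filter <- function(x, lo = DEFAULT_FILTER_LO, hi = DEFAULT_FILTER_HI) {
  UseMethod("range_filter")
}

#' @export
range_filter.numeric <- function(x, lo = DEFAULT_FILTER_LO,
                                 hi = DEFAULT_FILTER_HI) {
  abort_if(!(lo > 0 && hi > lo), "filter range requires 0 < lo < hi")
  ok <- x >= lo & x <= hi
  abort_if(sum(ok) < 2,
           "unusable series: fewer than two in-range intervals")
  if (all(ok)) return(x)
  idx <- seq_along(x)
  out <- x
  # rule = 2: flat extrapolation from the nearest in-range value at edges
  out[!ok] <- stats::approx(idx[ok], x[ok], xout = idx[!ok],
                            method = "linear", rule = 2)$y
  out
}

#' @export
range_filter.rr_series <- function(x, lo = DEFAULT_FILTER_LO,
                                   hi = DEFAULT_FILTER_HI) {
  replace_intervals(x, range_filter(x$intervals, lo = lo, hi = hi))
}

#' Drop the transient at the start of a segment
#'
#' Removes every interval whose onset (cumulative RR time from the segment
#' start) is earlier than `exclusion` seconds. Used to discard the first
#' 2 min of drug segments, where the response to the injection is still
#' settling.
#'
#' @param series An [rr_series()].
#' @param exclusion Seconds to drop from the start (>= 0).
#' @return The trimmed [rr_series()]; `exclusion = 0` is the identity.
#' @export
drop_transient <- function(series, exclusion = DEFAULT_DRUG_EXCLUSION_S) {
  stopifnot(inherits(series, "rr_series"))
  abort_if(exclusion < 0, "exclusion must be non-negative")
  if (exclusion == 0) return(series)
  onset <- c(0, cumsum(series$intervals))[seq_along(series$intervals)]
  keep <- onset >= exclusion
  abort_if(!any(keep), "unusable series: exclusion removes every interval")
  replace_intervals(series, series$intervals[keep])
}

#' Cut a series into non-overlapping fixed-length heartbeat windows
#'
#' Consecutive disjoint blocks of `n_beats` intervals, in temporal order;
#' a trailing remainder shorter than `n_beats` is discarded. A series
#' shorter than one window yields zero rows.
#'
#' @param series An [rr_series()].
#' @param n_beats Window length in beats (>= 2).
#' @return A tibble with one row per window: `subject_id`, `condition`,
#'   `age_months`, `window_index` (0-based), `n_beats`, and the list-column
#'   `intervals`.
#' @export
segment_windows <- function(series, n_beats) {
  stopifnot(inherits(series, "rr_series"))
  abort_if(!is_count(n_beats, 2L), "n_beats must be a count >= 2")
  n <- length(series$intervals) %/% n_beats
  if (n == 0) {
    return(tibble::tibble(
      subject_id = character(), condition = character(),
      age_months = numeric(), window_index = integer(),
      n_beats = integer(), intervals = list()))
  }
  blocks <- lapply(seq_len(n) - 1L, function(i) {
    series$intervals[(i * n_beats + 1L):((i + 1L) * n_beats)]
  })
  tibble::tibble(
    subject_id = series$subject_id,
    condition = series$condition,
    age_months = series$age_months,
    window_index = seq_len(n) - 1L,
    n_beats = as.integer(n_beats),
    intervals = blocks
  )
}

#' Preprocess one series into heartbeat windows
#'
#' Applies the standard chain: transient exclusion (drug segments only, by
#' default the first 120 s), range filtering with interpolation, then
#' non-overlapping windowing.
#'
#' @param series An [rr_series()].
#' @param n_beats Window length in beats.
#' @param lo,hi Filter bounds in seconds.
#' @param drug_exclusion Seconds excluded from the start of drug segments.
#' @return A window tibble as from [segment_windows()].
#' @export
preprocess_series <- function(series, n_beats, lo = DEFAULT_FILTER_LO,
                              hi = DEFAULT_FILTER_HI,
                              drug_exclusion = DEFAULT_DRUG_EXCLUSION_S) {
  if (identical(series$condition, "drug") && drug_exclusion > 0) {
    series <- drop_transient(series, drug_exclusion)
  }
  series <- range_filter(series, lo = lo, hi = hi)
  segment_windows(series, n_beats)
}

#' Preprocess a whole cohort into one window table
#'
#' @param cohort An [simulate_cohort()] result, or a list of [rr_series()].
#' @inheritParams preprocess_series
#' @return One tibble of windows across all series.
#' @export
preprocess_cohort <- function(cohort, n_beats, lo = DEFAULT_FILTER_LO,
                              hi = DEFAULT_FILTER_HI,
                              drug_exclusion = DEFAULT_DRUG_EXCLUSION_S) {
  series <- if (inherits(cohort, "rr_cohort")) cohort$series else cohort
  abort_if(length(series) == 0, "no series to preprocess")
  dplyr::bind_rows(lapply(series, preprocess_series, n_beats = n_beats,
                          lo = lo, hi = hi, drug_exclusion = drug_exclusion))
}

#' Read a plain-text RR file
#'
#' One interval in seconds per line; lines starting with `#` are comments.
#' Metadata (`subject_id`, `condition`, `age_months`) is recovered from
#' `# key: value` header comments when present, and can be overridden.
#'
#' @param path File path.
#' @param subject_id,condition,age_months Optional metadata overrides.
#' @return An [rr_series()].
#' @export
read_rr_file <- function(path, subject_id = NULL, condition = NULL,
                         age_months = NULL) {
  lines <- readLines(path)
  is_comment <- startsWith(trimws(lines), "#")
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  vals <- as.numeric(lines[!is_comment & nzchar(trimws(lines))])
  abort_if(any(is.na(vals)), paste0("non-numeric RR value in ", path))
  rr_series(
    vals,
    subject_id = subject_id %||% meta$subject_id %||% NA_character_,
    condition = condition %||% meta$condition %||% "basal",
    age_months = age_months %||%
      (if (is.null(meta$age_months)) NA_real_ else as.numeric(meta$age_months))
  )
}

#' Read a peak-time text file into an RR series
#'
#' One R-peak timestamp (seconds) per line, `#` comments allowed.
#'
#' @inheritParams read_rr_file
#' @return An [rr_series()] via [rr_from_peaks()].
#' @export
read_peaks_file <- function(path, subject_id = NA_character_,
                            condition = "basal", age_months = NA_real_) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  vals <- as.numeric(lines[keep])
  abort_if(any(is.na(vals)), paste0("non-numeric peak time in ", path))
  rr_from_peaks(vals, subject_id = subject_id, condition = condition,
                age_months = age_months)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param manifest Path to a manifest CSV
#'   (`subject_id, age_months, condition, file_path`) or to a directory
#'   containing `manifest.csv`.
#' @return A list of [rr_series()].
#' @export
read_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("subject_id", "age_months", "condition", "file_path")
  abort_if(!all(needed %in% names(man)),
           "manifest must have columns subject_id, age_months, condition, file_path")
  base <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$file_path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    read_rr_file(p, subject_id = man$subject_id[i],
                 condition = man$condition[i],
                 age_months = man$age_months[i])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
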