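# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state when `seed` is given; otherwise use
# the session RNG as-is (so callers can manage reproducibility themselves).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

#' Convert an RR interval to heart rate
#'
#' @param rr_seconds RR interval(s) in seconds.
#' @return Heart rate(s) in beats per minute.
#' @examples
#' rr_to_bpm(0.24) # 250 bpm
#' @export
rr_to_bpm <- function(rr_seconds) {
  abort_if(any(rr_seconds <= 0), "RR intervals must be positive")
  60 / rr_seconds
}
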