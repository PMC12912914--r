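# Internal helpers shared across modules.

clip01 <- function(x) pmin(1, pmax(0, x))

stop_invalid <- function(msg) abort(msg, class = "avstraj_invalid_input")
stop_undefined <- function(msg) abort(msg, class = "avstraj_undefined_metric")
stop_degenerate <- function(msg) abort(msg, class = "avstraj_degenerate_model")
stop_convergence <- function(msg) abort(msg, class = "avstraj_convergence")

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `estimate`, `conf.low`, `conf.high`.
#' @examples
#' wilson_ci(12, 16)
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  if (any(n <= 0)) stop_invalid("`n` must be positive.")
  if (any(x < 0 | x > n)) stop_invalid("`x` must lie in [0, n].")
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(
    estimate = p,
    conf.low = pmax(0, centre - half),
    conf.high = pmin(1, centre + half)
  )
}

# Validate a long score table and return it with canonical column names.
validate_scores <- function(scores) {
  need <- c("subject_id", "years_before", "score")
  if (!all(need %in% names(scores))) {
    stop_invalid(paste0(
      "`scores` must contain columns: ", paste(need, collapse = ", "), "."
    ))
  }
  if (nrow(scores) == 0) stop_invalid("`scores` has no rows.")
  if (any(!is.finite(scores$score)) || any(scores$score < 0 | scores$score > 1)) {
    stop_invalid("scores must be finite and in [0, 1].")
  }
  if (any(scores$years_before < 0)) {
    stop_invalid("`years_before` must be nonnegative (0 = procedure date).")
  }
  as_tibble(scores)
}
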