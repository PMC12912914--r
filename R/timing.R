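#' Mean time before the procedure at which a score threshold is first
#' exceeded
#'
#' Among subjects with at least `min_obs` observations, finds for each
#' subject the chronologically earliest observation (largest
#' years-before-procedure value) with score strictly above `threshold`,
#' and averages those first-detection times over the subjects with any
#' detection. The 95% CI is the normal approximation
#' `mean +/- 1.96 * SE`. Subjects who never cross contribute to
#' `n_eligible` but not to the mean.
#'
#' @param scores Long score table (`subject_id`, `years_before`, `score`).
#' @param threshold Score threshold in (0, 1).
#' @param min_obs Minimum number of observations for eligibility
#'   (default 5).
#' @return One-row tibble: `threshold`, `n_eligible`, `n_crossed`,
#'   `mean_years_before`, `conf.low`, `conf.high`.
#' @export
first_crossing <- function(scores, threshold, min_obs = 5) {
  if (threshold <= 0 || threshold >= 1) {
    stop_invalid("`threshold` must be in (0, 1).")
  }
  scores <- validate_scores(scores)
  per <- scores |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      first_cross = if (any(.data$score > threshold))
        max(.data$years_before[.data$score > threshold]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_obs >= min_obs)
  if (nrow(per) == 0) stop_undefined("no eligible subjects.")
  crossed <- per$first_cross[!is.na(per$first_cross)]
  m <- if (length(crossed) > 0) mean(crossed) else NA_real_
  se <- if (length(crossed) > 1) sd(crossed) / sqrt(length(crossed)) else NA_real_
  tibble(
    threshold = threshold,
    n_eligible = nrow(per),
    n_crossed = length(crossed),
    mean_years_before = m,
    conf.low = m - 1.96 * se,
    conf.high = m + 1.96 * se
  )
}

#' Proportion of subjects above a score threshold at a fixed time before
#' the procedure
#'
#' For each subject, selects the observation nearest to `at_years_before`
#' within `+/- window` years (ties broken toward the more recent, i.e.
#' smaller years-before, observation) and reports the proportion of the
#' contributing subjects whose selected score exceeds the threshold.
#'
#' @inheritParams first_crossing
#' @param at_years_before Evaluation time in years before the procedure.
#' @param window Half-width of the selection window in years
#'   (default 0.5).
#' @return One-row tibble: `threshold`, `at_years_before`,
#'   `n_contributing`, `proportion`.
#' @export
proportion_above <- function(scores, threshold, at_years_before,
                             window = 0.5) {
  if (at_years_before < 0 || at_years_before > 10) {
    stop_invalid("`at_years_before` must be in [0, 10].")
  }
  scores <- validate_scores(scores)
  sel <- scores |>
    dplyr::filter(abs(.data$years_before - at_years_before) <= window) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(abs(.data$years_before - at_years_before),
                   .data$years_before, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  if (nrow(sel) == 0) stop_undefined("no subject contributes an observation.")
  tibble(
    threshold = threshold,
    at_years_before = at_years_before,
    n_contributing = nrow(sel),
    proportion = mean(sel$score > threshold)
  )
}
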