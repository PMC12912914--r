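#' Area under the ROC curve for a continuous score
#'
#' Computes the rank-based (Mann–Whitney) AUROC: the probability that a
#' randomly chosen case scores higher than a randomly chosen non-case, with
#' ties counted one half. The confidence interval comes from a
#' case–control-stratified bootstrap (cases and non-cases resampled
#' separately) with percentile bounds.
#'
#' @param data A data frame of subjects.
#' @param score,truth Column names (unquoted) holding the continuous score
#'   and the binary case indicator (logical or 0/1).
#' @param ci Compute a bootstrap confidence interval? (default TRUE)
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble: `auroc`, `conf.low`, `conf.high`, `n_case`,
#'   `n_control`.
#' @export
auroc <- function(data, score, truth, ci = TRUE, n_boot = 2000,
                  level = 0.95, seed = 1) {
  s <- dplyr::pull(data, {{ score }})
  y <- as.integer(as.logical(dplyr::pull(data, {{ truth }})))
  est <- auroc_stat(s, y)
  out <- tibble(auroc = est, conf.low = NA_real_, conf.high = NA_real_,
                n_case = sum(y == 1), n_control = sum(y == 0))
  if (ci) {
    set.seed(seed)
    i_case <- which(y == 1)
    i_ctrl <- which(y == 0)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- c(
        i_case[sample.int(length(i_case), length(i_case), replace = TRUE)],
        i_ctrl[sample.int(length(i_ctrl), length(i_ctrl), replace = TRUE)]
      )
      auroc_stat(s[idx], y[idx])
    }, numeric(1))
    alpha <- (1 - level) / 2
    out$conf.low <- unname(quantile(boots, alpha))
    out$conf.high <- unname(quantile(boots, 1 - alpha))
  }
  out
}

# Mann-Whitney AUROC via midranks; ties counted 1/2.
auroc_stat <- function(s, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_undefined("AUROC needs both cases and non-cases.")
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal cutpoint for a continuous score
#'
#' Scans all observed score values as candidate thresholds under the rule
#' "score >= cutpoint is positive" and returns the one maximising Youden's
#' J = sensitivity + specificity - 1. Ties in J are broken toward the
#' larger cutpoint (fewer screen positives).
#'
#' @inheritParams auroc
#' @return A one-row tibble: `cutpoint`, `youden_j`, and the confusion
#'   summary columns of [confusion_summary()] at that cutpoint.
#' @export
youden_cutpoint <- function(data, score, truth) {
  s <- dplyr::pull(data, {{ score }})
  y <- as.integer(as.logical(dplyr::pull(data, {{ truth }})))
  if (length(unique(y)) < 2) {
    stop_undefined("Youden cutpoint needs both cases and non-cases.")
  }
  cand <- sort(unique(s))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  # At threshold c: positives are scores >= c.
  j <- vapply(cand, function(cut) {
    pos <- s >= cut
    sum(pos & y == 1) / n1 + sum(!pos & y == 0) / n0 - 1
  }, numeric(1))
  best <- max(j)
  cut <- max(cand[j >= best - 1e-12])  # ties -> larger cutpoint
  cs <- confusion_summary_vec(s, y, cut)
  dplyr::bind_cols(tibble(cutpoint = cut, youden_j = best), cs)
}

#' Confusion-matrix summary at a fixed cutpoint
#'
#' Counts TP/FP/TN/FN under "score >= cutpoint is positive" and reports
#' sensitivity, specificity, PPV and NPV with Wilson 95% intervals.
#'
#' @inheritParams auroc
#' @param cutpoint Threshold on the score scale.
#' @return A one-row tibble.
#' @export
confusion_summary <- function(data, score, truth, cutpoint) {
  s <- dplyr::pull(data, {{ score }})
  y <- as.integer(as.logical(dplyr::pull(data, {{ truth }})))
  confusion_summary_vec(s, y, cutpoint)
}

confusion_summary_vec <- function(s, y, cutpoint) {
  pos <- s >= cutpoint
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  fn <- sum(!pos & y == 1); tn <- sum(!pos & y == 0)
  prop <- function(x, n) {
    if (n == 0) return(tibble(estimate = NA_real_, conf.low = NA_real_,
                              conf.high = NA_real_))
    wilson_ci(x, n)
  }
  ci_se <- prop(tp, tp + fn); ci_sp <- prop(tn, tn + fp)
  ci_ppv <- prop(tp, tp + fp); ci_npv <- prop(tn, tn + fn)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ci_se$estimate, sens.low = ci_se$conf.low,
    sens.high = ci_se$conf.high,
    specificity = ci_sp$estimate, spec.low = ci_sp$conf.low,
    spec.high = ci_sp$conf.high,
    ppv = ci_ppv$estimate, ppv.low = ci_ppv$conf.low,
    ppv.high = ci_ppv$conf.high,
    npv = ci_npv$estimate, npv.low = ci_npv$conf.low,
    npv.high = ci_npv$conf.high
  )
}

#' Project test performance to a different disease prevalence
#'
#' Applies Bayes' theorem to a test's sensitivity and specificity to obtain
#' the positive and negative predictive values and the positive screen rate
#' expected in a population with a given prevalence:
#' `PPV = se * p / (se * p + (1 - sp) * (1 - p))`,
#' `NPV = sp * (1 - p) / (sp * (1 - p) + (1 - se) * p)`,
#' `screen rate = se * p + (1 - sp) * (1 - p)`.
#'
#' @param sensitivity,specificity Test operating characteristics in (0, 1).
#' @param prevalence Prevalence(s) in (0, 1); vectorised.
#' @return A tibble with one row per prevalence: `prevalence`, `ppv`,
#'   `npv`, `positive_screen_rate`.
#' @examples
#' prevalence_adjusted(0.750, 0.764, c(0.01, 0.05))
#' @export
prevalence_adjusted <- function(sensitivity, specificity, prevalence) {
  ok01 <- function(x) all(is.finite(x)) && all(x >= 0 & x <= 1)
  if (!ok01(sensitivity) || !ok01(specificity)) {
    stop_invalid("sensitivity and specificity must lie in [0, 1].")
  }
  if (!all(is.finite(prevalence)) || any(prevalence <= 0 | prevalence >= 1)) {
    stop_invalid("prevalence must lie in (0, 1).")
  }
  se <- sensitivity; sp <- specificity; p <- prevalence
  tibble(
    prevalence = p,
    ppv = se * p / (se * p + (1 - sp) * (1 - p)),
    npv = sp * (1 - p) / (sp * (1 - p) + (1 - se) * p),
    positive_screen_rate = se * p + (1 - sp) * (1 - p)
  )
}

#' Classify screening results against echocardiographic truth
#'
#' Adds a `screen_class` column (TP/FP/TN/FN) under the rule
#' "score >= cutpoint is a positive screen", where a case is a subject with
#' moderate/severe AS (mild AS counts as a non-case).
#'
#' @param data A screening cohort tibble with `score` and `severity_class`
#'   columns (as produced by [simulate_screening_cohort()]).
#' @param cutpoint Score threshold in \[0, 1\].
#' @return `data` with `screen_class` added (factor TP/FP/TN/FN).
#' @export
classify_screen <- function(data, cutpoint) {
  if (cutpoint < 0 || cutpoint > 1) stop_invalid("`cutpoint` must be in [0, 1].")
  dplyr::mutate(
    as_tibble(data),
    screen_class = factor(
      dplyr::case_when(
        score >= cutpoint & severity_class == "moderate_severe" ~ "TP",
        score >= cutpoint ~ "FP",
        severity_class == "moderate_severe" ~ "FN",
        TRUE ~ "TN"
      ),
      levels = c("TP", "FP", "TN", "FN")
    )
  )
}

#' Prognosis of false-positive screens versus true negatives
#'
#' Among subjects without moderate/severe AS at baseline, contrasts the
#' hazard of a future outcome between false positives (score at or above
#' the cutpoint) and true negatives, by Cox proportional-hazards
#' regression, optionally adjusted for the PCP-HF risk score. Kaplan–Meier
#' fits per group are retained for plotting.
#'
#' @param data Screening cohort tibble (see [simulate_screening_cohort()]).
#' @param cutpoint Score threshold defining a positive screen.
#' @param outcome `"as_hosp"` (AS hospitalisation) or `"hf"`
#'   (incident heart failure).
#' @param adjusted Adjust for `pcp_hf`? (default FALSE)
#' @return An object of class `fp_prognosis`: list with `contrast` (tibble
#'   of HR, Wald CI, p), `fit` (the coxph object), `km` (survfit by group),
#'   `groups` (group sizes and event counts).
#' @export
fp_prognosis <- function(data, cutpoint,
                         outcome = c("as_hosp", "hf"), adjusted = FALSE) {
  outcome <- match.arg(outcome)
  d <- classify_screen(data, cutpoint)
  d <- dplyr::filter(d, .data$screen_class %in% c("FP", "TN"))
  d$fp <- as.integer(d$screen_class == "FP")
  tcol <- paste0("time_to_", outcome)
  ecol <- paste0(outcome, "_event")
  d$.time <- d[[tcol]]
  d$.event <- d[[ecol]]
  if (sum(d$fp == 1) == 0 || sum(d$fp == 0) == 0) {
    stop_degenerate("need non-empty false-positive and true-negative groups.")
  }
  if (sum(d$.event[d$fp == 1]) < 1 || sum(d$.event[d$fp == 0]) < 1) {
    stop_degenerate("need at least one event in each screening group.")
  }
  fml <- if (adjusted) Surv(.time, .event) ~ fp + pcp_hf else
    Surv(.time, .event) ~ fp
  fit <- coxph(fml, data = d, ties = "efron")
  sm <- summary(fit)
  contrast <- tibble(
    outcome = outcome,
    adjusted = adjusted,
    term = rownames(sm$coefficients),
    hazard_ratio = unname(sm$conf.int[, "exp(coef)"]),
    conf.low = unname(sm$conf.int[, 3]),
    conf.high = unname(sm$conf.int[, 4]),
    p.value = unname(sm$coefficients[, "Pr(>|z|)"])
  )
  km <- survfit(Surv(.time, .event) ~ fp, data = d)
  structure(
    list(
      contrast = contrast, fit = fit, km = km,
      groups = tibble(
        group = c("false_positive", "true_negative"),
        n = c(sum(d$fp == 1), sum(d$fp == 0)),
        events = c(sum(d$.event[d$fp == 1]), sum(d$.event[d$fp == 0]))
      )
    ),
    class = "fp_prognosis"
  )
}

#' @export
print.fp_prognosis <- function(x, ...) {
  row <- x$contrast[x$contrast$term == "fp", ]
  cat(sprintf(
    "<fp_prognosis> %s (%s): HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
    row$outcome, if (row$adjusted) "adjusted" else "unadjusted",
    row$hazard_ratio, row$conf.low, row$conf.high, row$p.value
  ))
  invisible(x)
}

#' @rdname fp_prognosis
#' @param x An `fp_prognosis` object.
#' @param ... Unused.
#' @method tidy fp_prognosis
#' @export
tidy.fp_prognosis <- function(x, ...) x$contrast
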