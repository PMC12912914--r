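#' Sequential Cox models for mortality by trajectory cluster
#'
#' Fits the ladder of proportional-hazards models relating trajectory
#' cluster membership to all-cause mortality: Model 1 is unadjusted;
#' Model 2 adds STS risk score, valve size, Agatston calcium score, and
#' valve type; Model 3 adds body-mass index and pre-existing pacemaker.
#' The reference cluster is `stable_low`. Ties are handled by Efron's
#' method.
#'
#' @param subjects One row per subject with `time_years`, `event`, a
#'   cluster column, and the model covariates.
#' @param models Which models to fit (subset of 1:3, default all).
#' @param cluster_col Name of the cluster factor column (default
#'   `"cluster_label"`).
#' @return An object of class `cox_ladder`: list of fits plus a tidy
#'   hazard-ratio table.
#' @export
fit_cox_ladder <- function(subjects, models = 1:3,
                           cluster_col = "cluster_label") {
  subjects <- as_tibble(subjects)
  if (!cluster_col %in% names(subjects)) {
    stop_invalid(sprintf("column `%s` not found.", cluster_col))
  }
  cl <- subjects[[cluster_col]]
  if (!is.factor(cl)) cl <- factor(cl)
  if ("stable_low" %in% levels(cl)) cl <- stats::relevel(cl, "stable_low")
  subjects$.cluster <- cl
  if (length(unique(cl)) < 2) stop_invalid("need at least 2 clusters present.")
  if (sum(subjects$event) < 10) stop_degenerate("fewer than 10 events.")

  covs <- list(
    `1` = character(0),
    `2` = c("sts_score", "valve_size", "agatston", "valve_type"),
    `3` = c("sts_score", "valve_size", "agatston", "valve_type", "bmi",
            "pacemaker")
  )
  fits <- lapply(models, function(m) {
    terms <- c(".cluster", covs[[as.character(m)]])
    missing_cols <- setdiff(setdiff(terms, ".cluster"), names(subjects))
    if (length(missing_cols) > 0) {
      stop_invalid(paste0("missing covariates: ",
                          paste(missing_cols, collapse = ", ")))
    }
    fml <- as.formula(paste("Surv(time_years, event) ~",
                            paste(terms, collapse = " + ")))
    fit <- tryCatch(
      coxph(fml, data = subjects, ties = "efron"),
      error = function(e) stop_degenerate(paste("Cox fit failed:",
                                                conditionMessage(e)))
    )
    fit
  })
  names(fits) <- paste0("model", models)
  hr <- purrr::imap(fits, function(f, nm) {
    sm <- summary(f)
    tibble(
      model = as.integer(sub("model", "", nm)),
      term = rownames(sm$coefficients),
      hazard_ratio = unname(sm$conf.int[, "exp(coef)"]),
      conf.low = unname(sm$conf.int[, 3]),
      conf.high = unname(sm$conf.int[, 4]),
      p.value = unname(sm$coefficients[, "Pr(>|z|)"])
    )
  }) |> dplyr::bind_rows()
  structure(list(fits = fits, hr_table = hr, cluster_col = cluster_col,
                 data = subjects),
            class = "cox_ladder")
}

#' @export
print.cox_ladder <- function(x, ...) {
  cat("<cox_ladder> cluster hazard ratios (reference = stable_low)\n")
  print(as.data.frame(
    dplyr::filter(x$hr_table, grepl("^\\.cluster", .data$term)) |>
      dplyr::mutate(term = sub("^\\.cluster", "", .data$term))
  ), digits = 3)
  invisible(x)
}

#' @rdname fit_cox_ladder
#' @param x A `cox_ladder` object.
#' @param ... Unused.
#' @method tidy cox_ladder
#' @export
tidy.cox_ladder <- function(x, ...) {
  dplyr::mutate(x$hr_table, term = sub("^\\.cluster", "cluster:", .data$term))
}

#' @rdname fit_cox_ladder
#' @method glance cox_ladder
#' @export
glance.cox_ladder <- function(x, ...) {
  purrr::imap(x$fits, function(f, nm) {
    tibble(model = as.integer(sub("model", "", nm)),
           n = f$n, n_event = f$nevent,
           concordance = unname(f$concordance["concordance"]))
  }) |> dplyr::bind_rows()
}

#' Harrell's concordance index for right-censored survival
#'
#' The proportion of usable subject pairs in which the subject with the
#' higher predicted risk fails first. A pair is usable when the earlier
#' time is an event (the other subject is then known to survive longer),
#' including the case of an event tied in time with a censoring. Ties in
#' the risk score count one half; event–event ties in time are not
#' usable pairs.
#'
#' @param data A data frame of subjects.
#' @param time,event,risk Columns (unquoted): follow-up time, 0/1 event
#'   indicator, and predicted risk (higher = worse).
#' @return A one-row tibble: `c_index`, `n_pairs` (usable pairs),
#'   `concordant`, `tied_risk`.
#' @export
harrell_c <- function(data, time, event, risk) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.integer(dplyr::pull(data, {{ event }}))
  r <- dplyr::pull(data, {{ risk }})
  harrell_c_vec(t, e, r)
}

harrell_c_vec <- function(t, e, r) {
  ev <- which(e == 1)
  if (length(ev) == 0) stop_undefined("no comparable pairs (no events).")
  conc <- 0; ties <- 0; pairs <- 0
  for (i in ev) {
    later <- t > t[i] | (t == t[i] & e == 0)
    pairs <- pairs + sum(later)
    conc <- conc + sum(r[i] > r[later])
    ties <- ties + sum(r[i] == r[later])
    # event-event pairs: count each once via the earlier event
  }
  # event pairs with equal times were never marked 'later' -> excluded
  if (pairs == 0) stop_undefined("no comparable pairs.")
  tibble(c_index = (conc + 0.5 * ties) / pairs,
         n_pairs = pairs, concordant = conc, tied_risk = ties)
}

#' Absolute mortality risk at a horizon from a fitted Cox model
#'
#' Converts a proportional-hazards fit into per-subject probabilities of
#' death by `horizon` years via the Breslow baseline cumulative hazard:
#' `1 - S0(horizon) ^ exp(lp)`.
#'
#' @param fit A `coxph` object (or a `cox_ladder`, whose chosen model is
#'   used).
#' @param horizon Horizon in years.
#' @param newdata Optional data frame of subjects to predict for
#'   (defaults to the model frame).
#' @param model For a `cox_ladder`, which model number to use (default 1).
#' @return A numeric vector of probabilities in \[0, 1\].
#' @export
predicted_mortality <- function(fit, horizon, newdata = NULL, model = 1) {
  if (inherits(fit, "cox_ladder")) {
    if (is.null(newdata)) newdata <- fit$data
    fit <- fit$fits[[paste0("model", model)]]
  }
  if (!inherits(fit, "coxph")) stop_invalid("`fit` must be a coxph or cox_ladder.")
  bh <- basehaz(fit, centered = TRUE)
  if (horizon > max(bh$time)) {
    warn(sprintf("horizon %.3g beyond last observed time %.3g; using the last.",
                 horizon, max(bh$time)))
  }
  idx <- findInterval(horizon, bh$time)
  h0 <- if (idx == 0) 0 else bh$hazard[idx]
  lp <- if (is.null(newdata)) predict(fit, type = "lp") else
    predict(fit, newdata = newdata, type = "lp")
  clip01(1 - exp(-h0 * exp(lp)))
}

# KM survival at a horizon for a subject subset (extends beyond last time).
km_event_prob <- function(time, event, horizon) {
  if (length(time) == 0) return(NA_real_)
  sf <- survfit(Surv(time, event) ~ 1)
  s <- summary(sf, times = horizon, extend = TRUE)$surv
  1 - s
}

#' Categorical net reclassification improvement for survival outcomes
#'
#' Cross-classifies subjects by predicted risk category under a base and
#' an augmented model and computes the categorical NRI at a horizon:
#' `NRI_events = P(up | event) - P(down | event)`,
#' `NRI_non-events = P(down | non-event) - P(up | non-event)`, and their
#' sum. Censoring before the horizon is handled by the Kaplan–Meier
#' method: within each cross-classification cell the event probability by
#' the horizon is estimated by 1 - KM, so under complete follow-up the
#' estimator reduces exactly to the count-based NRI.
#' `method = "complete_case"` instead drops subjects censored before the
#' horizon.
#'
#' @param data A data frame of subjects.
#' @param base,augmented Columns (unquoted) of predicted event
#'   probabilities at the horizon under the two models.
#' @param time,event Follow-up columns (unquoted).
#' @param horizon Horizon in years.
#' @param cutoffs Increasing category boundaries in (0, 1)
#'   (default `c(0.05, 0.075, 0.10)`).
#' @param method `"km"` (default) or `"complete_case"`.
#' @return A one-row tibble: `horizon`, `nri_events`, `nri_nonevents`,
#'   `nri_overall`, `p_event`, `n`.
#' @export
categorical_nri <- function(data, base, augmented, time, event, horizon,
                            cutoffs = c(0.05, 0.075, 0.10),
                            method = c("km", "complete_case")) {
  method <- match.arg(method)
  if (any(diff(cutoffs) <= 0) || any(cutoffs <= 0 | cutoffs >= 1)) {
    stop_invalid("`cutoffs` must be strictly increasing within (0, 1).")
  }
  pb <- dplyr::pull(data, {{ base }})
  pa <- dplyr::pull(data, {{ augmented }})
  t <- dplyr::pull(data, {{ time }})
  e <- as.integer(dplyr::pull(data, {{ event }}))
  if (length(pb) != length(pa) || length(pb) != length(t)) {
    stop_invalid("probability and outcome vectors must align.")
  }
  brks <- c(-Inf, cutoffs, Inf)
  cb <- cut(pb, brks, labels = FALSE)
  ca <- cut(pa, brks, labels = FALSE)
  move <- sign(ca - cb)  # +1 up, -1 down, 0 same

  if (method == "complete_case") {
    keep <- (t >= horizon) | (e == 1 & t <= horizon)
    t <- t[keep]; e <- e[keep]; move <- move[keep]
    ev <- e == 1 & t <= horizon
    if (sum(ev) == 0) stop_undefined("no events by the horizon.")
    p_event <- mean(ev)
    nri_e <- (mean(move[ev] == 1) - mean(move[ev] == -1))
    nri_ne <- (mean(move[!ev] == -1) - mean(move[!ev] == 1))
    n_used <- length(t)
  } else {
    n <- length(t)
    p_event <- km_event_prob(t, e, horizon)
    if (is.na(p_event) || p_event <= 0) {
      stop_undefined("no events by the horizon.")
    }
    cell_stat <- function(sel) {
      if (!any(sel)) return(c(ev = 0, ne = 0))
      p <- km_event_prob(t[sel], e[sel], horizon)
      if (is.na(p)) p <- 0
      c(ev = sum(sel) / n * p, ne = sum(sel) / n * (1 - p))
    }
    up <- cell_stat(move == 1)
    down <- cell_stat(move == -1)
    nri_e <- (up[["ev"]] - down[["ev"]]) / p_event
    nri_ne <- (down[["ne"]] - up[["ne"]]) / (1 - p_event)
    n_used <- n
  }
  tibble(
    horizon = horizon,
    nri_events = nri_e,
    nri_nonevents = nri_ne,
    nri_overall = nri_e + nri_ne,
    p_event = p_event,
    n = n_used
  )
}

#' Percentile bootstrap confidence interval for subject-level statistics
#'
#' Resamples rows (subjects) with replacement, applies `statistic`, and
#' returns percentile bounds. Deterministic given the seed. Errors if the
#' statistic fails on more than 10% of resamples.
#'
#' @param data A data frame (one row per subject).
#' @param statistic Function `data -> named numeric vector`.
#' @param n_boot Number of resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed (default 1).
#' @return Tibble `term`, `estimate`, `conf.low`, `conf.high`, `n_boot`,
#'   `n_failed`.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000, level = 0.95,
                         seed = 1) {
  est <- statistic(data)
  if (is.null(names(est))) names(est) <- paste0("stat", seq_along(est))
  set.seed(seed)
  n <- nrow(data)
  draws <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(val)) failed <- failed + 1L else draws[b, ] <- val[names(est)]
  }
  if (failed > 0.10 * n_boot) {
    stop_degenerate(sprintf("statistic failed on %d of %d resamples.",
                            failed, n_boot))
  }
  alpha <- (1 - level) / 2
  tibble(
    term = names(est),
    estimate = unname(est),
    conf.low = apply(draws, 2, quantile, alpha, na.rm = TRUE),
    conf.high = apply(draws, 2, quantile, 1 - alpha, na.rm = TRUE),
    n_boot = n_boot,
    n_failed = failed
  )
}

#' Calibration of predicted against observed mortality
#'
#' Bins subjects by quantiles of predicted probability and compares the
#' mean prediction in each bin with the observed Kaplan–Meier mortality by
#' the horizon. Empty or duplicate-boundary bins are collapsed with a
#' warning.
#'
#' @param data A data frame of subjects.
#' @param predicted Column (unquoted) of predicted event probabilities.
#' @param time,event Follow-up columns (unquoted).
#' @param horizon Horizon in years.
#' @param n_bins Number of quantile bins (default 10).
#' @return An object of class `calibration_table` (a tibble with one row
#'   per bin: `bin`, `n`, `mean_predicted`, `observed`).
#' @export
calibration_table <- function(data, predicted, time, event, horizon,
                              n_bins = 10) {
  p <- dplyr::pull(data, {{ predicted }})
  t <- dplyr::pull(data, {{ time }})
  e <- as.integer(dplyr::pull(data, {{ event }}))
  brks <- unique(quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brks) - 1 < n_bins) {
    warn(sprintf("collapsed to %d bins (tied predicted quantiles).",
                 max(1, length(brks) - 1)))
  }
  if (length(brks) == 1) brks <- c(brks - 1e-9, brks + 1e-9)
  bin_of <- cut(p, brks, include.lowest = TRUE, labels = FALSE)
  bins <- sort(unique(bin_of))
  out <- tibble(
    bin = bins,
    n = vapply(bins, function(b) sum(bin_of == b), numeric(1)),
    mean_predicted = vapply(bins, function(b) mean(p[bin_of == b]),
                            numeric(1)),
    observed = vapply(bins, function(b) {
      km_event_prob(t[bin_of == b], e[bin_of == b], horizon)
    }, numeric(1))
  )
  class(out) <- c("calibration_table", class(out))
  attr(out, "horizon") <- horizon
  out
}

#' Risk reclassification gained by adding trajectory clusters
#'
#' For a base clinical risk score (e.g. STS or EuroSCORE II), compares a
#' base survival model with the base-plus-cluster model at one or more
#' horizons: Harrell's C for both, their difference, and the categorical
#' NRI, each with subject-level percentile-bootstrap confidence intervals
#' in which every model is refit on each resample.
#'
#' Base-model absolute risks are obtained by refitting a univariate Cox
#' model on log(score) and converting to horizon probabilities via the
#' Breslow baseline (`score_mode = "refit"`), since published surgical
#' scores are typically miscalibrated for this population;
#' `score_mode = "face_value"` instead uses score/100 directly at every
#' horizon.
#'
#' @param subjects One row per subject with `time_years`, `event`, the
#'   base score column, and a cluster column.
#' @param base_score Name of the base score column (percent scale),
#'   e.g. `"sts_score"`.
#' @param cluster_col Name of the cluster factor column.
#' @param horizons Horizons in years (default `c(1, 3)`).
#' @param cutoffs NRI category boundaries (default `c(0.05, 0.075, 0.10)`).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed.
#' @param score_mode `"refit"` (default) or `"face_value"`.
#' @param nri_method Passed to [categorical_nri()].
#' @return A tibble with one row per horizon: C-indices, C difference,
#'   NRI components, each with `conf.low`/`conf.high`.
#' @export
reclassification_analysis <- function(subjects, base_score = "sts_score",
                                      cluster_col = "cluster_label",
                                      horizons = c(1, 3),
                                      cutoffs = c(0.05, 0.075, 0.10),
                                      n_boot = 1000, seed = 1,
                                      score_mode = c("refit", "face_value"),
                                      nri_method = "km") {
  score_mode <- match.arg(score_mode)
  subjects <- as_tibble(subjects)
  for (col in c("time_years", "event", base_score, cluster_col)) {
    if (!col %in% names(subjects)) {
      stop_invalid(sprintf("column `%s` not found.", col))
    }
  }
  d <- subjects
  d$.score <- d[[base_score]]
  d$.cluster <- factor(d[[cluster_col]])
  if ("stable_low" %in% levels(d$.cluster)) {
    d$.cluster <- stats::relevel(d$.cluster, "stable_low")
  }

  one_horizon <- function(dd, horizon) {
    if (score_mode == "refit") {
      base_fit <- coxph(Surv(time_years, event) ~ log(.score), data = dd,
                        ties = "efron")
      p_base <- predicted_mortality(base_fit, horizon, newdata = dd)
      aug_fit <- coxph(Surv(time_years, event) ~ log(.score) + .cluster,
                       data = dd, ties = "efron")
      p_aug <- predicted_mortality(aug_fit, horizon, newdata = dd)
    } else {
      p_base <- clip01(dd$.score / 100)
      aug_fit <- coxph(Surv(time_years, event) ~ offset(log(.score)) +
                         .cluster, data = dd, ties = "efron")
      p_aug <- predicted_mortality(aug_fit, horizon, newdata = dd)
    }
    dd$.p_base <- p_base
    dd$.p_aug <- p_aug
    cb <- harrell_c(dd, time_years, event, .p_base)$c_index
    ca <- harrell_c(dd, time_years, event, .p_aug)$c_index
    nri <- categorical_nri(dd, .p_base, .p_aug, time_years, event, horizon,
                           cutoffs = cutoffs, method = nri_method)
    c(c_base = cb, c_augmented = ca, c_difference = ca - cb,
      nri_events = nri$nri_events, nri_nonevents = nri$nri_nonevents,
      nri_overall = nri$nri_overall)
  }

  purrr::map(horizons, function(h) {
    ci <- bootstrap_ci(d, function(dd) one_horizon(dd, h),
                       n_boot = n_boot, seed = seed)
    wide <- tibble(horizon = h, base_score = base_score, n_boot = n_boot)
    for (i in seq_len(nrow(ci))) {
      wide[[ci$term[i]]] <- ci$estimate[i]
      wide[[paste0(ci$term[i], ".low")]] <- ci$conf.low[i]
      wide[[paste0(ci$term[i], ".high")]] <- ci$conf.high[i]
    }
    wide
  }) |> dplyr::bind_rows()
}
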