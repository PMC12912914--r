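test_that("Harrell's C matches brute force and the survival package", {
  # perfectly ordered risk
  d <- tibble::tibble(time = 1:6, event = 1, risk = 6:1)
  expect_equal(harrell_c(d, time, event, risk)$c_index, 1)
  d$rev <- -d$risk
  expect_equal(harrell_c(d, time, event, rev)$c_index, 0)

  set.seed(14)
  n <- 100
  d <- tibble::tibble(
    time = rexp(n, 0.2),
    event = as.integer(runif(n) > 0.3),
    risk = round(rnorm(n), 1)  # rounding forces risk ties
  )
  # O(n^2) enumeration oracle
  conc <- 0; pairs <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      usable <- (d$time[i] < d$time[j] & d$event[i] == 1) ||
        (d$time[i] == d$time[j] & d$event[i] == 1 & d$event[j] == 0)
      if (usable) {
        pairs <- pairs + 1
        conc <- conc + (d$risk[i] > d$risk[j]) +
          0.5 * (d$risk[i] == d$risk[j])
      }
    }
  }
  mine <- harrell_c(d, time, event, risk)
  expect_equal(mine$c_index, conc / pairs)
  expect_equal(mine$n_pairs, pairs)
  # independent cross-check (continuous times, so tie conventions agree)
  cfit <- survival::concordance(survival::Surv(time, event) ~ risk, data = d,
                                reverse = TRUE)
  expect_equal(mine$c_index, unname(cfit$concordance))

  # invariance to strictly monotone transforms; complement symmetry sans ties
  d$risk2 <- exp(3 * d$risk)
  expect_equal(harrell_c(d, time, event, risk2)$c_index, mine$c_index)
  d$risk3 <- rnorm(n)
  d$risk3neg <- -d$risk3
  expect_equal(
    harrell_c(d, time, event, risk3)$c_index +
      harrell_c(d, time, event, risk3neg)$c_index, 1
  )
  d$event <- 0L
  expect_error(harrell_c(d, time, event, risk),
               class = "avstraj_undefined_metric")
})

test_that("the Cox ladder recovers null effects and demands valid inputs", {
  # a single null draw can exceed 3 SEs by chance, so pool a few seeds:
  # every |z| must stay below 4 and the per-term mean near 0
  zs <- NULL
  lad <- NULL
  for (s in c(41, 42, 43)) {
    cfg <- trajectory_config(n_subjects = 1500, seed = s,
                             class_hr = c(1, 1, 1), sts_effect = 0)
    co <- simulate_trajectory_cohort(cfg)
    subj <- co$subjects
    subj$cluster_label <- factor(
      c("stable_low", "accelerated", "persistently_high")[
        as.integer(subj$class_truth)],
      levels = c("stable_low", "accelerated", "persistently_high")
    )
    lad <- fit_cox_ladder(subj)
    for (m in 1:3) {
      fit <- lad$fits[[paste0("model", m)]]
      cl_terms <- grep("^\\.cluster", names(coef(fit)))
      z <- coef(fit)[cl_terms] / sqrt(diag(vcov(fit))[cl_terms])
      zs <- rbind(zs, z)
    }
  }
  expect_true(all(abs(zs) < 4))
  expect_true(all(abs(colMeans(zs)) < 1.8))
  # with purely noise covariates, adjustment barely moves the estimates
  hr <- lad$hr_table
  h1 <- hr$hazard_ratio[hr$model == 1 & grepl("cluster", hr$term)]
  h2 <- hr$hazard_ratio[hr$model == 2 & grepl("cluster", hr$term)]
  expect_lt(max(abs(log(h1) - log(h2))), 0.1)

  expect_error(fit_cox_ladder(subj, cluster_col = "nope"),
               class = "avstraj_invalid_input")
  few <- subj[1:20, ]
  few$event <- 0L
  expect_error(fit_cox_ladder(few), class = "avstraj_degenerate_model")
})

test_that("predicted mortality reduces to Kaplan-Meier and the closed form", {
  set.seed(51)
  lambda <- 0.15
  d <- tibble::tibble(
    time_years = rexp(800, lambda),
    event = 1L,
    noise = rnorm(800)
  )
  cens <- runif(800, 0, 12)
  d$event <- as.integer(d$time_years <= cens)
  d$time_years <- pmin(d$time_years, cens)

  # model with an uninformative covariate ~ pooled KM at the horizon
  fit <- survival::coxph(survival::Surv(time_years, event) ~ noise, data = d)
  p <- predicted_mortality(fit, 3, newdata = d)
  km <- 1 - summary(survival::survfit(survival::Surv(time_years, event) ~ 1,
                                      data = d), times = 3)$surv
  expect_equal(mean(p), km, tolerance = 0.02)
  # exponential closed form
  expect_equal(mean(p), 1 - exp(-3 * lambda), tolerance = 0.05)
  # probabilities valid and monotone in horizon
  expect_true(all(p >= 0 & p <= 1))
  p5 <- predicted_mortality(fit, 5, newdata = d)
  expect_true(all(p5 >= p - 1e-12))
  expect_warning(predicted_mortality(fit, 100, newdata = d), "beyond")
})

test_that("categorical NRI matches hand enumeration on a 12-subject toy", {
  # full follow-up: 4 deaths before the 3-year horizon, 8 survivors past it
  toy <- tibble::tibble(
    time = c(rep(2, 4), rep(10, 8)),
    event = c(rep(1, 4), rep(0, 8)),
    base = c(0.04, 0.06, 0.06, 0.12, 0.04, 0.04, 0.06, 0.06, 0.08, 0.08,
             0.12, 0.12),
    aug  = c(0.06, 0.06, 0.12, 0.09, 0.04, 0.06, 0.04, 0.06, 0.06, 0.09,
             0.12, 0.04)
  )
  # hand enumeration, bins (<5, 5-7.5, 7.5-10, >10)%:
  # events: up = subject 1 (bin1->2) and 3 (bin2->4); down = subject 4
  #   (bin4->3) -> (2 - 1)/4 = 0.25
  # non-events: up = subject 6 (bin1->2); down = subjects 7 (bin2->1),
  #   9 (bin3->2), 12 (bin4->1); subject 10 stays in bin3 (0.08 -> 0.09)
  #   -> (3 - 1)/8 = 0.25
  out <- categorical_nri(toy, base, aug, time, event, horizon = 3)
  expect_equal(out$nri_events, 0.25)
  expect_equal(out$nri_nonevents, 0.25)
  expect_equal(out$nri_overall, 0.5)
  # decomposition identity
  expect_equal(out$nri_overall, out$nri_events + out$nri_nonevents)
  # full follow-up: KM-weighted estimator equals the complete-case count NRI
  cc <- categorical_nri(toy, base, aug, time, event, horizon = 3,
                        method = "complete_case")
  expect_equal(out[1:4], cc[1:4])

  # identity augmentation -> all zeros
  out0 <- categorical_nri(toy, base, base, time, event, horizon = 3)
  expect_equal(out0$nri_overall, 0)
  # all events up one bin, all non-events down one bin -> overall 2
  toy2 <- tibble::tibble(
    time = rep(c(2, 10), each = 4), event = rep(c(1, 0), each = 4),
    base = rep(0.06, 8),
    aug = c(rep(0.09, 4), rep(0.04, 4))
  )
  out2 <- categorical_nri(toy2, base, aug, time, event, horizon = 3)
  expect_equal(out2$nri_overall, 2)
  toy2$event <- 0
  expect_error(categorical_nri(toy2, base, aug, time, event, horizon = 3),
               class = "avstraj_undefined_metric")
})

test_that("NRI's KM weighting handles censoring before the horizon", {
  set.seed(61)
  n <- 600
  d <- tibble::tibble(
    risk = runif(n),
    t_true = rexp(n, 0.1 * exp(2 * risk))
  )
  cens <- runif(n, 0, 8)
  d$time <- pmin(d$t_true, cens)
  d$event <- as.integer(d$t_true <= cens)
  d$base <- 0.3 * d$risk
  d$aug <- d$risk  # informative shift upward for high risk
  out <- categorical_nri(d, base, aug, time, event, horizon = 3)
  expect_true(is.finite(out$nri_overall))
  expect_equal(out$nri_overall, out$nri_events + out$nri_nonevents)
})

test_that("bootstrap CIs are deterministic, degenerate on constants, and shrink", {
  d <- tibble::tibble(x = rnorm(50, sd = 2) + 5)
  ci_const <- bootstrap_ci(d, function(dd) c(k = 1), n_boot = 50, seed = 3)
  expect_equal(ci_const$conf.low, ci_const$conf.high)
  expect_equal(ci_const$estimate, 1)

  ci1 <- bootstrap_ci(d, function(dd) c(m = mean(dd$x)), n_boot = 200, seed = 9)
  ci2 <- bootstrap_ci(d, function(dd) c(m = mean(dd$x)), n_boot = 200, seed = 9)
  expect_identical(ci1, ci2)

  # width scales roughly as 1/sqrt(n)
  set.seed(77)
  widths <- vapply(c(50, 800), function(n) {
    dd <- tibble::tibble(x = rnorm(n))
    ci <- bootstrap_ci(dd, function(z) c(m = mean(z$x)), n_boot = 300, seed = 5)
    ci$conf.high - ci$conf.low
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 4, tolerance = 0.35)

  # a statistic that works on the original data but fails on (almost every)
  # resample, because resampling with replacement duplicates rows
  expect_error(
    bootstrap_ci(d, function(dd) {
      if (anyDuplicated(dd$x) > 0) stop("duplicate rows")
      c(m = mean(dd$x))
    }, n_boot = 20, seed = 1),
    class = "avstraj_degenerate_model"
  )
})

test_that("calibration bins partition subjects and degrade gracefully", {
  set.seed(71)
  n <- 500
  d <- tibble::tibble(
    p = runif(n, 0.05, 0.6),
    t_true = rexp(n, 0.25)
  )
  d$time <- pmin(d$t_true, 6)
  d$event <- as.integer(d$t_true <= 6)
  cal <- calibration_table(d, p, time, event, horizon = 3, n_bins = 5)
  expect_equal(sum(cal$n), n)
  expect_true(all(cal$observed >= 0 & cal$observed <= 1))

  d$p_const <- 0.3
  expect_warning(
    cal1 <- calibration_table(d, p_const, time, event, horizon = 3),
    "collapsed"
  )
  expect_equal(nrow(cal1), 1)
  km <- 1 - summary(survival::survfit(survival::Surv(time, event) ~ 1,
                                      data = d), times = 3)$surv
  expect_equal(cal1$observed, km)
})

test_that("reclassification analysis reports coherent C and NRI columns", {
  co <- simulate_trajectory_cohort(trajectory_config(n_subjects = 400,
                                                     seed = 83))
  subj <- co$subjects
  subj$cluster_label <- factor(
    c("stable_low", "accelerated", "persistently_high")[
      as.integer(subj$class_truth)],
    levels = c("stable_low", "accelerated", "persistently_high")
  )
  rc <- reclassification_analysis(subj, horizons = 3, n_boot = 40, seed = 2)
  expect_equal(nrow(rc), 1)
  expect_true(all(c("c_base", "c_augmented", "c_difference", "nri_overall")
                  %in% names(rc)))
  expect_equal(rc$c_difference, rc$c_augmented - rc$c_base, tolerance = 1e-10)
  expect_equal(rc$nri_overall, rc$nri_events + rc$nri_nonevents,
               tolerance = 1e-10)
  expect_true(rc$c_base >= 0 && rc$c_base <= 1)
  expect_true(rc$c_augmented >= 0 && rc$c_augmented <= 1)
})
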