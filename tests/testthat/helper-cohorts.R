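# Small cohorts reused across tests. Built in code; sizes kept modest so the
# full suite stays fast.

small_trajectory_cohort <- function(n = 120, seed = 11, ...) {
  simulate_trajectory_cohort(trajectory_config(n_subjects = n, seed = seed, ...))
}

# Noise-free scores from hand-written constant trajectories.
constant_scores <- function(levels,
                            times = c(0.5, 2, 3.5, 5, 6.5, 8, 9, 9.5)) {
  purrr::imap(levels, function(lv, i) {
    tibble::tibble(
      subject_id = sprintf("C%02d", i),
      years_before = times,
      score = lv
    )
  }) |> dplyr::bind_rows()
}

# Well-separated three-class data for model-selection checks: constant
# levels far apart relative to noise.
separated_scores <- function(n_per_class = 40, noise = 0.02, seed = 1) {
  set.seed(seed)
  levels <- c(0.2, 0.5, 0.8)
  purrr::map(seq_len(3L * n_per_class), function(i) {
    cl <- ((i - 1L) %% 3L) + 1L
    m <- sample(3:6, 1)
    t <- sort(runif(m, 0, 10))
    tibble::tibble(
      subject_id = sprintf("W%03d", i),
      years_before = t,
      score = pmin(1, pmax(0, levels[cl] + rnorm(m, 0, noise))),
      truth = cl
    )
  }) |> dplyr::bind_rows()
}
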