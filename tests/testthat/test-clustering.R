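test_that("trajectory distance equals the naive per-point computation", {
  s <- constant_scores(c(0.5))
  expect_equal(trajectory_distance(s, function(t) rep(0.5, length(t)))$distance,
               0, ignore_attr = TRUE)

  # constant centroid c with scores c + d and c - d -> d^2
  s <- tibble::tibble(subject_id = "a", years_before = c(1, 2),
                      score = c(0.6 + 0.1, 0.6 - 0.1))
  expect_equal(trajectory_distance(s, function(t) rep(0.6, length(t)))$distance,
               0.01, ignore_attr = TRUE)

  set.seed(3)
  s <- tibble::tibble(subject_id = "b", years_before = sort(runif(6, 0, 10)),
                      score = runif(6))
  f <- function(t) 0.3 + 0.05 * t - 0.008 * t^2 + 0.0004 * t^3
  naive <- 0
  for (i in 1:6) naive <- naive + (s$score[i] - f(s$years_before[i]))^2
  expect_equal(trajectory_distance(s, f)$distance, naive / 6,
               ignore_attr = TRUE)
  expect_error(trajectory_distance(s[0, ], f), class = "avstraj_invalid_input")
})

test_that("M-step centroids reproduce constants, lines, and separated levels", {
  s <- constant_scores(rep(0.42, 6))
  asg <- stats::setNames(rep(1L, 6), unique(s$subject_id))
  ct <- fit_cluster_centroids(s, asg)[[1]]
  grid <- seq(0, 10, by = 0.25)
  expect_lt(max(abs(avstraj:::eval_centroid(ct, grid) - 0.42)), 1e-6)

  # noiseless linear trend recovered against its least-squares line
  set.seed(5)
  s <- purrr::map(1:8, function(i) {
    t <- sort(runif(5, 0, 10))
    tibble::tibble(subject_id = sprintf("L%02d", i), years_before = t,
                   score = 0.2 + 0.05 * t)
  }) |> dplyr::bind_rows()
  asg <- stats::setNames(rep(1L, 8), unique(s$subject_id))
  ct <- fit_cluster_centroids(s, asg)[[1]]
  expect_lt(max(abs(avstraj:::eval_centroid(ct, grid) - (0.2 + 0.05 * grid))),
            1e-3)

  # two constant clusters at 0.3 / 0.8
  s <- constant_scores(c(0.3, 0.3, 0.8, 0.8))
  asg <- stats::setNames(c(1L, 1L, 2L, 2L), unique(s$subject_id))
  cts <- fit_cluster_centroids(s, asg)
  expect_lt(max(abs(avstraj:::eval_centroid(cts[[1]], grid) - 0.3)), 1e-3)
  expect_lt(max(abs(avstraj:::eval_centroid(cts[[2]], grid) - 0.8)), 1e-3)
})

test_that("E-step picks the nearest centroid with lowest-index tie-breaks", {
  cts <- list(function(t) rep(0.2, length(t)), function(t) rep(0.8, length(t)))
  s <- constant_scores(c(0.8, 0.2, 0.5))
  out <- assign_clusters(s, cts)
  expect_equal(out$cluster, c(2L, 1L, 1L))  # 0.5 is equidistant -> index 1

  set.seed(12)
  s <- purrr::map(1:10, function(i) {
    tibble::tibble(subject_id = sprintf("R%02d", i),
                   years_before = sort(runif(4, 0, 10)), score = runif(4))
  }) |> dplyr::bind_rows()
  cts <- list(function(t) rep(0.3, length(t)),
              function(t) 0.1 + 0.06 * t,
              function(t) rep(0.7, length(t)))
  out <- assign_clusters(s, cts)
  # brute-force distance table
  for (id in unique(s$subject_id)) {
    sub <- s[s$subject_id == id, ]
    d <- vapply(cts, function(f) mean((sub$score - f(sub$years_before))^2),
                numeric(1))
    expect_equal(out$cluster[out$subject_id == id], which.min(d))
  }
})

test_that("EM recovers noiseless structure and is deterministic", {
  s <- constant_scores(c(0.3, 0.3, 0.3, 0.8, 0.8, 0.8, 0.8))
  m1 <- cluster_trajectories(s, k = 2, seed = 4, n_start = 3)
  truth <- c(1, 1, 1, 2, 2, 2, 2)
  expect_equal(adjusted_rand_index(m1$assignments$cluster, truth), 1)
  expect_lt(m1$objective, 1e-10)

  m2 <- cluster_trajectories(s, k = 2, seed = 4, n_start = 3)
  expect_identical(m1$assignments, m2$assignments)
  expect_identical(m1$objective, m2$objective)

  # k = 1: everything in one cluster, objective = pooled spline residual SSR
  m <- cluster_trajectories(s, k = 1, seed = 1, n_start = 1)
  expect_true(all(m$assignments$cluster == 1))
  asg <- stats::setNames(rep(1L, 7), unique(s$subject_id))
  ct <- fit_cluster_centroids(s, asg)[[1]]
  pred <- avstraj:::eval_centroid(ct, s$years_before)
  expect_equal(m$objective, sum((s$score - pred)^2), tolerance = 1e-8)

  expect_error(cluster_trajectories(s, k = 50), class = "avstraj_invalid_input")
})

test_that("EM objective is non-increasing and ends at an E-step fixed point", {
  co <- small_trajectory_cohort(n = 80, seed = 19)
  for (sd in 1:5) {
    run <- avstraj:::em_once(co$scores, k = 3, seed = sd, basis_dim = 8,
                             smooth = "fixed", max_iter = 50, tol = 1e-6)
    tr <- run$objective_trace
    rep_tr <- run$repair_trace
    if (length(tr) > 1) {
      steps_ok <- diff(tr) <= 1e-8 * tr[-length(tr)] | rep_tr[-1] > 0
      expect_true(all(steps_ok))
    }
    if (run$converged && sum(rep_tr) == 0) {
      re <- assign_clusters(co$scores, run$centroids)
      expect_equal(stats::setNames(re$cluster, re$subject_id)[
        names(run$assignments)], run$assignments, ignore_attr = TRUE)
    }
  }
})

test_that("BIC follows its closed form and separates clear structure", {
  co <- small_trajectory_cohort(n = 60, seed = 23)
  m <- cluster_trajectories(co$scores, k = 2, seed = 1, n_start = 2)
  p_eff <- sum(vapply(m$centroids, function(ct) ct$edf, numeric(1))) + m$k
  N <- m$n_obs
  expect_equal(m$bic, N * log(m$objective / N) + p_eff * log(N))

  # well-separated 3-level noiseless data: BIC prefers k = 3 over k = 2
  s <- constant_scores(c(rep(0.2, 4), rep(0.5, 4), rep(0.8, 4)))
  s$score <- s$score + rep_len(seq(-0.002, 0.002, length.out = 5), nrow(s))
  m2 <- cluster_trajectories(s, k = 2, seed = 1, n_start = 4)
  m3 <- cluster_trajectories(s, k = 3, seed = 1, n_start = 4)
  expect_lt(m3$bic, m2$bic)
})

test_that("silhouette matches a hand-computed toy table", {
  # fake model: two constant centroids, three constant subjects
  s <- constant_scores(c(0.2, 0.8, 0.5))
  model <- structure(list(
    k = 2,
    centroids = list(function(t) rep(0.2, length(t)),
                     function(t) rep(0.8, length(t))),
    assignments = tibble::tibble(subject_id = unique(s$subject_id),
                                 cluster = c(1L, 2L, 1L)),
    scores = s
  ), class = "traj_clusters")
  sil <- cluster_silhouette(model)
  # subject 1: a = 0, b = 0.36 -> 1; subject 2: a = 0, b = 0.36 -> 1
  # subject 3: a = b = 0.09 -> 0
  expect_equal(sil$per_subject$silhouette, c(1, 1, 0))
  expect_equal(sil$mean, 2 / 3)
  model$k <- 1
  expect_error(cluster_silhouette(model), class = "avstraj_undefined_metric")
})

test_that("adjusted Rand index matches the contingency formula and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)

  a <- c(1, 1, 1, 2, 2, 2, 3, 3)
  b <- c(1, 1, 2, 2, 2, 3, 3, 3)
  # hand contingency computation
  tab <- table(a, b)
  sij <- sum(choose(tab, 2)); sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2)); ex <- sa * sb / choose(8, 2)
  oracle <- (sij - ex) / ((sa + sb) / 2 - ex)
  expect_equal(adjusted_rand_index(a, b), oracle)
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))

  expect_error(
    adjusted_rand_index(stats::setNames(a, paste0("s", 1:8)),
                        stats::setNames(b, paste0("x", 1:8))),
    class = "avstraj_invalid_input"
  )
})

test_that("k-selection table has one row per candidate and flags structure", {
  s <- separated_scores(n_per_class = 15, seed = 2)
  sel <- suppressWarnings(select_k(s[, 1:3], k_range = 2:4, seeds_per_k = 3))
  expect_equal(nrow(sel$diagnostics), 3)
  expect_equal(sel$diagnostics$k, 2:4)
  expect_equal(sel$chosen_k, 3)
})

test_that("stability is perfect on separable data and reports a unit diagonal", {
  s <- constant_scores(c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8))
  st <- cluster_stability(s, k = 2, n_restarts = 4, n_boot = 3, seed = 6)
  expect_true(all(diag(st$ari_restarts) == 1))
  expect_true(all(st$ari_restarts == 1))
  expect_true(all(st$ari_bootstrap == 1))
  expect_equal(st$summary$mean_ari[st$summary$source == "overall"], 1)
})

test_that("semantic labels follow centroid geometry and ignore indexing", {
  mk_model <- function(perm) {
    cts <- list(
      function(t) rep(0.47, length(t)),
      function(t) ifelse(t >= 2, 0.58, 0.58 + 0.27 * (2 - t) / 2),
      function(t) rep(0.75, length(t))
    )[perm]
    structure(list(k = 3, centroids = cts,
                   assignments = tibble::tibble(subject_id = "a", cluster = 1L),
                   labels = NULL),
              class = "traj_clusters")
  }
  want <- c("stable_low", "accelerated", "persistently_high")
  for (perm in list(1:3, c(2, 3, 1), c(3, 1, 2))) {
    m <- label_clusters(mk_model(perm))
    lab <- as.character(m$labels$label[order(m$labels$cluster)])
    expect_equal(lab[match(1:3, perm)], want)
  }
  m2 <- mk_model(1:3); m2$k <- 2; m2$centroids <- m2$centroids[1:2]
  expect_warning(label_clusters(m2), "k = 3")
})

test_that("min_obs filtering drops short trajectories before clustering", {
  co <- small_trajectory_cohort(n = 100, seed = 29)
  m_all <- cluster_trajectories(co$scores, k = 2, seed = 1, n_start = 2)
  m_f <- cluster_trajectories(co$scores, k = 2, seed = 1, n_start = 2,
                              min_obs = 3)
  cnt <- table(co$scores$subject_id)
  expect_equal(m_f$n_subjects, sum(cnt >= 3))
  expect_gte(m_all$n_subjects, m_f$n_subjects)
})
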