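#' Mean-squared distance between a trajectory and a centroid curve
#'
#' The distance between a subject's irregular score series and a cluster
#' centroid is the mean over the subject's observations of the squared
#' residual to the centroid curve evaluated at the observation times.
#'
#' @param scores Long score table (`subject_id`, `years_before`, `score`).
#' @param centroid A centroid: either a function of time or a
#'   `traj_centroid` object from [fit_cluster_centroids()].
#' @return A tibble `subject_id`, `distance` (one row per subject).
#' @export
trajectory_distance <- function(scores, centroid) {
  scores <- validate_scores(scores)
  pred <- eval_centroid(centroid, scores$years_before)
  sq <- (scores$score - pred)^2
  agg <- rowsum(sq, scores$subject_id)
  cnt <- rowsum(rep(1, length(sq)), scores$subject_id)
  tibble(subject_id = rownames(agg), distance = agg[, 1] / cnt[, 1])
}

eval_centroid <- function(centroid, t) {
  if (inherits(centroid, "traj_centroid")) {
    if (centroid$type == "constant") return(rep(centroid$value, length(t)))
    as.numeric(predict(centroid$fit, newdata = data.frame(.t = t)))
  } else if (is.function(centroid)) {
    centroid(t)
  } else {
    stop_invalid("`centroid` must be a function or a traj_centroid.")
  }
}

#' Fit spline centroids to clustered trajectories (M-step)
#'
#' For each cluster, fits a low-rank thin-plate regression spline to the
#' pooled (time, score) points of its member trajectories. By default the
#' spline is unpenalized with fixed basis dimension, so the fit minimises
#' the pooled residual sum of squares exactly — which makes the EM
#' objective provably non-increasing. `smooth = "gcv"` instead selects the
#' smoothing penalty by generalized cross-validation.
#'
#' If a cluster holds fewer unique time points than the basis dimension,
#' the dimension is reduced with a warning; clusters with fewer than three
#' unique times get a constant (mean) centroid.
#'
#' @param scores Long score table.
#' @param assignments Tibble `subject_id`, `cluster` (integer), or a named
#'   vector of cluster indices.
#' @param basis_dim Spline basis dimension (default 8).
#' @param smooth `"fixed"` (unpenalized, default) or `"gcv"`.
#' @return A list of `traj_centroid` objects, one per cluster index.
#' @export
fit_cluster_centroids <- function(scores, assignments, basis_dim = 8,
                                  smooth = c("fixed", "gcv")) {
  smooth <- match.arg(smooth)
  scores <- validate_scores(scores)
  asg <- as_assignment_vector(assignments)
  cluster_of <- asg[scores$subject_id]
  if (anyNA(cluster_of)) stop_invalid("every subject needs an assignment.")
  ks <- sort(unique(asg))
  lapply(setNames(ks, ks), function(k) {
    sub <- data.frame(.t = scores$years_before[cluster_of == k],
                      .y = scores$score[cluster_of == k])
    if (nrow(sub) == 0) stop_invalid("empty cluster in M-step.")
    fit_one_centroid(sub, basis_dim, smooth)
  })
}

fit_one_centroid <- function(sub, basis_dim, smooth) {
  n_unique <- length(unique(sub$.t))
  if (n_unique < 3) {
    return(structure(
      list(type = "constant", value = mean(sub$.y), edf = 1, n = nrow(sub)),
      class = "traj_centroid"
    ))
  }
  k_eff <- min(basis_dim, n_unique)
  if (k_eff < basis_dim) {
    warn(sprintf("basis dimension reduced to %d (only %d unique times).",
                 k_eff, n_unique))
  }
  fx <- smooth == "fixed"
  # fixed knot grid over the 10-year window: the basis then depends only on
  # k_eff, not on which subjects are in the cluster, so the unpenalized
  # M-step provably never increases the EM objective
  fit <- mgcv::gam(.y ~ s(.t, bs = "tp", k = k_eff, fx = fx), data = sub,
                   knots = list(.t = seq(0, 10, length.out = k_eff)))
  structure(
    list(type = "spline", fit = fit, edf = sum(fit$edf) + 1, n = nrow(sub)),
    class = "traj_centroid"
  )
}

as_assignment_vector <- function(assignments) {
  if (is.data.frame(assignments)) {
    setNames(as.integer(assignments$cluster), assignments$subject_id)
  } else {
    if (is.null(names(assignments))) {
      stop_invalid("assignment vector must be named by subject_id.")
    }
    stats::setNames(as.integer(assignments), names(assignments))
  }
}

#' Assign trajectories to their nearest centroid (E-step)
#'
#' Each subject is assigned to the centroid minimising the mean squared
#' residual of its observations; ties go to the lowest cluster index.
#'
#' @param scores Long score table.
#' @param centroids List of centroids (functions or `traj_centroid`s).
#' @return A tibble `subject_id`, `cluster`, `distance`, with the full
#'   subject-by-cluster distance matrix in attribute `"distances"`.
#' @export
assign_clusters <- function(scores, centroids) {
  scores <- validate_scores(scores)
  dm <- distance_matrix(scores, centroids)
  cl <- max.col(-dm, ties.method = "first")
  out <- tibble(
    subject_id = rownames(dm),
    cluster = cl,
    distance = dm[cbind(seq_len(nrow(dm)), cl)]
  )
  attr(out, "distances") <- dm
  out
}

distance_matrix <- function(scores, centroids) {
  ids <- unique(scores$subject_id)
  cnt <- rowsum(rep(1, nrow(scores)), scores$subject_id)[ids, 1]
  dm <- vapply(centroids, function(ct) {
    pred <- eval_centroid(ct, scores$years_before)
    rowsum((scores$score - pred)^2, scores$subject_id)[ids, 1] / cnt
  }, numeric(length(ids)))
  dm <- matrix(dm, nrow = length(ids),
               dimnames = list(ids, seq_along(centroids)))
  dm
}

# One EM run from a seeded random initial assignment.
# Objective: total within-cluster sum of squared residuals over all
# observations (equivalently pooled MSE up to the fixed total N); both the
# unpenalized M-step and the nearest-centroid E-step can only decrease it.
em_once <- function(scores, k, seed, basis_dim, smooth, max_iter, tol) {
  ids <- unique(scores$subject_id)
  n_i <- rowsum(rep(1, nrow(scores)), scores$subject_id)[ids, 1]
  set.seed(seed)
  asg <- setNames(sample.int(k, length(ids), replace = TRUE), ids)
  # guarantee no empty initial cluster
  if (length(unique(asg)) < k) asg[seq_len(k)] <- seq_len(k)
  trace <- numeric(0)
  repairs <- integer(0)
  converged <- FALSE
  centroids <- NULL
  for (it in seq_len(max_iter)) {
    centroids <- fit_cluster_centroids(scores, asg, basis_dim, smooth)
    dm <- distance_matrix(scores, centroids)
    new_asg <- max.col(-dm, ties.method = "first")
    # empty-cluster repair: reseed with the subject worst-fit by its own
    # centroid (the one transition allowed to raise the objective)
    n_rep <- 0L
    repeat {
      missing_k <- setdiff(seq_len(k), unique(new_asg))
      if (length(missing_k) == 0) break
      cur <- dm[cbind(seq_along(ids), new_asg)]
      # only steal from clusters that keep >= 2 members, so the donor
      # cluster cannot itself empty (which could cycle forever)
      sizes <- tabulate(new_asg, nbins = k)
      cur[sizes[new_asg] < 2] <- -Inf
      worst <- which.max(cur)
      new_asg[worst] <- missing_k[1]
      n_rep <- n_rep + 1L
    }
    obj <- sum(dm[cbind(seq_along(ids), new_asg)] * n_i[ids])
    trace <- c(trace, obj)
    repairs <- c(repairs, n_rep)
    if (all(new_asg == asg)) {
      converged <- TRUE
      break
    }
    if (length(trace) >= 2) {
      prev <- trace[length(trace) - 1]
      if (abs(prev - obj) <= tol * max(prev, .Machine$double.eps)) {
        asg[] <- new_asg
        converged <- TRUE
        break
      }
    }
    asg[] <- new_asg
  }
  list(
    assignments = setNames(as.integer(asg), ids),
    centroids = centroids,
    objective = trace[length(trace)],
    objective_trace = trace,
    repair_trace = repairs,
    n_iterations = length(trace),
    converged = converged,
    seed = seed
  )
}

#' Cluster longitudinal score trajectories by EM with spline centroids
#'
#' Alternates between refitting per-cluster thin-plate spline centroids on
#' the pooled member observations (M-step) and reassigning each subject to
#' its nearest centroid in mean-squared-error distance (E-step), starting
#' from a seeded uniform-random assignment, until the assignments are a
#' fixed point, the objective change falls below `tol`, or `max_iter` is
#' reached. With `n_start > 1` the best of several seeded restarts (by
#' final objective) is returned. Clusters emptied during iteration are
#' reseeded with the currently worst-fit subject.
#'
#' @param scores Long score table (`subject_id`, `years_before`, `score`).
#' @param k Number of clusters (>= 1, <= number of subjects).
#' @param seed Base seed; restart `r` uses `seed + r - 1`.
#' @param n_start Number of random restarts (default 10).
#' @param max_iter Maximum EM iterations per restart (default 50).
#' @param tol Relative objective-change convergence tolerance
#'   (default 1e-6).
#' @param basis_dim Spline basis dimension (default 8).
#' @param smooth `"fixed"` (unpenalized spline, default) or `"gcv"`.
#' @param min_obs Drop subjects with fewer observations before clustering
#'   (default 1 keeps everyone; single-observation subjects are clustered
#'   on their single squared residual).
#' @return An object of class `traj_clusters`; see [tidy.traj_clusters()],
#'   [glance.traj_clusters()], [autoplot.traj_clusters()].
#' @examples
#' co <- simulate_trajectory_cohort(trajectory_config(n_subjects = 60, seed = 2))
#' m <- cluster_trajectories(co$scores, k = 3, n_start = 2)
#' glance(m)
#' @export
cluster_trajectories <- function(scores, k, seed = 1, n_start = 10,
                                 max_iter = 50, tol = 1e-6, basis_dim = 8,
                                 smooth = c("fixed", "gcv"), min_obs = 1) {
  smooth <- match.arg(smooth)
  scores <- validate_scores(scores)
  if (min_obs > 1) {
    keep <- dplyr::count(scores, .data$subject_id)
    keep <- keep$subject_id[keep$n >= min_obs]
    scores <- dplyr::filter(scores, .data$subject_id %in% keep)
    if (nrow(scores) == 0) stop_invalid("no subjects left after `min_obs` filter.")
  }
  n_subj <- length(unique(scores$subject_id))
  if (k < 1) stop_invalid("`k` must be >= 1.")
  if (k > n_subj) stop_invalid("`k` exceeds the number of subjects.")

  runs <- lapply(seq_len(n_start), function(r) {
    em_once(scores, k, seed + r - 1L, basis_dim, smooth, max_iter, tol)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]

  asg_tbl <- tibble(subject_id = names(best$assignments),
                    cluster = unname(best$assignments))
  dm <- distance_matrix(scores, best$centroids)
  per_subj <- dm[cbind(match(asg_tbl$subject_id, rownames(dm)),
                       asg_tbl$cluster)]
  n_i <- rowsum(rep(1, nrow(scores)), scores$subject_id)[asg_tbl$subject_id, 1]
  within <- tibble(cluster = sort(unique(asg_tbl$cluster))) |>
    dplyr::mutate(mse = vapply(.data$cluster, function(cl) {
      sel <- asg_tbl$cluster == cl
      sum(per_subj[sel] * n_i[sel]) / sum(n_i[sel])
    }, numeric(1)))

  model <- structure(
    list(
      k = k,
      centroids = best$centroids,
      assignments = asg_tbl,
      distance_to_centroid = per_subj,
      within_mse = list(total = best$objective / sum(n_i), per_cluster = within),
      objective = best$objective,
      objective_trace = best$objective_trace,
      repair_trace = best$repair_trace,
      n_iterations = best$n_iterations,
      converged = best$converged,
      seed = best$seed,
      seeds_tried = seed + seq_len(n_start) - 1L,
      basis_dim = basis_dim,
      smooth = smooth,
      n_subjects = n_subj,
      n_obs = nrow(scores),
      scores = scores,
      labels = NULL
    ),
    class = "traj_clusters"
  )
  model$bic <- cluster_bic(model)
  model$silhouette <- if (k >= 2) cluster_silhouette(model) else NULL
  model
}

#' Bayesian information criterion of a trajectory cluster model
#'
#' Gaussian working likelihood:
#' `BIC = N log(RSS / N) + p_eff log(N)`, where `N` is the total number of
#' observations, `RSS` the summed squared residuals to each subject's
#' assigned centroid, and `p_eff = k * (spline edf) + k` counts the
#' centroid coefficients plus one variance term per cluster.
#'
#' @param model A `traj_clusters` object.
#' @return The BIC (numeric scalar).
#' @export
cluster_bic <- function(model) {
  N <- model$n_obs
  rss <- model$objective
  p_eff <- sum(vapply(model$centroids, function(ct) ct$edf, numeric(1))) +
    model$k
  N * log(rss / N) + p_eff * log(N)
}

#' Centroid-based silhouette of a trajectory cluster model
#'
#' For each subject, `a` is the MSE distance to its own centroid and `b`
#' the minimum distance to any other centroid; the silhouette is
#' `(b - a) / max(a, b)`.
#'
#' @param model A `traj_clusters` object (k >= 2).
#' @return A list: `mean`, and `per_subject` tibble
#'   (`subject_id`, `cluster`, `silhouette`).
#' @export
cluster_silhouette <- function(model) {
  if (model$k < 2) stop_undefined("silhouette needs k >= 2.")
  dm <- distance_matrix(model$scores, model$centroids)
  idx <- match(model$assignments$subject_id, rownames(dm))
  a <- dm[cbind(idx, model$assignments$cluster)]
  dm_other <- dm[idx, , drop = FALSE]
  dm_other[cbind(seq_along(idx), model$assignments$cluster)] <- Inf
  b <- apply(dm_other, 1, min)
  s <- ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  list(
    mean = mean(s),
    per_subject = tibble(
      subject_id = model$assignments$subject_id,
      cluster = model$assignments$cluster,
      silhouette = s
    )
  )
}

#' Choose the number of trajectory clusters
#'
#' Fits best-of-seeds EM models for each candidate `k` and selects the `k`
#' minimising BIC. The mean silhouette is reported alongside; if the
#' silhouette-maximising `k` differs from the BIC-minimising `k`, the
#' diagnostics table flags the disagreement and BIC wins.
#'
#' @inheritParams cluster_trajectories
#' @param k_range Candidate cluster counts (default 2:6).
#' @param seeds_per_k Random restarts per candidate (default 10).
#' @return An object of class `traj_k_selection`: list with `chosen_k`,
#'   `diagnostics` (one row per k), `disagreement`, and `models`.
#' @export
select_k <- function(scores, k_range = 2:6, seeds_per_k = 10, seed = 1,
                     basis_dim = 8, smooth = c("fixed", "gcv"),
                     max_iter = 50, tol = 1e-6, min_obs = 1) {
  smooth <- match.arg(smooth)
  scores <- validate_scores(scores)
  n_subj <- length(unique(scores$subject_id))
  if (any(k_range < 2) || any(k_range > n_subj)) {
    stop_invalid("`k_range` must lie within [2, number of subjects].")
  }
  models <- lapply(k_range, function(k) {
    cluster_trajectories(scores, k, seed = seed, n_start = seeds_per_k,
                         max_iter = max_iter, tol = tol,
                         basis_dim = basis_dim, smooth = smooth,
                         min_obs = min_obs)
  })
  diagnostics <- tibble(
    k = k_range,
    bic = vapply(models, function(m) m$bic, numeric(1)),
    silhouette = vapply(models, function(m) m$silhouette$mean, numeric(1)),
    objective = vapply(models, function(m) m$objective, numeric(1)),
    converged = vapply(models, function(m) m$converged, logical(1))
  )
  k_bic <- diagnostics$k[which.min(diagnostics$bic)]
  k_sil <- diagnostics$k[which.max(diagnostics$silhouette)]
  structure(
    list(
      chosen_k = k_bic,
      diagnostics = diagnostics,
      disagreement = k_bic != k_sil,
      silhouette_k = k_sil,
      models = setNames(models, k_range)
    ),
    class = "traj_k_selection"
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same
#' subjects, from the standard permutation-model contingency-table
#' formula; 1 means identical up to relabelling.
#'
#' @param part1,part2 Cluster label vectors over the same subjects (if
#'   named, they are aligned by name).
#' @return The ARI (numeric scalar, at most 1).
#' @export
adjusted_rand_index <- function(part1, part2) {
  if (!is.null(names(part1)) && !is.null(names(part2))) {
    if (!setequal(names(part1), names(part2))) {
      stop_invalid("partitions cover different subject sets.")
    }
    part2 <- part2[names(part1)]
  }
  if (length(part1) != length(part2)) {
    stop_invalid("partitions must have the same length.")
  }
  tab <- table(part1, part2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Stability of a trajectory clustering
#'
#' Quantifies how reproducible a k-cluster solution is: (a) pairwise
#' adjusted Rand indices between assignment vectors from independent
#' random starts on the full data, and (b) ARIs between the full-data
#' assignments and assignments from refits on bootstrap resamples of
#' subjects (compared on the subjects shared with the original data).
#'
#' @inheritParams cluster_trajectories
#' @param n_restarts Independent random starts (default 20).
#' @param n_boot Bootstrap refits (default 50).
#' @return An object of class `traj_stability`: `ari_restarts` (matrix),
#'   `ari_bootstrap` (vector), `summary` (tibble of mean ARIs).
#' @export
cluster_stability <- function(scores, k, n_restarts = 20, n_boot = 50,
                              seed = 1, basis_dim = 8,
                              smooth = c("fixed", "gcv"), max_iter = 50,
                              tol = 1e-6) {
  smooth <- match.arg(smooth)
  scores <- validate_scores(scores)
  runs <- lapply(seq_len(n_restarts), function(r) {
    em_once(scores, k, seed + r - 1L, basis_dim, smooth, max_iter, tol)
  })
  m <- diag(1, n_restarts)
  for (i in seq_len(n_restarts)) {
    for (j in seq_len(n_restarts)) {
      if (j > i) {
        m[i, j] <- m[j, i] <-
          adjusted_rand_index(runs[[i]]$assignments, runs[[j]]$assignments)
      }
    }
  }
  ref <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  ids <- unique(scores$subject_id)
  ari_boot <- numeric(n_boot)
  if (n_boot > 0) {
    set.seed(seed + n_restarts)
    for (b in seq_len(n_boot)) {
      samp <- sample(ids, length(ids), replace = TRUE)
      keep <- unique(samp)
      sub <- dplyr::filter(scores, .data$subject_id %in% keep)
      run_b <- em_once(sub, k, seed + n_restarts + b, basis_dim, smooth,
                       max_iter, tol)
      shared <- intersect(names(run_b$assignments), names(ref$assignments))
      ari_boot[b] <- adjusted_rand_index(ref$assignments[shared],
                                         run_b$assignments[shared])
    }
  }
  restart_mean <- if (n_restarts > 1) {
    mean(m[upper.tri(m)])
  } else NA_real_
  structure(
    list(
      ari_restarts = m,
      ari_bootstrap = ari_boot,
      summary = tibble(
        source = c("restarts", "bootstrap", "overall"),
        mean_ari = c(restart_mean,
                     if (n_boot > 0) mean(ari_boot) else NA_real_,
                     mean(c(if (n_restarts > 1) m[upper.tri(m)],
                            if (n_boot > 0) ari_boot)))
      )
    ),
    class = "traj_stability"
  )
}

#' Attach semantic labels to a three-cluster solution
#'
#' Labels the clusters of a `k = 3` model by their centroid geometry:
#' `stable_low` is the cluster with the lowest mean centroid level; of the
#' remaining two, `accelerated` is the one whose centroid rises more over
#' the final 2 years before the procedure (centroid at 0 minus centroid at
#' 2 years); the third is `persistently_high`. For `k != 3` the model is
#' returned unchanged with a warning.
#'
#' @param model A `traj_clusters` object.
#' @return The model with `labels` set (tibble `cluster`, `label`) and a
#'   `label` column available via [tidy.traj_clusters()].
#' @export
label_clusters <- function(model) {
  if (model$k != 3) {
    warn("semantic labels are defined for k = 3 only; returning indices.")
    return(model)
  }
  grid <- seq(0, 10, by = 0.1)
  levels_mean <- vapply(model$centroids, function(ct) {
    mean(eval_centroid(ct, grid))
  }, numeric(1))
  at0 <- vapply(model$centroids, function(ct) eval_centroid(ct, 0), numeric(1))
  at2 <- vapply(model$centroids, function(ct) eval_centroid(ct, 2), numeric(1))
  if (anyDuplicated(round(levels_mean, 10))) {
    warn("tied centroid levels; breaking ties by cluster index.")
  }
  idx <- seq_len(3)
  low <- idx[order(levels_mean, idx)[1]]
  rest <- setdiff(idx, low)
  rise <- (at0 - at2)[rest]
  accel <- rest[order(-rise, rest)[1]]
  high <- setdiff(rest, accel)
  lab <- tibble(
    cluster = c(low, accel, high),
    label = factor(c("stable_low", "accelerated", "persistently_high"),
                   levels = c("stable_low", "accelerated", "persistently_high"))
  ) |> dplyr::arrange(.data$cluster)
  model$labels <- lab
  model
}

#' @export
print.traj_clusters <- function(x, ...) {
  cat(sprintf(
    "<traj_clusters> k = %d, %d subjects, %d obs; objective %.4f, BIC %.1f%s\n",
    x$k, x$n_subjects, x$n_obs, x$objective, x$bic,
    if (!is.null(x$silhouette)) sprintf(", mean silhouette %.3f",
                                        x$silhouette$mean) else ""
  ))
  print(table(x$assignments$cluster))
  invisible(x)
}

#' Tidy per-subject cluster assignments
#'
#' @param x A `traj_clusters` object.
#' @param ... Unused.
#' @return Tibble `subject_id`, `cluster`, `distance_to_centroid`, and
#'   `label` when [label_clusters()] has been applied.
#' @method tidy traj_clusters
#' @export
tidy.traj_clusters <- function(x, ...) {
  out <- dplyr::mutate(x$assignments, distance_to_centroid =
                         x$distance_to_centroid)
  if (!is.null(x$labels)) out <- dplyr::left_join(out, x$labels, by = "cluster")
  out
}

#' One-row fit summary of a trajectory cluster model
#'
#' @param x A `traj_clusters` object.
#' @param ... Unused.
#' @method glance traj_clusters
#' @export
glance.traj_clusters <- function(x, ...) {
  tibble(
    k = x$k,
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    objective = x$objective,
    within_mse = x$within_mse$total,
    bic = x$bic,
    silhouette = if (!is.null(x$silhouette)) x$silhouette$mean else NA_real_,
    n_iterations = x$n_iterations,
    converged = x$converged,
    seed = x$seed
  )
}

#' Evaluate the fitted centroids on a time grid
#'
#' @param model A `traj_clusters` object.
#' @param times Evaluation grid in years before the procedure.
#' @return Tibble `cluster`, `years_before`, `value` (+ `label` if set).
#' @export
centroid_curves <- function(model, times = seq(0, 10, by = 0.1)) {
  out <- purrr::imap(model$centroids, function(ct, nm) {
    tibble(cluster = as.integer(nm), years_before = times,
           value = eval_centroid(ct, times))
  }) |> dplyr::bind_rows()
  if (!is.null(model$labels)) {
    out <- dplyr::left_join(out, model$labels, by = "cluster")
  }
  out
}
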