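#' Configuration for an end-to-end pipeline run
#'
#' Bundles the stage parameters of the full analysis: cohort generation,
#' screening validation, trajectory clustering, survival/reclassification,
#' and threshold timing. Unknown keys are rejected. The configuration can
#' also be read from a YAML or JSON file with [read_pipeline_config()].
#'
#' @param screening A [screening_config()].
#' @param trajectory A [trajectory_config()].
#' @param cutpoint Screening cutpoint; `NULL` (default) re-estimates it by
#'   Youden's index on the generated cohort.
#' @param prevalence_grid Prevalences for the projection table
#'   (default 1–5%).
#' @param k Cluster count for the trajectory stage (default 3).
#' @param k_range Candidates for cluster-number selection, or `NULL` to
#'   skip selection (default `NULL`).
#' @param n_start EM restarts (default 10).
#' @param horizons Reclassification horizons in years (default `c(1, 3)`).
#' @param risk_cutoffs NRI category boundaries.
#' @param n_boot Bootstrap resamples for reclassification CIs
#'   (default 1000).
#' @param crossing_thresholds Thresholds for first-crossing summaries.
#' @param proportion_times Years-before values for threshold-proportion
#'   summaries.
#' @param proportion_thresholds Thresholds for those proportions.
#' @param min_obs_crossing Minimum ECG count for the crossing subset
#'   (default 5).
#' @param seed Master seed; stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(screening = screening_config(),
                            trajectory = trajectory_config(),
                            cutpoint = NULL,
                            prevalence_grid = seq(0.01, 0.05, by = 0.01),
                            k = 3,
                            k_range = NULL,
                            n_start = 10,
                            horizons = c(1, 3),
                            risk_cutoffs = c(0.05, 0.075, 0.10),
                            n_boot = 1000,
                            crossing_thresholds = c(0.60, 0.70, 0.80),
                            proportion_times = c(0.5, 5),
                            proportion_thresholds = c(0.50, 0.70),
                            min_obs_crossing = 5,
                            seed = 1) {
  structure(
    list(
      screening = screening, trajectory = trajectory, cutpoint = cutpoint,
      prevalence_grid = prevalence_grid, k = k, k_range = k_range,
      n_start = n_start, horizons = horizons, risk_cutoffs = risk_cutoffs,
      n_boot = n_boot, crossing_thresholds = crossing_thresholds,
      proportion_times = proportion_times,
      proportion_thresholds = proportion_thresholds,
      min_obs_crossing = min_obs_crossing, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override [pipeline_config()] defaults; nested `screening`
#' and `trajectory` blocks override the corresponding generator defaults.
#' Unknown keys raise an error naming the key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("the yaml package is needed to read YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  top <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), top)
  if (length(unknown) > 0) {
    stop_invalid(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  args <- raw
  if (!is.null(raw$screening)) {
    ok <- names(formals(screening_config))
    bad <- setdiff(names(raw$screening), ok)
    if (length(bad) > 0) {
      stop_invalid(paste0("unknown screening keys: ", paste(bad, collapse = ", ")))
    }
    args$screening <- do.call(screening_config, lapply(raw$screening, unlist))
  }
  if (!is.null(raw$trajectory)) {
    ok <- names(formals(trajectory_config))
    bad <- setdiff(names(raw$trajectory), ok)
    if (length(bad) > 0) {
      stop_invalid(paste0("unknown trajectory keys: ", paste(bad, collapse = ", ")))
    }
    args$trajectory <- do.call(trajectory_config, lapply(raw$trajectory, unlist))
  }
  do.call(pipeline_config, args)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

#' Run the analysis pipeline
#'
#' Executes one stage or the whole chain
#' (`simulate -> screen -> cluster -> survival -> timing -> report`),
#' writing each stage's artifacts under `outdir`:
#' `scores.csv` / `subjects.csv` (simulate), `screening_report.json` /
#' `table1.csv` (screen), `clusters.csv` / `centroids.csv` /
#' `cluster_diagnostics.json` (cluster), `cox_models.json` /
#' `reclassification.json` / `calibration.csv` (survival),
#' `timing_report.json` (timing), and `manifest.json` + `report.json`
#' (report). Later stages read the CSV artifacts of earlier stages, so
#' stages can be re-run individually against existing outputs.
#'
#' @param command One of `"simulate"`, `"screen"`, `"cluster"`,
#'   `"survival"`, `"timing"`, `"report"`, `"all"`.
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param seed Optional override of the config's master seed.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(command = c("all", "simulate", "screen", "cluster",
                                     "survival", "timing", "report"),
                         config = pipeline_config(), outdir, seed = NULL) {
  command <- match.arg(command)
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("`config` must come from pipeline_config().")
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$screening$seed <- as.integer(seed)
    config$trajectory$seed <- as.integer(seed) + 1L
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (command == "all") {
    c("simulate", "screen", "cluster", "survival", "timing", "report")
  } else {
    command
  }
  paths <- list()
  for (st in stages) {
    t0 <- Sys.time()
    paths <- c(paths, switch(
      st,
      simulate = stage_simulate(config, outdir),
      screen = stage_screen(config, outdir),
      cluster = stage_cluster(config, outdir),
      survival = stage_survival(config, outdir),
      timing = stage_timing(config, outdir),
      report = stage_report(config, outdir)
    ))
    message(sprintf("[%s] done in %.1fs", st,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(paths)
}

read_stage_csv <- function(outdir, file, cols) {
  path <- file.path(outdir, file)
  if (!file.exists(path)) {
    stop_invalid(sprintf("missing input artifact `%s`; run earlier stages.",
                         file))
  }
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(cols, names(d))
  if (length(miss) > 0) {
    stop_invalid(sprintf("%s lacks column(s): %s", file,
                         paste(miss, collapse = ", ")))
  }
  d
}

stage_simulate <- function(config, outdir) {
  scr <- simulate_screening_cohort(config$screening)
  traj <- simulate_trajectory_cohort(config$trajectory)
  p1 <- file.path(outdir, "screening_cohort.csv")
  p2 <- file.path(outdir, "scores.csv")
  p3 <- file.path(outdir, "subjects.csv")
  write.csv(scr, p1, row.names = FALSE)
  write.csv(traj$scores, p2, row.names = FALSE)
  write.csv(traj$subjects, p3, row.names = FALSE)
  list(screening_cohort = p1, scores = p2, subjects = p3)
}

stage_screen <- function(config, outdir) {
  d <- read_stage_csv(outdir, "screening_cohort.csv",
                      c("score", "severity_class"))
  d$case <- d$severity_class == "moderate_severe"
  roc <- auroc(d, score, case, n_boot = min(config$n_boot, 2000),
               seed = config$seed)
  yc <- youden_cutpoint(d, score, case)
  cut <- config$cutpoint %||% yc$cutpoint
  cs <- confusion_summary(d, score, case, cut)
  prev_obs <- mean(d$case)
  proj <- prevalence_adjusted(cs$sensitivity, cs$specificity,
                              c(prev_obs, config$prevalence_grid))
  table1 <- dplyr::mutate(
    proj,
    row = c("observed", sprintf("%g%%", 100 * config$prevalence_grid)),
    dplyr::across(c("ppv", "npv", "positive_screen_rate"), ~ 100 * .x)
  ) |>
    dplyr::select("row", "prevalence", "ppv", "npv", "positive_screen_rate")
  prog <- lapply(c("as_hosp", "hf"), function(oc) {
    lapply(c(FALSE, TRUE), function(adj) {
      tidy(fp_prognosis(d, cut, outcome = oc, adjusted = adj))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rep <- list(
    auroc = as.list(roc),
    youden = as.list(yc[, c("cutpoint", "youden_j")]),
    cutpoint_used = cut,
    confusion = as.list(cs),
    observed_prevalence = prev_obs,
    projections = proj,
    fp_prognosis = prog
  )
  p1 <- file.path(outdir, "screening_report.json")
  p2 <- file.path(outdir, "table1.csv")
  write_json_artifact(rep, p1)
  write.csv(table1, p2, row.names = FALSE)
  list(screening_report = p1, table1 = p2)
}

stage_cluster <- function(config, outdir) {
  scores <- read_stage_csv(outdir, "scores.csv",
                           c("subject_id", "years_before", "score"))
  selection <- NULL
  k <- config$k
  if (!is.null(config$k_range)) {
    selection <- select_k(scores, k_range = config$k_range,
                          seeds_per_k = config$n_start, seed = config$seed)
    k <- selection$chosen_k
  }
  model <- cluster_trajectories(scores, k, seed = config$seed,
                                n_start = config$n_start)
  if (k == 3) model <- label_clusters(model)
  stab <- cluster_stability(scores, k, n_restarts = 5, n_boot = 5,
                            seed = config$seed)
  assignments <- tidy(model)
  p1 <- file.path(outdir, "clusters.csv")
  p2 <- file.path(outdir, "centroids.csv")
  p3 <- file.path(outdir, "cluster_diagnostics.json")
  write.csv(assignments, p1, row.names = FALSE)
  write.csv(centroid_curves(model), p2, row.names = FALSE)
  write_json_artifact(list(
    glance = as.list(glance(model)),
    selection = if (!is.null(selection)) selection$diagnostics,
    selection_disagreement = if (!is.null(selection)) selection$disagreement,
    stability = stab$summary,
    seeds = model$seeds_tried
  ), p3)
  list(clusters = p1, centroids = p2, cluster_diagnostics = p3)
}

stage_survival <- function(config, outdir) {
  subjects <- read_stage_csv(outdir, "subjects.csv",
                             c("subject_id", "time_years", "event"))
  clusters <- read_stage_csv(outdir, "clusters.csv", c("subject_id", "cluster"))
  lab_col <- if ("label" %in% names(clusters)) "label" else "cluster"
  d <- dplyr::left_join(subjects, clusters, by = "subject_id")
  d$cluster_label <- factor(d[[lab_col]])
  ladder <- fit_cox_ladder(d, cluster_col = "cluster_label")
  recl <- lapply(intersect(c("sts_score", "euroscore2"), names(d)),
                 function(sc) {
    reclassification_analysis(d, base_score = sc,
                              cluster_col = "cluster_label",
                              horizons = config$horizons,
                              cutoffs = config$risk_cutoffs,
                              n_boot = config$n_boot, seed = config$seed)
  }) |> dplyr::bind_rows()
  h_cal <- max(config$horizons)
  base_fit <- coxph(Surv(time_years, event) ~ log(sts_score) + cluster_label,
                    data = d, ties = "efron")
  d$pred <- predicted_mortality(base_fit, h_cal, newdata = d)
  cal <- calibration_table(d, pred, time_years, event, h_cal)
  p1 <- file.path(outdir, "cox_models.json")
  p2 <- file.path(outdir, "reclassification.json")
  p3 <- file.path(outdir, "calibration.csv")
  write_json_artifact(list(hr_table = tidy(ladder), fit_summary = glance(ladder)),
                      p1)
  write_json_artifact(recl, p2)
  write.csv(as.data.frame(cal), p3, row.names = FALSE)
  list(cox_models = p1, reclassification = p2, calibration = p3)
}

stage_timing <- function(config, outdir) {
  scores <- read_stage_csv(outdir, "scores.csv",
                           c("subject_id", "years_before", "score"))
  crossings <- lapply(config$crossing_thresholds, function(th) {
    first_crossing(scores, th, min_obs = config$min_obs_crossing)
  }) |> dplyr::bind_rows()
  grid <- expand.grid(threshold = config$proportion_thresholds,
                      at = config$proportion_times)
  props <- purrr::map2(grid$threshold, grid$at, function(th, at) {
    proportion_above(scores, th, at)
  }) |> dplyr::bind_rows()
  p <- file.path(outdir, "timing_report.json")
  write_json_artifact(list(first_crossings = crossings,
                           proportions_above = props), p)
  list(timing_report = p)
}

stage_report <- function(config, outdir) {
  artifact_names <- c("screening_report.json", "cluster_diagnostics.json",
                      "cox_models.json", "reclassification.json",
                      "timing_report.json")
  present <- artifact_names[file.exists(file.path(outdir, artifact_names))]
  collated <- lapply(setNames(present, sub("\\.json$", "", present)),
                     function(f) {
    jsonlite::read_json(file.path(outdir, f), simplifyVector = TRUE)
  })
  files <- setdiff(list.files(outdir), c("report.json", "manifest.json"))
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("avstraj")),
    artifacts = tibble(
      file = files,
      md5 = unname(tools::md5sum(file.path(outdir, files)))
    )
  )
  p1 <- file.path(outdir, "report.json")
  p2 <- file.path(outdir, "manifest.json")
  write_json_artifact(collated, p1)
  write_json_artifact(manifest, p2)
  list(report = p1, manifest = p2)
}
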