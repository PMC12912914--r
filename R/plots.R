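# ggplot2 display methods. The time axis is years before the procedure,
# plotted reversed so the procedure (t = 0) sits on the right.

#' Plot trajectories and fitted cluster centroids
#'
#' Spaghetti plot of the clustered trajectories (thin lines, one per
#' subject) with the fitted spline centroid of each cluster overlaid.
#'
#' @param object A `traj_clusters` object.
#' @param max_subjects Subsample at most this many subjects for the
#'   spaghetti layer (default 300).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot traj_clusters
#' @export
autoplot.traj_clusters <- function(object, max_subjects = 300, ...) {
  asg <- tidy(object)
  grp <- if ("label" %in% names(asg)) "label" else "cluster"
  ids <- unique(asg$subject_id)
  if (length(ids) > max_subjects) {
    ids <- sample(ids, max_subjects)
  }
  d <- dplyr::inner_join(object$scores, asg, by = "subject_id") |>
    dplyr::filter(.data$subject_id %in% ids) |>
    dplyr::mutate(.grp = factor(.data[[grp]]))
  cc <- centroid_curves(object) |>
    dplyr::mutate(.grp = factor(if (grp == "label") .data$label else
      .data$cluster))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$years_before, y = .data$score,
                                  colour = .data$.grp)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.15, linewidth = 0.3) +
    ggplot2::geom_line(data = cc, ggplot2::aes(y = .data$value),
                       linewidth = 1.2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Years before procedure", y = "AS score",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Plot cluster-number selection diagnostics
#'
#' @param object A `traj_k_selection` from [select_k()].
#' @param ... Unused.
#' @return A ggplot of BIC and mean silhouette against k.
#' @method autoplot traj_k_selection
#' @export
autoplot.traj_k_selection <- function(object, ...) {
  d <- tidyr::pivot_longer(object$diagnostics,
                           c("bic", "silhouette"),
                           names_to = "criterion", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "Number of clusters", y = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration plot of predicted versus observed mortality
#'
#' @param object A `calibration_table`.
#' @param ... Unused.
#' @return A ggplot with the identity line for reference.
#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = sprintf("Mean predicted %g-year mortality", attr(object, "horizon")),
      y = "Observed (Kaplan-Meier)"
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for the false-positive prognosis contrast
#'
#' @param x An `fp_prognosis` object.
#' @param ... Unused.
#' @return A ggplot of the two survival curves.
#' @export
plot_fp_survival <- function(x, ...) {
  sf <- x$km
  d <- tibble(
    time = sf$time,
    surv = sf$surv,
    group = rep(c("true_negative", "false_positive"), sf$strata)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(NA, 1)) +
    ggplot2::labs(x = "Years of follow-up", y = "Event-free proportion",
                  colour = "Screening group") +
    ggplot2::theme_minimal()
}
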