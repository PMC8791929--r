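#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier step curves
#'
#' @param object A `tp53_km` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tp53_km <- function(object, ...) {
  d <- tidy(object)
  # prepend t = 0, S = 1 per group for conventional curves
  d0 <- d |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, estimate = 1)
  dplyr::bind_rows(d0, d) |>
    ggplot2::ggplot(ggplot2::aes(
      .data$time, .data$estimate, colour = .data$group
    )) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Months", y = "Survival probability", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the CCF cutoff scan
#'
#' AUC over the CCF-threshold grid and horizons, faceted by endpoint;
#' significant grid points are outlined.
#'
#' @param object A `tp53_ccf_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tp53_ccf_scan <- function(object, ...) {
  d <- dplyr::filter(object$grid, !is.na(.data$auc),
                     .data$ccf_threshold <= 100)
  ggplot2::ggplot(d, ggplot2::aes(
    .data$horizon, .data$ccf_threshold, fill = .data$auc
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = dplyr::filter(d, .data$significant), size = 0.6
    ) +
    ggplot2::facet_wrap(~endpoint) +
    ggplot2::scale_fill_gradient2(
      midpoint = 0.5, low = "steelblue", mid = "white", high = "firebrick"
    ) +
    ggplot2::labs(
      x = "Horizon (months)", y = "CCF threshold (%)", fill = "AUC(t)"
    ) +
    ggplot2::theme_minimal()
}

#' Swimmer-style plot of TP53 status evolution
#'
#' One horizontal lane per paired patient, showing the detailed status at
#' diagnosis and relapse coloured by acquisition class.
#'
#' @param records Evolution records from [track_evolution()].
#' @return A ggplot.
#' @export
plot_evolution <- function(records) {
  d <- records |>
    dplyr::mutate(
      patient_id = stats::reorder(.data$patient_id,
                                  as.integer(.data$acquisition))
    ) |>
    tidyr::pivot_longer(
      c("status_dx", "status_rel"),
      names_to = "timepoint", values_to = "status"
    ) |>
    dplyr::mutate(
      timepoint = dplyr::if_else(.data$timepoint == "status_dx",
                                 "diagnosis", "relapse")
    )
  ggplot2::ggplot(d, ggplot2::aes(
    .data$timepoint, .data$patient_id, group = .data$patient_id,
    colour = .data$acquisition
  )) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status), size = 2) +
    ggplot2::labs(x = NULL, y = NULL, colour = "Transition",
                  shape = "TP53 status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
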