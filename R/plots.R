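#' Plot a closed-form observable scan
#'
#' Facets each observable of a [kin_scan()] tibble against force; scans
#' of several motors (row-bound) are overlaid by colour.
#'
#' @param object A `kin_scan` tibble.
#' @param vars Observable columns to facet (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(kin_scan("DmK", seq(0, 7.9, by = 0.1)))
#' @method autoplot kin_scan
#' @export
autoplot.kin_scan <- function(object,
                              vars = c("velocity_nm_s", "ratio",
                                       "randomness", "N",
                                       "power_kBT_s", "efficiency"),
                              ...) {
  long <- tidyr::pivot_longer(object, cols = dplyr::any_of(vars),
                              names_to = "observable")
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$force_pN, .data$value,
                               colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "Force (pN)", y = NULL, colour = "Motor") +
    ggplot2::theme_bw()
}

#' Plot a simulated stepping trace
#'
#' Staircase of the centre-of-mass position; under backward load the
#' bead-position series is overlaid.
#'
#' @param object A `kin_trace` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_trace
#' @export
autoplot.kin_trace <- function(object, ...) {
  bead <- bead_position_series(object)
  com <- object$com_samples
  p <- ggplot2::ggplot(com, ggplot2::aes(.data$time, .data$com_nm)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::labs(x = "Time (s)", y = "Position (nm)",
                  title = sprintf("%s, F = %g pN", object$params$name,
                                  object$conditions$force)) +
    ggplot2::theme_bw()
  if (object$conditions$force > 0) {
    p <- p + ggplot2::geom_step(
      data = bead, ggplot2::aes(.data$time, .data$position_nm),
      colour = "steelblue", alpha = 0.7)
  }
  p
}

#' Plot a force-velocity fit
#'
#' Data points (with error bars when uncertainties are present) and the
#' fitted model curve.
#'
#' @param object A `kin_fit` object from [fit_force_velocity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_fit
#' @export
autoplot.kin_fit <- function(object, ...) {
  stopifnot(grepl("force_velocity", object$model))
  d <- object$data
  full <- utils::modifyList(as.list(object$estimates), object$fixed)
  if (is.null(full$P0_zero)) full$P0_zero <- 1
  full <- utils::modifyList(full, list(name = "fit"))
  p_fit <- do.call(make_motor_params, full)
  grid <- tibble::tibble(
    force_pN = seq(min(d$force_pN), max(d$force_pN), length.out = 200))
  grid$velocity_nm_s <- kin_velocity(grid$force_pN, p_fit)
  g <- ggplot2::ggplot(d, ggplot2::aes(.data$force_pN,
                                       .data$velocity_nm_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Force (pN)", y = "Velocity (nm/s)") +
    ggplot2::theme_bw()
  if ("sigma_nm_s" %in% names(d)) {
    g <- g + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$velocity_nm_s - .data$sigma_nm_s,
                   ymax = .data$velocity_nm_s + .data$sigma_nm_s),
      width = 0.1)
  }
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
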