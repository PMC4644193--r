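# ggplot2 quick-look plots. Plots are conveniences, not part of the numeric
# surface of the package.

#' Plot a frequency-response curve
#'
#' Phase lag and modulation index versus angular frequency (log axis), with
#' error bars where standard deviations are present.
#'
#' @param object An [fd_response] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fd_response <- function(object, ...) {
  df <- as_tibble(object)
  long <- dplyr::bind_rows(
    tibble(freq_rad_s = df$freq_rad_s, value = df$phase_deg,
           sd = df$phase_sd %||% rep(NA_real_, nrow(df)),
           what = "phase (deg)"),
    tibble(freq_rad_s = df$freq_rad_s, value = df$mod,
           sd = df$mod_sd %||% rep(NA_real_, nrow(df)),
           what = "modulation index")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq_rad_s, y = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$what), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "angular frequency (rad/s)", y = NULL)
}

#' Plot per-harmonic estimates
#'
#' Modulation ratios (stems) and phase delays versus harmonic order.
#'
#' @param object A `harmonic_estimates` tibble from [harmonic_phases()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.harmonic_estimates <- function(object, ...) {
  df <- as_tibble(object)
  long <- dplyr::bind_rows(
    tibble(k = df$k, value = df$mod, sd = df$mod_sd, what = "mod ratio"),
    tibble(k = df$k, value = df$phase_deg, sd = df$phase_sd, what = "phase delay (deg)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$k, yend = 0),
                          data = ~ dplyr::filter(.x, .data$what == "mod ratio"),
                          alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$what), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "harmonic order k", y = NULL)
}

#' Plot driver and response waveforms
#'
#' @param driver,response [sampled_signal()] tibbles (response optional).
#' @return A ggplot object.
#' @export
plot_waveforms <- function(driver, response = NULL) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(driver), signal = "driver"),
    if (!is.null(response)) dplyr::mutate(as_tibble(response), signal = "response")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$value,
                                   colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}

#' Plot a lifetime fit against its data
#'
#' Observed phase (and modulation, if fitted) with the fitted model curve
#' evaluated on a dense grid.
#'
#' @param object A `lifetime_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lifetime_fit <- function(object, ...) {
  obs <- object$curve
  grid <- 10^seq(log10(min(obs$freq_rad_s)), log10(max(obs$freq_rad_s)),
                 length.out = 200)
  pred <- phase_mod(object$model, grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$freq_rad_s, y = .data$phase_deg)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_line(data = as_tibble(pred), colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "angular frequency (rad/s)", y = "phase lag (deg)")
}
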