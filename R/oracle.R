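# Brute-force numeric forward simulators. These are deliberately independent
# of the closed forms in closed_form.R: every analytic response is validated
# against this module.

# One single-pole stage: exact convolution of exp(-g t) with the
# piecewise-linear interpolant of `x` on a uniform grid of step dt.
# Returns the response sampled at the grid nodes, zero initial condition.
# Exact per step, so there is no stability constraint even when g*dt >> 1
# (the recursion then simply tracks the drive quasi-statically).
single_pole_step <- function(x, g, dt) {
  n <- length(x)
  E <- exp(-g * dt)
  I0 <- (1 - E) / g                       # int_0^dt e^{-g(dt-u)} du
  # int_0^dt e^{-g(dt-u)} (u/dt) du
  I1 <- I0 - (1 - E - E * g * dt) / (g^2 * dt)
  w <- x[-n] * (I0 - I1) + x[-1] * I1     # per-step source term
  out <- stats::filter(w, filter = E, method = "recursive")
  c(0, as.numeric(out))
}

#' Convolution response of a multi-exponential model (numeric oracle)
#'
#' Forward-simulates the fluorescence response to an arbitrary sampled drive
#' as the convolution of the drive with the impulse response
#' \eqn{\sum_k f_k e^{-\Gamma_k t}} (zero initial populations). The
#' implementation is an exponential-integrator recursion that is exact for a
#' piecewise-linear drive, so it is second-order accurate in the sampling of
#' the true drive and unconditionally stable across widely separated rates.
#' The DC gain is \eqn{\sum_k f_k/\Gamma_k}.
#'
#' @param model A [multiexp_model()]. The fractions are used directly as the
#'   impulse-response weights of the components.
#' @param drive A [sampled_signal()] excitation waveform.
#' @return A [sampled_signal()] response on the same time grid.
#' @export
convolve_response <- function(model, drive) {
  if (!inherits(model, "multiexp_model")) abort("`model` must be a multiexp_model.")
  if (is.null(drive) || nrow(drive) == 0L) abort("`drive` must be a non-empty sampled signal.")
  if (!inherits(drive, "sampled_signal")) drive <- sampled_signal(drive$t_s, drive$value)
  dt <- signal_dt(drive)
  tau_min <- min(model$components$lifetime_s)
  if (dt > tau_min / 20) {
    warn(sprintf(
      "Drive step dt = %.3g s under-resolves the fastest lifetime (%.3g s); results may lose accuracy.",
      dt, tau_min))
  }
  out <- numeric(nrow(drive))
  for (i in seq_len(nrow(model$components))) {
    out <- out + model$components$fraction[i] *
      single_pole_step(drive$value, model$components$rate[i], dt)
  }
  sampled_signal(drive$t_s, out)
}

#' Integrate the full three-level rate equations (numeric oracle)
#'
#' Integrates the complete linear system for the three level populations,
#' including ground-state depletion (no weak-pumping assumption):
#' \deqn{\dot n_1 = \Gamma_{31} n_3 + \Gamma_{21} n_2 - \Gamma_{13}(t) n_1}
#' \deqn{\dot n_2 = \Gamma_{32} n_3 - \Gamma_{21} n_2}
#' \deqn{\dot n_3 = -(\Gamma_{31} + \Gamma_{32}) n_3 + \Gamma_{13}(t) n_1}
#' The drive signal supplies the time-varying pump rate
#' \eqn{\Gamma_{13}(t)}, interpolated linearly between samples. Total
#' population is conserved exactly by the equations and to integrator
#' tolerance by the solver (a stiff-capable method, since the rates can span
#' many decades).
#'
#' @param m A [three_level_model()] (initial populations are taken from it).
#' @param drive_gamma13 A [sampled_signal()] of pump rates (1/s, nonnegative).
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `t_s`, `n1`, `n2`, `n3` on the drive grid.
#' @export
three_level_integrate <- function(m, drive_gamma13, rtol = 1e-10, atol = 1e-12) {
  if (!inherits(m, "three_level_model")) abort("`m` must be a three_level_model.")
  if (!inherits(drive_gamma13, "sampled_signal")) {
    drive_gamma13 <- sampled_signal(drive_gamma13$t_s, drive_gamma13$value)
  }
  if (any(drive_gamma13$value < 0)) abort("Pump rate drive must be nonnegative.")
  g13 <- approxfun(drive_gamma13$t_s, drive_gamma13$value, rule = 2)
  deriv <- function(t, y, parms) {
    p <- g13(t)
    list(c(
      m$gamma_31 * y[3] + m$gamma_21 * y[2] - p * y[1],
      m$gamma_32 * y[3] - m$gamma_21 * y[2],
      -(m$gamma_31 + m$gamma_32) * y[3] + p * y[1]
    ))
  }
  y0 <- c(n1 = m$n1_0, n2 = m$n2_0, n3 = m$n3_0)
  sol <- try(deSolve::lsoda(y0, drive_gamma13$t_s, deriv, parms = NULL,
                            rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < nrow(drive_gamma13)) {
    abort(sprintf(
      "Three-level integration failed (stiffest rate %.3g /s); try a finer drive grid.",
      max(m$gamma_21, m$gamma_31 + m$gamma_32, max(drive_gamma13$value))))
  }
  tibble(t_s = drive_gamma13$t_s, n1 = sol[, "n1"], n2 = sol[, "n2"],
         n3 = sol[, "n3"])
}
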