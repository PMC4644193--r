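#' Multi-exponential fluorophore model
#'
#' A fluorophore whose emission decays as a weighted sum of single-exponential
#' components. In the frequency domain each component is a single-pole low-pass
#' filter, and the whole model has transfer function
#' \eqn{F(i\omega) = \sum_k f_k / (1 + i\omega\tau_k)} where the fractions
#' \eqn{f_k} are the DC (low-frequency) amplitude weights of the components.
#'
#' Fractions are not forced to sum to one; [phase_mod()] normalizes by the DC
#' value so only their ratios matter for phase and modulation.
#'
#' @param fractions Either a numeric vector of nonnegative component weights,
#'   or a data frame with columns `fraction` and `lifetime_s`.
#' @param lifetimes_s Numeric vector of component lifetimes in seconds
#'   (ignored when `fractions` is a data frame).
#' @param rel_tol Relative tolerance below which two lifetimes are considered
#'   indistinct (fit identifiability guard).
#'
#' @return An object of class `multiexp_model` with a `components` tibble
#'   (`fraction`, `lifetime_s`, `rate`, the rate being \eqn{\Gamma_k = 1/\tau_k}).
#' @examples
#' m <- multiexp_model(c(0.9, 0.1), c(1, 0.001))
#' phase_mod(m, omega = 10^seq(-2, 4, length.out = 7))
#' @export
multiexp_model <- function(fractions, lifetimes_s = NULL, rel_tol = 1e-6) {
  if (is.data.frame(fractions)) {
    comp <- fractions
    if (!all(c("fraction", "lifetime_s") %in% names(comp))) {
      abort("Component data frame needs columns `fraction` and `lifetime_s`.")
    }
    fractions <- comp$fraction
    lifetimes_s <- comp$lifetime_s
  }
  if (length(fractions) < 1L || length(fractions) != length(lifetimes_s)) {
    abort("Need at least one component, with matching `fractions` and `lifetimes_s`.")
  }
  if (!all(is.finite(lifetimes_s)) || any(lifetimes_s <= 0)) {
    abort("All lifetimes must be finite and strictly positive.")
  }
  if (!all(is.finite(fractions)) || any(fractions < 0)) {
    abort("All fractions must be finite and nonnegative.")
  }
  if (!any(fractions > 0)) {
    abort("At least one fraction must be positive.")
  }
  tau <- sort(lifetimes_s)
  if (length(tau) > 1L && any(diff(tau) / tau[-length(tau)] < rel_tol)) {
    abort("Lifetimes must be pairwise distinct (within `rel_tol`) for identifiability.")
  }
  structure(
    list(components = tibble(
      fraction = as.numeric(fractions),
      lifetime_s = as.numeric(lifetimes_s),
      rate = 1 / as.numeric(lifetimes_s)
    )),
    class = "multiexp_model"
  )
}

#' @export
print.multiexp_model <- function(x, ...) {
  cat("<multiexp_model> with", nrow(x$components), "component(s)\n")
  print(x$components)
  invisible(x)
}

#' Three-level fluorescence system
#'
#' Pump (rate `gamma_13`) from the ground level 1 into level 3, fast relaxation
#' `gamma_32` into the emitting level 2, slow radiative return `gamma_21` to
#' ground, and an optional direct leak `gamma_31`. The fluorescence signal is
#' proportional to the level-2 population.
#'
#' @param gamma_13 Drive coupling rate (1/s), baseline value; the numeric
#'   oracle accepts a time-varying drive that scales this path.
#' @param gamma_21,gamma_31,gamma_32 Relaxation rates (1/s); `gamma_21` and
#'   `gamma_32` must be positive (the fluorescence path must exist).
#' @param n1_0,n2_0,n3_0 Initial level populations (dimensionless, >= 0).
#' @return An object of class `three_level_model`.
#' @examples
#' tl <- three_level_model(gamma_13 = 0.01, gamma_21 = 1, gamma_31 = 0, gamma_32 = 1e6)
#' three_level_transfer(tl)
#' @export
three_level_model <- function(gamma_13 = 0, gamma_21, gamma_31 = 0, gamma_32,
                              n1_0 = 1, n2_0 = 0, n3_0 = 0) {
  for (nm in c("gamma_13", "gamma_21", "gamma_31", "gamma_32",
               "n1_0", "n2_0", "n3_0")) {
    stopifnot_scalar(get(nm), nm, nonneg = TRUE)
  }
  if (gamma_21 <= 0 || gamma_32 <= 0) {
    abort("`gamma_21` and `gamma_32` must be > 0: the fluorescence path must exist.")
  }
  structure(
    list(gamma_13 = gamma_13, gamma_21 = gamma_21, gamma_31 = gamma_31,
         gamma_32 = gamma_32, n1_0 = n1_0, n2_0 = n2_0, n3_0 = n3_0),
    class = "three_level_model"
  )
}

#' @export
print.three_level_model <- function(x, ...) {
  cat("<three_level_model>\n")
  cat(sprintf("  gamma_13 = %g  gamma_21 = %g  gamma_31 = %g  gamma_32 = %g\n",
              x$gamma_13, x$gamma_21, x$gamma_31, x$gamma_32))
  cat(sprintf("  initial populations: n1 = %g, n2 = %g, n3 = %g\n",
              x$n1_0, x$n2_0, x$n3_0))
  invisible(x)
}

#' Pole-zero linear filter
#'
#' A rational transfer function \eqn{H(s) = g \prod_j (s - z_j) / \prod_j (s - p_j)}.
#' All poles must lie in the closed left half-plane (stability).
#'
#' @param gain Real gain factor.
#' @param poles Complex (or real) vector of poles, in rad/s.
#' @param zeros Complex (or real) vector of zeros, in rad/s.
#' @return An object of class `linear_filter`.
#' @examples
#' lp <- linear_filter(gain = 1, poles = -1)   # single-pole low-pass, DC gain 1
#' phase_mod(lp, omega = 1)                    # 45 degrees, 1/sqrt(2)
#' @export
linear_filter <- function(gain = 1, poles = complex(0), zeros = complex(0)) {
  stopifnot_scalar(gain, "gain")
  poles <- as.complex(poles)
  zeros <- as.complex(zeros)
  if (any(Re(poles) > 0)) {
    abort("All poles must have nonpositive real part (stable filter).")
  }
  structure(list(gain = gain, poles = poles, zeros = zeros),
            class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  cat("<linear_filter>\n")
  cat("  gain :", format(x$gain), "\n")
  cat("  poles:", if (length(x$poles)) paste(format(x$poles), collapse = ", ") else "(none)", "\n")
  cat("  zeros:", if (length(x$zeros)) paste(format(x$zeros), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Evaluate a transfer function at angular frequencies
#'
#' Evaluates the complex transfer function of a model at `s = i*omega`.
#'
#' @param x A `multiexp_model`, `linear_filter`, or `three_level_model`.
#' @param omega Numeric vector of angular frequencies (rad/s); may be negative.
#' @return Complex vector, one value per `omega`.
#' @examples
#' transfer_eval(multiexp_model(1, 1), 1)  # 0.5 - 0.5i
#' @export
transfer_eval <- function(x, omega) UseMethod("transfer_eval")

#' @rdname transfer_eval
#' @export
transfer_eval.multiexp_model <- function(x, omega) {
  if (!is.numeric(omega) || !all(is.finite(omega))) {
    abort("`omega` must be finite and real.")
  }
  f <- x$components$fraction
  tau <- x$components$lifetime_s
  # sum_k f_k / (1 + i*omega*tau_k); rows = components, cols = omega
  denom <- 1 + 1i * outer(tau, omega)
  as.vector(colSums(f / denom))
}

#' @rdname transfer_eval
#' @export
transfer_eval.linear_filter <- function(x, omega) {
  if (!is.numeric(omega) || !all(is.finite(omega))) {
    abort("`omega` must be finite and real.")
  }
  s <- 1i * omega
  num <- rep(as.complex(x$gain), length(omega))
  for (z in x$zeros) num <- num * (s - z)
  den <- rep(1 + 0i, length(omega))
  for (p in x$poles) den <- den * (s - p)
  if (any(Mod(den) == 0)) {
    abort("Transfer function has a pole on the imaginary axis at a requested omega.")
  }
  num / den
}

#' @rdname transfer_eval
#' @export
transfer_eval.three_level_model <- function(x, omega) {
  transfer_eval(three_level_transfer(x), omega)
}

#' Phase lag and modulation index of a model
#'
#' For each angular frequency, computes the phase lag of the response behind
#' the excitation (reported positive, the frequency-domain fluorescence
#' plotting convention) and the modulation index, i.e. \eqn{|F(i\omega)|}
#' normalized to the DC value so that `mod` is 1 at \eqn{\omega = 0}. For a
#' single lifetime, \eqn{\tan\Phi = \omega\tau} and
#' \eqn{Mod = 1/\sqrt{1 + (\omega\tau)^2}}.
#'
#' For `linear_filter` objects the phase is accumulated pole by pole (and zero
#' by zero), so cascades report an unwrapped lag that can exceed 90 degrees —
#' 180 degrees for a two-pole system, and up to `90 * n` for `n` stages.
#'
#' @inheritParams transfer_eval
#' @param omega Numeric vector of angular frequencies (rad/s), each >= 0.
#' @return An [fd_response] tibble with columns `freq_rad_s`, `phase_deg`, `mod`.
#' @examples
#' phase_mod(multiexp_model(1, 1), c(0, 1))   # 0 and 45 degrees
#' @export
phase_mod <- function(x, omega) UseMethod("phase_mod")

#' @export
phase_mod.multiexp_model <- function(x, omega) {
  if (any(omega < 0)) abort("`omega` must be >= 0 for phase_mod().")
  F0 <- sum(x$components$fraction)
  if (F0 == 0) abort("Invalid model: all fractions are zero, |F(0)| = 0.")
  Fv <- transfer_eval(x, omega)
  fd_response(tibble(
    freq_rad_s = as.numeric(omega),
    phase_deg = -deg(Arg(Fv)),
    mod = Mod(Fv) / F0
  ))
}

#' @export
phase_mod.linear_filter <- function(x, omega) {
  if (any(omega < 0)) abort("`omega` must be >= 0 for phase_mod().")
  H0 <- transfer_eval(x, 0)
  if (Mod(H0) == 0 || !is.finite(Mod(H0))) {
    abort("Cannot normalize modulation: |H(0)| is zero or infinite (pole/zero at origin).")
  }
  # unwrapped lag: sum of per-pole arctan contributions minus per-zero ones
  s <- 1i * omega
  lag <- numeric(length(omega))
  for (p in x$poles) lag <- lag + Arg(s - p) - Arg(-p)
  for (z in x$zeros) lag <- lag - (Arg(s - z) - Arg(-z))
  Hv <- transfer_eval(x, omega)
  fd_response(tibble(
    freq_rad_s = as.numeric(omega),
    phase_deg = deg(lag),
    mod = Mod(Hv) / Mod(H0)
  ))
}

#' @export
phase_mod.three_level_model <- function(x, omega) {
  phase_mod(three_level_transfer(x), omega)
}

#' Transfer function of the three-level system
#'
#' Under weak pumping (undepleted ground level), the level-2 population
#' responds to the drive through a second-order low-pass filter with gain
#' `gamma_32` and poles at `-gamma_21` and `-(gamma_31 + gamma_32)`. Turn-on
#' transient terms (initial populations) are not part of the transfer
#' function; they are retained only in the time-domain oracle
#' ([three_level_integrate()]).
#'
#' When `gamma_32 >> gamma_21` the second pole lies far beyond the measurement
#' band and its wing cancels the `gamma_32` gain, collapsing the response onto
#' the familiar single-pole low-pass; for comparable rates the two stages
#' cascade and the phase lag extends up to 180 degrees.
#'
#' @param m A [three_level_model()].
#' @return A [linear_filter()].
#' @export
three_level_transfer <- function(m) {
  if (!inherits(m, "three_level_model")) abort("`m` must be a three_level_model.")
  if (m$gamma_21 <= 0 || m$gamma_32 <= 0) {
    abort("Invalid model: gamma_21 and gamma_32 must be positive.")
  }
  linear_filter(gain = m$gamma_32,
                poles = c(-m$gamma_21, -(m$gamma_31 + m$gamma_32)))
}

#' Cascade linear filters
#'
#' The transfer function of the chain driver -> fluorophore -> detector is the
#' product of the member transfer functions: gains multiply and pole/zero
#' lists concatenate, so the cascade phase lag is the sum of the member lags.
#'
#' @param ... `linear_filter` objects, or a single list of them.
#' @return A [linear_filter()].
#' @examples
#' lp <- linear_filter(1, poles = -1)
#' phase_mod(cascade(lp, lp), omega = 1)$phase_deg  # 90
#' @export
cascade <- function(...) {
  filters <- list(...)
  if (length(filters) == 1L && is.list(filters[[1]]) &&
      !inherits(filters[[1]], "linear_filter")) {
    filters <- filters[[1]]
  }
  if (length(filters) == 0L) abort("Cannot cascade an empty list of filters.")
  ok <- vapply(filters, inherits, logical(1), what = "linear_filter")
  if (!all(ok)) abort("All arguments to cascade() must be linear_filter objects.")
  linear_filter(
    gain = prod(vapply(filters, function(f) f$gain, numeric(1))),
    poles = do.call(c, lapply(filters, function(f) f$poles)),
    zeros = do.call(c, lapply(filters, function(f) f$zeros))
  )
}

#' Circuit-equivalent lifetime of an RC low-pass stage
#'
#' Maps a single resistor-capacitor low-pass stage to the fluorescence
#' lifetime it emulates: \eqn{\tau = 2\pi R C}.
#'
#' @param resistance_ohm Resistance in ohms (> 0). Vectorized.
#' @param capacitance_f Capacitance in farads (> 0). Vectorized.
#' @return Lifetime(s) in seconds.
#' @examples
#' lifetime_from_rc(159e3, 1e-6)   # ~ 1 s
#' @export
lifetime_from_rc <- function(resistance_ohm, capacitance_f) {
  if (!is.numeric(resistance_ohm) || !is.numeric(capacitance_f) ||
      any(!is.finite(resistance_ohm)) || any(!is.finite(capacitance_f)) ||
      any(resistance_ohm <= 0) || any(capacitance_f <= 0)) {
    abort("Resistance and capacitance must be finite and > 0.")
  }
  2 * pi * resistance_ohm * capacitance_f
}

#' RC stage presets for the two-stage low-pass phase curves
#'
#' Component values for the cascaded two-stage low-pass circuit whose phase
#' response emulates the three-level system: a slow first stage with a
#' 2-pi-R-C lifetime of 1 s, and two alternative fast second stages. The two
#' circulated labellings of the fast stages (as curve "a" vs curve "b") are
#' mutually inconsistent between the component values and the quoted fast
#' rates, so both parameter sets are exposed here without asserting which
#' label is correct; `fast_rate_per_s` is simply `1 / (2*pi*R*C)` for each set.
#'
#' @return A tibble with columns `stage`, `r_ohm`, `c_f`, `lifetime_s`,
#'   `fast_rate_per_s`.
#' @export
rc_stage_presets <- function() {
  tbl <- tibble(
    stage = c("slow_stage_1", "fast_stage_alt1", "fast_stage_alt2"),
    r_ohm = c(159e3, 1.6e3, 0.159),
    c_f = c(1e-6, 100e-9, 10e-12)
  )
  tbl$lifetime_s <- lifetime_from_rc(tbl$r_ohm, tbl$c_f)
  tbl$fast_rate_per_s <- 1 / tbl$lifetime_s
  tbl
}

#' Phase/modulation frequency-response table
#'
#' A tibble subclass holding a frequency response: strictly increasing-or-
#' equal-frequency rows are not enforced (the constructor sorts), but lengths
#' must match, modulation must lie in `[0, 1 + eps]`, and phases must be
#' finite. Optional per-point standard deviations `phase_sd`, `mod_sd`.
#'
#' @param x A data frame with columns `freq_rad_s`, `phase_deg`, `mod` and
#'   optionally `phase_sd`, `mod_sd`.
#' @param mod_eps Slack allowed above 1 for the modulation index (noise).
#' @return The input as a sorted tibble of class `fd_response`.
#' @export
fd_response <- function(x, mod_eps = 1e-6) {
  x <- as_tibble(x)
  need <- c("freq_rad_s", "phase_deg", "mod")
  if (!all(need %in% names(x))) {
    abort("fd_response needs columns freq_rad_s, phase_deg, mod.")
  }
  if (!all(is.finite(x$phase_deg))) abort("Phases must be finite.")
  if (any(x$mod < 0 | x$mod > 1 + mod_eps, na.rm = TRUE)) {
    abort("Modulation index must lie in [0, 1 + eps].")
  }
  x <- dplyr::arrange(x, .data$freq_rad_s)
  class(x) <- c("fd_response", class(x))
  x
}
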