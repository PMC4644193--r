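#' Parametric periodic excitation specification
#'
#' Describes a drive waveform: `delta` (single-sample impulse), `sine`
#' (bias + A sin), `biased_cosine` (`A (1 - cos)/2`, touching zero),
#' `square_biased` (bias + A * sign square, default swinging 0 to 2A), or
#' `pulse_train` (rectangular pulses of height A and width `duty` periods).
#' Realized excitation must be nonnegative everywhere — there is no negative
#' population in an excited state, so negative-going drives are rejected.
#'
#' @param kind One of `"delta"`, `"sine"`, `"biased_cosine"`,
#'   `"square_biased"`, `"pulse_train"`.
#' @param freq_hz Fundamental frequency in Hz (> 0; not used for `delta`).
#' @param amplitude Drive amplitude A (>= 0), linear units.
#' @param bias Additive bias (>= 0). Defaults to `amplitude` for `sine` and
#'   `square_biased` (so the drive touches zero), 0 otherwise.
#' @param duty Duty cycle in (0, 1); required for (and only for) `pulse_train`.
#' @return An object of class `drive_spec` (omega in rad/s is derived).
#' @examples
#' drive_spec("square_biased", freq_hz = 10)
#' drive_spec("pulse_train", freq_hz = 250, duty = 0.1)
#' @export
drive_spec <- function(kind, freq_hz = NULL, amplitude = 1, bias = NULL,
                       duty = NULL) {
  kind <- match.arg(kind, c("delta", "sine", "biased_cosine", "square_biased",
                            "pulse_train"))
  stopifnot_scalar(amplitude, "amplitude", nonneg = TRUE)
  if (kind != "delta") {
    stopifnot_scalar(freq_hz, "freq_hz", positive = TRUE)
  }
  if (is.null(bias)) {
    bias <- if (kind %in% c("sine", "square_biased")) amplitude else 0
  }
  stopifnot_scalar(bias, "bias", nonneg = TRUE)
  if (kind == "pulse_train") {
    stopifnot_scalar(duty, "duty", positive = TRUE)
    if (duty >= 1) abort("`duty` must lie in (0, 1).")
  } else if (!is.null(duty)) {
    abort("`duty` is only meaningful for kind = \"pulse_train\".")
  }
  if (kind %in% c("sine", "square_biased") && bias < amplitude) {
    abort("Negative-going drive: `bias` must be >= `amplitude` so the excitation stays nonnegative.")
  }
  structure(
    list(kind = kind, freq_hz = freq_hz,
         omega = if (is.null(freq_hz)) NULL else hz_to_rad(freq_hz),
         amplitude = amplitude, bias = bias, duty = duty),
    class = "drive_spec"
  )
}

#' @export
print.drive_spec <- function(x, ...) {
  cat("<drive_spec>", x$kind)
  if (!is.null(x$freq_hz)) cat(sprintf(" @ %g Hz", x$freq_hz))
  cat(sprintf(", amplitude %g, bias %g", x$amplitude, x$bias))
  if (!is.null(x$duty)) cat(sprintf(", duty %g", x$duty))
  cat("\n")
  invisible(x)
}

#' Uniformly sampled signal
#'
#' A two-column tibble (`t_s`, `value`) of class `sampled_signal`, sampled on
#' a uniform grid.
#'
#' @param t_s Sample times in seconds (uniformly spaced, length >= 2).
#' @param value Real sample values (finite).
#' @return A `sampled_signal` tibble.
#' @export
sampled_signal <- function(t_s, value) {
  if (length(t_s) < 2L || length(t_s) != length(value)) {
    abort("Need at least 2 samples and matching `t_s`/`value` lengths.")
  }
  if (!all(is.finite(value)) || !all(is.finite(t_s))) {
    abort("Sample times and values must be finite.")
  }
  dt <- diff(t_s)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]) || dt[1] <= 0) {
    abort("`t_s` must be a uniformly spaced, increasing grid.")
  }
  out <- tibble(t_s = as.numeric(t_s), value = as.numeric(value))
  class(out) <- c("sampled_signal", class(out))
  out
}

# dt of a sampled signal (validated uniform at construction)
signal_dt <- function(sig) sig$t_s[2] - sig$t_s[1]
signal_fs <- function(sig) 1 / signal_dt(sig)

#' Generate a sampled drive waveform
#'
#' Samples the excitation described by a [drive_spec()] on a uniform grid.
#' Rectangular edges (square, pulse train) are aligned to sample boundaries:
#' the pulse width of a `pulse_train` is rounded to the nearest whole sample,
#' so one exact period contains `round(duty * fs / freq)` nonzero samples.
#' The `delta` kind realizes an impulse of area `amplitude` as a single
#' nonzero sample of value `amplitude * fs` one sample after the start.
#'
#' @param spec A [drive_spec()].
#' @param fs Sampling rate in Hz.
#' @param duration Duration in seconds. For later FFT analysis this should
#'   cover an integer number of fundamental periods; a warning is issued
#'   otherwise.
#' @param t0 Start time (default 0).
#' @return A [sampled_signal()] tibble.
#' @export
generate_drive <- function(spec, fs, duration, t0 = 0) {
  if (!inherits(spec, "drive_spec")) abort("`spec` must be a drive_spec.")
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  n <- round(fs * duration)
  if (n < 2) abort("Duration too short: need at least 2 samples.")
  t <- t0 + (seq_len(n) - 1) / fs
  if (spec$kind != "delta") {
    n_cycles <- duration * spec$freq_hz
    if (abs(n_cycles - round(n_cycles)) > 1e-9) {
      warn(sprintf(
        "Duration covers %.6g fundamental cycles (non-integer); FFT analysis of this record will leak.",
        n_cycles))
    }
  }
  value <- switch(
    spec$kind,
    delta = {
      # one-sample impulse, placed one sample in so that its piecewise-linear
      # triangle (width 2/fs, peak amplitude*fs) integrates to exactly
      # `amplitude` on the grid
      v <- numeric(n)
      v[2] <- spec$amplitude * fs
      v
    },
    sine = spec$bias + spec$amplitude * sin(spec$omega * (t - t0)),
    biased_cosine = spec$amplitude * (1 - cos(spec$omega * (t - t0))) / 2,
    square_biased = {
      frac <- ((t - t0) * spec$freq_hz) %% 1
      # samples landing exactly on an edge can round to 1 - eps or 0.5 - eps;
      # snap them so edges are classified consistently
      frac[1 - frac < 1e-9] <- 0
      frac[abs(frac - 0.5) < 1e-9] <- 0.5
      spec$bias + spec$amplitude * ifelse(frac < 0.5, 1, -1)
    },
    pulse_train = {
      spc <- fs / spec$freq_hz               # samples per period
      m <- round(spec$duty * spc)            # on-samples, edge-aligned
      if (m < 1) abort("Sampling rate too low: pulse width rounds to zero samples.")
      j <- seq_len(n) - 1
      ifelse((j %% spc) < m, spec$amplitude, 0)
    }
  )
  if (any(value < 0)) abort("Generated drive goes negative; excitation must be nonnegative.")
  sampled_signal(t, value)
}

#' Harmonic amplitude envelope of a duty-cycle pulse train
#'
#' Continuous-time Fourier magnitude of harmonic `k` of a unit-height
#' rectangular pulse train with duty cycle `D`:
#' \eqn{Mod_k = D\,|\sin(\pi k D)/(\pi k D)|}. A harmonic is exactly nulled
#' whenever `k * D` is an integer — for `D = 1/10`, every tenth harmonic; for
#' the square wave `D = 1/2`, every even harmonic.
#'
#' @param duty Duty cycle in (0, 1).
#' @param k Harmonic order(s), integer >= 1. Vectorized.
#' @return Dimensionless amplitude(s) (the DC term, `k = 0`, would be `D`).
#' @export
pulse_train_harmonic_mod <- function(duty, k) {
  stopifnot_scalar(duty, "duty", positive = TRUE)
  if (duty >= 1) abort("`duty` must lie in (0, 1).")
  check_order(k)
  x <- k * duty
  out <- duty * abs(sin(pi * x) / (pi * x))
  out[abs(x - round(x)) < 1e-9] <- 0
  out
}

#' Harmonic phase law of a duty-cycle pulse train
#'
#' The phase delay of harmonic peak `k` of a rectangular pulse train is
#' linear in the order: \eqn{\Phi_k = \pi k D} (in degrees, `180 * k * duty`),
#' a slope of `180 * duty` degrees per harmonic. The phase is undefined at
#' nulled harmonics (`k * D` integer); requesting one is an error.
#'
#' @inheritParams pulse_train_harmonic_mod
#' @param wrap `"none"` for the unwrapped linear law, or `"pm90"` to map into
#'   (-90, 90] degrees, the arctangent-compatible plotting convention that
#'   gives the phase-vs-order graph its sawtooth look.
#' @return Phase delay(s) in degrees.
#' @export
pulse_train_harmonic_phase <- function(duty, k, wrap = c("none", "pm90")) {
  stopifnot_scalar(duty, "duty", positive = TRUE)
  if (duty >= 1) abort("`duty` must lie in (0, 1).")
  check_order(k)
  wrap <- match.arg(wrap)
  x <- k * duty
  if (any(abs(x - round(x)) < 1e-9)) {
    abort("Phase is undefined at nulled harmonics (k * duty is an integer).")
  }
  phi <- 180 * x
  if (wrap == "pm90") phi <- wrap_deg(phi, 180)
  phi
}

# map phase into (-period/2, period/2]
wrap_deg <- function(phi, period = 360) {
  out <- phi %% period
  out[out > period / 2] <- out[out > period / 2] - period
  out
}

check_order <- function(k) {
  if (length(k) < 1L || any(!is.finite(k)) || any(k < 1) ||
      any(abs(k - round(k)) > 0)) {
    abort("Harmonic order `k` must be integer(s) >= 1.")
  }
}

#' Fundamental advantage of square-wave over sine driving
#'
#' The Fourier fundamental of a unit square wave has amplitude `4/pi`, about
#' 27 % more intense than a unit sine running from the same supply rails.
#'
#' @return A tibble with `ratio` (`4/pi`) and `excess_percent`
#'   (`100 * (4/pi - 1)`).
#' @export
square_fundamental_gain <- function() {
  tibble(ratio = 4 / pi, excess_percent = 100 * (4 / pi - 1))
}

#' Relative harmonic amplitudes of a square wave
#'
#' Odd harmonics only, weighted by the inverse of the order (`1/k`,
#' normalized to 1 at the fundamental); even orders are absent.
#'
#' @param k Harmonic order(s), integer >= 1. Vectorized.
#' @return Relative amplitude(s).
#' @export
square_harmonic_amplitude <- function(k) {
  check_order(k)
  ifelse(k %% 2 == 1, 1 / k, 0)
}

#' One-sided harmonic content of a sampled periodic signal
#'
#' FFT-based harmonic table for a record covering an integer number of
#' fundamental periods (rectangular window on exact cycles). Amplitudes are
#' complex-exponential coefficient magnitudes `|X_k| / N` (so a unit-height
#' duty-`D` pulse train gives `D |sinc(pi k D)|`, and `sin(omega t)` gives
#' 1/2 at `k = 1`); phases are lags in degrees, positive for a waveform
#' delayed relative to a cosine-aligned reference.
#'
#' With `edge_correct = TRUE` (default) the phase of each harmonic is
#' advanced by `180 * k / N` degrees, compensating the half-sample offset
#' between sample-aligned rectangle edges and the continuous-time rectangle
#' starting at t = 0; with it, a duty-`D` pulse train with integer `D * N`
#' reproduces the continuous law `180 * k * D` exactly.
#'
#' @param sig A [sampled_signal()].
#' @param fundamental_hz Fundamental frequency of the record in Hz; the
#'   record length must be an integer number of periods and each period an
#'   integer number of samples.
#' @param max_order Highest harmonic order to report (below Nyquist).
#' @param edge_correct Apply the half-sample phase correction.
#' @return Tibble with columns `k` (0 = DC), `freq_rad_s`, `amp`, `phase_deg`
#'   (NA at DC).
#' @export
harmonic_content <- function(sig, fundamental_hz, max_order = 50,
                             edge_correct = TRUE) {
  if (!inherits(sig, "sampled_signal")) sig <- sampled_signal(sig$t_s, sig$value)
  stopifnot_scalar(fundamental_hz, "fundamental_hz", positive = TRUE)
  n <- nrow(sig)
  fs <- signal_fs(sig)
  spc <- fs / fundamental_hz
  if (abs(spc - round(spc)) > 1e-6 * spc) {
    abort("Samples per period must be an integer for exact-cycle FFT analysis.")
  }
  cycles <- n / spc
  if (abs(cycles - round(cycles)) > 1e-6) {
    abort("Record must cover an integer number of fundamental periods.")
  }
  if (max_order >= spc / 2) {
    abort("`max_order` must be below Nyquist (samples-per-period / 2).")
  }
  X <- fft(sig$value) / n
  k <- 0:max_order
  bins <- round(k * cycles) + 1L
  coef <- X[bins]
  phase <- -deg(Arg(coef))
  if (edge_correct) phase <- phase + 180 * k / spc
  phase[1] <- NA_real_
  tibble(
    k = k,
    freq_rad_s = hz_to_rad(k * fundamental_hz),
    amp = Mod(coef),
    phase_deg = phase
  )
}
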