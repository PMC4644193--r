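# Synthetic acquisition generator: emulates the experimental chain
# (driver electronics -> fluorophore -> band-limited detector -> digitizer
# noise) so the whole pipeline is testable without laboratory data.

#' Synthetic acquisition specification
#'
#' Bundles everything needed to simulate one digitized driver/response pair:
#' the fluorophore model, the drive, the sampling, an optional band-limited
#' detector stage, additive Gaussian digitizer noise, and a seed fixing all
#' randomness.
#'
#' @param model A [multiexp_model()] (fractions act as impulse-response
#'   weights, see [convolve_response()]), a [three_level_model()] (the drive
#'   waveform scales its `gamma_13` pump path), or `NULL` for a purely
#'   frequency-flat emitter (then `flat_gain` must be positive).
#' @param drive A [drive_spec()].
#' @param fs_hz Sampling rate (Hz).
#' @param duration_s Record duration (s).
#' @param detector Optional [linear_filter()] for the detection electronics
#'   (real poles only, no zeros); `NULL` means an ideal all-pass detector.
#' @param noise_sd Standard deviation of additive white Gaussian noise on the
#'   response (response units, >= 0).
#' @param flat_gain Gain of a zero-lag frequency-flat emission path added to
#'   the response — a fluorophore whose lifetime is far below the resolvable
#'   band behaves exactly like this over the whole measurement range.
#' @param seed Integer seed fixing the noise draw.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(model, drive, fs_hz, duration_s, detector = NULL,
                             noise_sd = 0, flat_gain = 0, seed = 1L) {
  if (!is.null(model) &&
      !inherits(model, c("multiexp_model", "three_level_model"))) {
    abort("`model` must be a multiexp_model, three_level_model, or NULL.")
  }
  if (is.null(model) && flat_gain <= 0) {
    abort("With `model = NULL`, `flat_gain` must be positive.")
  }
  if (!inherits(drive, "drive_spec")) abort("`drive` must be a drive_spec.")
  stopifnot_scalar(fs_hz, "fs_hz", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(flat_gain, "flat_gain", nonneg = TRUE)
  if (!is.null(detector)) {
    if (!inherits(detector, "linear_filter")) {
      abort("`detector` must be a linear_filter or NULL.")
    }
    if (length(detector$zeros) > 0) {
      abort("Detector filters with zeros are not supported; use poles (low-pass stages) only.")
    }
    nyq <- pi * fs_hz
    pm <- Mod(detector$poles)
    if (any(pm >= nyq / 10 & pm <= nyq * 10)) {
      warn("Detector pole within a decade of the Nyquist rate: its dynamics are under-resolved at this fs.")
    }
  }
  structure(list(model = model, drive = drive, fs_hz = fs_hz,
                 duration_s = duration_s, detector = detector,
                 noise_sd = noise_sd, flat_gain = flat_gain,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Apply a low-pass detector filter to a sampled signal
#'
#' Convolves the signal with the impulse response of a pole-only filter
#' (cascaded single-pole stages, each applied by the exact
#' exponential-integrator recursion) and multiplies by the gain. A filter
#' such as `linear_filter(gain = a, poles = -a)` is a unity-DC-gain
#' band-limiting stage with corner rate `a`.
#'
#' @param sig A [sampled_signal()].
#' @param filter A [linear_filter()] with real nonzero poles and no zeros.
#' @return The filtered [sampled_signal()].
#' @export
apply_filter <- function(sig, filter) {
  if (!inherits(filter, "linear_filter")) abort("`filter` must be a linear_filter.")
  if (length(filter$zeros) > 0) abort("Zeros are not supported in time-domain filtering.")
  if (any(Im(filter$poles) != 0) || any(Re(filter$poles) >= 0)) {
    abort("Time-domain filtering needs strictly negative real poles.")
  }
  if (!inherits(sig, "sampled_signal")) sig <- sampled_signal(sig$t_s, sig$value)
  dt <- signal_dt(sig)
  v <- sig$value
  for (p in Re(filter$poles)) v <- single_pole_step(v, -p, dt)
  sampled_signal(sig$t_s, filter$gain * v)
}

#' Simulate one driver/response acquisition
#'
#' Generates the drive waveform, forward-simulates the fluorophore with the
#' numeric oracle (convolution for multi-exponential models, full rate
#' equations for three-level models, plus any frequency-flat path), passes
#' the result through the detector filter, and adds seeded Gaussian noise.
#' Identical specs (including seed) give bit-identical outputs; noise-free
#' simulations do not consume randomness at all.
#'
#' @param spec An [acquisition_spec()].
#' @return A list with elements `driver` and `response`, both
#'   [sampled_signal()] tibbles on the same grid.
#' @export
simulate_acquisition <- function(spec) {
  if (!inherits(spec, "acquisition_spec")) abort("`spec` must be an acquisition_spec.")
  driver <- generate_drive(spec$drive, spec$fs_hz, spec$duration_s)
  resp <- numeric(nrow(driver))
  if (inherits(spec$model, "multiexp_model")) {
    resp <- convolve_response(spec$model, driver)$value
  } else if (inherits(spec$model, "three_level_model")) {
    pump <- sampled_signal(driver$t_s, spec$model$gamma_13 * driver$value)
    resp <- three_level_integrate(spec$model, pump)$n2
  }
  if (spec$flat_gain > 0) resp <- resp + spec$flat_gain * driver$value
  response <- sampled_signal(driver$t_s, resp)
  if (!is.null(spec$detector)) response <- apply_filter(response, spec$detector)
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
                              rnorm(nrow(response), sd = spec$noise_sd))
    response <- sampled_signal(response$t_s, response$value + noise)
  }
  list(driver = driver, response = response)
}

#' Slow/fast fluorophore mixture acquisitions (synthetic fixture)
#'
#' Emulates the classic two-fluorophore bench experiment: a slow emitter with
#' a half-millisecond lifetime (uranyl-like) mixed with an effectively
#' instantaneous fast emitter (picosecond coumarin-like, modelled as a
#' zero-lag frequency-flat path since its lag is immeasurable anywhere in the
#' probed band), driven by square waves at three fundamentals — 10 Hz,
#' 250 Hz, and 2.5 kHz — whose harmonics up to order 50 together span
#' 10 Hz to 125 kHz. `slow_fraction` is the slow component's share of the DC
#' emission amplitude.
#'
#' The kernel weight of the slow component is `slow_fraction / tau_slow_s`,
#' so after the convolution's `1/Gamma` DC gain the slow and flat paths carry
#' DC amplitudes `slow_fraction` and `1 - slow_fraction`: the extracted phase
#' curve equals the two-component transfer-function mixture with those
#' amplitude fractions. The detector is a single pole 100 times above the
#' highest probed harmonic (effectively transparent). The sampling rate per
#' fundamental keeps the drive step at or below a twentieth of the slow
#' lifetime.
#'
#' @param slow_fraction Slow-component DC amplitude fraction in \[0, 1\].
#' @param seed Base seed; acquisition `i` uses `seed + i`.
#' @param noise_sd Additive response noise. No noise magnitude is available
#'   for the emulated bench setup, so the default (0.01 of the DC response
#'   level) is an arbitrary choice at a realistic scale.
#' @param tau_slow_s Slow lifetime (default 0.5 ms).
#' @param fundamentals_hz Square-wave fundamentals.
#' @param cycles_per_block,n_blocks Cycle-averaging structure used when the
#'   records are analyzed (the duration is sized to cover them).
#' @param max_order Highest harmonic order of interest (sets the detector
#'   corner and minimum sampling rate).
#' @return A list of [acquisition_spec()] objects, one per fundamental, with
#'   the analysis parameters attached as attributes `cycles_per_block`,
#'   `n_blocks`, `max_order`, `fundamentals_hz`.
#' @export
mixture_fixture <- function(slow_fraction, seed = 1L, noise_sd = 0.01,
                            tau_slow_s = 5e-4,
                            fundamentals_hz = c(10, 250, 2500),
                            cycles_per_block = 20, n_blocks = 4,
                            max_order = 50) {
  if (slow_fraction < 0 || slow_fraction > 1) {
    abort("`slow_fraction` must lie in [0, 1].")
  }
  w_max <- hz_to_rad(max(fundamentals_hz) * max_order)
  detector <- linear_filter(gain = 100 * w_max, poles = -100 * w_max)
  model <- if (slow_fraction > 0) {
    multiexp_model(slow_fraction / tau_slow_s, tau_slow_s)
  } else {
    NULL
  }
  specs <- purrr::imap(as.list(fundamentals_hz), function(f0, i) {
    spc <- 2^ceiling(log2(max(8 * max_order, 20 / (f0 * tau_slow_s))))
    settle <- ceiling(10 * tau_slow_s * f0)   # settle window: 10 lifetimes
    acquisition_spec(
      model = model,
      drive = drive_spec("square_biased", freq_hz = f0),
      fs_hz = f0 * spc,
      duration_s = (n_blocks * cycles_per_block + settle) / f0,
      detector = detector,
      noise_sd = noise_sd,
      flat_gain = 1 - slow_fraction,
      seed = seed + i
    )
  })
  attr(specs, "cycles_per_block") <- cycles_per_block
  attr(specs, "n_blocks") <- n_blocks
  attr(specs, "max_order") <- max_order
  attr(specs, "fundamentals_hz") <- fundamentals_hz
  attr(specs, "settle_cycles") <- ceiling(10 * tau_slow_s * fundamentals_hz)
  specs
}

#' Simulate, demodulate, and merge a set of acquisitions
#'
#' Convenience wrapper running the full pipeline on a list of
#' [acquisition_spec()]s (e.g. from [mixture_fixture()]): simulate each
#' acquisition, extract per-harmonic phase/modulation estimates, and merge
#' everything into one frequency-response curve.
#'
#' @param specs List of [acquisition_spec()]s (analysis parameters are read
#'   from its attributes when present).
#' @param max_order,cycles_per_block,n_blocks,settle_cycles,wrap Passed to
#'   [harmonic_phases()]; defaults come from the attributes set by
#'   [mixture_fixture()] (`settle_cycles` is recycled across acquisitions).
#' @return An [fd_response] tibble.
#' @export
reconstruct_phase_curve <- function(specs,
                                    max_order = attr(specs, "max_order") %||% 50,
                                    cycles_per_block = attr(specs, "cycles_per_block") %||% 100,
                                    n_blocks = attr(specs, "n_blocks") %||% 1L,
                                    settle_cycles = attr(specs, "settle_cycles") %||% 0L,
                                    wrap = "pm180") {
  if (inherits(specs, "acquisition_spec")) specs <- list(specs)
  settle_cycles <- rep_len(settle_cycles, length(specs))
  estimates <- purrr::imap(specs, function(sp, i) {
    acq <- simulate_acquisition(sp)
    harmonic_phases(acq$driver, acq$response, fundamental = sp$drive$omega,
                    max_order = max_order, cycles_per_block = cycles_per_block,
                    n_blocks = n_blocks, wrap = wrap,
                    settle_cycles = settle_cycles[i])
  })
  build_frequency_response(estimates)
}
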