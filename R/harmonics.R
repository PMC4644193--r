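# Data-reduction pipeline: cycle averaging of digitized driver/response
# records, FFT demodulation, per-harmonic phase delays and modulation ratios
# with block statistics, and assembly of multi-fundamental sweeps into one
# frequency-response curve.

# Resample a signal onto a grid with an integer number of samples per cycle
# (linear interpolation), returning the signal plus the integer spc. Records
# already synchronized to the fundamental pass through untouched.
sync_to_cycles <- function(sig, omega_fund) {
  dt <- signal_dt(sig)
  period <- 2 * pi / omega_fund
  spc_raw <- period / dt
  if (abs(spc_raw - round(spc_raw)) < 1e-9 * spc_raw) {
    return(list(sig = sig, spc = as.integer(round(spc_raw))))
  }
  spc <- as.integer(round(spc_raw))
  if (spc < 4L) abort("Fewer than 4 samples per fundamental cycle after resampling.")
  n_cycles <- floor(nrow(sig) * dt / period)
  if (n_cycles < 1L) abort("Record shorter than one fundamental period.")
  t_new <- sig$t_s[1] + (seq_len(n_cycles * spc) - 1) * (period / spc)
  v_new <- stats::approx(sig$t_s, sig$value, xout = t_new, rule = 2)$y
  list(sig = sampled_signal(t_new, v_new), spc = spc)
}

#' Block cycle-averaging of a periodic record
#'
#' Splits a digitized record into `n_blocks` consecutive blocks of
#' `cycles_per_block` fundamental cycles each and averages the cycles within
#' every block pointwise, yielding one low-noise single-cycle waveform per
#' block (residual noise falls as the square root of the cycle count). If the
#' sampling is not synchronized to the fundamental, the record is first
#' linearly resampled onto the nearest integer samples-per-cycle grid.
#'
#' @param sig A [sampled_signal()].
#' @param fundamental Fundamental angular frequency (rad/s).
#' @param cycles_per_block Cycles averaged into each block (typically 100).
#' @param n_blocks Number of independent blocks.
#' @return A tibble with columns `block`, `t_s` (time within the cycle),
#'   `value`.
#' @export
cycle_average <- function(sig, fundamental, cycles_per_block, n_blocks = 1L) {
  if (!inherits(sig, "sampled_signal")) sig <- sampled_signal(sig$t_s, sig$value)
  stopifnot_scalar(fundamental, "fundamental", positive = TRUE)
  synced <- sync_to_cycles(sig, fundamental)
  spc <- synced$spc
  needed <- n_blocks * cycles_per_block * spc
  if (nrow(synced$sig) < needed) {
    abort(sprintf(
      "Record too short: %d samples available, %d required (%d blocks x %d cycles x %d samples/cycle).",
      nrow(synced$sig), needed, n_blocks, cycles_per_block, spc))
  }
  v <- synced$sig$value[seq_len(needed)]
  arr <- array(v, dim = c(spc, cycles_per_block, n_blocks))
  avg <- apply(arr, c(1, 3), mean)
  tibble(
    block = rep(seq_len(n_blocks), each = spc),
    t_s = rep((seq_len(spc) - 1) * (2 * pi / fundamental) / spc, n_blocks),
    value = as.vector(avg)
  )
}

#' Per-harmonic phase delays and modulation ratios (FFT lock-in)
#'
#' The digital equivalent of multi-frequency lock-in detection: both the
#' driver and the response records are block cycle-averaged, each averaged
#' cycle is Fourier transformed, and for every harmonic order whose driver
#' bin carries power the phase delay of the response behind the driver and
#' the modulation ratio are computed per block, then aggregated across blocks
#' (circular mean for phase; standard deviations across blocks).
#'
#' The modulation ratio is `|R_k| / |D_k|` normalized by the DC-bin ratio, so
#' it tends to 1 at low frequency regardless of detector gain or offsets.
#' Harmonic orders whose driver bin power falls below `power_floor` times the
#' fundamental bin power (even orders of a square wave, nulled comb orders)
#' are omitted, with a message naming them.
#'
#' @param driver,response [sampled_signal()] records on the same time grid.
#' @param fundamental Fundamental angular frequency of the drive (rad/s).
#' @param max_order Highest harmonic order to attempt (must be below Nyquist).
#' @param cycles_per_block,n_blocks Block structure for [cycle_average()].
#' @param wrap Phase reporting convention: `"pm180"` (principal value),
#'   `"pm90"` (arctangent convention, sawtooth across nulls), or `"unwrap"`
#'   (cumulative unwrapping across increasing order, for e.g. transport
#'   delays whose phase grows without bound).
#' @param settle_cycles Initial fundamental cycles discarded before blocking,
#'   so that turn-on transients (which persist for several lifetimes after
#'   the drive starts) do not bias the steady-state harmonic estimates.
#' @param power_floor Driver bin power threshold, relative to the fundamental
#'   bin.
#' @return A tibble of class `harmonic_estimates`: `k`, `freq_rad_s`,
#'   `phase_deg`, `phase_sd`, `mod`, `mod_sd`, `n_blocks`. Standard
#'   deviations are `NA` when `n_blocks < 2`.
#' @export
harmonic_phases <- function(driver, response, fundamental, max_order = 50,
                            cycles_per_block = 100, n_blocks = 1L,
                            wrap = c("pm180", "pm90", "unwrap"),
                            settle_cycles = 0L,
                            power_floor = 1e-6) {
  wrap <- match.arg(wrap)
  if (!inherits(driver, "sampled_signal")) driver <- sampled_signal(driver$t_s, driver$value)
  if (!inherits(response, "sampled_signal")) response <- sampled_signal(response$t_s, response$value)
  if (nrow(driver) != nrow(response) ||
      max(abs(driver$t_s - response$t_s)) > 1e-9 * signal_dt(driver)) {
    abort("Driver and response must share the same time grid.")
  }
  if (settle_cycles > 0) {
    spc0 <- sync_to_cycles(driver, fundamental)$spc
    drop <- settle_cycles * spc0
    if (nrow(driver) <= drop) {
      abort(sprintf("Record too short to discard %d settle cycle(s).", settle_cycles))
    }
    driver <- sampled_signal(driver$t_s[-seq_len(drop)], driver$value[-seq_len(drop)])
    response <- sampled_signal(response$t_s[-seq_len(drop)], response$value[-seq_len(drop)])
  }
  d_blocks <- cycle_average(driver, fundamental, cycles_per_block, n_blocks)
  r_blocks <- cycle_average(response, fundamental, cycles_per_block, n_blocks)
  spc <- sum(d_blocks$block == 1L)
  if (max_order >= spc / 2) {
    abort("`max_order` must be below Nyquist (samples per cycle / 2).")
  }

  per_block <- purrr::map(seq_len(n_blocks), function(b) {
    D <- fft(d_blocks$value[d_blocks$block == b]) / spc
    R <- fft(r_blocks$value[r_blocks$block == b]) / spc
    k <- seq_len(max_order)
    tibble(
      block = b, k = k,
      d_power = Mod(D[k + 1])^2,
      fund_power = Mod(D[2])^2,
      phase = Arg(D[k + 1]) - Arg(R[k + 1]),          # + for causal lag
      mod = (Mod(R[k + 1]) / Mod(D[k + 1])) / (Mod(R[1]) / Mod(D[1]))
    )
  })
  per_block <- dplyr::bind_rows(per_block)

  kept <- per_block |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      keep = all(.data$d_power > power_floor * .data$fund_power),
      # circular mean, then sd of deviations unwrapped around it
      phase_mean = Arg(sum(exp(1i * .data$phase))),
      phase_sd = if (dplyr::n() > 1) {
        dev <- wrap_deg(deg(.data$phase - Arg(sum(exp(1i * .data$phase)))), 360)
        stats::sd(dev)
      } else NA_real_,
      mod_mean = mean(.data$mod),
      mod_sd = if (dplyr::n() > 1) stats::sd(.data$mod) else NA_real_,
      .groups = "drop"
    )

  dropped <- kept$k[!kept$keep]
  if (length(dropped) > 0) {
    inform(sprintf(
      "Omitting harmonic order(s) %s: driver power below floor (nulled or absent harmonics).",
      paste(dropped, collapse = ", ")))
  }
  kept <- kept[kept$keep, ]
  phase_deg <- deg(kept$phase_mean)
  phase_deg <- switch(wrap,
    pm180 = phase_deg,
    pm90 = wrap_deg(phase_deg, 180),
    unwrap = unwrap_deg(phase_deg)
  )
  out <- tibble(
    k = kept$k,
    freq_rad_s = kept$k * fundamental,
    phase_deg = phase_deg,
    phase_sd = kept$phase_sd,
    mod = kept$mod_mean,
    mod_sd = kept$mod_sd,
    n_blocks = as.integer(n_blocks)
  )
  class(out) <- c("harmonic_estimates", class(out))
  out
}

# cumulative unwrap of a phase sequence (degrees): choose each value within
# 180 of its predecessor
unwrap_deg <- function(phi) {
  if (length(phi) < 2) return(phi)
  out <- phi
  for (i in 2:length(phi)) {
    out[i] <- out[i - 1] + wrap_deg(phi[i] - out[i - 1], 360)
  }
  out
}

#' Merge harmonic sweeps into one frequency-response curve
#'
#' Assembles per-harmonic estimates from one or more fundamentals into a
#' single phase/modulation curve sorted by absolute frequency. Three
#' square-wave fundamentals at 10 Hz, 250 Hz, and 2.5 kHz with 50 harmonics
#' span 10 Hz to 125 kHz. Estimates landing on the same absolute frequency
#' are averaged with inverse-variance weights when standard deviations are
#' available (so merged uncertainties never exceed the individual ones), and
#' with equal weights otherwise.
#'
#' @param estimates A `harmonic_estimates` tibble (from [harmonic_phases()]),
#'   or a list of them / row-bound tibbles from several fundamentals.
#' @return An [fd_response] tibble (`freq_rad_s`, `phase_deg`, `mod`,
#'   `phase_sd`, `mod_sd`).
#' @export
build_frequency_response <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- dplyr::bind_rows(estimates)
  }
  if (is.null(estimates) || nrow(estimates) == 0L) {
    abort("No harmonic estimates to merge.")
  }
  merged <- estimates |>
    dplyr::mutate(freq_key = signif(.data$freq_rad_s, 12)) |>
    dplyr::group_by(.data$freq_key) |>
    dplyr::summarise(
      freq_rad_s = .data$freq_rad_s[1],
      ph = list(weighted_merge(.data$phase_deg, .data$phase_sd)),
      mo = list(weighted_merge(.data$mod, .data$mod_sd)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      phase_deg = purrr::map_dbl(.data$ph, "mean"),
      phase_sd = purrr::map_dbl(.data$ph, "sd"),
      mod = purrr::map_dbl(.data$mo, "mean"),
      mod_sd = purrr::map_dbl(.data$mo, "sd")
    ) |>
    dplyr::select("freq_rad_s", "phase_deg", "mod", "phase_sd", "mod_sd") |>
    dplyr::arrange(.data$freq_rad_s)
  fd_response(merged, mod_eps = Inf)
}

# inverse-variance merge when all sds known and positive; plain mean otherwise
weighted_merge <- function(x, s) {
  if (length(x) == 1L) return(list(mean = x, sd = s))
  if (all(is.finite(s)) && all(s > 0)) {
    w <- 1 / s^2
    list(mean = sum(w * x) / sum(w), sd = sqrt(1 / sum(w)))
  } else {
    list(mean = mean(x), sd = if (all(is.finite(s))) sqrt(mean(s^2) / length(s)) else NA_real_)
  }
}
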