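# Shared helpers for the suite. Oracles here are deliberately naive and
# independent of the package's own numerics.

# O(n^2) trapezoid-rule convolution of a drive with sum_k f_k exp(-g_k t):
# an independent check on the exponential-integrator recursion.
naive_convolution <- function(fractions, rates, drive_values, dt) {
  n <- length(drive_values)
  t <- (seq_len(n) - 1) * dt
  out <- numeric(n)
  for (j in 2:n) {
    tp <- t[seq_len(j)]                    # integration variable t'
    g <- drive_values[seq_len(j)]
    kern <- rep(0, j)
    for (i in seq_along(fractions)) {
      kern <- kern + fractions[i] * exp(-rates[i] * (t[j] - tp))
    }
    integrand <- kern * g
    out[j] <- sum((integrand[-1] + integrand[-j]) / 2) * dt
  }
  out
}

# steady-state sample of a periodic response: values with t > settle
steady <- function(t, settle) t > settle

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}

# random single-pole low-pass with unity DC gain
random_lowpass <- function(rate) linear_filter(gain = rate, poles = -rate)

# Max abs deviation between the square-wave residue series and the
# convolution oracle at steady state, on a grid whose samples sit exactly on
# the square edges (the sampled rectangle's piecewise-linear edge is then
# half a sample early, compensated when evaluating the series).
square_oracle_error <- function(g, w, n_terms = 1500) {
  tau <- 1 / g; period <- 2 * pi / w
  spc <- 2 * ceiling(250 * max(1, period / tau))
  dt <- period / spc
  n_cyc <- ceiling(12 * tau / period) + 2
  drv <- generate_drive(drive_spec("square_biased", freq_hz = w / (2 * pi)),
                        fs = 1 / dt, duration = n_cyc * period)
  num <- convolve_response(multiexp_model(1, tau), drv)
  late <- which(drv$t_s > 11 * tau)
  idx <- late[unique(round(seq(1, length(late), length.out = 2000)))]
  cf <- square_response(g, w, drv$t_s[idx] + dt / 2, n_terms = n_terms)
  max(abs(num$value[idx] - cf))
}
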