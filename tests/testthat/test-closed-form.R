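test_that("delta-excitation decay is a plain exponential", {
  expect_identical(delta_response(1, 1, 0), 1)
  expect_equal(delta_response(1, 2, 1), 2 * exp(-1), tolerance = 1e-12)
  expect_equal(delta_response(2, 1, log(2) / 2), 0.5, tolerance = 1e-12)
  expect_error(delta_response(1, 1, -0.1), ">= 0")
  expect_error(delta_response(0, 1, 1), "> 0")
})

test_that("sine response satisfies its boundary condition and frequency limits", {
  withr::with_seed(5, {
    for (i in 1:5) {
      g <- 10^runif(1, -1, 2); A <- runif(1, 0.5, 2); w <- 10^runif(1, -1, 2)
      expect_equal(sine_response(g, A, w, 0, n0 = 0), 0)
      n0 <- runif(1)
      expect_equal(sine_response(g, A, w, 0, n0 = n0), n0)
    }
  })

  # low frequency (omega << gamma): in-phase sine of amplitude A/gamma
  t <- seq(0, 30, by = 1e-3)
  late <- steady(t, 12 / 1000)
  v <- sine_response(1000, 1, 1, t)
  expect_rel_error(v[late], sin(t[late]) / 1000, 0.002)

  # high frequency (omega >> gamma): quadrature cosine of amplitude A/omega
  late <- steady(t, 12)
  v <- sine_response(1, 1, 1000, t)
  expect_rel_error(v[late], -cos(1000 * t[late]) / 1000, 0.002)
})

test_that("sine transient decays no slower than exp(-gamma t)", {
  g <- 2; A <- 1; w <- 3
  t <- seq(0, 6, by = 0.01)
  d <- g^2 + w^2
  ss <- A * (g * sin(w * t) - w * cos(w * t)) / d
  dev <- abs(sine_response(g, A, w, t) - ss)
  # log-linear bound: dev <= C exp(-g t) with C from the t=0 deviation
  C <- dev[1] * 1.01 + 1e-12
  expect_true(all(dev <= C * exp(-g * t) + 1e-12))
})

test_that("biased-cosine response starts at zero and has mean A/(2 gamma)", {
  withr::with_seed(13, {
    for (i in 1:5) {
      g <- 10^runif(1, -1, 1); A <- runif(1, 0.5, 2); w <- 10^runif(1, -1, 1)
      expect_equal(biased_cosine_response(g, A, w, 0), 0, tolerance = 1e-14)
      # steady-state mean over one period: DC gain 1/gamma times drive mean A/2
      period <- 2 * pi / w
      t <- seq(30 / g, 30 / g + period, length.out = 4001)
      expect_equal(mean(biased_cosine_response(g, A, w, t[-1])), A / (2 * g),
                   tolerance = 1e-6)
    }
  })
})

test_that("the literal published biased-cosine form fails the t = 0 boundary", {
  # kept behind a flag for comparison: its cosine sign makes n(0) nonzero
  v0 <- biased_cosine_response(1, 1, 1, 0, literal = TRUE)
  expect_gt(abs(v0), 0.1)
  expect_equal(biased_cosine_response(1, 1, 1, 0, literal = FALSE), 0,
               tolerance = 1e-14)
})

test_that("biased-cosine closed form matches the convolution oracle pointwise", {
  t <- seq(0, 30, length.out = 30000)
  drv <- sampled_signal(t, (1 - cos(t)) / 2)
  oracle <- convolve_response(multiexp_model(1, 1), drv)
  cf <- biased_cosine_response(1, 1, 1, t)
  expect_lt(max(abs(oracle$value - cf)), 1e-6)
})

test_that("square-wave response has the expected DC level and shark's-fin shape", {
  # long-time mean over one period equals 1/gamma
  g <- 1; w <- 1
  period <- 2 * pi / w
  t <- seq(30, 30 + period, length.out = 8001)
  expect_equal(mean(square_response(g, w, t[-1], n_terms = 2000)), 1 / g,
               tolerance = 1e-4)

  # slow drive: rounded square wave, plateau ~ 2/gamma, trough ~ 0
  w_slow <- 0.01
  t_slow <- seq(30 / g, 30 / g + 2 * pi / w_slow, length.out = 8001)
  v <- square_response(g, w_slow, t_slow, n_terms = 2000)
  expect_equal(max(v), 2 / g, tolerance = 0.01)
  expect_equal(min(v), 0, tolerance = 0.01)

  # peak-to-peak amplitude decreases monotonically with drive frequency
  p2p <- vapply(10^seq(log10(0.2), log10(20), length.out = 8), function(wk) {
    tt <- seq(30 / g, 30 / g + 2 * pi / wk, length.out = 4001)
    vv <- square_response(g, wk, tt, n_terms = 1000)
    max(vv) - min(vv)
  }, numeric(1))
  expect_true(all(diff(p2p) < 0))
})

test_that("square-wave series matches the convolution oracle at steady state", {
  spc <- 2000
  drv <- generate_drive(drive_spec("square_biased", freq_hz = 1 / (2 * pi)),
                        fs = spc / (2 * pi), duration = 40 * pi)
  oracle <- convolve_response(multiexp_model(1, 1), drv)
  dt <- drv$t_s[2] - drv$t_s[1]
  # sampled rectangle edges sit half a sample early relative to the ideal
  # square; evaluate the series on the shifted grid to compare like with like
  cf <- square_response(1, 1, drv$t_s + dt / 2, n_terms = 200)
  late <- steady(drv$t_s, 15)
  expect_lt(max(abs(oracle$value - cf)[late]), 1e-3)
})

test_that("closed forms agree with the oracle across random parameter draws", {
  withr::with_seed(42, {
    draws <- tibble::tibble(g = 10^runif(20, -0.5, 1.5),
                            w = 10^runif(20, -0.5, 1.5))
  })
  for (i in seq_len(nrow(draws))) {
    g <- draws$g[i]; w <- draws$w[i]
    tau <- 1 / g; period <- 2 * pi / w
    dt <- min(tau, period) / 500
    t_end <- (ceiling(12 * tau / period) + 3) * period  # integer cycles
    t <- seq(0, t_end, by = dt)

    # impulse: oracle with an interior one-sample spike of area `a`
    a <- 0.7
    spike <- numeric(length(t)); spike[5] <- a / dt
    imp <- convolve_response(multiexp_model(1, tau), sampled_signal(t, spike))
    after <- seq_along(t) > 6
    expect_rel_error(imp$value[after],
                     a * exp(-g * (t[after] - t[5])), 5e-3)

    # biased cosine: pointwise, including the transient
    drv <- sampled_signal(t, (1 - cos(w * t)) / 2)
    bc <- convolve_response(multiexp_model(1, tau), drv)
    expect_lt(max(abs(bc$value - biased_cosine_response(g, 1, w, t))),
              1e-4 / g)

    # square wave at steady state (edge-aligned grid, half-sample shift)
    expect_lt(square_oracle_error(g, w), 1e-3)
  }
})

test_that("responses to nonnegative drives stay nonnegative", {
  withr::with_seed(99, {
    for (i in 1:8) {
      g <- 10^runif(1, -1, 1); w <- 10^runif(1, -1, 1)
      t <- seq(0, 20 / g, length.out = 4000)
      expect_true(all(biased_cosine_response(g, 1, w, t) >= -1e-12))
      expect_true(all(square_response(g, w, t, n_terms = 1500) >= -5e-4))
      expect_true(all(delta_response(g, 1, t) >= 0))
    }
  })
})
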