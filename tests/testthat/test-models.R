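test_that("multi-exponential transfer function evaluates the weighted pole sum", {
  m1 <- multiexp_model(1, 1)
  expect_equal(transfer_eval(m1, 1), 0.5 - 0.5i)

  m2 <- multiexp_model(c(0.9, 0.1), c(1, 0.001))
  expect_identical(transfer_eval(m2, 0), 1 + 0i)   # DC: exact sum of fractions

  # conjugate symmetry at +/- omega for random models
  withr::with_seed(11, {
    for (i in 1:10) {
      K <- sample(1:3, 1)
      m <- multiexp_model(runif(K), sort(10^runif(K, -4, 1)))
      w <- 10^runif(5, -2, 5)
      expect_equal(transfer_eval(m, -w), Conj(transfer_eval(m, w)))
    }
  })
})

test_that("model constructors enforce their invariants", {
  expect_error(multiexp_model(numeric(0), numeric(0)), "at least one")
  expect_error(multiexp_model(1, -1), "positive")
  expect_error(multiexp_model(c(0, 0), c(1, 2)), "positive")
  expect_error(multiexp_model(-0.1, 1), "nonnegative")
  expect_error(multiexp_model(c(1, 1), c(1, 1 + 1e-9)), "distinct")
  expect_silent(multiexp_model(c(1, 0), c(1, 2)))  # one zero fraction is fine

  expect_error(three_level_model(gamma_21 = 0, gamma_32 = 1), "must be > 0")
  expect_error(three_level_model(gamma_21 = 1, gamma_32 = 0), "must be > 0")
  expect_error(linear_filter(poles = 1), "nonpositive")
})

test_that("phase and modulation follow the single-lifetime arctangent law", {
  m <- multiexp_model(1, 1)
  pm <- phase_mod(m, c(0, 1))
  expect_equal(pm$phase_deg, c(0, 45), tolerance = 1e-12)
  expect_equal(pm$mod, c(1, 1 / sqrt(2)), tolerance = 1e-12)

  # tan(phase) = omega * tau across a grid and random lifetimes
  withr::with_seed(7, {
    for (tau in 10^runif(5, -4, 1)) {
      w <- 10^seq(-3, 3, length.out = 200) / tau
      pm <- phase_mod(multiexp_model(1, tau), w)
      expect_equal(tan(pm$phase_deg * pi / 180), w * tau, tolerance = 1e-9)
      expect_equal(pm$mod, 1 / sqrt(1 + (w * tau)^2), tolerance = 1e-12)
      # strict monotonicity: phase up, mod down
      expect_true(all(diff(pm$phase_deg) > 0))
      expect_true(all(diff(pm$mod) < 0))
    }
  })

  # phase approaches 90 degrees from below as omega grows
  high <- phase_mod(m, 10^seq(4, 8, 1))
  expect_true(all(diff(high$phase_deg) > 0))
  expect_true(all(high$phase_deg < 90))
  expect_gt(max(high$phase_deg), 89.99)
})

test_that("parallel mixtures keep the phase inside [0, 90) at all frequencies", {
  withr::with_seed(23, {
    for (i in 1:10) {
      K <- sample(2:4, 1)
      m <- multiexp_model(runif(K, 0.05, 1), sort(10^runif(K, -5, 0)))
      pm <- phase_mod(m, 10^seq(-3, 8, length.out = 300))
      expect_true(all(pm$phase_deg >= 0 & pm$phase_deg < 90))
      expect_true(all(pm$mod <= 1 + 1e-12))
    }
  })
})

test_that("two-component mixture shows an interior phase maximum below 90 degrees", {
  m <- multiexp_model(c(0.9, 0.1), c(1, 0.001))
  w <- 10^seq(-2, 6, length.out = 20000)
  ph <- phase_mod(m, w)$phase_deg
  expect_true(all(ph < 90))
  # local (turnover) maximum in the band between the two poles
  band <- w > 0.1 & w < 100
  i_loc <- which(band)[which.max(ph[band])]
  expect_gt(w[i_loc], 1)          # beyond the slow knee
  expect_lt(w[i_loc], 100)        # interior, not at the band edge
  expect_lt(ph[i_loc], 90)
  # the curve declines after the local maximum before the fast pole takes over
  expect_lt(ph[which.min(abs(w - 300))], ph[i_loc])
})

test_that("three-level transfer is the two-pole cascade with the stated gain", {
  tl <- three_level_model(gamma_21 = 1, gamma_31 = 0, gamma_32 = 1)
  H <- three_level_transfer(tl)
  expect_equal(sort(Re(H$poles)), c(-1, -1))
  expect_equal(Mod(transfer_eval(H, 0)), 1)        # DC gain G32/(G21*(G31+G32))

  # fast relaxation limit: wing of the far pole cancels the gain -> single pole
  fast <- three_level_model(gamma_21 = 1, gamma_31 = 0, gamma_32 = 1e11)
  w <- 10^seq(-2, 2, length.out = 100)
  ph <- phase_mod(fast, w)$phase_deg
  expect_lt(max(abs(ph - atan(w) * 180 / pi)), 0.1)
  expect_equal(phase_mod(fast, 1)$phase_deg, 45, tolerance = 1e-3)

  # second-order system: phase lag saturates at 180 degrees
  slow <- three_level_model(gamma_21 = 1, gamma_31 = 0, gamma_32 = 1)
  expect_gt(phase_mod(slow, 1e7)$phase_deg, 179.99)
  expect_true(all(phase_mod(slow, 10^seq(-2, 7, 1))$phase_deg < 180))
})

test_that("cascades multiply gains, concatenate poles, and add phases", {
  lp <- random_lowpass(1)
  one <- cascade(lp)
  expect_equal(one$poles, lp$poles)
  expect_equal(one$gain, lp$gain)

  two <- cascade(lp, lp)
  expect_equal(phase_mod(two, 1)$phase_deg, 90, tolerance = 1e-12)

  # additivity on random filters, to 1e-9 degrees
  withr::with_seed(31, {
    for (i in 1:10) {
      f1 <- random_lowpass(10^runif(1, -2, 3))
      f2 <- random_lowpass(10^runif(1, -2, 3))
      w <- 10^runif(6, -2, 4)
      ph_casc <- phase_mod(cascade(f1, f2), w)$phase_deg
      ph_sum <- phase_mod(f1, w)$phase_deg + phase_mod(f2, w)$phase_deg
      expect_lt(max(abs(ph_casc - ph_sum)), 1e-9)
    }
  })

  # fluorophore pole + detector pole: total phase is the sum of arctans
  fl <- random_lowpass(2)
  det <- random_lowpass(50)
  w <- 10^seq(-1, 4, length.out = 50)
  expect_equal(phase_mod(cascade(fl, det), w)$phase_deg,
               (atan(w / 2) + atan(w / 50)) * 180 / pi, tolerance = 1e-10)

  expect_error(cascade(), "empty")
  expect_error(cascade(list()), "empty")
})

test_that("RC low-pass stages map to lifetimes via 2*pi*R*C", {
  expect_equal(lifetime_from_rc(159e3, 1e-6), 0.99903, tolerance = 1e-4)
  expect_equal(lifetime_from_rc(1.6e3, 100e-9), 1.005e-3, tolerance = 1e-3)
  expect_identical(lifetime_from_rc(1 / (2 * pi), 1), 1)
  expect_error(lifetime_from_rc(-1, 1), "> 0")
  expect_error(lifetime_from_rc(1, 0), "> 0")

  presets <- rc_stage_presets()
  expect_equal(presets$lifetime_s[presets$stage == "slow_stage_1"], 1,
               tolerance = 1e-3)
  # the two fast-stage parameter sets, exposed without label arbitration
  expect_equal(sort(presets$fast_rate_per_s[-1]),
               sort(1 / (2 * pi * c(1.6e3 * 100e-9, 0.159 * 10e-12))))
})

test_that("frequency-response container validates and sorts", {
  tbl <- tibble::tibble(freq_rad_s = c(2, 1), phase_deg = c(10, 5), mod = c(0.9, 1))
  fr <- fd_response(tbl)
  expect_s3_class(fr, "fd_response")
  expect_equal(fr$freq_rad_s, c(1, 2))
  expect_error(fd_response(dplyr::mutate(tbl, mod = c(1.5, 1))), "\\[0, 1")
  expect_error(fd_response(dplyr::mutate(tbl, phase_deg = c(Inf, 0))), "finite")
})
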