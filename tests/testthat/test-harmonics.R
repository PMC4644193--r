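test_that("cycle averaging preserves constants and exact periodicity", {
  t <- (0:9999) / 1000
  const <- sampled_signal(t, rep(2.5, length(t)))
  ca <- cycle_average(const, fundamental = 2 * pi * 10, cycles_per_block = 10,
                      n_blocks = 5)
  expect_equal(unique(ca$value), 2.5)
  expect_identical(nrow(ca), 5L * 100L)

  sine <- sampled_signal(t, sin(2 * pi * 10 * t) + 1)
  ca <- cycle_average(sine, 2 * pi * 10, cycles_per_block = 20, n_blocks = 2)
  one_cycle <- sin(2 * pi * 10 * t[1:100]) + 1
  expect_lt(max(abs(ca$value - rep(one_cycle, 2))), 1e-12)

  expect_error(cycle_average(sine, 2 * pi * 10, 100, 2), "too short")
})

test_that("averaging 100 cycles suppresses white noise by about 10x", {
  t <- (0:199999) / 1000   # 200 s at 1 kHz; 10 Hz fundamental
  sigma <- 0.3
  resid <- withr::with_seed(101, {
    vapply(1:50, function(i) {
      sig <- sampled_signal(t[1:10000],
                            sin(2 * pi * 10 * t[1:10000]) +
                              rnorm(10000, sd = sigma))
      ca <- cycle_average(sig, 2 * pi * 10, cycles_per_block = 100,
                          n_blocks = 1)
      sqrt(mean((ca$value - sin(2 * pi * 10 * ca$t_s))^2))
    }, numeric(1))
  })
  expect_equal(mean(resid), sigma / 10, tolerance = 0.2)
})

test_that("identical driver and response give zero phase and unit mod ratio", {
  t <- (0:7999) / 800
  sig <- sampled_signal(t, 1.3 + ifelse((t * 4) %% 1 < 0.5, 1, 0))
  est <- suppressMessages(
    harmonic_phases(sig, sig, 2 * pi * 4, max_order = 10,
                    cycles_per_block = 10, n_blocks = 4))
  expect_lt(max(abs(est$phase_deg)), 1e-10)
  expect_lt(max(abs(est$mod - 1)), 1e-10)
})

test_that("square-driven single lifetime yields arctan(k w0 tau) per harmonic", {
  tau <- 1; f0 <- 0.2; w0 <- 2 * pi * f0
  drv <- generate_drive(drive_spec("square_biased", freq_hz = f0),
                        fs = f0 * 2048, duration = 30 / f0)
  resp <- convolve_response(multiexp_model(1, tau), drv)
  est <- suppressMessages(
    harmonic_phases(drv, resp, w0, max_order = 25, cycles_per_block = 10,
                    n_blocks = 2, settle_cycles = 5))
  expect_true(all(est$k %% 2 == 1))   # even square harmonics never reported
  expect_lt(max(abs(est$phase_deg - atan(est$k * w0 * tau) * 180 / pi)), 0.05)
})

test_that("a pure transport delay gives phase linear in harmonic order", {
  f0 <- 0.2; w0 <- 2 * pi * f0
  fs <- f0 * 2048
  drv <- generate_drive(drive_spec("pulse_train", freq_hz = f0, duty = 0.1),
                        fs = fs, duration = 20 / f0)
  nd <- 37                              # integer-sample circular delay
  n <- nrow(drv)
  delayed <- drv$value[((seq_len(n) - 1 - nd) %% n) + 1]
  resp <- sampled_signal(drv$t_s, delayed)
  est <- suppressMessages(
    harmonic_phases(drv, resp, w0, max_order = 25, cycles_per_block = 10,
                    n_blocks = 2, wrap = "unwrap"))
  td <- nd / fs
  expect_lt(max(abs(est$phase_deg - est$k * w0 * td * 180 / pi)), 0.05)
  # nulled comb orders (k = 10, 20) are never reported
  expect_false(any(est$k %in% c(10, 20)))
})

test_that("phase estimates ignore response gain and DC offset", {
  tau <- 0.5; f0 <- 0.5; w0 <- 2 * pi * f0
  drv <- generate_drive(drive_spec("square_biased", freq_hz = f0),
                        fs = f0 * 1024, duration = 30 / f0)
  resp <- convolve_response(multiexp_model(1, tau), drv)
  scaled <- sampled_signal(resp$t_s, 7.3 * resp$value + 2.1)
  a <- suppressMessages(harmonic_phases(drv, resp, w0, 15, 10, 2,
                                        settle_cycles = 5))
  b <- suppressMessages(harmonic_phases(drv, scaled, w0, 15, 10, 2,
                                        settle_cycles = 5))
  expect_equal(a$phase_deg, b$phase_deg, tolerance = 1e-9)
})

test_that("phase scatter across blocks shrinks as 1/sqrt(n_blocks)", {
  f0 <- 2; w0 <- 2 * pi * f0; fs <- f0 * 256
  tau <- 0.1
  drv <- generate_drive(drive_spec("square_biased", freq_hz = f0),
                        fs = fs, duration = 200 / f0)
  clean <- convolve_response(multiexp_model(1, tau), drv)
  sds <- withr::with_seed(555, {
    vapply(c(4, 16), function(nb) {
      reps <- vapply(1:12, function(i) {
        noisy <- sampled_signal(clean$t_s,
                                clean$value + rnorm(nrow(clean), sd = 0.02))
        est <- suppressMessages(
          harmonic_phases(drv, noisy, w0, max_order = 1, cycles_per_block = 10,
                          n_blocks = nb, settle_cycles = 10))
        est$phase_deg[1]
      }, numeric(1))
      sd(reps)
    }, numeric(1))
  })
  # quadrupling the block count should halve the scatter, within MC error
  expect_equal(sds[2] / sds[1], 0.5, tolerance = 0.5)
})

test_that("unsynchronized sampling is resampled without losing phase accuracy", {
  tau <- 1; f0 <- 0.21113; w0 <- 2 * pi * f0
  fs <- 500    # non-integer samples per cycle
  drv <- generate_drive(drive_spec("sine", freq_hz = f0), fs = fs,
                        duration = 40 / f0)
  resp <- convolve_response(multiexp_model(1, tau), drv)
  est <- suppressMessages(suppressWarnings(
    harmonic_phases(drv, resp, w0, max_order = 1, cycles_per_block = 10,
                    n_blocks = 2, settle_cycles = 8)))
  expect_equal(est$phase_deg[1], atan(w0 * tau) * 180 / pi, tolerance = 0.05)
})

test_that("merging sweeps pools overlapping estimates by inverse variance", {
  est1 <- tibble::tibble(k = 1:3, freq_rad_s = c(10, 20, 30),
                         phase_deg = c(1, 2, 3), phase_sd = c(0.1, 0.1, 0.1),
                         mod = c(1, 0.9, 0.8), mod_sd = c(0.01, 0.01, 0.01),
                         n_blocks = 4L)
  single <- build_frequency_response(est1)
  expect_identical(nrow(single), 3L)
  expect_equal(single$freq_rad_s, c(10, 20, 30))

  # duplicate sweep at the same fundamental: merged sd is smaller
  merged <- build_frequency_response(list(est1, est1))
  expect_identical(nrow(merged), 3L)
  expect_true(all(merged$phase_sd < est1$phase_sd))
  expect_equal(merged$phase_sd, est1$phase_sd / sqrt(2))

  # inverse-variance weighting pulls toward the precise estimate
  est2 <- dplyr::mutate(est1, phase_deg = phase_deg + 1, phase_sd = 1)
  m2 <- build_frequency_response(list(est1, est2))
  expect_true(all(abs(m2$phase_deg - est1$phase_deg) < 0.02))

  expect_error(build_frequency_response(list()), "No harmonic")
})

test_that("noise-free pipeline phase equals arctan(omega tau) at every harmonic", {
  withr::with_seed(77, {
    for (i in 1:4) {
      tau <- 10^runif(1, -1, 0.5)
      f0 <- 10^runif(1, -1, 0) / tau
      w0 <- 2 * pi * f0
      kind <- sample(c("square_biased", "pulse_train"), 1)
      spec <- if (kind == "pulse_train") {
        drive_spec(kind, freq_hz = f0, duty = 0.1)
      } else {
        drive_spec(kind, freq_hz = f0)
      }
      settle <- ceiling(12 * tau * f0) + 1
      drv <- generate_drive(spec, fs = f0 * 2048, duration = (settle + 20) / f0)
      resp <- convolve_response(multiexp_model(1, tau), drv)
      est <- suppressMessages(
        harmonic_phases(drv, resp, w0, max_order = 20, cycles_per_block = 10,
                        n_blocks = 2, settle_cycles = settle))
      expect_lt(max(abs(est$phase_deg - atan(est$k * w0 * tau) * 180 / pi)),
                0.1)
    }
  })
})
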