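# Inverse problem: recover lifetimes and fractional amplitudes of a
# multi-exponential model from a measured phase (and/or modulation) curve by
# weighted nonlinear least squares on an unconstrained parameterization
# (log-lifetimes and softmax fractions), with multi-start.

# theta = c(log_tau[1..K], logit[2..K]); fractions = softmax(c(0, logits))
theta_to_model <- function(theta, K) {
  log_tau <- theta[seq_len(K)]
  logits <- c(0, theta[K + seq_len(K - 1)])
  f <- exp(logits - max(logits))
  list(tau = exp(log_tau), fraction = f / sum(f))
}

predict_curve <- function(theta, K, omega) {
  p <- theta_to_model(theta, K)
  Fv <- colSums(p$fraction / (1 + 1i * outer(p$tau, omega)))
  list(phase = -deg(Arg(Fv)), mod = Mod(Fv))  # fractions sum to 1, F(0) = 1
}

fit_residuals <- function(theta, K, omega, obs_phase, obs_mod, w_phase, w_mod, use) {
  pred <- predict_curve(theta, K, omega)
  r <- numeric(0)
  if (use %in% c("phase", "both")) r <- c(r, sqrt(w_phase) * (obs_phase - pred$phase))
  if (use %in% c("mod", "both")) r <- c(r, sqrt(w_mod) * (obs_mod - pred$mod))
  r
}

#' Fit lifetimes and fractions to a frequency-response curve
#'
#' Weighted nonlinear least squares of the multi-exponential transfer
#' function's predicted phase (and/or modulation) against an observed
#' [fd_response] curve. Lifetimes are optimized as logarithms and fractions
#' through a softmax, guaranteeing positivity without constrained solvers and
#' accommodating lifetimes separated by several decades. Because the
#' two-component phase objective is multimodal, the optimizer is restarted
#' from `n_starts` random log-uniform lifetime draws spanning the curve's
#' frequency range (plus one deterministic quantile-spread start), and the
#' best converged optimum is returned.
#'
#' Phase-only fitting is the default: the modulation curve of a two-component
#' mixture differs only subtly from a single-exponential one, whereas the
#' phase curve carries the distinctive turnover.
#'
#' @param curve An [fd_response] tibble (columns `freq_rad_s`, `phase_deg`,
#'   `mod`, optional `phase_sd`, `mod_sd` used as inverse-variance weights).
#' @param n_components Number of exponential components to fit (>= 1).
#' @param use Which observables enter the objective: `"phase"`, `"mod"`, or
#'   `"both"`.
#' @param n_starts Number of random multi-starts (default 8).
#' @param seed Seed for the start draws (fixed so fits are reproducible).
#' @return An object of class `lifetime_fit` with elements `model` (the
#'   fitted [multiexp_model()], components sorted by descending lifetime),
#'   `estimates`, `vcov` (covariance of log-lifetimes and logit-fractions),
#'   `objective`, `sigma`, `converged`, `n_iter`, `n_obs`. Methods:
#'   [tidy.lifetime_fit()], [glance.lifetime_fit()], `print`, `autoplot`.
#' @export
fit_lifetimes <- function(curve, n_components, use = c("phase", "mod", "both"),
                          n_starts = 8, seed = 171) {
  use <- match.arg(use)
  K <- n_components
  if (!is_scalar_number(K) || K < 1) abort("`n_components` must be >= 1.")
  K <- as.integer(K)
  need <- c("freq_rad_s", "phase_deg", "mod")
  if (!all(need %in% names(curve))) {
    abort("`curve` needs columns freq_rad_s, phase_deg, mod.")
  }
  curve <- dplyr::arrange(as_tibble(curve), .data$freq_rad_s)
  curve <- curve[curve$freq_rad_s > 0, ]
  n_par <- 2L * K - 1L
  if (nrow(curve) < 2L * n_par) {
    abort(sprintf("Need at least %d curve points to fit %d component(s).",
                  2L * n_par, K))
  }
  omega <- curve$freq_rad_s
  span_decades <- log10(max(omega) / min(omega))
  identifiable <- span_decades >= (K - 1) * 0.5
  if (!identifiable) {
    warn(sprintf(
      "Curve spans only %.2f frequency decades; %d components may not be identifiable.",
      span_decades, K))
  }

  wt <- function(sd_col) {
    s <- curve[[sd_col]]
    if (!is.null(s) && all(is.finite(s)) && all(s > 0)) 1 / s^2 else rep(1, nrow(curve))
  }
  w_phase <- wt("phase_sd")
  w_mod <- wt("mod_sd")

  obj <- function(theta) {
    r <- fit_residuals(theta, K, omega, curve$phase_deg, curve$mod,
                       w_phase, w_mod, use)
    0.5 * sum(r^2)
  }

  # deterministic start: lifetimes at quantiles of 1/omega; plus random starts
  lo <- 1 / max(omega); hi <- 1 / min(omega)
  starts <- list(c(log(exp(seq(log(lo), log(hi), length.out = K + 2))[1 + seq_len(K)]),
                   rep(0, K - 1)))
  rand <- withr::with_seed(seed, {
    purrr::map(seq_len(n_starts), function(i) {
      c(sort(stats::runif(K, log(lo), log(hi)), decreasing = TRUE), rep(0, K - 1))
    })
  })
  starts <- c(starts, rand)

  fits <- purrr::map(starts, function(th0) {
    tryCatch(
      optim(th0, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0L) abort("Optimization failed from every start.")
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  if (best$convergence != 0 && all(vapply(fits, function(f) f$convergence != 0, logical(1)))) {
    warn("No start reported clean convergence; returning best objective found.")
  }

  # sort components by descending lifetime and rebuild theta consistently
  p <- theta_to_model(best$par, K)
  ord <- order(p$tau, decreasing = TRUE)
  tau_s <- p$tau[ord]; frac_s <- p$fraction[ord]
  logits_s <- log(frac_s / frac_s[1])
  theta_hat <- c(log(tau_s), logits_s[-1])

  if (any(frac_s < 1e-4)) {
    warn("A fitted fraction is below 1e-4; that component is effectively absent (identifiability guard).")
  }

  # covariance of (log tau, logits) from the weighted Jacobian
  res <- fit_residuals(theta_hat, K, omega, curve$phase_deg, curve$mod,
                       w_phase, w_mod, use)
  J <- num_jacobian(function(th) fit_residuals(th, K, omega, curve$phase_deg,
                                               curve$mod, w_phase, w_mod, use),
                    theta_hat)
  dof <- max(length(res) - n_par, 1L)
  s2 <- sum(res^2) / dof
  JTJ <- crossprod(J)
  vcov <- tryCatch(s2 * solve(JTJ), error = function(e) {
    s2 * MASS_ginv(JTJ)
  })
  vcov <- (vcov + t(vcov)) / 2
  par_names <- c(paste0("log_tau_", seq_len(K)),
                 if (K > 1) paste0("logit_f_", 2:K))
  dimnames(vcov) <- list(par_names, par_names)

  model <- multiexp_model(frac_s, tau_s, rel_tol = 0)
  structure(list(
    model = model,
    theta = setNames(theta_hat, par_names),
    vcov = vcov,
    objective = best$value,
    sigma = sqrt(s2),
    converged = best$convergence == 0,
    n_iter = best$counts[["function"]],
    n_obs = length(res),
    n_components = K,
    use = use,
    identifiable = identifiable,
    curve = curve
  ), class = "lifetime_fit")
}

# central-difference Jacobian of a vector-valued function
num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    J[, j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  J
}

# Moore-Penrose fallback for a singular normal matrix (degenerate fits)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("<lifetime_fit> %d component(s), fit on %s, %s\n",
              x$n_components, x$use,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  cat(sprintf("objective %.6g, sigma %.4g, n_obs %d\n",
              x$objective, x$sigma, x$n_obs))
  invisible(x)
}

#' Tidy a lifetime fit
#'
#' One row per fitted quantity on the natural scale: lifetimes in seconds and
#' fractional amplitudes. Standard errors are delta-method propagations from
#' the log-lifetime / logit-fraction covariance; confidence intervals for
#' lifetimes are computed on the log scale (hence asymmetric and always
#' positive).
#'
#' @param x A `lifetime_fit`.
#' @param conf.level Confidence level for the intervals.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.lifetime_fit <- function(x, conf.level = 0.68, ...) {
  K <- x$n_components
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tau <- x$model$components$lifetime_s
  frac <- x$model$components$fraction
  se_logtau <- sqrt(pmax(diag(x$vcov)[seq_len(K)], 0))

  # fractions: delta method through the softmax on logits (first logit fixed 0)
  if (K > 1) {
    idx <- K + seq_len(K - 1)
    V_logit <- x$vcov[idx, idx, drop = FALSE]
    # d f_i / d logit_j = f_i (delta_ij - f_j), j = 2..K
    Jf <- matrix(0, K, K - 1)
    for (i in seq_len(K)) {
      for (j in seq_len(K - 1)) {
        Jf[i, j] <- frac[i] * ((i == j + 1) - frac[j + 1])
      }
    }
    se_frac <- sqrt(pmax(diag(Jf %*% V_logit %*% t(Jf)), 0))
  } else {
    se_frac <- 0
  }

  tibble(
    term = c(paste0("tau_", seq_len(K)), paste0("fraction_", seq_len(K))),
    estimate = c(tau, frac),
    std.error = c(tau * se_logtau, se_frac),
    conf.low = c(tau * exp(-z * se_logtau), pmax(frac - z * se_frac, 0)),
    conf.high = c(tau * exp(z * se_logtau), pmin(frac + z * se_frac, 1))
  )
}

#' Fit-level summary of a lifetime fit
#'
#' @param x A `lifetime_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `objective`, `sigma`, `n_obs`, `n_components`,
#'   `converged`, `n_iter`, `identifiable`.
#' @exportS3Method generics::glance
glance.lifetime_fit <- function(x, ...) {
  tibble(
    objective = x$objective, sigma = x$sigma, n_obs = x$n_obs,
    n_components = x$n_components, converged = x$converged,
    n_iter = as.integer(x$n_iter), identifiable = x$identifiable
  )
}

#' Family of mixture phase curves
#'
#' Deterministic phase (and modulation) curves of two-component mixtures
#' spanning a range of slow-component amplitude fractions — the
#' slow/fast masking family: beyond the slow component's knee the phase
#' turns over, and at any such frequency the lag decreases as the fast
#' fraction grows, because the demodulated slow emission degenerates into a
#' DC light level while the fast component still follows the drive.
#'
#' @param slow_fractions Numeric vector of slow-component fractions in
#'   \[0, 1\].
#' @param tau_slow_s,tau_fast_s Slow and fast lifetimes in seconds
#'   (`tau_slow_s > tau_fast_s`).
#' @param omega Angular frequency grid (rad/s).
#' @return A tibble: `slow_fraction`, `freq_rad_s`, `phase_deg`, `mod`.
#' @export
mixture_phase_family <- function(slow_fractions, tau_slow_s, tau_fast_s, omega) {
  if (any(slow_fractions < 0 | slow_fractions > 1)) {
    abort("`slow_fractions` must lie in [0, 1].")
  }
  if (tau_slow_s <= tau_fast_s) abort("`tau_slow_s` must exceed `tau_fast_s`.")
  purrr::map_dfr(slow_fractions, function(f) {
    m <- if (f == 0) {
      multiexp_model(1, tau_fast_s)
    } else if (f == 1) {
      multiexp_model(1, tau_slow_s)
    } else {
      multiexp_model(c(f, 1 - f), c(tau_slow_s, tau_fast_s))
    }
    pm <- phase_mod(m, omega)
    tibble(slow_fraction = f, freq_rad_s = pm$freq_rad_s,
           phase_deg = pm$phase_deg, mod = pm$mod)
  })
}
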