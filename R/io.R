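# CSV / JSON interchange. Conventions: comma-separated, '.' decimal, header
# row mandatory, UTF-8; stored frequencies always in rad/s with explicit
# column names, user-facing CLI flags in Hz.

#' Read and write sampled waveforms as CSV
#'
#' Two-column time series with header `t_s,value`.
#'
#' @param sig A [sampled_signal()].
#' @param path File path.
#' @return `read_waveform_csv()` returns a [sampled_signal()];
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
write_waveform_csv <- function(sig, path) {
  if (!inherits(sig, "sampled_signal")) sig <- sampled_signal(sig$t_s, sig$value)
  readr::write_csv(as_tibble(sig)[c("t_s", "value")], path)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t_s", "value") %in% names(x))) {
    abort(sprintf("%s: expected columns t_s,value.", path))
  }
  sampled_signal(x$t_s, x$value)
}

#' Read and write frequency-response curves as CSV
#'
#' Header `freq_rad_s,phase_deg,mod,phase_sd,mod_sd` (the sd columns may be
#' empty).
#'
#' @param resp An [fd_response] tibble.
#' @param path File path.
#' @return `read_response_csv()` returns an [fd_response];
#'   `write_response_csv()` returns `path` invisibly.
#' @export
write_response_csv <- function(resp, path) {
  out <- as_tibble(resp)
  for (col in c("phase_sd", "mod_sd")) {
    if (is.null(out[[col]])) out[[col]] <- NA_real_
  }
  readr::write_csv(out[c("freq_rad_s", "phase_deg", "mod", "phase_sd", "mod_sd")],
                   path)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("freq_rad_s", "phase_deg", "mod") %in% names(x))) {
    abort(sprintf("%s: expected columns freq_rad_s,phase_deg,mod[,phase_sd,mod_sd].", path))
  }
  fd_response(x, mod_eps = Inf)
}

#' Read and write per-harmonic estimate tables as CSV
#'
#' Header `k,freq_rad_s,phase_deg,phase_sd,mod,mod_sd,n_blocks`.
#'
#' @param est A `harmonic_estimates` tibble from [harmonic_phases()].
#' @param path File path.
#' @return `read_harmonics_csv()` returns a `harmonic_estimates` tibble;
#'   `write_harmonics_csv()` returns `path` invisibly.
#' @export
write_harmonics_csv <- function(est, path) {
  readr::write_csv(as_tibble(est), path)
  invisible(path)
}

#' @rdname write_harmonics_csv
#' @export
read_harmonics_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("k", "freq_rad_s", "phase_deg", "mod")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s: expected columns %s.", path, paste(need, collapse = ",")))
  }
  class(x) <- c("harmonic_estimates", class(x))
  x
}

#' Serialize and parse model specifications as JSON
#'
#' Multi-exponential models are stored as
#' `{"components": [{"fraction": f, "lifetime_s": tau}, ...]}` and
#' three-level models as
#' `{"three_level": {"g13": ..., "g21": ..., "g31": ..., "g32": ...}}`.
#' `read_model_json()` accepts either a file path or a literal JSON string.
#'
#' @param model A [multiexp_model()] or [three_level_model()].
#' @param path File path.
#' @param x File path or JSON string.
#' @return `read_model_json()` returns the model object;
#'   `write_model_json()` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "multiexp_model")) {
    list(components = purrr::pmap(model$components[c("fraction", "lifetime_s")],
                                  function(fraction, lifetime_s) {
                                    list(fraction = fraction, lifetime_s = lifetime_s)
                                  }))
  } else if (inherits(model, "three_level_model")) {
    list(three_level = list(g13 = model$gamma_13, g21 = model$gamma_21,
                            g31 = model$gamma_31, g32 = model$gamma_32))
  } else {
    abort("`model` must be a multiexp_model or three_level_model.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(x) {
  obj <- parse_json_arg(x)
  model_from_config(obj)
}

parse_json_arg <- function(x) {
  if (length(x) == 1L && is.character(x) && !grepl("[{\\[]", x) && file.exists(x)) {
    jsonlite::read_json(x)
  } else if (is.character(x)) {
    jsonlite::parse_json(paste(x, collapse = "\n"))
  } else {
    x
  }
}

model_from_config <- function(obj) {
  if (!is.null(obj$components)) {
    comp <- dplyr::bind_rows(lapply(obj$components, as_tibble))
    multiexp_model(comp)
  } else if (!is.null(obj$three_level)) {
    tl <- obj$three_level
    three_level_model(gamma_13 = tl$g13 %||% 0, gamma_21 = tl$g21,
                      gamma_31 = tl$g31 %||% 0, gamma_32 = tl$g32)
  } else {
    abort("Model JSON needs a `components` or `three_level` entry.")
  }
}

drive_from_config <- function(obj) {
  drive_spec(kind = obj$kind, freq_hz = obj$freq_hz,
             amplitude = obj$amplitude %||% 1,
             bias = obj$bias, duty = obj$duty)
}

acquisition_from_config <- function(obj, seed = NULL) {
  model <- if (is.null(obj$model)) NULL else model_from_config(obj$model)
  detector <- if (is.null(obj$detector)) NULL else {
    linear_filter(gain = obj$detector$gain %||% 1,
                  poles = unlist(obj$detector$poles))
  }
  acquisition_spec(
    model = model,
    drive = drive_from_config(obj$drive),
    fs_hz = obj$fs_hz, duration_s = obj$duration_s,
    detector = detector,
    noise_sd = obj$noise_sd %||% 0,
    flat_gain = obj$flat_gain %||% 0,
    seed = seed %||% obj$seed %||% 1L
  )
}

#' Write a lifetime fit as JSON
#'
#' Keys: `lifetimes_s`, `fractions`, `covariance` (of log-lifetimes and
#' logit-fractions), `objective`, `sigma`, `n_iter`, `converged`.
#'
#' @param fit A `lifetime_fit` from [fit_lifetimes()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "lifetime_fit")) abort("`fit` must be a lifetime_fit.")
  jsonlite::write_json(list(
    lifetimes_s = fit$model$components$lifetime_s,
    fractions = fit$model$components$fraction,
    covariance = unclass(fit$vcov),
    objective = fit$objective,
    sigma = fit$sigma,
    n_iter = fit$n_iter,
    converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
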