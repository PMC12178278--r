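# Forward model: log-Gaussian SF tuning, gamma HIRF, predicted BOLD.

#' Parameter bounds for the pSFT model
#'
#' The box constraints used both by the grid searches and by the bounded
#' optimizer: peak SF `mu` in \[0.009, 6\] cpd, bandwidth `sigma` in
#' \[0.1, 4\], scaling `beta` in \[-25, 25\], baseline `beta0` in
#' \[-10, 10\].
#'
#' @return Named list of length-2 numeric vectors `mu`, `sigma`, `beta`,
#'   `beta0`.
#' @export
psft_bounds <- function() {
  list(mu = c(0.009, 6), sigma = c(0.1, 4), beta = c(-25, 25), beta0 = c(-10, 10))
}

#' pSFT parameter set
#'
#' @param mu Peak SF in cpd (the SF producing the maximum response).
#' @param sigma Tuning bandwidth parameter of the log-Gaussian exponent.
#' @param beta BOLD scaling coefficient (percent signal change units).
#' @param beta0 BOLD baseline.
#' @param check If TRUE (default), reject parameters outside [psft_bounds()].
#' @return Named numeric vector of class `psft_params`.
#' @export
psft_params <- function(mu, sigma, beta = 1, beta0 = 0, check = TRUE) {
  stopifnot(is.finite(mu), is.finite(sigma), is.finite(beta), is.finite(beta0))
  if (mu <= 0 || sigma <= 0) stopf("mu and sigma must be positive")
  if (check) {
    b <- psft_bounds()
    for (nm in names(b)) {
      v <- get(nm)
      if (v < b[[nm]][1] - 1e-12 || v > b[[nm]][2] + 1e-12)
        stopf("%s = %g outside bounds [%g, %g]", nm, v, b[[nm]][1], b[[nm]][2])
    }
  }
  structure(c(mu = mu, sigma = sigma, beta = beta, beta0 = beta0),
            class = "psft_params")
}

#' Log-Gaussian spatial-frequency response
#'
#' Response of a population tuned to peak SF `mu` with bandwidth `sigma`
#' when probed at SF `f`:
#' `R(f) = exp(-(log f - log mu)^2 / (2 sigma^2))`.
#' The response is 1 at `f = mu` and symmetric in log-SF, so
#' `sf_response(mu * k, ...) == sf_response(mu / k, ...)`. At the blank
#' sentinel SF (0.0001 cpd) the response is numerically negligible for any
#' in-bounds `mu`, which is how blank periods enter the model.
#'
#' @param f Probe SF in cpd (vectorized); must be positive.
#' @param mu Peak SF in cpd; positive scalar.
#' @param sigma Bandwidth; positive scalar.
#' @return Numeric vector of responses in \[0, 1\].
#' @export
sf_response <- function(f, mu, sigma) {
  if (any(!is.finite(f)) || any(f <= 0)) stopf("f must be positive and finite")
  if (length(mu) != 1 || length(sigma) != 1 || mu <= 0 || sigma <= 0)
    stopf("mu and sigma must be positive scalars")
  exp(-((log(f) - log(mu))^2) / (2 * sigma^2))
}

#' Hemodynamic impulse response specification
#'
#' A gamma-shaped HIRF with time constant `tau` (1.08 s), integer phase
#' delay `n_phase` (3), and an onset delay `onset_delay` (2.05 s) between
#' stimulus onset and the start of the BOLD response. In continuous time
#' `h(t) = ((t - d)/tau)^(n-1) exp(-(t - d)/tau) / (tau (n-1)!)` for
#' `t >= d` and 0 before, i.e. a unit-mass gamma density with shape
#' `n_phase` and scale `tau`, shifted by `onset_delay`; its mode is at
#' `d + (n-1) tau` = 4.21 s with the defaults.
#'
#' @param tau Time constant in seconds (default 1.08).
#' @param n_phase Integer phase delay (default 3).
#' @param onset_delay Stimulus-to-response delay in seconds (default 2.05).
#' @return List of class `hirf_spec`.
#' @export
hirf_spec <- function(tau = 1.08, n_phase = 3L, onset_delay = 2.05) {
  stopifnot(tau > 0, onset_delay >= 0)
  if (abs(n_phase - round(n_phase)) > 1e-9 || n_phase < 1)
    stopf("n_phase must be a positive integer")
  structure(list(tau = tau, n_phase = as.integer(round(n_phase)),
                 onset_delay = onset_delay), class = "hirf_spec")
}

#' Continuous-time HIRF density
#'
#' @param t Time in seconds (vectorized).
#' @param spec An [hirf_spec()].
#' @return h(t); zero for `t < onset_delay`.
#' @export
hirf_density <- function(t, spec = hirf_spec()) {
  s <- (t - spec$onset_delay) / spec$tau
  out <- numeric(length(t))
  pos <- s > 0
  n <- spec$n_phase
  out[pos] <- s[pos]^(n - 1) * exp(-s[pos]) / (spec$tau * factorial(n - 1))
  out
}

#' Sampled HIRF convolution kernel
#'
#' Samples the continuous HIRF at TR midpoints over a window of
#' `length_s` seconds and scales by the TR, so the kernel weights
#' approximate the continuous unit mass. A warning is raised if the window
#' captures less than 99% of the kernel mass.
#'
#' @param spec An [hirf_spec()].
#' @param tr Sampling interval in seconds (default 1).
#' @param length_s Kernel window in seconds (default 32).
#' @return Numeric vector of kernel weights, with the sample times in
#'   attribute `"times"`.
#' @export
hirf_kernel <- function(spec = hirf_spec(), tr = 1, length_s = 32) {
  stopifnot(tr > 0, length_s > 0)
  n <- as.integer(ceiling(length_s / tr))
  times <- (seq_len(n) - 0.5) * tr
  w <- hirf_density(times, spec) * tr
  mass <- sum(w)
  if (mass < 0.99)
    warning(sprintf("kernel window of %g s captures only %.1f%% of the HIRF mass",
                    length_s, 100 * mass))
  structure(w, times = times)
}

# Causal discrete convolution truncated to the input length.
convolve_causal <- function(x, kernel) {
  n <- length(x)
  full <- convolve(x, rev(kernel), type = "open")
  full[seq_len(n)]
}

#' Predicted BOLD time series from the pSFT model
#'
#' `B(t) = beta0 + beta * (R\[f(t)\] * h)(t)`: the log-Gaussian response to
#' the per-TR stimulus SF track, causally convolved with the sampled HIRF
#' and truncated to the input length. Blank handling is input-side only:
#' blank TRs carry the sentinel SF, whose response is effectively zero.
#'
#' @param sf_track Per-TR stimulus SF (cpd): a numeric vector or a
#'   `psft_sf_sequence` (its `sf_per_tr` is used).
#' @param params A [psft_params()] vector (or any named vector with `mu`,
#'   `sigma`, `beta`, `beta0`).
#' @param spec An [hirf_spec()].
#' @param tr Sampling interval in seconds (default 1).
#' @param kernel_length_s HIRF window in seconds (default 32).
#' @return Numeric vector of predicted percent signal change, same length
#'   as the input track.
#' @export
predict_bold <- function(sf_track, params, spec = hirf_spec(), tr = 1,
                         kernel_length_s = 32) {
  sf_track <- as_sf_track(sf_track)
  if (length(sf_track) == 0) stopf("empty SF track")
  p <- as.list(params[c("mu", "sigma", "beta", "beta0")])
  r <- sf_response(sf_track, p$mu, p$sigma)
  k <- hirf_kernel(spec, tr = tr, length_s = kernel_length_s)
  p$beta0 + p$beta * convolve_causal(r, k)
}

as_sf_track <- function(x) {
  if (inherits(x, "psft_sf_sequence")) x$sf_per_tr else as.numeric(x)
}
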