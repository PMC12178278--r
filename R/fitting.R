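# pSFT model fitting: block concatenation, coarse-to-fine grid search,
# bounded nonlinear least squares.
#
# All grid evaluations share one algebraic shortcut. For a fixed SF track
# the predicted series is linear in the vector of per-level responses:
# with L = the distinct SFs in the track, M the (T x |L|) matrix whose
# columns are the HIRF-convolved indicator tracks of each level, and
# r(mu, sigma) the level responses, the prediction with beta = 1,
# beta0 = 0 is M %*% r. SSE against y then needs only crossprod(M, y),
# crossprod(M) and colSums(M), so thousands of (mu, sigma) cells cost one
# small matrix product instead of one convolution each. This is exactly
# equivalent to convolving per cell (predict_bold is the cross-check in
# the tests).

#' Precompute the linear basis of a stimulus SF track
#'
#' @param sf_track Per-TR SF track (numeric or `psft_sf_sequence`).
#' @param spec An [hirf_spec()].
#' @param tr Sampling interval in seconds.
#' @param kernel_length_s HIRF window in seconds.
#' @return List of class `psft_basis` with the level set, the convolved
#'   indicator matrix `M`, and its sufficient statistics.
#' @keywords internal
#' @export
psft_basis <- function(sf_track, spec = hirf_spec(), tr = 1,
                       kernel_length_s = 32) {
  f <- as_sf_track(sf_track)
  if (length(f) == 0) stopf("empty SF track")
  levels <- sort(unique(f))
  k <- hirf_kernel(spec, tr = tr, length_s = kernel_length_s)
  M <- vapply(levels, function(l) convolve_causal(as.numeric(f == l), k),
              numeric(length(f)))
  structure(list(levels = levels, M = M, G = crossprod(M), s = colSums(M),
                 n = length(f), spec = spec, tr = tr,
                 kernel_length_s = kernel_length_s),
            class = "psft_basis")
}

# Level-response matrix for a grid of (mu, sigma) cells: |levels| x n_cells.
level_responses <- function(levels, mu, sigma) {
  lf <- log(levels)
  # outer over cells; exp of -(lf - log mu)^2 / (2 sigma^2)
  d <- outer(lf, log(mu), "-")
  exp(-sweep(d^2, 2, 2 * sigma^2, "/"))
}

# SSE over grid cells with beta = 1, beta0 = 0.
grid_sse <- function(basis, y, mu, sigma) {
  R <- level_responses(basis$levels, mu, sigma)
  My <- crossprod(basis$M, y) # |L| x 1
  sum(y^2) - 2 * drop(crossprod(R, My)) + colSums(R * (basis$G %*% R))
}

# Pick the minimizing cell(s), averaging exact ties (SSE compared after
# rounding to 12 significant digits so floating-point noise cannot
# suppress the documented averaging rule).
grid_argmin <- function(mu, sigma, sse) {
  key <- signif(sse, 12)
  win <- which(key == min(key))
  list(mu = mean(mu[win]), sigma = mean(sigma[win]), sse = min(sse),
       n_tied = length(win))
}

#' Coarse grid search for pSFT initialization
#'
#' Evaluates the model SSE on a 10 x 10 grid — `mu` logarithmically spaced
#' over \[0.009, 6\] and `sigma` linearly spaced over \[0.1, 4\] — with
#' `beta` fixed to 1 and `beta0` to 0, and returns the minimizing pair
#' (exact ties averaged).
#'
#' @param y Measured BOLD series (percent signal change).
#' @param sf_track Matching per-TR SF track.
#' @param n_mu,n_sigma Grid sizes (defaults 10 and 10).
#' @param basis Optional precomputed [psft_basis()] for `sf_track`.
#' @param ... Passed to [psft_basis()] when `basis` is NULL.
#' @return List with `mu`, `sigma`, `sse`, and the full `grid` data.frame.
#' @export
coarse_grid_search <- function(y, sf_track, n_mu = 10, n_sigma = 10,
                               basis = NULL, ...) {
  if (is.null(basis)) basis <- psft_basis(sf_track, ...)
  stopifnot(length(y) == basis$n)
  b <- psft_bounds()
  mu_g <- exp(seq(log(b$mu[1]), log(b$mu[2]), length.out = n_mu))
  sg_g <- seq(b$sigma[1], b$sigma[2], length.out = n_sigma)
  cells <- expand.grid(mu = mu_g, sigma = sg_g)
  sse <- grid_sse(basis, y, cells$mu, cells$sigma)
  out <- grid_argmin(cells$mu, cells$sigma, sse)
  out$grid <- cbind(cells, sse = sse)
  out
}

#' Fine grid search around the coarse optimum
#'
#' 100 logarithmically spaced `mu` values and 100 linearly spaced `sigma`
#' values spanning half to double the coarse optimum (clipped to the
#' global bounds), again with `beta = 1`, `beta0 = 0`; exact ties in the
#' minimum are averaged. The result is the starting point for the
#' nonlinear optimization.
#'
#' @param y Measured BOLD series.
#' @param sf_track Matching per-TR SF track.
#' @param coarse_best List with `mu` and `sigma` (as returned by
#'   [coarse_grid_search()]).
#' @param n_mu,n_sigma Grid sizes (defaults 100 and 100).
#' @param basis Optional precomputed [psft_basis()].
#' @param ... Passed to [psft_basis()] when `basis` is NULL.
#' @return A [psft_params()] with the minimizing `mu`, `sigma` and
#'   `beta = 1`, `beta0 = 0`; grid SSE in attribute `"sse"`.
#' @export
fine_grid_search <- function(y, sf_track, coarse_best, n_mu = 100,
                             n_sigma = 100, basis = NULL, ...) {
  if (is.null(basis)) basis <- psft_basis(sf_track, ...)
  stopifnot(length(y) == basis$n)
  b <- psft_bounds()
  mu_span <- pmin(pmax(c(coarse_best$mu / 2, coarse_best$mu * 2), b$mu[1]), b$mu[2])
  sg_span <- pmin(pmax(c(coarse_best$sigma / 2, coarse_best$sigma * 2),
                       b$sigma[1]), b$sigma[2])
  mu_g <- exp(seq(log(mu_span[1]), log(mu_span[2]), length.out = n_mu))
  sg_g <- seq(sg_span[1], sg_span[2], length.out = n_sigma)
  cells <- expand.grid(mu = mu_g, sigma = sg_g)
  sse <- grid_sse(basis, y, cells$mu, cells$sigma)
  out <- grid_argmin(cells$mu, cells$sigma, sse)
  structure(psft_params(out$mu, out$sigma, beta = 1, beta0 = 0),
            sse = out$sse, n_tied = out$n_tied)
}

# SSE of arbitrary (mu, sigma, beta, beta0) through the basis.
basis_sse <- function(basis, y, mu, sigma, beta, beta0) {
  r <- sf_response(basis$levels, mu, sigma)
  pred <- beta0 + beta * drop(basis$M %*% r)
  sum((y - pred)^2)
}

#' Fit the pSFT model to one voxel's series
#'
#' Bounded nonlinear least squares over (`mu`, `sigma`, `beta`, `beta0`)
#' minimizing the SSE between predicted and measured percent signal
#' change, started from the coarse-to-fine grid-search solution (computed
#' internally when `init` is NULL). Optimization uses L-BFGS-B on
#' (log mu, sigma, beta, beta0) within [psft_bounds()]. The returned
#' solution never has SSE above the initialization's: if the optimizer
#' fails or worsens the objective, the initialization is returned with
#' `converged = FALSE`.
#'
#' @param y Measured BOLD series (percent signal change).
#' @param sf_track Matching per-TR SF track (numeric or
#'   `psft_sf_sequence`).
#' @param init Optional [psft_params()] starting point; default is the
#'   grid-search initialization.
#' @param basis Optional precomputed [psft_basis()] for `sf_track`.
#' @param voxel_id,condition Identifiers carried into the result.
#' @param maxit Maximum optimizer iterations (default 500).
#' @param factr L-BFGS-B relative-reduction tolerance factor (default
#'   4.5e7, i.e. about 1e-8 relative SSE change).
#' @param ... Passed to [psft_basis()] when `basis` is NULL.
#' @return Object of class `psft_fit`: list with `params`, `sse`, `r2`
#'   (percent), `converged`, `init`, `init_sse`, `n`, `voxel_id`,
#'   `condition`.
#' @export
fit_psft <- function(y, sf_track, init = NULL, basis = NULL,
                     voxel_id = NA_character_, condition = NA_character_,
                     maxit = 500, factr = 4.5e7, ...) {
  if (is.null(basis)) basis <- psft_basis(sf_track, ...)
  stopifnot(length(y) == basis$n)
  if (is.null(init)) {
    cg <- coarse_grid_search(y, sf_track = NULL, basis = basis)
    init <- fine_grid_search(y, sf_track = NULL, coarse_best = cg, basis = basis)
  }
  b <- psft_bounds()
  init_sse <- basis_sse(basis, y, init["mu"], init["sigma"],
                        init["beta"], init["beta0"])

  obj <- function(par) basis_sse(basis, y, exp(par[1]), par[2], par[3], par[4])
  lower <- c(log(b$mu[1]), b$sigma[1], b$beta[1], b$beta0[1])
  upper <- c(log(b$mu[2]), b$sigma[2], b$beta[2], b$beta0[2])
  start <- pmin(pmax(c(log(init[["mu"]]), init[["sigma"]], init[["beta"]],
                       init[["beta0"]]), lower), upper)
  opt <- try(optim(start, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit, factr = factr)),
             silent = TRUE)

  ok <- !inherits(opt, "try-error") && is.finite(opt$value) &&
    opt$value <= init_sse + 1e-10 * max(1, init_sse)
  if (ok) {
    params <- psft_params(exp(opt$par[1]), opt$par[2], opt$par[3], opt$par[4])
    sse <- min(opt$value, init_sse) # guard tiny numerical excess
    if (opt$value > init_sse) { params <- init; sse <- init_sse }
    converged <- opt$convergence == 0
  } else {
    params <- init
    sse <- init_sse
    converged <- FALSE
  }

  structure(list(params = params, sse = sse,
                 r2 = r_squared_sse(sse, y), converged = converged,
                 init = init, init_sse = init_sse, n = basis$n,
                 voxel_id = voxel_id, condition = condition),
            class = "psft_fit")
}

#' @export
print.psft_fit <- function(x, ...) {
  cat(sprintf(
    "pSFT fit%s: mu = %.4g cpd, sigma = %.4g, beta = %.4g, beta0 = %.4g\n  SSE = %.6g, R2 = %.2f%%, converged = %s\n",
    if (!is.na(x$voxel_id)) paste0(" [", x$voxel_id, "]") else "",
    x$params[["mu"]], x$params[["sigma"]], x$params[["beta"]],
    x$params[["beta0"]], x$sse, x$r2, x$converged))
  invisible(x)
}

r_squared_sse <- function(sse, measured) {
  tss <- sum((measured - mean(measured))^2)
  if (tss == 0) return(structure(0, zero_variance = TRUE))
  100 * (1 - sse / tss)
}

#' Percent variance explained
#'
#' `R2 = 100 * (1 - SSE / total sum of squares about the mean)`. Can be
#' negative when the prediction is worse than the mean. A zero-variance
#' measured series yields 0 with attribute `zero_variance = TRUE`.
#'
#' @param predicted,measured Equal-length numeric vectors (length >= 2).
#' @return R-squared in percent.
#' @export
r_squared <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured), length(measured) >= 2)
  r_squared_sse(sum((measured - predicted)^2), measured)
}

#' Convert a raw series to percent signal change
#'
#' `100 * (x - m) / m` with `m` the mean over blank TRs (the grand mean if
#' no blank index is given or blanks are absent).
#'
#' @param x Raw series.
#' @param blank_idx Optional integer indices of blank TRs.
#' @return Percent-signal-change series.
#' @export
percent_signal_change <- function(x, blank_idx = NULL) {
  m <- if (length(blank_idx)) mean(x[blank_idx]) else mean(x)
  if (!is.finite(m) || m == 0) stopf("normalizer mean is zero or non-finite")
  100 * (x - m) / m
}

#' Re-anchor a percent-signal-change series at its blank-period baseline
#'
#' Subtracts the mean over blank TRs, so blank periods read 0% signal.
#' This is the additive counterpart of the blank-mean percent-signal-change
#' convention for series already in percent units, and it is what makes the
#' grid searches' fixed `beta0 = 0` a sensible working assumption; the
#' residual offset is still absorbed by the free `beta0` in the final
#' bounded fit. With no blank TRs the grand mean is used.
#'
#' @param y Percent-signal-change series (vector or voxels-by-TR matrix).
#' @param sf_track Matching SF track identifying blank TRs.
#' @param blank_code Blank sentinel SF (default 1e-4 cpd).
#' @return `y` with the blank-period mean removed (per row for matrices).
#' @export
rebaseline_to_blanks <- function(y, sf_track, blank_code = 1e-4) {
  idx <- which(as_sf_track(sf_track) == blank_code)
  if (is.matrix(y)) {
    m <- if (length(idx)) rowMeans(y[, idx, drop = FALSE]) else rowMeans(y)
    y - m
  } else {
    y - if (length(idx)) mean(y[idx]) else mean(y)
  }
}

#' Concatenate matching condition blocks across runs
#'
#' Splices, in run order, every block whose condition matches, together
#' with its trailing blank period, from both the measured series and the
#' stimulus SF track (blanks keep the sentinel SF). With the default
#' 9-run session and 2 blocks per condition per run this yields the 18
#' spliced blocks per condition that the model is fitted to.
#'
#' @param runs List of runs; each a list with elements `design`
#'   (`psft_run_design`), `sfseq` (`psft_sf_sequence`), and `series` (a
#'   numeric vector per TR, or a voxels-by-TR matrix).
#' @param condition Condition label to extract; must occur in every run.
#' @return List with `series` (vector or matrix), `sf_track`, and
#'   `boundaries` (data.frame `run`, `block`, `start`, `end`: spliced-index
#'   extents of each block-plus-blank segment).
#' @export
concatenate_condition_blocks <- function(runs, condition) {
  stopifnot(length(runs) >= 1)
  seg_series <- list(); seg_track <- list()
  bnd <- list(); pos <- 0L; k <- 0L
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    d <- run$design
    stopifnot(inherits(d, "psft_run_design"))
    if (r > 1) {
      d1 <- runs[[1]]$design
      if (d$tr_seconds != d1$tr_seconds || d$n_blocks != d1$n_blocks ||
          d$block_duration != d1$block_duration ||
          d$blank_duration != d1$blank_duration)
        stopf("run %d has a different TR or block structure than run 1", r)
    }
    js <- which(d$condition_per_block == condition)
    if (length(js) == 0) stopf("condition '%s' absent from run %d", condition, r)
    track <- as_sf_track(run$sfseq)
    mat <- is.matrix(run$series)
    n_tr <- if (mat) ncol(run$series) else length(run$series)
    stopifnot(n_tr == d$n_trs, length(track) == d$n_trs)
    for (j in js) {
      idx <- block_trs(d, j, include_blank = TRUE)
      k <- k + 1L
      seg_series[[k]] <- if (mat) run$series[, idx, drop = FALSE] else run$series[idx]
      seg_track[[k]] <- track[idx]
      bnd[[k]] <- data.frame(run = r, block = j, start = pos + 1L,
                             end = pos + length(idx))
      pos <- pos + length(idx)
    }
  }
  series <- if (is.matrix(runs[[1]]$series)) do.call(cbind, seg_series)
            else unlist(seg_series, use.names = FALSE)
  list(series = series, sf_track = unlist(seg_track, use.names = FALSE),
       boundaries = do.call(rbind, bnd))
}

#' Exhaustive-grid fit with closed-form scaling (independent oracle)
#'
#' Brute-force reference fit: evaluates a dense grid over (`mu`, `sigma`)
#' — `n_mu` log-spaced by `n_sigma` linearly spaced cells over the full
#' bounds — and solves (`beta`, `beta0`) in closed form by ordinary least
#' squares per cell. Used to validate the coarse-to-fine pipeline; it
#' shares no code path with the optimizer beyond the forward model.
#'
#' @param y Measured series.
#' @param sf_track Matching SF track.
#' @param n_mu,n_sigma Grid sizes (defaults 400 and 400).
#' @param basis Optional precomputed [psft_basis()].
#' @param ... Passed to [psft_basis()] when `basis` is NULL.
#' @return List with `mu`, `sigma`, `beta`, `beta0`, `sse`, and the grid
#'   steps `mu_step` (log ratio) and `sigma_step`.
#' @export
exhaustive_grid_fit <- function(y, sf_track, n_mu = 400, n_sigma = 400,
                                basis = NULL, ...) {
  if (is.null(basis)) basis <- psft_basis(sf_track, ...)
  stopifnot(length(y) == basis$n)
  b <- psft_bounds()
  mu_g <- exp(seq(log(b$mu[1]), log(b$mu[2]), length.out = n_mu))
  sg_g <- seq(b$sigma[1], b$sigma[2], length.out = n_sigma)
  cells <- expand.grid(mu = mu_g, sigma = sg_g)

  R <- level_responses(basis$levels, cells$mu, cells$sigma)
  n <- basis$n
  Sy <- sum(y); Syy <- sum(y^2)
  Sp <- drop(crossprod(R, basis$s))            # sum of prediction
  Spp <- colSums(R * (basis$G %*% R))          # sum of squared prediction
  Spy <- drop(crossprod(R, crossprod(basis$M, y)))
  Spp_c <- Spp - Sp^2 / n
  Spy_c <- Spy - Sp * Sy / n
  beta <- ifelse(Spp_c > 1e-12, Spy_c / pmax(Spp_c, 1e-300), 0)
  beta <- pmin(pmax(beta, b$beta[1]), b$beta[2])
  beta0 <- pmin(pmax(Sy / n - beta * Sp / n, b$beta0[1]), b$beta0[2])
  sse <- Syy - 2 * beta0 * Sy - 2 * beta * Spy + n * beta0^2 +
    2 * beta0 * beta * Sp + beta^2 * Spp

  win <- which(signif(sse, 12) == min(signif(sse, 12)))
  list(mu = mean(cells$mu[win]), sigma = mean(cells$sigma[win]),
       beta = mean(beta[win]), beta0 = mean(beta0[win]), sse = min(sse),
       mu_step = log(b$mu[2] / b$mu[1]) / (n_mu - 1),
       sigma_step = diff(b$sigma) / (n_sigma - 1))
}

#' Fit every voxel of a simulated or measured session for one condition
#'
#' Convenience driver: concatenates the condition's blocks across runs,
#' precomputes the stimulus basis once, and runs the coarse-to-fine +
#' bounded least-squares fit for each voxel row.
#'
#' @param runs List of runs as in [concatenate_condition_blocks()], with
#'   `series` a voxels-by-TR matrix (rownames taken as voxel ids).
#' @param condition Condition label.
#' @param rebaseline Re-anchor each spliced series at its blank-period
#'   mean before fitting (default TRUE; see [rebaseline_to_blanks()]).
#' @param ... Passed to [fit_psft()].
#' @return data.frame with one row per voxel: `voxel_id`, `condition`,
#'   `mu`, `sigma`, `beta`, `beta0`, `sse`, `r2`, `converged`.
#' @export
fit_population <- function(runs, condition, rebaseline = TRUE, ...) {
  cc <- concatenate_condition_blocks(runs, condition)
  stopifnot(is.matrix(cc$series))
  if (rebaseline)
    cc$series <- rebaseline_to_blanks(cc$series, cc$sf_track,
                                      runs[[1]]$sfseq$blank_code)
  basis <- psft_basis(cc$sf_track)
  ids <- rownames(cc$series)
  if (is.null(ids)) ids <- sprintf("v%04d", seq_len(nrow(cc$series)))
  fits <- lapply(seq_len(nrow(cc$series)), function(i) {
    f <- fit_psft(cc$series[i, ], sf_track = NULL, basis = basis,
                  voxel_id = ids[i], condition = condition, ...)
    data.frame(voxel_id = ids[i], condition = condition,
               mu = f$params[["mu"]], sigma = f$params[["sigma"]],
               beta = f$params[["beta"]], beta0 = f$params[["beta0"]],
               sse = f$sse, r2 = as.numeric(f$r2), converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, fits)
}
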