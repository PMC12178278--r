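# Block concatenation, grid searches, bounded least squares, R-squared.

test_that("condition blocks splice with their trailing blanks across runs", {
  pop <- sample_population(2, seed = 1)
  sched <- build_session_schedule(9, seed = 3)
  sess <- simulate_session(pop, sched, seed = 3)
  cc <- concatenate_condition_blocks(sess, "AttendLSF")
  expect_identical(nrow(cc$boundaries), 18L)          # 9 runs x 2 blocks
  expect_identical(ncol(cc$series), cc$boundaries$end[18])
  expect_length(cc$sf_track, cc$boundaries$end[18])
  # every segment ends with blank-sentinel TRs (the trailing 10 s blank)
  for (i in seq_len(18)) {
    tail_idx <- (cc$boundaries$end[i] - 8):cc$boundaries$end[i]
    expect_true(all(cc$sf_track[tail_idx] == sess[[1]]$sfseq$blank_code))
  }
})

test_that("a single matching block splices to ceil(50.5) TRs and round-trips", {
  d <- build_run_design(n_blocks = 1, conditions = "OnlyOne", seed = 2)
  s <- build_probe_sf_sequence(d, seed = 2)
  series <- matrix(rnorm(d$n_trs), 1)
  cc <- concatenate_condition_blocks(list(list(design = d, sfseq = s,
                                               series = series)), "OnlyOne")
  expect_identical(ncol(cc$series), 51L)
  idx <- psft:::block_trs(d, 1, include_blank = TRUE)
  expect_equal(cc$series[1, ], series[1, idx])
  expect_equal(cc$sf_track, s$sf_per_tr[idx])
  expect_error(concatenate_condition_blocks(list(list(design = d, sfseq = s,
                                                      series = series)), "Other"),
               "absent")
})

test_that("coarse grid spans the full bounds with 100 cells", {
  s <- default_sequence()
  y <- predict_bold(s, psft_params(1, 0.8, 1, 0))
  cg <- coarse_grid_search(y, s$sf_per_tr)
  expect_identical(nrow(cg$grid), 100L)
  expect_equal(range(cg$grid$mu), c(0.009, 6))
  expect_equal(range(cg$grid$sigma), c(0.1, 4))
})

test_that("noiseless data generated at a coarse grid node is found exactly", {
  s <- default_sequence()
  mu_node <- exp(seq(log(0.009), log(6), length.out = 10))[6]
  sg_node <- seq(0.1, 4, length.out = 10)[4]
  y <- predict_bold(s, psft_params(mu_node, sg_node, 1, 0))
  cg <- coarse_grid_search(y, s$sf_per_tr)
  expect_equal(cg$mu, mu_node, tolerance = 1e-12)
  expect_equal(cg$sigma, sg_node, tolerance = 1e-12)
})

test_that("fine grid has 10,000 cells, spans half-to-double, clips at bounds", {
  s <- default_sequence()
  y <- predict_bold(s, psft_params(1, 0.8, 1, 0)) + 0.05
  basis <- psft_basis(s$sf_per_tr)
  cg <- coarse_grid_search(y, NULL, basis = basis)
  fg <- fine_grid_search(y, NULL, coarse_best = cg, basis = basis)
  expect_within(fg[["mu"]], cg$mu / 2 - 1e-12, cg$mu * 2 + 1e-12)
  expect_lte(attr(fg, "sse"), cg$sse * (1 + 1e-9))
  # a coarse best near the upper sigma bound must clip, not escape
  fg2 <- fine_grid_search(y, NULL, coarse_best = list(mu = 5, sigma = 3.9),
                          basis = basis)
  expect_lte(fg2[["sigma"]], 4)
  expect_lte(fg2[["mu"]], 6)
})

test_that("exactly tied grid minima are averaged", {
  tie <- psft:::grid_argmin(mu = c(1, 2, 3), sigma = c(0.5, 0.7, 0.9),
                            sse = c(5, 5, 7))
  expect_equal(tie$mu, 1.5)
  expect_equal(tie$sigma, 0.6)
  expect_identical(tie$n_tied, 2L)
  # sub-rounding SSE differences do not suppress the averaging rule
  tie2 <- psft:::grid_argmin(mu = c(1, 2), sigma = c(0.5, 0.7),
                             sse = c(5, 5 * (1 + 1e-14)))
  expect_equal(tie2$mu, 1.5)
})

test_that("noiseless fits recover parameters within 1% and never worsen the init", {
  s <- default_sequence()
  basis <- psft_basis(s$sf_per_tr)
  cases <- list(c(0.4, 0.6, 1.5, 0.3), c(2.5, 1.2, 0.8, -0.2), c(1, 2.5, 0.5, 0))
  for (p in cases) {
    y <- predict_bold(s, psft_params(p[1], p[2], p[3], p[4]))
    f <- fit_psft(y, NULL, basis = basis)
    expect_lt(abs(f$params[["mu"]] - p[1]) / p[1], 0.01)
    expect_lt(abs(f$params[["sigma"]] - p[2]) / p[2], 0.01)
    expect_lte(f$sse, f$init_sse)
    expect_true(f$converged)
  }
})

test_that("fits are deterministic, in-bounds, and SSE never exceeds the init", {
  s <- default_sequence()
  basis <- psft_basis(s$sf_per_tr)
  b <- psft_bounds()
  set.seed(42)
  for (i in 1:8) {
    y <- predict_bold(s, psft_params(runif(1, 0.1, 5), runif(1, 0.2, 3.5),
                                     runif(1, -2, 2), runif(1, -1, 1))) +
      rnorm(313, 0, 0.5)
    f1 <- fit_psft(y, NULL, basis = basis)
    f2 <- fit_psft(y, NULL, basis = basis)
    expect_identical(f1$params, f2$params)
    expect_lte(f1$sse, f1$init_sse)
    expect_within(f1$params[["mu"]], b$mu[1], b$mu[2])
    expect_within(f1$params[["sigma"]], b$sigma[1], b$sigma[2])
    expect_within(f1$params[["beta"]], b$beta[1], b$beta[2])
    expect_within(f1$params[["beta0"]], b$beta0[1], b$beta0[2])
  }
})

test_that("a constant series fits with near-zero SSE and flagged R-squared", {
  s <- default_sequence()
  y <- rep(0.8, 313)
  f <- fit_psft(y, s$sf_per_tr)
  expect_lt(f$sse, 1e-10)
  expect_equal(as.numeric(f$r2), 0)
  expect_true(isTRUE(attr(f$r2, "zero_variance")))
})

test_that("R-squared follows the coefficient-of-determination convention", {
  y <- c(1, 2, 3, 4, 6)
  expect_equal(r_squared(y, y), 100)
  expect_equal(as.numeric(r_squared(rep(mean(y), 5), y)), 0)
  expect_lt(r_squared(rev(y), y), 0)
})

test_that("grid SSE through the basis equals direct convolution per cell", {
  s <- default_sequence()
  basis <- psft_basis(s$sf_per_tr)
  set.seed(7)
  y <- rnorm(313)
  for (p in list(c(0.3, 0.5), c(1.7, 2.2), c(5.5, 3.8))) {
    direct <- sum((y - predict_bold(s$sf_per_tr, psft_params(p[1], p[2], 1, 0)))^2)
    via_basis <- psft:::grid_sse(basis, y, p[1], p[2])
    expect_equal(via_basis, direct, tolerance = 1e-9)
  }
})

test_that("percent signal change normalizes against the blank mean", {
  x <- c(100, 100, 102, 104)
  expect_equal(percent_signal_change(x, blank_idx = 1:2), c(0, 0, 2, 4))
  expect_equal(mean(percent_signal_change(x)), 0)
  expect_error(percent_signal_change(c(0, 0)), "zero")
})

test_that("the optimizer beats the exhaustive-grid oracle on small cases", {
  s <- default_sequence()
  basis <- psft_basis(s$sf_per_tr)
  set.seed(13)
  for (i in 1:3) {
    y <- predict_bold(s, psft_params(runif(1, 0.3, 3), runif(1, 0.3, 2), 1.2, 0.1)) +
      rnorm(313, 0, 0.4)
    f <- fit_psft(y, NULL, basis = basis)
    bf <- exhaustive_grid_fit(y, NULL, n_mu = 150, n_sigma = 150, basis = basis)
    expect_lte(f$sse, bf$sse * (1 + 1e-9))
  }
})
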