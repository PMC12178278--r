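# Ground-truth populations, attention shifts, and simulated BOLD series.

test_that("populations are reproducible and respect the probe aperture", {
  pop <- sample_population(120, seed = 9)
  expect_identical(pop, sample_population(120, seed = 9))
  expect_false(identical(pop$mu, sample_population(120, seed = 10)$mu))
  expect_within(min(pop$prf_ecc), 0.16, 9.8)
  expect_within(max(pop$prf_ecc), 0.16, 9.8)
  expect_true(all(pop$prf_polar > 100 & pop$prf_polar < 260)) # left wedge
  right <- sample_population(60, seed = 9, hemifield = "right")
  expect_true(all(right$prf_polar > 280 | right$prf_polar < 80))
  expect_identical(nrow(sample_population(0, seed = 1)), 0L)
})

test_that("ground-truth tuning follows the eccentricity trends and stays in bounds", {
  pop <- sample_population(500, seed = 4)
  expect_lt(cor(pop$prf_ecc, pop$mu, method = "spearman"), -0.5)
  expect_gt(cor(pop$prf_ecc, pop$sigma, method = "spearman"), 0.5)
  b <- psft_bounds()
  expect_true(all(pop$mu > b$mu[1] & pop$mu < b$mu[2]))
  expect_true(all(pop$sigma > b$sigma[1] & pop$sigma < b$sigma[2]))
  expect_true(all(pop$beta > b$beta[1] & pop$beta < b$beta[2]))
  # bandwidth also rises across the ROI hierarchy
  m <- tapply(pop$sigma, pop$roi, mean)
  expect_true(m[["V1"]] < m[["V2"]] && m[["V2"]] < m[["V3"]])
})

test_that("attention shifts invert the modulation index exactly", {
  pop <- sample_population(50, seed = 6)
  # a voxel whose baseline peak equals the attended SF does not move
  pop$mu[1] <- 0.5
  sh <- apply_attention_shift(pop, "AttendLSF", shift_model(0.5, -10, 3))
  expect_equal(sh$mu[1], 0.5)
  # dissimilarity +1 octave at slope -10 %/oct forces AMI(peak) = -10
  pop$mu[2] <- 1
  sh <- apply_attention_shift(pop, "AttendLSF", shift_model(0.5, -10, 3))
  expect_equal(ami(sh$mu[2], 1), -10)
  # generally AMI == slope * dissimilarity for every voxel
  d <- dissimilarity_octaves(pop$mu, 0.5)
  expect_equal(ami(sh$mu, pop$mu), -10 * d, tolerance = 1e-12)
  expect_equal(ami(sh$sigma, pop$sigma), 3 * d, tolerance = 1e-12)
  # baseline condition returns the ground truth untouched
  base <- apply_attention_shift(pop, "AttendFixation", NULL)
  expect_equal(base$mu, pop$mu)
})

test_that("out-of-bounds shifts are clipped with a warning", {
  pop <- sample_population(3, seed = 2)
  pop$mu[] <- 4.5 # far above the 2 cpd attended SF -> large attractive shift
  expect_warning(
    sh <- apply_attention_shift(pop, "AttendHSF", shift_model(2, 60, 0)),
    "clipped")
  expect_true(all(sh$mu <= 6))
})

test_that("noiseless simulation equals the forward model exactly", {
  pop <- sample_population(3, seed = 8, noise_sd = 0)
  d <- default_design(); s <- default_sequence()
  sim <- simulate_timeseries(pop, "AttendFixation", d, s, seed = 1)
  for (v in 1:3) {
    pred <- predict_bold(s, psft_params(pop$mu[v], pop$sigma[v],
                                        pop$beta[v], pop$beta0[v]))
    expect_equal(sim[v, ], pred, ignore_attr = TRUE)
  }
})

test_that("noise has the configured SD and is seed-stable per condition", {
  pop <- sample_population(1, seed = 3, noise_sd = 0.7)
  d <- default_design(); s <- default_sequence()
  pred <- predict_bold(s, psft_params(pop$mu, pop$sigma, pop$beta, pop$beta0))
  resid <- unlist(lapply(1:40, function(k)
    simulate_timeseries(pop, "AttendFixation", d, s, seed = k)[1, ] - pred))
  expect_equal(sd(resid), 0.7, tolerance = 0.05 * 0.7) # ~12,500 samples
  a <- simulate_timeseries(pop, "AttendFixation", d, s, seed = 5)
  expect_identical(a, simulate_timeseries(pop, "AttendFixation", d, s, seed = 5))
  # zero-slope shift models: identical params, different noise across conditions
  flat <- default_shift_models(peak_slope = 0, bandwidth_slope = 0)
  b <- simulate_timeseries(pop, "AttendLSF", d, s, seed = 5, models = flat)
  expect_false(identical(a, b))
})

test_that("misaligned design and sequence are rejected", {
  pop <- sample_population(1, seed = 1)
  d <- default_design()
  s_short <- build_probe_sf_sequence(build_run_design(n_blocks = 3, seed = 1), seed = 1)
  expect_error(simulate_timeseries(pop, "AttendFixation", d, s_short, seed = 1),
               "misaligned")
})

test_that("interleaved runs switch parameters at block boundaries", {
  pop <- sample_population(1, seed = 5, noise_sd = 0)
  pop$mu <- 1; pop$sigma <- 0.6; pop$beta <- 1; pop$beta0 <- 0
  d <- build_run_design(seed = 17)
  s <- build_probe_sf_sequence(d, seed = 17)
  run <- simulate_run(pop, d, s, seed = 1)[1, ]
  # reconstruct with an explicit per-TR response using each block's condition
  bi <- psft:::tr_block_index(d)
  models <- default_shift_models()
  r <- numeric(d$n_trs)
  for (t in seq_len(d$n_trs)) {
    cn <- if (is.na(bi[t])) "AttendFixation" else d$condition_per_block[bi[t]]
    p <- apply_attention_shift(pop, cn, models[[cn]])
    r[t] <- sf_response(s$sf_per_tr[t], p$mu, p$sigma)
  }
  expected <- psft:::convolve_causal(r, hirf_kernel())
  expect_equal(run, expected, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("noise calibration hits the expected variance-explained target", {
  pop <- sample_population(20, seed = 12)
  d <- default_design(); s <- default_sequence()
  cal <- calibrate_noise_sd(pop, d, s, target_r2 = 0.4)
  pred <- psft:::predict_matrix(
    apply_attention_shift(pop, "AttendFixation", NULL), s$sf_per_tr)
  sig_sd <- apply(pred, 1, sd)
  expect_equal(cal$noise_sd, sig_sd * sqrt(1.5), tolerance = 1e-12)
})

test_that("population tables serialize to plain text", {
  pop <- sample_population(5, seed = 2)
  d <- default_design(); s <- default_sequence()
  sim <- simulate_timeseries(pop, "AttendFixation", d, s, seed = 1)
  dir <- file.path(tempdir(), "synthpop")
  write_population(pop, list(AttendFixation = sim), dir, seed = 2)
  back <- read.delim(file.path(dir, "voxels.tsv"))
  expect_equal(back$mu, pop$mu, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "series_AttendFixation.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
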