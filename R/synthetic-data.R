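# Synthetic voxel populations with known ground-truth tuning, used for
# parameter-recovery and slope-recovery validation of the pipeline.

# Per-ROI generative defaults. Baseline peak SF follows a log-linear
# decline with eccentricity, log mu = a - b * ecc, spanning roughly
# 0.3-3 cpd over the 0.16-9.8 deg probe aperture and sitting lower/steeper
# for V3; bandwidth rises linearly with eccentricity and ROI order. These
# emulate the canonical eccentricity trends (peak falls, bandwidth rises
# from V1 to V3); the exact coefficients are package defaults, not
# measured values.
roi_profiles <- function() {
  data.frame(
    roi = c("V1", "V2", "V3"),
    mu_a = log(c(3.0, 2.6, 2.0)), mu_b = c(0.21, 0.21, 0.19),
    sigma_c = c(0.8, 1.0, 1.2), sigma_d = c(0.06, 0.08, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Sample a synthetic voxel population with ground-truth tuning
#'
#' Draws voxels with pRF attributes (eccentricity within the probe
#' aperture, polar angle inside the hemifield wedge, size increasing with
#' eccentricity, fit quality) and baseline pSFT parameters that follow the
#' canonical trends: peak SF declines log-linearly with eccentricity and
#' bandwidth rises with eccentricity and ROI order V1 to V3, with
#' log-normal scatter. All ground-truth parameters lie strictly inside the
#' optimizer bounds so recovery is feasible.
#'
#' @param n_voxels Number of voxels.
#' @param roi_mix Named proportions over V1/V2/V3 (must sum to 1).
#' @param seed Integer seed.
#' @param hemifield `"left"` or `"right"`: which hemifield the probe
#'   occupied (determines the polar-angle wedge of the sampled pRFs).
#' @param ecc_range Eccentricity range in degrees (default the probe
#'   aperture, 0.16 to 9.8).
#' @param noise_sd Default per-voxel measurement noise SD in percent
#'   signal change (constant 0.5 unless recalibrated with
#'   [calibrate_noise_sd()]).
#' @param subject Subject label recorded on every row.
#' @return data.frame of class `psft_population`: `voxel_id`, `subject`,
#'   `roi`, `prf_ecc`, `prf_polar`, `prf_size`, `prf_r2`, baseline
#'   ground-truth `mu`, `sigma`, `beta`, `beta0`, and `noise_sd`.
#' @export
sample_population <- function(n_voxels, roi_mix = c(V1 = 0.45, V2 = 0.35, V3 = 0.20),
                              seed = 1L, hemifield = c("left", "right"),
                              ecc_range = c(0.16, 9.8), noise_sd = 0.5,
                              subject = "S1") {
  hemifield <- match.arg(hemifield)
  stopifnot(n_voxels >= 0, abs(sum(roi_mix) - 1) < 1e-8)
  if (n_voxels == 0) {
    out <- data.frame(voxel_id = character(0), subject = character(0),
                      roi = character(0), prf_ecc = numeric(0),
                      prf_polar = numeric(0), prf_size = numeric(0),
                      prf_r2 = numeric(0), mu = numeric(0), sigma = numeric(0),
                      beta = numeric(0), beta0 = numeric(0),
                      noise_sd = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("psft_population", "data.frame")
    return(out)
  }
  prof <- roi_profiles()
  out <- with_seed(seed, {
    roi <- sample(names(roi_mix), n_voxels, replace = TRUE, prob = roi_mix)
    ecc <- runif(n_voxels, ecc_range[1], ecc_range[2])
    polar <- if (hemifield == "left") runif(n_voxels, 100, 260)
             else runif(n_voxels, 280, 440) %% 360
    size <- pmax(0.15, 0.5 + 0.15 * ecc + rnorm(n_voxels, 0, 0.15))
    r2 <- runif(n_voxels, 2, 80)
    i <- match(roi, prof$roi)
    mu <- exp(prof$mu_a[i] - prof$mu_b[i] * ecc + rnorm(n_voxels, 0, 0.15))
    sigma <- prof$sigma_c[i] + prof$sigma_d[i] * ecc + rnorm(n_voxels, 0, 0.10)
    data.frame(
      voxel_id = sprintf("%s_v%04d", subject, seq_len(n_voxels)),
      subject = subject, roi = roi, prf_ecc = ecc, prf_polar = polar,
      prf_size = size, prf_r2 = r2,
      mu = pmin(pmax(mu, 0.05), 4.8),
      sigma = pmin(pmax(sigma, 0.15), 3.5),
      beta = rlnorm(n_voxels, 0, 0.2),
      beta0 = rnorm(n_voxels, 0, 0.2),
      noise_sd = noise_sd, stringsAsFactors = FALSE
    )
  })
  class(out) <- c("psft_population", "data.frame")
  out
}

#' Attentional shift model for the generator
#'
#' Specifies how attending an SF moves a voxel's ground-truth tuning: the
#' condition parameters are constructed so that the attentional modulation
#' index equals `slope * dissimilarity` exactly, where dissimilarity is
#' the octave distance of the baseline peak from the attended SF. Negative
#' `peak_slope` is attractive (peaks move toward the attended SF).
#'
#' @param attended_sf Attended SF in cpd.
#' @param peak_slope Peak AMI (percent) per octave of dissimilarity
#'   (default -10, attractive).
#' @param bandwidth_slope Bandwidth AMI (percent) per octave (default +3,
#'   the sharper-to-broader direction).
#' @return List of class `shift_model`.
#' @export
shift_model <- function(attended_sf, peak_slope = -10, bandwidth_slope = 3) {
  stopifnot(attended_sf > 0)
  structure(list(attended_sf = attended_sf, peak_slope = peak_slope,
                 bandwidth_slope = bandwidth_slope), class = "shift_model")
}

#' Default shift models for the two attention conditions
#'
#' @param peak_slope,bandwidth_slope Shared slopes (AMI percent per
#'   octave) applied in both conditions.
#' @return Named list of [shift_model()] for AttendLSF (0.5 cpd) and
#'   AttendHSF (2 cpd).
#' @export
default_shift_models <- function(peak_slope = -10, bandwidth_slope = 3) {
  sfs <- attended_sfs()
  stats::setNames(lapply(names(sfs), function(cn)
    shift_model(sfs[[cn]], peak_slope, bandwidth_slope)), names(sfs))
}

# Invert AMI = v for parameter b (baseline): condition value
# a = b (100 + v) / (100 - v). Requires |v| < 100.
invert_ami <- function(b, v) {
  if (any(abs(v) >= 100))
    stopf("configured shift implies |AMI| >= 100%%; reduce the slope")
  b * (100 + v) / (100 - v)
}

#' Ground-truth parameters of a population under an attention condition
#'
#' For the baseline condition the ground-truth parameters are returned
#' unchanged. For an attention condition, each voxel's peak and bandwidth
#' are shifted so that the AMI against baseline equals
#' `slope * dissimilarity_octaves(baseline mu, attended SF)` exactly
#' (the generative inverse of the measured-slope analysis). Shifted
#' parameters escaping the optimizer bounds are clipped and flagged.
#'
#' @param population A [sample_population()] data.frame.
#' @param condition Condition label.
#' @param model A [shift_model()]; ignored for the baseline condition.
#' @param baseline Baseline condition label (default `"AttendFixation"`).
#' @return data.frame `voxel_id`, `mu`, `sigma`, `beta`, `beta0`,
#'   `clipped`.
#' @export
apply_attention_shift <- function(population, condition, model = NULL,
                                  baseline = "AttendFixation") {
  out <- data.frame(voxel_id = population$voxel_id, mu = population$mu,
                    sigma = population$sigma, beta = population$beta,
                    beta0 = population$beta0, clipped = FALSE,
                    stringsAsFactors = FALSE)
  if (condition == baseline || nrow(out) == 0) return(out)
  stopifnot(inherits(model, "shift_model"))
  b <- psft_bounds()
  dis <- dissimilarity_octaves(population$mu, model$attended_sf)
  mu_c <- invert_ami(population$mu, model$peak_slope * dis)
  sg_c <- invert_ami(population$sigma, model$bandwidth_slope * dis)
  clip <- mu_c < b$mu[1] | mu_c > b$mu[2] | sg_c < b$sigma[1] | sg_c > b$sigma[2]
  out$mu <- pmin(pmax(mu_c, b$mu[1]), b$mu[2])
  out$sigma <- pmin(pmax(sg_c, b$sigma[1]), b$sigma[2])
  out$clipped <- clip
  if (any(clip))
    warning(sprintf("%d voxel(s) clipped to the parameter bounds after the attention shift",
                    sum(clip)))
  out
}

# Noiseless predictions for a whole parameter table over one track,
# through the shared basis (rows = voxels).
predict_matrix <- function(params_df, sf_track, basis = NULL) {
  if (is.null(basis)) basis <- psft_basis(sf_track)
  R <- level_responses(basis$levels, params_df$mu, params_df$sigma) # L x V
  P <- basis$M %*% R # T x V
  t(sweep(sweep(P, 2, params_df$beta, "*"), 2, params_df$beta0, "+"))
}

#' Simulate per-condition BOLD time series for a population
#'
#' Forward-model prediction for every voxel as if the whole run were
#' spent in `condition`, plus i.i.d. Gaussian measurement noise of each
#' voxel's `noise_sd`, seeded per voxel and condition.
#'
#' @param population A [sample_population()] data.frame.
#' @param condition Condition label.
#' @param design A `psft_run_design`.
#' @param sfseq Matching `psft_sf_sequence`.
#' @param seed Integer seed (combined with voxel index and condition).
#' @param models Named list of [shift_model()] per attention condition
#'   (default [default_shift_models()]).
#' @param baseline Baseline condition label.
#' @return Voxels-by-TR matrix of percent signal change (rownames =
#'   voxel ids).
#' @export
simulate_timeseries <- function(population, condition, design, sfseq,
                                seed = 1L, models = default_shift_models(),
                                baseline = "AttendFixation") {
  stopifnot(inherits(design, "psft_run_design"),
            inherits(sfseq, "psft_sf_sequence"))
  if (sfseq$n_trs != design$n_trs)
    stopf("design (%d TRs) and sequence (%d TRs) are misaligned",
          design$n_trs, sfseq$n_trs)
  pars <- apply_attention_shift(population, condition, models[[condition]],
                                baseline = baseline)
  pred <- predict_matrix(pars, sfseq$sf_per_tr)
  ci <- match(condition, c(baseline, names(models)))
  noisy <- add_noise(pred, population$noise_sd, seed, ci)
  rownames(noisy) <- population$voxel_id
  noisy
}

add_noise <- function(pred, noise_sd, seed, cond_index) {
  out <- pred
  for (v in seq_len(nrow(pred))) {
    if (noise_sd[v] > 0)
      out[v, ] <- pred[v, ] + with_seed(
        derive_seed(seed, v * 13L + cond_index),
        rnorm(ncol(pred), 0, noise_sd[v]))
  }
  out
}

#' Simulate one run with its per-block condition schedule
#'
#' Builds the neural response track TR by TR using the parameters of the
#' condition each block belongs to (blank TRs respond at the sentinel SF,
#' so their condition is immaterial), convolves once with the HIRF, and
#' adds seeded Gaussian noise. This mirrors how an interleaved scan mixes
#' conditions within a run, including hemodynamic bleed across block
#' boundaries.
#'
#' @inheritParams simulate_timeseries
#' @param run Run index used in the noise sub-seed.
#' @return Voxels-by-TR matrix of percent signal change.
#' @export
simulate_run <- function(population, design, sfseq, seed = 1L,
                         models = default_shift_models(),
                         baseline = "AttendFixation", run = 1L) {
  stopifnot(sfseq$n_trs == design$n_trs)
  conds <- unique_conditions(design)
  bi <- tr_block_index(design)
  k <- hirf_kernel()
  track <- sfseq$sf_per_tr
  n_vox <- nrow(population)
  pred <- matrix(0, n_vox, design$n_trs)
  for (v in seq_len(n_vox)) {
    r <- numeric(design$n_trs)
    for (cn in conds) {
      pars <- apply_attention_shift(population[v, , drop = FALSE], cn,
                                    models[[cn]], baseline = baseline)
      sel <- !is.na(bi) & design$condition_per_block[pmax(bi, 1L)] == cn
      resp_c <- sf_response(track, pars$mu, pars$sigma)
      r[sel] <- resp_c[sel]
      # blanks: response at the sentinel SF (identical across conditions)
      if (cn == conds[1]) r[is.na(bi)] <- resp_c[is.na(bi)]
    }
    pred[v, ] <- population$beta0[v] + population$beta[v] * convolve_causal(r, k)
  }
  out <- add_noise(pred, population$noise_sd, derive_seed(seed, run), 0L)
  rownames(out) <- population$voxel_id
  out
}

#' Simulate a full multi-run session
#'
#' @inheritParams simulate_run
#' @param schedule List of run designs from [build_session_schedule()].
#' @param seqs Optional list of `psft_sf_sequence` per run; generated from
#'   each run's seed when NULL.
#' @return List of runs, each a list with `design`, `sfseq`, `series` —
#'   the input format of [concatenate_condition_blocks()] and
#'   [fit_population()].
#' @export
simulate_session <- function(population, schedule, seqs = NULL, seed = 1L,
                             models = default_shift_models(),
                             baseline = "AttendFixation") {
  if (is.null(seqs))
    seqs <- lapply(schedule, function(d) build_probe_sf_sequence(d, seed = d$seed))
  stopifnot(length(seqs) == length(schedule))
  lapply(seq_along(schedule), function(r) {
    list(design = schedule[[r]], sfseq = seqs[[r]],
         series = simulate_run(population, schedule[[r]], seqs[[r]],
                               seed = seed, models = models,
                               baseline = baseline, run = r))
  })
}

#' Calibrate per-voxel noise to a target expected fit quality
#'
#' Sets each voxel's `noise_sd` so the expected variance-explained of the
#' (noiseless-signal) model equals `target_r2`:
#' `noise_sd = sd(signal) * sqrt((1 - t) / t)`. The signal is the
#' baseline-condition prediction over the spliced baseline track — the
#' series the model is actually fitted to.
#'
#' @param population A [sample_population()] data.frame.
#' @param design A `psft_run_design`.
#' @param sfseq Matching `psft_sf_sequence`.
#' @param target_r2 Target expected R-squared as a fraction (default 0.4).
#' @param baseline Baseline condition label.
#' @return The population with `noise_sd` replaced.
#' @export
calibrate_noise_sd <- function(population, design, sfseq, target_r2 = 0.4,
                               baseline = "AttendFixation") {
  stopifnot(target_r2 > 0, target_r2 < 1)
  pars <- apply_attention_shift(population, baseline, NULL, baseline = baseline)
  pred <- predict_matrix(pars, sfseq$sf_per_tr)
  sig_sd <- apply(pred, 1, sd)
  population$noise_sd <- sig_sd * sqrt((1 - target_r2) / target_r2)
  population
}

#' Write a synthetic population and its time series to plain-text files
#'
#' @param population A [sample_population()] data.frame.
#' @param series Named list of voxels-by-TR matrices (one per condition),
#'   or NULL to write only the voxels table.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the JSON manifest.
#' @return Invisibly, the directory.
#' @export
write_population <- function(population, series = NULL, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(population, file.path(dir, "voxels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cn in names(series))
    write.table(series[[cn]], file.path(dir, paste0("series_", cn, ".tsv")),
                sep = "\t", quote = FALSE, row.names = TRUE, col.names = FALSE)
  jsonlite::write_json(
    list(n_voxels = nrow(population), seed = seed,
         conditions = names(series) %||% character(0)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
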