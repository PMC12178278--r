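# Attentional modulation: AMI, octave dissimilarity, modulation records,
# subject-wise slopes.

#' Attentional modulation index
#'
#' `AMI(%) = 100 * (a - b) / (a + b)`, with `a` the attention-condition
#' parameter estimate and `b` the baseline estimate, so a negative peak
#' AMI is a downward shift of the peak relative to baseline. For positive
#' inputs the index is bounded in (-100, 100) and antisymmetric in its
#' arguments. Pairs with `a + b == 0` are undefined and returned as NA
#' with a warning.
#'
#' @param a Attention-condition estimate(s).
#' @param b Baseline estimate(s).
#' @return AMI in percent (vectorized).
#' @export
ami <- function(a, b) {
  out <- 100 * (a - b) / (a + b)
  zero <- (a + b) == 0
  if (any(zero)) {
    warning(sprintf("%d AMI value(s) undefined (a + b = 0); returned NA", sum(zero)))
    out[zero] <- NA_real_
  }
  out
}

#' Octave dissimilarity from the attended spatial frequency
#'
#' `log2(mu_baseline / attended_sf)`: positive when the baseline peak is
#' above the attended SF. A voxel with a 1 cpd baseline peak is +1 octave
#' from the 0.5 cpd low-SF stream and simultaneously -1 octave from the
#' 2 cpd high-SF stream; the two dissimilarities always differ by exactly
#' `log2(2.0 / 0.5) = 2` octaves.
#'
#' @param mu_baseline Baseline peak SF(s) in cpd; positive.
#' @param attended_sf Attended SF in cpd; positive.
#' @return Dissimilarity in octaves (vectorized).
#' @export
dissimilarity_octaves <- function(mu_baseline, attended_sf) {
  if (any(mu_baseline <= 0) || any(attended_sf <= 0))
    stopf("spatial frequencies must be positive")
  log2(mu_baseline / attended_sf)
}

#' Per-voxel modulation records
#'
#' Joins per-condition fits into one record per voxel and attention
#' condition: peak and bandwidth AMIs against the baseline condition, the
#' baseline dissimilarity from both attended SFs, and the identifiers
#' needed for slope and group statistics. Voxels lacking a baseline fit or
#' the condition fit are dropped.
#'
#' @param fits Fits table (`voxel_id`, `condition`, `mu`, `sigma`; `roi`
#'   joined from `voxels` if absent).
#' @param voxels Voxels table supplying `subject`, `roi`, `prf_ecc`,
#'   `prf_size`.
#' @param baseline Baseline condition label.
#' @param attended Named attended SFs per condition (default
#'   [attended_sfs()]).
#' @return data.frame with `voxel_id`, `subject`, `roi`, `condition`,
#'   `ami_peak`, `ami_bandwidth`, `dissim` (from that condition's attended
#'   SF), `dissim_lsf`, `dissim_hsf`, `prf_ecc`, `prf_size`.
#' @export
compute_modulation <- function(fits, voxels, baseline = "AttendFixation",
                               attended = attended_sfs()) {
  if (!"roi" %in% names(fits))
    fits$roi <- voxels$roi[match(fits$voxel_id, voxels$voxel_id)]
  base <- fits[fits$condition == baseline, , drop = FALSE]
  recs <- lapply(names(attended), function(cn) {
    att <- fits[fits$condition == cn, , drop = FALSE]
    i <- match(att$voxel_id, base$voxel_id)
    att <- att[!is.na(i), , drop = FALSE]
    bi <- i[!is.na(i)]
    vi <- match(att$voxel_id, voxels$voxel_id)
    data.frame(
      voxel_id = att$voxel_id,
      subject = voxels$subject[vi], roi = att$roi, condition = cn,
      ami_peak = ami(att$mu, base$mu[bi]),
      ami_bandwidth = ami(att$sigma, base$sigma[bi]),
      dissim = dissimilarity_octaves(base$mu[bi], attended[[cn]]),
      dissim_lsf = dissimilarity_octaves(base$mu[bi], attended[["AttendLSF"]]),
      dissim_hsf = dissimilarity_octaves(base$mu[bi], attended[["AttendHSF"]]),
      prf_ecc = voxels$prf_ecc[vi], prf_size = voxels$prf_size[vi],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, recs)
}

#' First-degree least-squares slope
#'
#' Ordinary least squares of `y` on `x` (a first-degree polynomial fit).
#'
#' @param x Predictor values (at least two distinct).
#' @param y Outcome values (AMI, percent).
#' @return List with `slope`, `intercept`, and `n`.
#' @export
fit_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) stopf("predictor is constant; slope undefined")
  co <- coef(lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]), n = length(x))
}

#' Subject-wise modulation slopes
#'
#' For each subject, ROI and attention condition, the least-squares slope
#' of an AMI outcome against a predictor: the octave dissimilarity from
#' that condition's attended SF (default), pRF eccentricity, or pRF size.
#'
#' @param modulation A [compute_modulation()] table.
#' @param predictor One of `"dissim"`, `"prf_ecc"`, `"prf_size"`.
#' @param outcome One of `"ami_peak"`, `"ami_bandwidth"`.
#' @return data.frame `subject`, `roi`, `condition`, `predictor`,
#'   `outcome`, `slope`, `intercept`, `n_voxels`.
#' @export
subject_slopes <- function(modulation,
                           predictor = c("dissim", "prf_ecc", "prf_size"),
                           outcome = c("ami_peak", "ami_bandwidth")) {
  predictor <- match.arg(predictor)
  outcome <- match.arg(outcome)
  groups <- unique(modulation[c("subject", "roi", "condition")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- modulation$subject == g$subject & modulation$roi == g$roi &
      modulation$condition == g$condition
    x <- modulation[[predictor]][sel]
    y <- modulation[[outcome]][sel]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 2 || length(unique(x[keep])) < 2) return(NULL)
    fs <- fit_slope(x[keep], y[keep])
    data.frame(subject = g$subject, roi = g$roi, condition = g$condition,
               predictor = predictor, outcome = outcome, slope = fs$slope,
               intercept = fs$intercept, n_voxels = fs$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-subject AMI summaries
#'
#' Unweighted subject means of an AMI outcome per ROI and condition — the
#' inputs to the group-level tests.
#'
#' @param modulation A [compute_modulation()] table.
#' @param outcome `"ami_peak"` or `"ami_bandwidth"`.
#' @return data.frame `subject`, `roi`, `condition`, `value`.
#' @export
subject_summary <- function(modulation, outcome = c("ami_peak", "ami_bandwidth")) {
  outcome <- match.arg(outcome)
  agg <- aggregate(modulation[[outcome]],
                   by = modulation[c("subject", "roi", "condition")],
                   FUN = mean, na.rm = TRUE)
  names(agg)[4] <- "value"
  agg
}
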