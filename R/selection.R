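# Voxel selection: pRF-based criteria, pSFT-fit criteria, and the
# per-(ROI x condition) 3-SD outlier exclusion.
#
# Endpoint conventions (documented once, tested at the boundaries):
# "within 0.16-9.8 deg" and "between 0.01 and 5" are closed intervals;
# ">0.1 deg", ">10%" and the polar-angle windows are strict inequalities.

#' Voxel selection criteria
#'
#' @param ecc_range Closed pRF eccentricity interval in degrees.
#' @param min_prf_size Strict lower bound on pRF diameter (degrees).
#' @param min_prf_r2 Strict lower bound on pRF fit quality (percent).
#' @param min_psft_r2 Strict lower bound on pSFT fit quality (percent).
#' @param mu_range Closed interval for the fitted peak (cpd).
#' @param sigma_range Closed interval for the fitted bandwidth.
#' @param outlier_sd Group outlier threshold in SD units.
#' @param polar_windows Polar-angle wedges (degrees, strict bounds) per
#'   probe hemifield; the right-hemifield window wraps through 0/360.
#' @return List of class `selection_criteria`.
#' @export
selection_criteria <- function(ecc_range = c(0.16, 9.8), min_prf_size = 0.1,
                               min_prf_r2 = 10, min_psft_r2 = 10,
                               mu_range = c(0.01, 5), sigma_range = c(0.10, 4),
                               outlier_sd = 3,
                               polar_windows = list(left = c(100, 260),
                                                    right = c(280, 80))) {
  structure(list(ecc_range = ecc_range, min_prf_size = min_prf_size,
                 min_prf_r2 = min_prf_r2, min_psft_r2 = min_psft_r2,
                 mu_range = mu_range, sigma_range = sigma_range,
                 outlier_sd = outlier_sd, polar_windows = polar_windows),
            class = "selection_criteria")
}

in_polar_window <- function(theta, window) {
  theta <- theta %% 360
  if (window[1] < window[2]) theta > window[1] & theta < window[2]
  else theta > window[1] | theta < window[2] # wraps through 0/360
}

#' Apply the pRF-based inclusion criteria
#'
#' Keeps voxels whose pRF eccentricity lies in the closed aperture range,
#' whose pRF diameter and fit quality exceed their strict thresholds, and
#' whose polar angle falls strictly inside the probe hemifield's wedge
#' (the right-hemifield wedge, 280 to 80 degrees, wraps through zero).
#'
#' @param voxels data.frame with `prf_ecc`, `prf_polar`, `prf_size`,
#'   `prf_r2`, `voxel_id`.
#' @param criteria A [selection_criteria()].
#' @param hemifield `"left"` or `"right"` probe hemifield.
#' @return Character vector of surviving `voxel_id`s, with per-criterion
#'   removal counts in attribute `"attrition"`.
#' @export
apply_prf_criteria <- function(voxels, criteria = selection_criteria(),
                               hemifield = c("left", "right")) {
  hemifield <- match.arg(hemifield)
  need <- c("voxel_id", "prf_ecc", "prf_polar", "prf_size", "prf_r2")
  if (!all(need %in% names(voxels)))
    stopf("voxels table lacks column(s): %s",
          paste(setdiff(need, names(voxels)), collapse = ", "))
  ok_ecc <- voxels$prf_ecc >= criteria$ecc_range[1] &
    voxels$prf_ecc <= criteria$ecc_range[2]
  ok_size <- voxels$prf_size > criteria$min_prf_size
  ok_polar <- in_polar_window(voxels$prf_polar,
                              criteria$polar_windows[[hemifield]])
  ok_r2 <- voxels$prf_r2 > criteria$min_prf_r2
  keep <- ok_ecc & ok_size & ok_polar & ok_r2
  structure(voxels$voxel_id[keep],
            attrition = c(eccentricity = sum(!ok_ecc), size = sum(!ok_size),
                          polar_angle = sum(!ok_polar), prf_r2 = sum(!ok_r2)))
}

#' Apply the pSFT-fit inclusion criteria
#'
#' Keeps fits with R-squared strictly above the threshold, fitted peak in
#' the closed \[0.01, 5\] cpd interval, and fitted bandwidth in the closed
#' \[0.10, 4\] interval. By default a voxel must pass in every condition
#' present (so modulation indices are computable for all its conditions);
#' set `require_all_conditions = FALSE` to filter rows independently.
#'
#' @param fits data.frame with `voxel_id`, `condition`, `mu`, `sigma`,
#'   `r2`.
#' @param criteria A [selection_criteria()].
#' @param require_all_conditions Drop a voxel everywhere unless all its
#'   rows pass (default TRUE).
#' @return The surviving rows of `fits`.
#' @export
apply_psft_criteria <- function(fits, criteria = selection_criteria(),
                                require_all_conditions = TRUE) {
  if (nrow(fits) == 0) return(fits)
  ok <- fits$r2 > criteria$min_psft_r2 &
    fits$mu >= criteria$mu_range[1] & fits$mu <= criteria$mu_range[2] &
    fits$sigma >= criteria$sigma_range[1] & fits$sigma <= criteria$sigma_range[2]
  if (require_all_conditions) {
    bad <- unique(fits$voxel_id[!ok])
    fits[!(fits$voxel_id %in% bad), , drop = FALSE]
  } else {
    fits[ok, , drop = FALSE]
  }
}

#' Exclude group-wise parameter outliers
#'
#' Removes a voxel from every condition if, within any (ROI, condition)
#' group it belongs to, its fitted peak or bandwidth lies strictly beyond
#' `k_sd` standard deviations from that group's mean. Group means and SDs
#' are computed once on the incoming table (single pass, no iteration
#' after removals). Groups of size 1 are kept and flagged with a warning
#' (their SD is undefined).
#'
#' @param fits data.frame with `voxel_id`, `roi`, `condition`, `mu`,
#'   `sigma`.
#' @param k_sd Threshold in SD units (default 3).
#' @return Surviving rows of `fits`, with the excluded voxel ids in
#'   attribute `"excluded"`.
#' @export
exclude_outliers <- function(fits, k_sd = 3) {
  if (nrow(fits) == 0) return(fits)
  stopifnot(all(c("voxel_id", "roi", "condition", "mu", "sigma") %in% names(fits)))
  key <- interaction(fits$roi, fits$condition, drop = TRUE)
  bad <- logical(nrow(fits))
  singletons <- FALSE
  for (g in levels(key)) {
    i <- which(key == g)
    if (length(i) < 2) { singletons <- TRUE; next }
    for (col in c("mu", "sigma")) {
      v <- fits[[col]][i]
      m <- mean(v); s <- sd(v)
      bad[i] <- bad[i] | abs(v - m) > k_sd * s
    }
  }
  if (singletons)
    warning("group(s) of size 1 kept: SD undefined for outlier screening")
  excluded <- unique(fits$voxel_id[bad])
  structure(fits[!(fits$voxel_id %in% excluded), , drop = FALSE],
            excluded = excluded)
}

#' Full voxel selection pipeline
#'
#' pRF criteria, then pSFT-fit criteria, then the group-wise outlier
#' exclusion, returning surviving fits (joined with ROI labels from the
#' voxels table) and an attrition log.
#'
#' @param voxels Voxels table (see [apply_prf_criteria()]).
#' @param fits Fits table (see [apply_psft_criteria()]); `roi` is joined
#'   from `voxels` if absent.
#' @param criteria A [selection_criteria()].
#' @param hemifield Probe hemifield.
#' @return Surviving fits, with a named count vector in attribute
#'   `"attrition"` and the survival fraction in attribute `"survival"`.
#' @export
select_voxels <- function(voxels, fits, criteria = selection_criteria(),
                          hemifield = c("left", "right")) {
  hemifield <- match.arg(hemifield)
  n0 <- length(unique(fits$voxel_id))
  if (!"roi" %in% names(fits))
    fits$roi <- voxels$roi[match(fits$voxel_id, voxels$voxel_id)]
  ids <- apply_prf_criteria(voxels, criteria, hemifield)
  f1 <- fits[fits$voxel_id %in% ids, , drop = FALSE]
  f2 <- apply_psft_criteria(f1, criteria)
  f3 <- exclude_outliers(f2, criteria$outlier_sd)
  n <- function(f) length(unique(f$voxel_id))
  structure(f3,
            attrition = c(input = n0, after_prf = n(f1), after_psft = n(f2),
                          after_outliers = n(f3)),
            survival = if (n0 > 0) n(f3) / n0 else NA_real_)
}
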