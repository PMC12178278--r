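# Bandpass filtering of grayscale stimulus images: centered 2D FFT,
# circularly symmetric smoothed annular filter, normalization,
# rectification, and 0-255 quantization.

# 2D fftshift / ifftshift (DC moves to row floor(n/2)+1, matching the
# centered frequency grid below).
fftshift2 <- function(m) {
  r <- nrow(m); c <- ncol(m)
  m[c((floor(r / 2) + 1):r, seq_len(floor(r / 2))),
    c((floor(c / 2) + 1):c, seq_len(floor(c / 2)))]
}

ifftshift2 <- function(m) {
  r <- nrow(m); c <- ncol(m)
  m[c((ceiling(r / 2) + 1):r, seq_len(ceiling(r / 2))),
    c((ceiling(c / 2) + 1):c, seq_len(ceiling(c / 2)))]
}

#' Bandpass filter specification
#'
#' Radial cutoffs default to `center_sf * (1 -/+ filter_width)`, i.e. a
#' relative passband of width 0.2 about the center SF; explicit `f_low` /
#' `f_high` override this. Frequencies are in cycles per degree; `ppd`
#' (pixels per degree) converts them to cycles per pixel internally, with
#' Nyquist at `ppd / 2` cpd.
#'
#' @param center_sf Passband center in cpd.
#' @param ppd Pixels per degree of visual angle.
#' @param filter_width Relative half-width of the passband (default 0.2).
#' @param f_low,f_high Optional explicit radial cutoffs (cpd).
#' @param smooth_sd Gaussian smoothing SD of the filter, in pixels; when
#'   NULL it is resolved by image kind in [filter_image()] (3 px for
#'   letters, `ppd / 10` for noise).
#' @return List of class `bandpass_spec`.
#' @export
bandpass_spec <- function(center_sf, ppd, filter_width = 0.2, f_low = NULL,
                          f_high = NULL, smooth_sd = NULL) {
  stopifnot(center_sf > 0, ppd > 0, filter_width > 0, filter_width < 1)
  f_low <- f_low %||% (center_sf * (1 - filter_width))
  f_high <- f_high %||% (center_sf * (1 + filter_width))
  nyquist <- ppd / 2
  if (!(f_low > 0 && f_low < f_high)) stopf("need 0 < f_low < f_high")
  if (f_high > nyquist)
    stopf("f_high = %g cpd exceeds the Nyquist frequency %g cpd", f_high, nyquist)
  structure(list(center_sf = center_sf, filter_width = filter_width,
                 f_low = f_low, f_high = f_high, nyquist = nyquist,
                 ppd = ppd, smooth_sd = smooth_sd),
            class = "bandpass_spec")
}

#' Construct the circularly symmetric bandpass filter grid
#'
#' An annular passband (1 inside `[f_low, f_high]`, 0 outside) on the
#' centered 2D frequency grid, smoothed with a Gaussian kernel of
#' `smooth_sd` pixels, then min-max normalized to \[0, 1\]. The grid is
#' laid out for a centered (fftshifted) spectrum.
#'
#' @param shape Integer vector `c(rows, cols)` of the target image.
#' @param spec A [bandpass_spec()] with `smooth_sd` resolved.
#' @return Matrix in \[0, 1\] of dimension `shape`.
#' @export
make_bandpass_filter <- function(shape, spec) {
  stopifnot(inherits(spec, "bandpass_spec"), length(shape) == 2, all(shape >= 8))
  sdpix <- spec$smooth_sd
  if (is.null(sdpix)) stopf("smooth_sd unresolved; set it in bandpass_spec()")
  fr <- ((seq_len(shape[1]) - 1) - floor(shape[1] / 2)) / shape[1]
  fc <- ((seq_len(shape[2]) - 1) - floor(shape[2] / 2)) / shape[2]
  r_cpd <- sqrt(outer(fr^2, fc^2, "+")) * spec$ppd
  raw <- (r_cpd >= spec$f_low & r_cpd <= spec$f_high) * 1
  sm <- EBImage::gblur(raw, sigma = sdpix)
  rng <- range(sm)
  if (diff(rng) < 1e-12) stopf("degenerate filter: passband vanished after smoothing")
  (sm - rng[1]) / diff(rng)
}

#' Bandpass filter a grayscale stimulus image
#'
#' The full pipeline: luminance complement (letters only), centered 2D
#' FFT, multiplication by the normalized bandpass filter, inverse FFT
#' (real part), min-subtraction then division by the range (letters) or by
#' the pre-subtraction maximum (noise), rectification, and conversion to
#' the visible 0-255 range by scaling by 127 and adding 127. Values
#' beyond the representable range are clipped; the clipped fraction is
#' reported in attribute `"clip_fraction"`.
#'
#' @param image Single-channel numeric matrix; values in \[0, 1\] or
#'   \[0, 255\] (rescaled internally).
#' @param spec A [bandpass_spec()].
#' @param kind `"letter"` or `"noise"`; selects the complement step, the
#'   normalization branch, and the default smoothing SD (3 px for
#'   letters, `ppd / 10` for noise).
#' @return Matrix of 8-bit values in \[0, 255\].
#' @export
filter_image <- function(image, spec, kind = c("letter", "noise")) {
  kind <- match.arg(kind)
  if (!is.matrix(image) || !is.numeric(image))
    stopf("image must be a single-channel numeric matrix")
  img <- image
  if (max(img) > 1.5) img <- img / 255
  if (kind == "letter") img <- 1 - img  # reverse luminance: letters to white

  if (is.null(spec$smooth_sd))
    spec$smooth_sd <- if (kind == "letter") 3 else spec$ppd / 10
  filt <- make_bandpass_filter(dim(img), spec)

  Fc <- fftshift2(fft(img))
  out <- Re(fft(ifftshift2(Fc * filt), inverse = TRUE)) / length(img)

  rng <- range(out)
  shifted <- out - rng[1]
  denom <- if (kind == "letter") diff(rng) else max(out)
  norm <- if (abs(denom) < 1e-12) shifted * 0 else shifted / denom
  vis <- abs(norm) * 127 + 127
  clip <- mean(vis < 0 | vis > 255)
  structure(pmin(pmax(vis, 0), 255), clip_fraction = clip)
}

#' Read a grayscale image from PNG or TIFF
#'
#' @param path File path; format chosen by extension.
#' @return Numeric matrix in \[0, 1\]. Multi-channel images are rejected.
#' @export
read_grayscale <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stopf("unsupported image format: .%s", ext))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1]
    else stopf("multi-channel image rejected; supply a single-channel grayscale image")
  }
  img
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param image Matrix in \[0, 255\] (as produced by [filter_image()]) or
#'   \[0, 1\].
#' @param path Output path; format chosen by extension.
#' @return Invisibly, the path.
#' @export
write_grayscale <- function(image, path) {
  img <- if (max(image) > 1.5) image / 255 else image
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = , tiff = tiff::writeTIFF(img, path),
         stopf("unsupported image format: .%s", ext))
  invisible(path)
}
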