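#' Spectral conditioning configuration
#'
#' @param sg_window Savitzky-Golay window length in points (odd, greater
#'   than `sg_order`). Default 11.
#' @param sg_order Savitzky-Golay polynomial order. Default 3.
#' @param norm normalization applied after smoothing: `"vector"` (L2 norm
#'   1, the default -- gives scale invariance ahead of classification),
#'   `"area"` (unit integrated absolute intensity) or `"none"`.
#' @return a `prep_config` object.
#' @export
prep_config <- function(sg_window = 11, sg_order = 3,
                        norm = c("vector", "area", "none")) {
  norm <- match.arg(norm)
  if (sg_window %% 2 == 0) stop("sg_window must be odd")
  if (sg_window <= sg_order) stop("sg_window must exceed sg_order")
  structure(list(sg_window = sg_window, sg_order = sg_order, norm = norm),
            class = "prep_config")
}

#' Condition a spectrum: smooth, then normalize
#'
#' Savitzky-Golay polynomial moving-window smoothing followed by the
#' configured normalization. Smoothing is exact on polynomials up to
#' `sg_order`, so constant and affine spectra pass through unchanged.
#'
#' @param s a [spectrum()] or [spectrum_set()].
#' @param cfg a [prep_config()].
#' @return conditioned object of the same class.
#' @export
condition <- function(s, cfg = prep_config()) UseMethod("condition")

condition_vec <- function(y, cfg) {
  if (length(y) <= cfg$sg_window)
    stop("smoothing window exceeds spectrum length")
  sm <- as.numeric(signal::sgolayfilt(y, p = cfg$sg_order, n = cfg$sg_window))
  switch(cfg$norm,
         vector = {
           nrm <- sqrt(sum(sm^2))
           if (nrm == 0) sm else sm / nrm
         },
         area = {
           a <- sum(abs(sm))
           if (a == 0) sm else sm / a
         },
         none = sm)
}

#' @export
condition.raman_spectrum <- function(s, cfg = prep_config()) {
  spectrum(s$wavenumber, condition_vec(s$intensity, cfg), meta = s$meta)
}

#' @export
condition.spectrum_set <- function(s, cfg = prep_config()) {
  spectrum_set(s$wavenumber, apply(s$intensity, 2, condition_vec, cfg = cfg),
               labels = s$labels, group = s$group, meta = s$meta)
}

#' First derivative of a spectrum
#'
#' Central finite differences dI/dnu at interior points, one-sided at the
#' two endpoints.
#'
#' @param s a [spectrum()] with at least 3 points.
#' @return a `raman_spectrum` of derivative values.
#' @export
first_derivative <- function(s) {
  y <- s$intensity; x <- s$wavenumber
  n <- length(y)
  if (n < 3) stop("need at least 3 points for a derivative")
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  i <- 2:(n - 1)
  d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  spectrum(x, d, meta = s$meta)
}

#' Signal-to-noise ratio of a Raman peak
#'
#' `(max intensity within peak_wn +/- signal_halfwidth - mean(noise window))
#' / SD(noise window)`. The noise window must not overlap the peak
#' neighborhood.
#'
#' @param s a [spectrum()].
#' @param peak_wn peak position (cm-1).
#' @param signal_halfwidth half-width of the peak search window (cm-1).
#' @param noise_window a [band_window()] used as the noise reference.
#' @return SNR (dimensionless).
#' @export
peak_snr <- function(s, peak_wn, signal_halfwidth = 10,
                     noise_window = band_window(400, 700, "noise")) {
  if (noise_window$hi >= peak_wn - signal_halfwidth &&
      noise_window$lo <= peak_wn + signal_halfwidth)
    stop("noise window overlaps the peak neighborhood")
  sig <- s$wavenumber >= peak_wn - signal_halfwidth &
    s$wavenumber <= peak_wn + signal_halfwidth
  noi <- s$wavenumber >= noise_window$lo & s$wavenumber <= noise_window$hi
  if (!any(sig)) stop("peak window does not overlap the axis")
  if (sum(noi) < 2) stop("noise window too small")
  nsd <- stats::sd(s$intensity[noi])
  if (nsd == 0) stop("zero-variance noise window: SNR undefined")
  (max(s$intensity[sig]) - mean(s$intensity[noi])) / nsd
}

#' Interquartile-range outlier threshold
#'
#' Tukey fences with k = 1.5 and type-7 (linear-interpolation) quartiles;
#' outliers are one-sided, above the upper fence -- the convention used to
#' define a critical autofluorescence value above which tissue
#' fluorescence is considered abnormal.
#'
#' @param values numeric vector, length >= 4.
#' @return an `iqr_result`: list with `q1`, `q3`, `iqr`, `upper_fence`,
#'   `critical_value` (= `upper_fence`) and `outlier_idx`.
#' @export
iqr_threshold <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) stop("need at least 4 values")
  if (!all(is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence <- q[2] + 1.5 * iqr
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr, upper_fence = fence,
                 critical_value = fence,
                 outlier_idx = which(values > fence)),
            class = "iqr_result")
}

#' Spectral stability improvement factor
#'
#' Ratio of a reference intensity SD to a new intensity SD; values above 1
#' mean the new acquisition mode (e.g. guided probe positioning) is more
#' stable than the reference (e.g. manual operation).
#'
#' @param sd_ref reference intensity SD.
#' @param sd_new comparison intensity SD (> 0).
#' @return fold improvement `sd_ref / sd_new`.
#' @export
stability_fold <- function(sd_ref, sd_new) {
  if (!is.finite(sd_new) || sd_new <= 0) stop("sd_new must be > 0")
  sd_ref / sd_new
}
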