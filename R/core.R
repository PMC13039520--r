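#' ramanicg: dual-modal ICG-fluorescence / Raman tumor-margin analysis
#'
#' Core containers are plain S3 lists: a [spectrum()] holds one
#' wavenumber-indexed intensity vector, a [spectrum_set()] holds many spectra
#' on one shared axis as a wavenumber-by-spectrum matrix. Band windows for the
#' fingerprint (FP, 800-1800 cm-1) and high-wave-number (HWN, 2800-3050 cm-1)
#' regions are provided by [band_window()] / [bands()].
#'
#' @useDynLib ramanicg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor cor.test kmeans mad median pnorm quantile
#'   rbinom rlnorm rnorm runif sd var rmultinom setNames predict
#' @importFrom utils read.csv write.csv head tail
#' @keywords internal
"_PACKAGE"

#' Validate a wavenumber axis
#'
#' A wavenumber axis is a strictly increasing, finite numeric vector of Raman
#' shifts in cm-1 with at least two points.
#'
#' @param values numeric vector of Raman shifts (cm-1).
#' @return the validated numeric vector, classed `"wn_axis"`.
#' @export
wn_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("wavenumber axis needs at least 2 points")
  if (!all(is.finite(values)))
    stop("wavenumber axis must be finite")
  if (any(diff(values) <= 0))
    stop("axis not increasing: wavenumbers must be strictly monotone increasing")
  structure(values, class = "wn_axis")
}

#' Spectral band window
#'
#' Closed wavenumber interval `[lo, hi]`. The two diagnostic bands are the
#' fingerprint band FP = \[800, 1800\] cm-1 (proteins, lipids, nucleic acids)
#' and the high-wave-number band HWN = \[2800, 3050\] cm-1 (CH2/CH3
#' stretching of lipids and proteins).
#'
#' @param lo,hi band limits in cm-1, `lo < hi`.
#' @param name band label, e.g. `"FP"`, `"HWN"` or `"full"`.
#' @return a `band_window` object.
#' @examples
#' band_window(800, 1800, "FP")
#' bands()$HWN
#' @export
band_window <- function(lo, hi, name = "custom") {
  if (is.na(lo) || is.na(hi) || lo >= hi)
    stop("band window requires lo < hi")
  structure(list(lo = lo, hi = hi, name = name), class = "band_window")
}

#' @rdname band_window
#' @export
bands <- function() {
  list(
    FP   = band_window(800, 1800, "FP"),
    HWN  = band_window(2800, 3050, "HWN"),
    full = band_window(-Inf, Inf, "full")
  )
}

#' @export
print.band_window <- function(x, ...) {
  cat(sprintf("<band %s: [%s, %s] cm-1>\n", x$name, format(x$lo), format(x$hi)))
  invisible(x)
}

#' Single Raman spectrum
#'
#' @param wavenumber wavenumber axis (cm-1), strictly increasing.
#' @param intensity intensity counts (arbitrary units), same length as axis.
#' @param meta named list of acquisition metadata. Defaults carry the
#'   acquisition protocol used throughout: 3 s exposure, 250 mW laser power,
#'   single accumulation.
#' @return a `raman_spectrum` object.
#' @export
spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- wn_axis(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(wavenumber))
    stop("intensity and wavenumber lengths differ")
  if (!all(is.finite(intensity)))
    stop("intensities must be finite")
  defaults <- list(exposure_s = 3, laser_mW = 250, accumulations = 1, icg_amp = NA_real_)
  meta <- utils::modifyList(defaults, meta)
  structure(list(wavenumber = as.numeric(wavenumber), intensity = intensity,
                 meta = meta), class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum: %d points, %.1f-%.1f cm-1>\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Set of Raman spectra on a shared axis
#'
#' Stored as a wavenumber-by-spectrum intensity matrix plus optional class
#' labels (0 = brain, 1 = glioma) and region/group ids.
#'
#' @param wavenumber shared axis (cm-1).
#' @param intensity numeric matrix, `length(wavenumber)` rows, one column per
#'   spectrum.
#' @param labels optional integer vector in \{0, 1\}, one per spectrum.
#' @param group optional region/group id per spectrum.
#' @param meta named list of set-level metadata.
#' @return a `spectrum_set` object.
#' @export
spectrum_set <- function(wavenumber, intensity, labels = NULL, group = NULL,
                         meta = list()) {
  wavenumber <- as.numeric(wn_axis(wavenumber))
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(wavenumber))
    stop("intensity matrix must have one row per wavenumber")
  if (!all(is.finite(intensity)))
    stop("intensities must be finite")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != ncol(intensity))
      stop("one label per spectrum required")
    if (!all(labels %in% c(0L, 1L)))
      stop("labels must be 0 (brain) or 1 (glioma)")
  }
  if (!is.null(group) && length(group) != ncol(intensity))
    stop("one group id per spectrum required")
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 labels = labels, group = group, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set: %d spectra x %d points, %.1f-%.1f cm-1%s>\n",
              ncol(x$intensity), nrow(x$intensity),
              min(x$wavenumber), max(x$wavenumber),
              if (!is.null(x$labels)) sprintf(", labeled (%d glioma)",
                                              sum(x$labels)) else ""))
  invisible(x)
}

#' Number of spectra in a set
#' @param x a `spectrum_set`.
#' @export
nspec <- function(x) ncol(x$intensity)

#' Extract one spectrum from a set
#' @param set a `spectrum_set`.
#' @param i spectrum index.
#' @return a `raman_spectrum`.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(i >= 1, i <= nspec(set))
  spectrum(set$wavenumber, set$intensity[, i],
           meta = list(label = if (!is.null(set$labels)) set$labels[i] else NA))
}

#' Read spectra from CSV
#'
#' Two layouts are supported. `"long"`: columns `wavenumber`, `intensity`
#' and optionally `spectrum_id` (one block per spectrum, all blocks on the
#' same axis). `"matrix"`: first column `wavenumber`, each remaining column
#' one spectrum. The axis must be strictly increasing.
#'
#' @param path CSV file path.
#' @param layout `"matrix"` (default) or `"long"`.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(path, layout = c("matrix", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  num_or_die <- function(x, what) {
    y <- suppressWarnings(as.numeric(x))
    if (anyNA(y) && !anyNA(x)) stop("non-numeric cells in ", what)
    if (anyNA(y)) stop("missing/non-numeric cells in ", what)
    y
  }
  if (layout == "matrix") {
    if (ncol(df) < 2L) stop("matrix layout needs wavenumber + >= 1 spectrum column")
    wn <- num_or_die(df[[1]], "wavenumber column")
    ints <- vapply(df[-1], num_or_die, numeric(nrow(df)), what = "intensity columns")
    ints <- matrix(ints, nrow = nrow(df),
                   dimnames = list(NULL, names(df)[-1]))
    spectrum_set(wn, ints)
  } else {
    need <- c("wavenumber", "intensity")
    if (!all(need %in% names(df)))
      stop("long layout needs columns 'wavenumber' and 'intensity'")
    id <- if ("spectrum_id" %in% names(df)) df$spectrum_id else rep(1L, nrow(df))
    wn_all <- num_or_die(df$wavenumber, "wavenumber")
    int_all <- num_or_die(df$intensity, "intensity")
    ids <- unique(id)
    wn <- wn_all[id == ids[1]]
    ints <- vapply(ids, function(k) {
      sel <- id == k
      if (!isTRUE(all.equal(wn_all[sel], wn)))
        stop("all spectra in a long CSV must share one axis")
      int_all[sel]
    }, numeric(length(wn)))
    ints <- matrix(ints, nrow = length(wn),
                   dimnames = list(NULL, as.character(ids)))
    spectrum_set(wn, ints)
  }
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]; the round trip preserves values to
#' numeric-text precision (values are written with 15 significant digits).
#'
#' @param set a [spectrum_set()] (a single `raman_spectrum` is accepted and
#'   promoted to a one-spectrum set).
#' @param path output CSV path.
#' @param layout `"matrix"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, layout = c("matrix", "long")) {
  layout <- match.arg(layout)
  if (inherits(set, "raman_spectrum"))
    set <- spectrum_set(set$wavenumber, matrix(set$intensity, ncol = 1))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (layout == "matrix") {
    n <- nspec(set)
    cols <- colnames(set$intensity)
    if (is.null(cols)) cols <- paste0("spec", seq_len(max(n, 0L)))
    header <- paste(c("wavenumber", cols), collapse = ",")
    if (n == 0L || nrow(set$intensity) == 0L) {
      writeLines(header, path)
      return(invisible(path))
    }
    body <- apply(cbind(set$wavenumber, set$intensity), 1L,
                  function(r) paste(fmt(r), collapse = ","))
    writeLines(c(header, body), path)
  } else {
    header <- "wavenumber,intensity,spectrum_id"
    n <- nspec(set)
    if (n == 0L) {
      writeLines(header, path)
      return(invisible(path))
    }
    lines <- unlist(lapply(seq_len(n), function(j) {
      paste(fmt(set$wavenumber), fmt(set$intensity[, j]), j, sep = ",")
    }))
    writeLines(c(header, lines), path)
  }
  invisible(path)
}

#' Restrict a spectrum to a band window
#'
#' Keeps all axis points `w` with `lo <= w <= hi` (closed interval, order
#' preserved). Idempotent. Works on single spectra and sets.
#'
#' @param s a `raman_spectrum` or `spectrum_set`.
#' @param band a [band_window()].
#' @return object of the same class restricted to the band.
#' @export
extract_band <- function(s, band) UseMethod("extract_band")

#' @export
extract_band.raman_spectrum <- function(s, band) {
  keep <- s$wavenumber >= band$lo & s$wavenumber <= band$hi
  if (!any(keep))
    stop("band [", band$lo, ", ", band$hi, "] does not overlap the axis")
  spectrum(s$wavenumber[keep], s$intensity[keep], meta = s$meta)
}

#' @export
extract_band.spectrum_set <- function(s, band) {
  keep <- s$wavenumber >= band$lo & s$wavenumber <= band$hi
  if (!any(keep))
    stop("band [", band$lo, ", ", band$hi, "] does not overlap the axis")
  spectrum_set(s$wavenumber[keep], s$intensity[keep, , drop = FALSE],
               labels = s$labels, group = s$group, meta = s$meta)
}

#' Resample a spectrum onto a target axis
#'
#' Piecewise-linear interpolation of intensity onto `target`. Extrapolation
#' is refused: the target must lie within the source range. Spectra on
#' different axes must be resampled explicitly before pooling; no implicit
#' alignment is ever performed.
#'
#' @param s a `raman_spectrum`.
#' @param target numeric target axis (cm-1), strictly increasing.
#' @return a `raman_spectrum` on `target`.
#' @export
resample_spectrum <- function(s, target) {
  target <- as.numeric(wn_axis(target))
  if (min(target) < min(s$wavenumber) || max(target) > max(s$wavenumber))
    stop("extrapolation requested: target axis exceeds source range")
  y <- stats::approx(s$wavenumber, s$intensity, xout = target,
                     method = "linear", ties = "ordered")$y
  spectrum(target, y, meta = s$meta)
}
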