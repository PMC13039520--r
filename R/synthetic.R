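#' Default wavenumber axis for synthetic spectra
#'
#' 400 to 3100 cm-1 at 2 cm-1 spacing (1351 points), covering both the
#' fingerprint and high-wave-number diagnostic bands.
#' @return numeric axis vector.
#' @export
default_axis <- function() seq(400, 3100, by = 2)

#' Characteristic peak table for brain and glioma tissue
#'
#' Pseudo-Voigt peak centers with class-specific relative amplitudes.
#' Directions of contrast follow the tissue biochemistry: structural
#' protein / lipid peaks (963, 1261, 1430, 1647, 2842, 2856 cm-1) are
#' elevated in normal brain (organized neuropil, myelin-rich lipids), while
#' phenylalanine (997 cm-1), tryptophan-associated protein signal
#' (1207 cm-1) and the CH3 protein stretch (2940 cm-1) are elevated in
#' glioma (heightened protein synthesis). Absolute amplitudes are model
#' choices; only the contrast directions are biologically constrained.
#'
#' @return data.frame with columns `center`, `fwhm`, `amp_brain`,
#'   `amp_glioma`.
#' @export
raman_peaks <- function() {
  data.frame(
    center     = c(963, 997, 1207, 1261, 1430, 1442, 1647, 1654,
                   2842, 2856, 2880, 2940),
    fwhm       = rep(12, 12),
    amp_brain  = c(1.00, 0.45, 0.35, 0.90, 0.85, 0.70, 1.00, 0.80,
                   1.30, 1.20, 1.00, 0.85),
    amp_glioma = c(0.55, 1.00, 0.80, 0.50, 0.50, 0.65, 0.60, 0.75,
                   0.70, 0.65, 0.90, 1.40)
  )
}

# pseudo-Voigt line shape, unit height, 50/50 Gaussian/Lorentzian mix
pseudo_voigt <- function(x, center, fwhm) {
  u <- (x - center) / fwhm
  0.5 * exp(-4 * log(2) * u^2) + 0.5 / (1 + 4 * u^2)
}

#' ICG fluorescence background curve
#'
#' Broad log-normal-shaped band peaking near 531 cm-1 in Raman-shift
#' coordinates with a long high-wavenumber tail, the shape of ICG emission
#' under 785-nm excitation expressed on the shift axis. `amp` scales
#' linearly with dye concentration: `amp = 1` corresponds to the
#' 1e-9 M-equivalent regime in which Raman peaks remain recoverable;
#' `amp = 10` to the 1e-8 M-equivalent regime in which they are buried.
#'
#' @param wavenumber axis (cm-1).
#' @param amp background amplitude (a.u.); `>= 0`.
#' @param peak_shift apex position in cm-1 (default 531).
#' @param width log-scale width of the band (dimensionless, default 0.9).
#' @return background intensity vector.
#' @export
icg_background <- function(wavenumber, amp, peak_shift = 531, width = 0.9) {
  if (amp < 0) stop("amp must be >= 0")
  t0 <- 250  # shift origin of the log-normal envelope
  t <- pmax(wavenumber - t0, .Machine$double.eps)
  m <- peak_shift - t0
  shape <- exp(-(log(t / m))^2 / (2 * width^2))
  # height 20 at amp = 1: fluorescence dwarfs unit-height Raman peaks
  amp * 20 * shape
}

#' Simulate one tissue Raman spectrum
#'
#' Intensity is the sum of class-specific pseudo-Voigt peaks (amplitudes
#' multiplicatively jittered per spectrum), the ICG fluorescence background,
#' and i.i.d. Gaussian noise. The pure Raman component and the background
#' are kept in `meta` so downstream recovery can be scored against truth.
#'
#' @param class_label 0 (brain) or 1 (glioma).
#' @param icg_amp ICG background amplitude (a.u.), see [icg_background()].
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param seed optional integer seed for reproducibility.
#' @param axis wavenumber axis, default [default_axis()].
#' @param contrast scale in \[0, 1\] shrinking class amplitude differences
#'   toward their mean (1 = full contrast, 0 = indistinguishable classes).
#' @param jitter_sd SD of the per-peak multiplicative log-normal jitter.
#' @return a [spectrum()]; `meta$raman` holds the noiseless peak sum,
#'   `meta$background` the fluorescence component.
#' @export
make_spectrum <- function(class_label, icg_amp = 1, noise_sd = 0.05,
                          seed = NULL, axis = default_axis(), contrast = 1,
                          jitter_sd = 0.1) {
  if (!class_label %in% c(0, 1)) stop("unknown class label: ", class_label)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pk <- raman_peaks()
  mid <- (pk$amp_brain + pk$amp_glioma) / 2
  amp <- if (class_label == 0) pk$amp_brain else pk$amp_glioma
  amp <- mid + contrast * (amp - mid)
  jit <- stats::rlnorm(nrow(pk), meanlog = 0, sdlog = jitter_sd)
  raman <- rep(0, length(axis))
  for (i in seq_len(nrow(pk)))
    raman <- raman + amp[i] * jit[i] * pseudo_voigt(axis, pk$center[i], pk$fwhm[i])
  bg <- icg_background(axis, icg_amp)
  noise <- if (noise_sd > 0) stats::rnorm(length(axis), 0, noise_sd) else 0
  spectrum(axis, raman + bg + noise,
           meta = list(icg_amp = icg_amp, label = class_label,
                       raman = raman, background = bg))
}

#' Simulate a balanced two-class spectrum set
#'
#' @param n_per_class spectra per class (>= 1).
#' @param icg_amp,noise_sd,contrast passed to [make_spectrum()].
#' @param seed integer seed; the whole set is deterministic given the seed.
#' @return a [spectrum_set()] with labels `c(rep(0, n), rep(1, n))`; the
#'   noiseless Raman components are kept in `meta$truth` (matrix).
#' @export
make_dataset <- function(n_per_class, icg_amp = 1, noise_sd = 0.05,
                         seed = 1, contrast = 1) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  set.seed(seed)
  axis <- default_axis()
  labels <- rep(c(0L, 1L), each = n_per_class)
  ints <- matrix(0, nrow = length(axis), ncol = 2 * n_per_class)
  truth <- matrix(0, nrow = length(axis), ncol = 2 * n_per_class)
  for (j in seq_along(labels)) {
    s <- make_spectrum(labels[j], icg_amp = icg_amp, noise_sd = noise_sd,
                       axis = axis, contrast = contrast)
    ints[, j] <- s$intensity
    truth[, j] <- s$meta$raman
  }
  spectrum_set(axis, ints, labels = labels,
               meta = list(truth = truth, icg_amp = icg_amp,
                           noise_sd = noise_sd, seed = seed))
}

#' Simulate a co-registered dual-modal tissue phantom
#'
#' A circular tumor of radius `tumor_radius` sits at the image center. The
#' per-pixel tumor infiltration fraction steps down radially: 1 in the
#' core, 0.65 in the inner margin band (the last `margin_px` pixels inside
#' the true boundary, emulating the 60-70 percent infiltration of the
#' highest-agreement fluorescence region), 0.2 in the inner half of the
#' halo annulus outside the true boundary (the roughly 20 percent
#' infiltration of the transitional zone), and 0 in the outer half of the
#' halo and beyond -- fluorescent but cancer-free tissue, the
#' false-positive dilemma of dye-based margins. The ICG fluorescence image
#' is a smoothed four-step radial profile (per-pixel SNR targets of about
#' 5, 3.5, 2.4 and 1.5 background SDs over core, margin band, inner halo
#' and outer halo) scaled by `icg_amp`, plus Gaussian background noise, so
#' that the SNR = 3 contour tracks the true tumor boundary while the
#' SNR = 1 contour tracks the halo edge: fluorescence overestimates, by
#' construction, as ICG does in tissue. Per-pixel Raman spectra are
#' brain/glioma mixtures with glioma weight equal to the infiltration
#' fraction, contaminated by an ICG background proportional to the local
#' fluorescence level, sampled on a regular sub-lattice of step
#' `spectrum_step` pixels.
#'
#' @param shape image size in pixels, `c(rows, cols)` (default 64 x 64).
#' @param tumor_radius true tumor radius in pixels.
#' @param halo_width width of the fluorescent halo beyond the true boundary
#'   (pixels; 0 = no overestimation).
#' @param icg_amp fluorescence amplitude scale; also scales the ICG
#'   background injected into the per-pixel spectra.
#' @param seed integer seed.
#' @param spectrum_step sub-lattice step for per-pixel spectra (1 = every
#'   pixel).
#' @param noise_sd spectral noise SD.
#' @param margin_px width of the 0.65-infiltration inner margin band.
#' @return a `phantom`: list with `truth_mask`, `infiltration`,
#'   `fluor_image`, `background_roi` (logical mask of ICG-free pixels),
#'   `grid` (a `spectral_grid`: coords + [spectrum_set()]), `halo_width`,
#'   `bg_mean`, `bg_sd`.
#' @export
make_phantom <- function(shape = c(64, 64), tumor_radius = 18,
                         halo_width = 5, icg_amp = 1, seed = 1,
                         spectrum_step = 2, noise_sd = 0.05,
                         margin_px = 3) {
  nr <- shape[1]; nc <- shape[2]
  if (tumor_radius + halo_width >= min(nr, nc) / 2)
    stop("geometry exceeds image: tumor_radius + halo_width too large")
  set.seed(seed)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  d <- sqrt(outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+"))
  truth <- d <= tumor_radius
  infil <- matrix(0, nr, nc)
  infil[d <= tumor_radius] <- 0.65
  infil[d <= tumor_radius - margin_px] <- 1
  halo <- d > tumor_radius & d <= tumor_radius + halo_width
  halo_in <- d > tumor_radius & d <= tumor_radius + halo_width / 2
  infil[halo_in] <- 0.2
  # fluorescence: four-step radial profile (SNR targets ~5/3.5/2.4/1.5),
  # light smoothing, background noise
  bg_mean <- 10; bg_sd <- 2
  step_img <- matrix(0, nr, nc)
  step_img[truth] <- 5
  step_img[d > tumor_radius - margin_px & d <= tumor_radius] <- 3.5
  step_img[halo] <- 1.5
  step_img[halo_in] <- 2.4
  sm <- if (any(step_img > 0)) gaussian_blur(step_img, sigma = 0.5) else step_img
  # background SD is dominated by healthy-tissue autofluorescence
  # heterogeneity; over the strong specific ICG signal the relative pixel
  # fluctuation is smaller, so fluorescent regions get 0.3 sigma_B noise
  noise_scale <- ifelse(step_img > 0, 0.3, 1) * bg_sd
  fluor <- bg_mean + icg_amp * bg_sd * sm +
    matrix(stats::rnorm(nr * nc, 0, 1), nr, nc) * noise_scale
  background_roi <- d > tumor_radius + halo_width + 4
  # per-pixel spectra on a sub-lattice
  rows <- seq(1, nr, by = spectrum_step)
  cols <- seq(1, nc, by = spectrum_step)
  coords <- as.matrix(expand.grid(row = rows, col = cols))
  axis <- default_axis()
  ints <- matrix(0, nrow = length(axis), ncol = nrow(coords))
  for (k in seq_len(nrow(coords))) {
    r <- coords[k, 1]; c <- coords[k, 2]
    w <- infil[r, c]
    s0 <- make_spectrum(0, icg_amp = 0, noise_sd = 0)
    s1 <- make_spectrum(1, icg_amp = 0, noise_sd = 0)
    # spectral ICG contamination tracks the local fluorescence level:
    # ~icg_amp in the tumor core, weaker over the halo, none outside
    local_icg <- icg_amp * sm[r, c] / 5
    y <- (1 - w) * s0$meta$raman + w * s1$meta$raman +
      icg_background(axis, local_icg) +
      stats::rnorm(length(axis), 0, noise_sd)
    ints[, k] <- y
  }
  grid <- spectral_grid(height = nr, width = nc, coords = coords,
                        set = spectrum_set(axis, ints),
                        step = spectrum_step)
  structure(list(truth_mask = truth, infiltration = infil,
                 fluor_image = fluor, background_roi = background_roi,
                 grid = grid, halo_width = halo_width,
                 tumor_radius = tumor_radius,
                 bg_mean = bg_mean, bg_sd = bg_sd, icg_amp = icg_amp,
                 seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %dx%d px, tumor r=%g, halo=%g px, %d spectra>\n",
              nrow(x$fluor_image), ncol(x$fluor_image), x$tumor_radius,
              x$halo_width, nspec(x$grid$set)))
  invisible(x)
}

#' Regular grid of per-pixel spectra
#'
#' @param height,width full image size in pixels.
#' @param coords integer matrix (n x 2) of `row`, `col` sample positions.
#' @param set a [spectrum_set()], one spectrum per coordinate row.
#' @param step sub-lattice step in pixels (metadata).
#' @param step_um physical step size in micrometers (metadata; mapping
#'   acquisitions in this workflow use 2).
#' @return a `spectral_grid` object.
#' @export
spectral_grid <- function(height, width, coords, set, step = 1, step_um = 2) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nspec(set))
    stop("one spectrum per coordinate required")
  structure(list(height = height, width = width, coords = coords,
                 set = set, step = step, step_um = step_um),
            class = "spectral_grid")
}

# separable Gaussian blur with reflected edges (small sigma, small kernels)
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(r)]), v, rev(v[n + 1 - seq_len(r)]))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  out <- apply(img, 2, blur_1d)
  t(apply(out, 1, blur_1d))
}
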