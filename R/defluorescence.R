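#' Configuration for penalized least-squares baseline estimation
#'
#' The ICG fluorescence background under 785-nm excitation is a broad, smooth
#' curve that dwarfs the narrow Raman peaks riding on it. The baseline
#' estimator solves, at each reweighting iteration, the penalized system
#' `(W + lambda * D'D) z = W y`, where `D` is the second-order
#' finite-difference operator and `W` a diagonal weight matrix updated
#' asymmetrically so that points above the running baseline (Raman peaks)
#' contribute little.
#'
#' @param lam smoothness weight lambda (> 0). Larger values give stiffer
#'   baselines. Default 200: on a 2 cm-1 axis this is stiff enough to ride
#'   over 12 cm-1 FWHM Raman peaks yet flexible enough to follow the
#'   curved apex of the ICG emission near 531 cm-1; much larger values
#'   leave apex residuals that dominate the corrected spectrum.
#' @param n_latent number of leading smooth (low-frequency cosine) components
#'   retained in the latent baseline summary `w` reported alongside the full
#'   baseline. Default 3.
#' @param max_iter maximum reweighting iterations (>= 1).
#' @param tol relative-change convergence tolerance on the baseline.
#' @param asym_p asymmetry weight in (0, 1): weight given to points lying
#'   above the baseline (peaks); points below get `1 - asym_p`.
#' @return an `epls_config` object.
#' @export
epls_config <- function(lam = 200, n_latent = 3, max_iter = 50,
                        tol = 1e-6, asym_p = 0.01) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be > 0")
  if (asym_p <= 0 || asym_p >= 1) stop("asym_p must be in (0, 1)")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (n_latent < 1) stop("n_latent must be >= 1")
  structure(list(lam = lam, n_latent = n_latent, max_iter = max_iter,
                 tol = tol, asym_p = asym_p), class = "epls_config")
}

# diagonals of crossprod(D) for the second-order difference operator on n
# points: closed-form bands, avoids building the sparse matrix per spectrum
penalty_bands <- function(n, lam) {
  stopifnot(n >= 5)
  list(p0 = lam * c(1, 5, rep(6, n - 4), 5, 1),
       p1 = lam * c(-2, rep(-4, n - 3), -2),
       p2 = lam * rep(1, n - 2))
}

#' Estimate the fluorescence baseline of a spectrum
#'
#' Iteratively reweighted penalized least squares: weights start uniform,
#' the banded system `(W + lambda * D'D) z = W y` is solved exactly at each
#' iteration (O(n) banded Cholesky), and weights are then set to `asym_p`
#' where the residual `y - z` is positive and `1 - asym_p` where it is not.
#' Iteration stops when the relative baseline change drops below `tol`.
#' The converged baseline is additionally projected onto its `n_latent`
#' leading discrete-cosine components to give the smooth latent summary `w`.
#'
#' @param s a [spectrum()] with at least 10 points.
#' @param cfg an [epls_config()].
#' @return an `epls_model`: list with `baseline` (estimated baseline vector),
#'   `w` (latent smooth projection of the baseline), `lam`, `n_iter_used`,
#'   `roughness` (`||D baseline||^2`), and the input axis.
#' @export
epls_baseline <- function(s, cfg = epls_config()) {
  y <- s$intensity
  n <- length(y)
  if (n < 10) stop("spectrum too short for baseline estimation (need >= 10 points)")
  if (!all(is.finite(y))) stop("non-finite intensities")
  pb <- penalty_bands(n, cfg$lam)
  wts <- rep(1, n)
  z <- y
  n_iter <- 0L
  for (it in seq_len(cfg$max_iter)) {
    z_new <- penta_solve(wts, wts * y, pb$p0, pb$p1, pb$p2)
    n_iter <- it
    delta <- sqrt(sum((z_new - z)^2)) / max(sqrt(sum(z^2)), .Machine$double.eps)
    z <- z_new
    wts <- ifelse(y - z > 0, cfg$asym_p, 1 - cfg$asym_p)
    if (it > 1 && delta < cfg$tol) break
  }
  # latent smooth summary: least-squares projection onto leading DCT modes
  k <- seq_len(cfg$n_latent) - 1
  i <- seq_len(n)
  basis <- vapply(k, function(kk) cos(pi * kk * (i - 0.5) / n), numeric(n))
  coef <- qr.solve(basis, z)
  w <- as.numeric(basis %*% coef)
  structure(list(baseline = z, w = w, lam = cfg$lam, n_iter_used = n_iter,
                 roughness = sum(diff(z, differences = 2)^2),
                 wavenumber = s$wavenumber),
            class = "epls_model")
}

#' Subtract the fluorescence baseline and repair artifacts
#'
#' Subtracts the estimated baseline from the measured spectrum, flags
#' residual artifact points (negative excursions and first-difference
#' spikes, see [detect_artifacts()]), and repairs each flagged run by
#' piecewise-linear interpolation between its flanking valid neighbors
#' ([repair_gaps()]). At every non-repaired point the identity
#' `corrected + baseline == original` holds to machine precision. Flagged
#' runs touching the spectrum edge have no flanking neighbor and are left
#' unrepaired.
#'
#' @param s a [spectrum()].
#' @param cfg an [epls_config()].
#' @param z_thresh robust-SD multiple for artifact flagging (default 4).
#' @return list with `corrected` (a `raman_spectrum`), `model` (the
#'   [epls_baseline()] fit) and `artifact_mask` (logical, repaired points).
#' @export
epls_correct <- function(s, cfg = epls_config(), z_thresh = 4) {
  model <- epls_baseline(s, cfg)
  resid <- s$intensity - model$baseline
  corrected <- spectrum(s$wavenumber, resid, meta = s$meta)
  mask <- detect_artifacts(corrected, z_thresh = z_thresh)
  mask <- drop_edge_runs(mask)
  if (any(mask)) corrected <- repair_gaps(corrected, mask)
  list(corrected = corrected, model = model, artifact_mask = mask)
}

# unflag flagged runs touching either end (no flanking valid point)
drop_edge_runs <- function(mask) {
  n <- length(mask)
  if (n == 0 || !any(mask)) return(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] && (starts[j] == 1L || ends[j] == n))
      mask[starts[j]:ends[j]] <- FALSE
  }
  mask
}

#' Repair flagged points by piecewise-linear interpolation
#'
#' Each maximal run of flagged points is replaced by the straight line
#' `y = y1 + (x - x1) (y2 - y1) / (x2 - x1)` through the two valid points
#' flanking the run; unflagged points are untouched. This restores spectral
#' continuity after baseline subtraction without the oscillations of
#' higher-order interpolants.
#'
#' @param s a [spectrum()].
#' @param artifact_mask logical vector, `TRUE` at points to repair. The
#'   first and last points must be valid.
#' @return the repaired `raman_spectrum`.
#' @export
repair_gaps <- function(s, artifact_mask) {
  y <- s$intensity
  x <- s$wavenumber
  n <- length(y)
  mask <- as.logical(artifact_mask)
  if (length(mask) != n) stop("mask length must match spectrum length")
  if (!any(mask)) return(s)
  if (mask[1] || mask[n])
    stop("flagged run touches spectrum edge: no flanking valid point")
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i1 <- starts[j] - 1L
    i2 <- ends[j] + 1L
    x1 <- x[i1]; y1 <- y[i1]; x2 <- x[i2]; y2 <- y[i2]
    idx <- starts[j]:ends[j]
    y[idx] <- y1 + (x[idx] - x1) * (y2 - y1) / (x2 - x1)
  }
  spectrum(x, y, meta = s$meta)
}

#' Flag post-subtraction artifact points
#'
#' After baseline subtraction the residual can exhibit local artifacts where
#' the fluorescence background varies steeply. Two symptoms are flagged:
#' points more negative than `-z_thresh` times the local noise SD (noise SD
#' estimated robustly as `mad(diff(y)) / sqrt(2)`), and points whose first
#' difference exceeds `z_thresh` times the robust SD of all first
#' differences. The rules assume the spectrum carries measurement noise;
#' on noiseless synthetic signals the degenerate noise estimate can make
#' the spike rule flag genuine sharp features.
#'
#' @param corrected a baseline-corrected [spectrum()].
#' @param z_thresh robust-SD multiple (default 4).
#' @return logical mask, `TRUE` at flagged points.
#' @export
detect_artifacts <- function(corrected, z_thresh = 4) {
  y <- corrected$intensity
  n <- length(y)
  d <- diff(y)
  noise_sd <- stats::mad(d) / sqrt(2)
  sd_d <- stats::mad(d)
  mask <- y < -z_thresh * noise_sd
  if (sd_d > 0) {
    spike <- abs(d) > z_thresh * sd_d
    # a large jump into point i+1 implicates that point
    mask[which(spike) + 1L] <- TRUE
  }
  mask
}

#' Spectral fidelity (Pearson correlation)
#'
#' Pearson correlation between the intensity vectors of two spectra on the
#' same axis; used to quantify how faithfully the Raman component survives
#' fluorescence rejection at a given ICG concentration.
#'
#' @param a,b `raman_spectrum` objects on the same axis.
#' @return Pearson r in \[-1, 1\].
#' @export
fidelity <- function(a, b) {
  if (length(a$intensity) != length(b$intensity) ||
      any(a$wavenumber != b$wavenumber))
    stop("spectra must share one axis")
  if (stats::var(a$intensity) == 0 || stats::var(b$intensity) == 0)
    stop("zero-variance input: fidelity undefined")
  stats::cor(a$intensity, b$intensity)
}
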