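#' Per-pixel glioma probability map
#'
#' Runs the full per-spectrum pipeline at every grid point: fluorescence
#' baseline rejection ([epls_correct()]), conditioning ([condition()]),
#' band extraction and classifier prediction. When the grid is a
#' sub-lattice of the image, the probability map is bilinearly interpolated
#' back to full resolution.
#'
#' @param grid a [spectral_grid()].
#' @param model a `raman_classifier` whose band the grid axis covers.
#' @param epls an [epls_config()] for baseline rejection.
#' @param prep a [prep_config()] for conditioning.
#' @param correct if `FALSE`, skip baseline rejection (for grids already
#'   corrected).
#' @return numeric `height x width` matrix of probabilities in \[0, 1\].
#' @export
classify_map <- function(grid, model, epls = epls_config(),
                         prep = prep_config(), correct = TRUE) {
  set <- grid_pipeline(grid$set, epls, prep, correct)
  proba <- predict_proba(model, set)
  grid_to_image(grid, proba)
}

# shared per-pixel preprocessing: correct each spectrum, then condition
grid_pipeline <- function(set, epls, prep, correct = TRUE) {
  if (correct) {
    ints <- apply(set$intensity, 2, function(y) {
      epls_correct(spectrum(set$wavenumber, y), epls)$corrected$intensity
    })
    set <- spectrum_set(set$wavenumber, ints, labels = set$labels,
                        group = set$group, meta = set$meta)
  }
  condition(set, prep)
}

# scatter per-sample values onto the full image; bilinear interpolation
# between lattice points when the grid is subsampled
grid_to_image <- function(grid, values, interpolate = TRUE) {
  rows <- sort(unique(grid$coords[, 1]))
  cols <- sort(unique(grid$coords[, 2]))
  sub <- matrix(NA_real_, length(rows), length(cols))
  sub[cbind(match(grid$coords[, 1], rows), match(grid$coords[, 2], cols))] <-
    values
  if (length(rows) == grid$height && length(cols) == grid$width)
    return(sub)
  out <- matrix(0, grid$height, grid$width)
  for (r in seq_len(grid$height)) {
    fr <- stats::approx(rows, seq_along(rows), xout = r, rule = 2)$y
    for (c in seq_len(grid$width)) {
      fc <- stats::approx(cols, seq_along(cols), xout = c, rule = 2)$y
      out[r, c] <- if (interpolate) bilinear_at(sub, fr, fc)
                   else sub[round(fr), round(fc)]
    }
  }
  out
}

#' Corrected peak-intensity map
#'
#' Baseline-corrected intensity at the axis point nearest `peak_wn`, per
#' pixel. Diagnostic single-band images (e.g. 1207 cm-1 protein signal,
#' 2856 cm-1 lipid signal) visualize tumor/brain contrast directly.
#'
#' @param grid a [spectral_grid()].
#' @param peak_wn peak position (cm-1), inside the grid axis range.
#' @param epls an [epls_config()].
#' @param correct if `FALSE`, use raw intensities.
#' @return numeric `height x width` intensity matrix.
#' @export
peak_intensity_map <- function(grid, peak_wn, epls = epls_config(),
                               correct = TRUE) {
  wn <- grid$set$wavenumber
  if (peak_wn < min(wn) || peak_wn > max(wn))
    stop("peak outside the grid axis")
  idx <- which.min(abs(wn - peak_wn))
  vals <- apply(grid$set$intensity, 2, function(y) {
    if (correct)
      epls_correct(spectrum(wn, y), epls)$corrected$intensity[idx]
    else y[idx]
  })
  grid_to_image(grid, vals)
}

#' Unsupervised cluster map of a spectral grid
#'
#' K-means over conditioned band vectors; spatially maps spectra by
#' overall similarity without using labels. Deterministic per seed.
#'
#' @param grid a [spectral_grid()].
#' @param n_clusters number of clusters (>= 2).
#' @param band a [band_window()].
#' @param seed integer seed.
#' @param epls,prep,correct as in [classify_map()].
#' @return integer `height x width` label matrix (nearest-neighbor filled
#'   when the grid is subsampled).
#' @export
cluster_map <- function(grid, n_clusters = 2, band = bands()$FP, seed = 1,
                        epls = epls_config(), prep = prep_config(),
                        correct = TRUE) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (n_clusters > nspec(grid$set)) stop("n_clusters exceeds number of pixels")
  set <- grid_pipeline(grid$set, epls, prep, correct)
  X <- t(extract_band(set, band)$intensity)
  if (nrow(unique(X)) < n_clusters)
    warning("fewer distinct spectra than clusters; duplicate centroids")
  set.seed(seed)
  km <- stats::kmeans(X, centers = min(n_clusters, nrow(unique(X))),
                      nstart = 5)
  img <- grid_to_image(grid, km$cluster, interpolate = FALSE)
  mode(img) <- "integer"
  img
}

#' Threshold an image into a mask and extract its outer boundary
#'
#' `mask = image >= threshold`; only the largest connected component
#' (8-connectivity) is retained. The contour is the set of mask pixels
#' adjacent (4-neighborhood) to a non-mask pixel or the image border.
#' Optional Gaussian smoothing of the image before thresholding
#' (`smooth_sigma` in pixels) regularizes noisy per-pixel fields --
#' recommended for probability maps, where uncorrelated per-spectrum
#' prediction noise otherwise erodes the margin ring.
#'
#' @param image numeric matrix (probability or intensity map).
#' @param threshold scalar threshold.
#' @param smooth_sigma Gaussian pre-smoothing SD in pixels (0 = none).
#' @return list with `mask` (logical matrix) and `contour` (logical
#'   matrix of boundary pixels).
#' @export
extract_boundary <- function(image, threshold, smooth_sigma = 0) {
  if (!all(is.finite(image))) stop("image must be finite")
  if (smooth_sigma > 0) image <- gaussian_blur(image, smooth_sigma)
  mask <- image >= threshold
  if (!any(mask)) stop("empty mask: no pixel reaches the threshold")
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  list(mask = mask, contour = mask_contour(mask))
}

# boundary pixels of a binary mask (4-neighborhood erosion difference)
mask_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  mask & !inner
}

#' Compare modality boundaries against the ground-truth tumor mask
#'
#' Quantifies margin overestimation: areas and area ratios of the
#' fluorescence- and Raman-derived masks relative to truth, and the mean
#' signed margin offset -- for each truth-contour pixel, the distance to
#' the nearest contour pixel of the compared mask, signed positive when
#' the truth-contour pixel lies inside the compared mask (the mask extends
#' outward past the true margin) and negative when outside it.
#'
#' @param truth_mask,fluor_mask,raman_mask logical matrices of one shape;
#'   `truth_mask` non-empty.
#' @return a `boundary_comparison`: list with `area_truth`, `area_fluor`,
#'   `area_raman`, `over_ratio_fluor`, `over_ratio_raman`,
#'   `mean_margin_offset_fluor`, `mean_margin_offset_raman` (pixels).
#' @export
compare_boundaries <- function(truth_mask, fluor_mask, raman_mask) {
  dims <- lapply(list(truth_mask, fluor_mask, raman_mask), dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("mask shapes differ")
  if (!any(truth_mask)) stop("empty truth mask")
  at <- sum(truth_mask); af <- sum(fluor_mask); ar <- sum(raman_mask)
  offset <- function(mask) {
    tc <- which(mask_contour(truth_mask), arr.ind = TRUE)
    mc <- mask_contour(mask)
    if (!any(mc)) return(NA_real_)
    # distance of every pixel to the nearest contour pixel of `mask`
    dist_img <- EBImage::distmap(1 - mc)
    d <- dist_img[tc]
    sgn <- ifelse(mask[tc], 1, -1)
    mean(sgn * d)
  }
  structure(list(area_truth = at, area_fluor = af, area_raman = ar,
                 over_ratio_fluor = af / at, over_ratio_raman = ar / at,
                 mean_margin_offset_fluor = offset(fluor_mask),
                 mean_margin_offset_raman = offset(raman_mask)),
            class = "boundary_comparison")
}

#' @export
print.boundary_comparison <- function(x, ...) {
  cat(sprintf(paste0("<boundary_comparison: over-ratio fluor %.3f ",
                     "(offset %+.2f px), raman %.3f (offset %+.2f px)>\n"),
              x$over_ratio_fluor, x$mean_margin_offset_fluor,
              x$over_ratio_raman, x$mean_margin_offset_raman))
  invisible(x)
}

#' Logistic trend of a peak intensity profile across the tumor margin
#'
#' Fits a logistic curve to a gray-value or peak-intensity profile sampled
#' along a line crossing the margin and reports the slope sign: a
#' gradient-like monotone transition (rather than a step) is the expected
#' signature of infiltrative margins.
#'
#' @param profile numeric intensity sequence along the scan line.
#' @return list with `slope_sign` (+1 increasing, -1 decreasing, 0 flat)
#'   and the fitted values.
#' @export
margin_trend <- function(profile) {
  n <- length(profile)
  if (n < 5) stop("profile too short")
  x <- seq_len(n)
  rng <- range(profile)
  if (diff(rng) == 0)
    return(list(slope_sign = 0, fitted = rep(rng[1], n)))
  p01 <- (profile - rng[1]) / diff(rng)
  fit <- suppressWarnings(stats::glm(p01 ~ x, family = stats::quasibinomial()))
  co <- stats::coef(fit)[2]
  list(slope_sign = sign(unname(co)),
       fitted = rng[1] + diff(rng) * stats::fitted(fit))
}
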