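#' Per-pixel fluorescence SNR map
#'
#' Standardizes each pixel against a healthy-tissue (ICG-free) background
#' region of interest: `SNR_i = (S_i - mu_B) / sigma_B`, where `mu_B` and
#' `sigma_B` are the mean and SD of the background pixels. Values may be
#' negative; the map is affine-invariant under gain/offset changes of the
#' image (given the same ROI).
#'
#' @param image numeric matrix of gray values.
#' @param background_roi logical matrix of the same shape marking
#'   background pixels (non-empty), or a list `(row, col, height, width)`
#'   rectangle.
#' @return list with `snr` (matrix), `mu_B`, `sigma_B`, `roi`.
#' @export
snr_map <- function(image, background_roi) {
  image <- as.matrix(image)
  if (is.list(background_roi)) {
    r <- background_roi
    roi <- matrix(FALSE, nrow(image), ncol(image))
    roi[r$row:(r$row + r$height - 1), r$col:(r$col + r$width - 1)] <- TRUE
  } else roi <- as.matrix(background_roi)
  if (!identical(dim(roi), dim(image)))
    stop("background ROI shape differs from image")
  if (!any(roi)) stop("empty background ROI")
  bg <- image[roi]
  mu <- mean(bg)
  sig <- stats::sd(bg)
  if (!is.finite(sig) || sig == 0)
    stop("zero background variance: SNR undefined")
  list(snr = (image - mu) / sig, mu_B = mu, sigma_B = sig, roi = roi)
}

#' Discretize an SNR map into fluorescence regions
#'
#' Five levels: background for SNR < 1, region-n for n <= SNR < n + 1
#' (n = 1, 2, 3), and region-4 for SNR >= 4. Bins are half-open with
#' closed lower bounds, consistent with region-4's "SNR >= 4" definition.
#'
#' @param snr numeric matrix (or vector) of finite SNR values.
#' @return integer matrix of labels in \{0 (background), 1, 2, 3, 4\},
#'   classed `region_label_map` when the input is a matrix.
#' @export
bin_regions <- function(snr) {
  if (!all(is.finite(snr))) stop("SNR values must be finite")
  lab <- pmin(pmax(floor(snr), 0), 4)
  lab[snr < 1] <- 0
  mode(lab) <- "integer"
  if (is.matrix(snr)) class(lab) <- c("region_label_map", class(lab))
  lab
}

#' Gray-value profile along a polyline
#'
#' Samples the image by bilinear interpolation at unit-spaced points along
#' the polyline (arc length parameterization), preserving order. Pixel
#' coordinates are `(row, col)` with the first pixel at `(1, 1)`.
#'
#' @param image numeric matrix.
#' @param polyline numeric matrix (n x 2) of ordered `(row, col)` vertices.
#' @return numeric vector of gray values; its length is the rounded total
#'   arc length plus one.
#' @export
path_profile <- function(image, polyline) {
  polyline <- as.matrix(polyline)
  if (ncol(polyline) != 2 || nrow(polyline) < 2)
    stop("polyline needs >= 2 (row, col) vertices")
  if (any(polyline[, 1] < 1 | polyline[, 1] > nrow(image) |
          polyline[, 2] < 1 | polyline[, 2] > ncol(image)))
    stop("polyline out of image bounds")
  seg <- sqrt(rowSums(diff(polyline)^2))
  total <- sum(seg)
  if (total == 0) stop("degenerate polyline: zero arc length")
  # round(total) + 1 samples at (approximately unit) even arc spacing
  ts <- seq(0, total, length.out = max(round(total), 1) + 1)
  cum <- c(0, cumsum(seg))
  pts <- t(vapply(ts, function(t) {
    j <- max(which(cum <= t + 1e-12)); j <- min(j, length(seg))
    f <- if (seg[j] == 0) 0 else (t - cum[j]) / seg[j]
    polyline[j, ] + f * (polyline[j + 1, ] - polyline[j, ])
  }, numeric(2)))
  vapply(seq_len(nrow(pts)), function(i)
    bilinear_at(image, pts[i, 1], pts[i, 2]), numeric(1))
}

# bilinear interpolation at fractional (row, col)
bilinear_at <- function(image, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  r0 <- min(max(r0, 1), nrow(image) - 1L)
  c0 <- min(max(c0, 1), ncol(image) - 1L)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * image[r0, c0] +
    (1 - fr) * fc * image[r0, c0 + 1] +
    fr * (1 - fc) * image[r0 + 1, c0] +
    fr * fc * image[r0 + 1, c0 + 1]
}

#' Per-region gray-value statistics
#'
#' @param labels a [bin_regions()] label map.
#' @param image gray-value matrix of the same shape.
#' @return data.frame with one row per occurring region: `region`, `mean`,
#'   `sd`, `area` (pixel count). Areas sum to the image size.
#' @export
region_stats <- function(labels, image) {
  if (!identical(dim(labels)[1:2], dim(image)[1:2]))
    stop("labels and image shapes differ")
  regs <- sort(unique(as.integer(labels)))
  do.call(rbind, lapply(regs, function(g) {
    v <- image[labels == g]
    data.frame(region = g, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               area = length(v))
  }))
}

#' Read a grayscale image (PNG, TIFF or CSV matrix)
#'
#' @param path file path; format chosen by extension.
#' @return numeric matrix of gray values.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
      tiff::readTIFF(path)
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  unname(img)
}

#' Write a grayscale image (PNG, TIFF or CSV matrix)
#'
#' PNG/TIFF output is rescaled to \[0, 1\]; CSV keeps raw values.
#'
#' @param image numeric matrix.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(image, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  rng <- range(image)
  sc <- if (diff(rng) == 0) image * 0 else (image - rng[1]) / diff(rng)
  switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
      png::writePNG(sc, path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
      tiff::writeTIFF(sc, path)
    },
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Five-level pseudo-color palette for region maps
#'
#' Fixed palette used when rendering [bin_regions()] label maps; cosmetic.
#' @return named character vector of colors for background and regions 1-4.
#' @export
region_palette <- function() {
  c(background = "#202020", region1 = "#2c7bb6", region2 = "#abd9e9",
    region3 = "#fdae61", region4 = "#d7191c")
}
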