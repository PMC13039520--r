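# one small phantom + model shared across blocks in this file
ph <- small_phantom(seed = 1)
model <- trained_model(n_per_class = 150, seed = 7)

test_that("probability maps separate pure-class grids and stay in [0, 1]", {
  axis <- default_axis()
  mk_grid <- function(cl) {
    set.seed(60 + cl)
    ints <- sapply(1:16, function(i)
      make_spectrum(cl, icg_amp = 0.5, noise_sd = 0.05)$intensity)
    spectral_grid(4, 4, as.matrix(expand.grid(row = 1:4, col = 1:4)),
                  spectrum_set(axis, ints))
  }
  p0 <- classify_map(mk_grid(0), model)
  p1 <- classify_map(mk_grid(1), model)
  expect_true(all(p0 >= 0 & p0 <= 1))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_lt(mean(p0), 0.5)
  expect_gt(mean(p1), 0.5)
})

test_that("probability map recovers the phantom tumor against truth", {
  prob <- classify_map(ph$grid, model)
  expect_equal(dim(prob), c(32, 32))
  raman <- extract_boundary(prob, 0.5, smooth_sigma = 2)
  # Raman-positive area tracks the true tumor area
  expect_lt(abs(sum(raman$mask) / sum(ph$truth_mask) - 1), 0.15)
})

test_that("corrected peak-intensity maps show the expected tissue contrast", {
  m1207 <- peak_intensity_map(ph$grid, 1207)
  m2856 <- peak_intensity_map(ph$grid, 2856)
  expect_gt(mean(m1207[ph$truth_mask]), mean(m1207[!ph$truth_mask]))
  expect_gt(mean(m2856[!ph$truth_mask]), mean(m2856[ph$truth_mask]))
  expect_error(peak_intensity_map(ph$grid, 9999), "outside")
  # constant grid maps to a constant image
  axis <- seq(800, 1800, 10)
  g <- spectral_grid(2, 2, as.matrix(expand.grid(row = 1:2, col = 1:2)),
                     spectrum_set(axis, matrix(5, length(axis), 4)))
  expect_true(all(peak_intensity_map(g, 1207, correct = FALSE) == 5))
})

test_that("k-means cluster maps align with the tumor and are reproducible", {
  cl <- cluster_map(ph$grid, n_clusters = 2, seed = 3)
  truth_at <- ph$truth_mask
  # best-permutation agreement with the truth mask
  agree <- max(mean((cl == 1) == truth_at), mean((cl == 2) == truth_at))
  expect_gte(agree, 0.8)
  expect_identical(cl, cluster_map(ph$grid, n_clusters = 2, seed = 3))
  expect_error(cluster_map(ph$grid, n_clusters = 1), ">= 2")
  # identical spectra collapse to one effective cluster
  axis <- seq(800, 1800, 10)
  g <- spectral_grid(2, 2, as.matrix(expand.grid(row = 1:2, col = 1:2)),
                     spectrum_set(axis, matrix(1, length(axis), 4)))
  expect_warning(cluster_map(g, n_clusters = 2, correct = FALSE),
                 "duplicate|distinct")
})

test_that("boundary extraction finds the rim of a disk field", {
  d <- sqrt(outer((1:40 - 20.5)^2, (1:40 - 20.5)^2, "+"))
  prob <- 1 / (1 + exp(d - 10))  # disk of radius ~10
  b <- extract_boundary(prob, 0.5)
  rim <- which(b$contour, arr.ind = TRUE)
  rim_d <- sqrt((rim[, 1] - 20.5)^2 + (rim[, 2] - 20.5)^2)
  expect_true(all(abs(rim_d - 10) < 1.6))
  expect_error(extract_boundary(prob, 2), "empty mask")
  full <- extract_boundary(prob + 1, 0)
  expect_true(all(full$mask))
})

test_that("boundary comparison scores identical, dilated and phantom masks", {
  d <- sqrt(outer((1:40 - 20.5)^2, (1:40 - 20.5)^2, "+"))
  truth <- d <= 10
  same <- compare_boundaries(truth, truth, truth)
  expect_equal(same$over_ratio_fluor, 1)
  expect_equal(same$over_ratio_raman, 1)
  expect_equal(same$mean_margin_offset_raman, 0)
  h <- 4
  dilated <- d <= 10 + h
  cmp <- compare_boundaries(truth, dilated, truth)
  expect_gt(cmp$over_ratio_fluor, 1)
  expect_lt(abs(cmp$mean_margin_offset_fluor - h), 1)
  expect_error(compare_boundaries(truth, dilated[1:39, ], truth), "shape")
  expect_error(compare_boundaries(truth & FALSE, truth, truth), "empty truth")
})

test_that("fluorescence overestimates the phantom margin while Raman does not", {
  sm <- snr_map(ph$fluor_image, ph$background_roi)
  fluor <- extract_boundary(sm$snr, 1)
  prob <- classify_map(ph$grid, model)
  raman <- extract_boundary(prob, 0.5, smooth_sigma = 2)
  cmp <- compare_boundaries(ph$truth_mask, fluor$mask, raman$mask)
  expect_gt(cmp$over_ratio_fluor, cmp$over_ratio_raman)
  expect_gt(cmp$mean_margin_offset_fluor, cmp$mean_margin_offset_raman)
})

test_that("glioma-call rates step up through the fluorescence regions", {
  # transitional region-2 (0.2 infiltration) must sit strictly between the
  # cancer-free region-1 and the heavily infiltrated region-3
  big <- make_phantom(seed = 1)
  sm <- snr_map(big$fluor_image, big$background_roi)
  reg <- bin_regions(sm$snr)[big$grid$coords]
  prepped <- prep_set(big$grid$set)
  pred <- predict_label(predict_proba(model, prepped))
  rate <- vapply(1:3, function(g) mean(pred[reg == g]), numeric(1))
  expect_lt(rate[1], rate[2])
  expect_lt(rate[2], rate[3])
})

test_that("margin trend detects the gradient direction across the margin", {
  expect_equal(margin_trend(seq(0, 1, length.out = 20))$slope_sign, 1)
  expect_equal(margin_trend(seq(5, 2, length.out = 20))$slope_sign, -1)
  expect_equal(margin_trend(rep(2, 20))$slope_sign, 0)
})
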