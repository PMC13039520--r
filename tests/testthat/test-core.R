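test_that("wavenumber axis validation rejects bad axes", {
  expect_error(wn_axis(c(1000, 900, 800)), "not increasing")
  expect_error(wn_axis(c(800, 800, 900)), "not increasing")
  expect_error(wn_axis(5), "at least 2")
  expect_error(wn_axis(c(1, NA, 3)), "finite")
  expect_equal(as.numeric(wn_axis(c(800, 900, 1000))), c(800, 900, 1000))
})

test_that("band constants match the diagnostic band definitions", {
  b <- bands()
  expect_equal(c(b$FP$lo, b$FP$hi), c(800, 1800))
  expect_equal(c(b$HWN$lo, b$HWN$hi), c(2800, 3050))
  expect_error(band_window(1800, 800), "lo < hi")
})

test_that("long CSV layout reads a single spectrum", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,intensity", "800,1.0", "900,2.0", "1000,3.0"), f)
  s <- read_spectra(f, layout = "long")
  expect_equal(nspec(s), 1L)
  expect_equal(s$wavenumber, c(800, 900, 1000))
  expect_equal(as.numeric(s$intensity), c(1, 2, 3))
})

test_that("matrix CSV layout reads multiple spectra on a shared axis", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,a,b", "800,1,4", "900,2,5", "1000,3,6"), f)
  s <- read_spectra(f, layout = "matrix")
  expect_equal(nspec(s), 2L)
  expect_equal(unname(s$intensity[, 2]), c(4, 5, 6))
})

test_that("non-monotone axis and bad cells are rejected on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,a", "1000,1", "900,2", "800,3"), f)
  expect_error(read_spectra(f), "not increasing")
  writeLines(c("wavenumber,a", "800,x", "900,2"), f)
  expect_error(read_spectra(f), "non-numeric|missing")
  expect_error(read_spectra("no/such/file.csv"), "not found")
})

test_that("write/read round trip preserves axis and intensities", {
  set.seed(42)
  axis <- sort(runif(40, 400, 3100))
  ints <- matrix(rnorm(40 * 3, 100, 30), nrow = 40)
  s <- spectrum_set(axis, ints)
  for (layout in c("matrix", "long")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_spectra(s, f, layout = layout)
    s2 <- read_spectra(f, layout = layout)
    expect_equal(s2$wavenumber, s$wavenumber, tolerance = 1e-12)
    expect_lt(max(abs(s2$intensity - s$intensity) / pmax(abs(s$intensity), 1)),
              1e-9)
  }
})

test_that("empty spectrum set writes a header-only file", {
  s <- spectrum_set(c(800, 900), matrix(numeric(0), nrow = 2, ncol = 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, f)
  expect_equal(length(readLines(f)), 1L)
})

test_that("extract_band keeps exactly the closed-interval points", {
  axis <- seq(400, 3100, by = 2)
  s <- spectrum(axis, seq_along(axis))
  fp <- extract_band(s, bands()$FP)
  expect_true(all(fp$wavenumber >= 800 & fp$wavenumber <= 1800))
  expect_equal(range(fp$wavenumber), c(800, 1800))  # closed endpoints kept
  # brute-force count oracle on random axes
  set.seed(7)
  for (i in 1:10) {
    ax <- sort(runif(60, 400, 3100))
    b <- band_window(900, 2500)
    n_oracle <- 0L
    for (w in ax) if (w >= b$lo && w <= b$hi) n_oracle <- n_oracle + 1L
    got <- extract_band(spectrum(ax, rnorm(60)), b)
    expect_equal(length(got$wavenumber), n_oracle)
  }
})

test_that("extract_band is idempotent and rejects empty overlap", {
  s <- spectrum(seq(400, 3100, 2), rnorm(1351))
  once <- extract_band(s, bands()$HWN)
  twice <- extract_band(once, bands()$HWN)
  expect_identical(once$intensity, twice$intensity)
  expect_error(extract_band(s, band_window(5000, 6000)), "overlap")
})

test_that("resample is exact on affine spectra and identity on own axis", {
  axis <- seq(400, 1000, by = 3)
  s <- spectrum(axis, 0.5 * axis + 7)
  target <- seq(450, 950, by = 2.5)
  r <- resample_spectrum(s, target)
  expect_equal(r$intensity, 0.5 * target + 7, tolerance = 1e-12)
  same <- resample_spectrum(s, axis)
  expect_equal(same$intensity, s$intensity, tolerance = 1e-12)
  const <- resample_spectrum(spectrum(axis, rep(3, length(axis))), target)
  expect_equal(const$intensity, rep(3, length(target)), tolerance = 1e-12)
})

test_that("resample matches the per-point two-point interpolation oracle", {
  set.seed(11)
  axis <- sort(runif(50, 400, 1400))
  y <- rnorm(50)
  s <- spectrum(axis, y)
  target <- sort(runif(30, min(axis), max(axis)))
  r <- resample_spectrum(s, target)
  oracle <- vapply(target, function(x) {
    i <- max(which(axis <= x))
    if (axis[i] == x) return(y[i])
    y[i] + (x - axis[i]) * (y[i + 1] - y[i]) / (axis[i + 1] - axis[i])
  }, numeric(1))
  expect_equal(r$intensity, oracle, tolerance = 1e-12)
  expect_error(resample_spectrum(s, c(300, 500)), "extrapolation")
})
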