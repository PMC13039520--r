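test_that("all-zero spectrum yields an all-zero baseline", {
  s <- spectrum(seq(400, 700, 2), rep(0, 151))
  m <- epls_baseline(s)
  expect_lt(max(abs(m$baseline)), 1e-12)
})

test_that("a pure smooth background is reproduced to within 1% of range", {
  axis <- default_axis()
  bg <- icg_background(axis, amp = 1)
  m <- epls_baseline(spectrum(axis, bg))
  expect_lt(max(abs(m$baseline - bg)), 0.01 * diff(range(bg)))
})

test_that("baseline stays near zero when no background is present", {
  # isolated narrow peaks on a flat zero baseline: the estimator should
  # leave them essentially untouched
  axis <- default_axis()
  pv <- function(c) {
    u <- (axis - c) / 12
    0.5 * exp(-4 * log(2) * u^2) + 0.5 / (1 + 4 * u^2)
  }
  s <- spectrum(axis, pv(800) + pv(1400) + pv(2000))
  m <- epls_baseline(s)
  expect_lt(max(abs(m$baseline)), 0.15 * max(s$intensity))
  corrected <- spectrum(axis, s$intensity - m$baseline)
  expect_gt(fidelity(corrected, s), 0.99)
})

test_that("corrected + baseline reconstructs the input at non-repaired points", {
  s <- make_spectrum(1, icg_amp = 1, noise_sd = 0.05, seed = 12)
  out <- epls_correct(s)
  keep <- !out$artifact_mask
  expect_lt(max(abs(out$corrected$intensity[keep] + out$model$baseline[keep] -
                    s$intensity[keep])), 1e-12)
})

test_that("baseline roughness is non-increasing in lambda", {
  s <- make_spectrum(0, icg_amp = 1, noise_sd = 0.05, seed = 3)
  rough <- vapply(c(10, 100, 1000, 1e4, 1e5), function(l)
    epls_baseline(s, epls_config(lam = l))$roughness, numeric(1))
  expect_true(all(diff(rough) <= 0))
})

test_that("baseline mean does not exceed the input mean on peak+background data", {
  for (seed in 1:5) {
    s <- make_spectrum(seed %% 2, icg_amp = 1, noise_sd = 0.05, seed = seed)
    m <- epls_baseline(s)
    expect_lte(mean(m$baseline), mean(s$intensity))
  }
})

test_that("repair_gaps reproduces the two-point interpolation formula", {
  # the worked example: (x1,y1)=(0,0), (x2,y2)=(2,4) -> y(1) = 2
  s <- spectrum(c(0, 1, 2), c(0, 99, 4))
  fixed <- repair_gaps(s, c(FALSE, TRUE, FALSE))
  expect_equal(fixed$intensity[2], 2)
  # a gap inside an affine signal is reconstructed exactly
  axis <- seq(400, 500, 2)
  aff <- spectrum(axis, 3 * axis - 5)
  mask <- rep(FALSE, length(axis)); mask[10:14] <- TRUE
  broken <- spectrum(axis, replace(aff$intensity, 10:14, 0))
  expect_equal(repair_gaps(broken, mask)$intensity, aff$intensity,
               tolerance = 1e-12)
})

test_that("repair_gaps matches a per-gap oracle on random masks", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 60
    x <- sort(runif(n, 400, 1000))
    y <- rnorm(n)
    mask <- rep(FALSE, n)
    mask[sample(2:(n - 1), 12)] <- TRUE
    got <- repair_gaps(spectrum(x, y), mask)$intensity
    # independent oracle: walk each flagged point to its flanking valid
    # neighbors and apply the two-point formula directly
    oracle <- y
    for (i in which(mask)) {
      i1 <- i; while (mask[i1]) i1 <- i1 - 1
      i2 <- i; while (mask[i2]) i2 <- i2 + 1
      oracle[i] <- y[i1] + (x[i] - x[i1]) * (y[i2] - y[i1]) / (x[i2] - x[i1])
    }
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_identical(got[!mask], y[!mask])
  }
})

test_that("repair_gaps refuses runs touching the spectrum edge", {
  s <- spectrum(1:10, rnorm(10))
  expect_error(repair_gaps(s, c(TRUE, rep(FALSE, 9))), "edge")
  expect_error(repair_gaps(s, c(rep(FALSE, 9), TRUE)), "edge")
})

test_that("artifact detection flags dips and spikes but not smooth signals", {
  axis <- seq(400, 1400, 2)
  smooth <- spectrum(axis, 2 + sin(axis / 50))
  expect_false(any(detect_artifacts(smooth)))
  expect_false(any(detect_artifacts(spectrum(axis, rep(5, length(axis))))))
  set.seed(2)
  y <- rnorm(length(axis), 0, 0.1)
  dip_at <- 250
  y[dip_at] <- -10 * 0.1 / sqrt(2) * 1.5  # far below -4 local noise SDs
  mask <- detect_artifacts(spectrum(axis, y))
  expect_true(mask[dip_at])
})

test_that("fidelity is the Pearson correlation", {
  axis <- c(400, 500, 600)
  a <- spectrum(axis, c(1, 2, 3))
  expect_equal(fidelity(a, a), 1.0)
  expect_equal(fidelity(a, spectrum(axis, -c(1, 2, 3))), -1.0)
  # closed form for (1,2,3) vs (1,2,4): r = 1.5 / sqrt(1 * 7/3)
  b <- spectrum(axis, c(1, 2, 4))
  expect_equal(fidelity(a, b), 1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_error(fidelity(a, spectrum(axis, c(2, 2, 2))), "variance")
})

test_that("correction fidelity degrades from the low- to high-ICG regime", {
  rs <- sapply(c(1, 10), function(amp) {
    median(vapply(1:12, function(i) {
      s <- make_spectrum(i %% 2, icg_amp = amp, noise_sd = 0.05, seed = 400 + i)
      out <- epls_correct(s)
      fidelity(out$corrected, spectrum(s$wavenumber, s$meta$raman))
    }, numeric(1)))
  })
  expect_lt(rs[2], rs[1])
})
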