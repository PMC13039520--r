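---
title: "Dual-modal fluorescence–Raman margin mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modal fluorescence–Raman margin mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanicg)
```

## The problem

Indocyanine green (ICG) accumulates where the blood–brain barrier is
disrupted, so its fluorescence highlights *structurally* abnormal tissue —
which systematically extends beyond the *molecularly* malignant tissue.
Raman spectroscopy reads molecular composition directly but is slow and
point-wise, and under a shared 785-nm excitation the ICG emission buries
the Raman signal. This package implements a search-and-confirm workflow:
segment the fluorescence image into suspicion regions, sample Raman spectra
inside them, reject the fluorescence baseline, classify each spectrum, and
quantify where the two modalities agree and where the dye overestimates.

## Fluorescence baseline rejection

On the Raman-shift axis the ICG emission is a broad, smooth curve with its
apex near 531 cm⁻¹ and a long high-wavenumber tail, typically one to two
orders of magnitude taller than the Raman peaks riding on it. The baseline
estimator solves, at each reweighting iteration, the penalized
least-squares system

$$(W + \lambda D^\top D)\, z = W y,$$

with $D$ the second-order finite-difference operator, and updates the
diagonal weights asymmetrically: points above the running baseline (Raman
peaks) get weight `asym_p`, points below get `1 - asym_p`. The iteration
stops when the relative baseline change falls below `tol`. The converged
baseline is also projected onto its `n_latent` leading discrete-cosine
modes, giving a smooth latent summary `w` that is reported alongside the
full baseline (it is *not* used for subtraction). The banded system is
solved exactly in O(n) by a compiled pentadiagonal Cholesky, so per-pixel
correction of whole spectral maps is cheap.

Two numerical conventions matter and are deliberate:

* **Corrections conserve signal.** At every non-repaired point,
  `corrected + baseline` equals the input to machine precision; only
  flagged artifact runs are replaced.
* **Artifact repair is strictly local.** Flagged runs are rebuilt by the
  two-point linear rule $y = y_1 + (x - x_1)(y_2 - y_1)/(x_2 - x_1)$
  between their flanking valid neighbors, preserving local gradients
  without the ringing of higher-order interpolants. Runs touching the
  spectrum edge have no flanking pair and are left alone.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `lam` | 200 | smoothness weight λ (dimensionless, axis-spacing dependent) |
| `asym_p` | 0.01 | weight of points above the baseline |
| `n_latent` | 3 | DCT modes in the latent summary `w` |
| `max_iter`, `tol` | 50, 1e-6 | reweighting iteration control |
| `z_thresh` | 4 | robust-SD multiple for artifact flagging |

λ = 200 was chosen by the shape of the problem, not fitted to data: on a
2 cm⁻¹ axis the baseline must follow the sharply curved ICG apex (a pure
noiseless background is reproduced to within 1% of its range) while riding
over 12 cm⁻¹-FWHM Raman peaks. Orders of magnitude stiffer settings
(λ ≥ 10⁴) leave apex residuals several times taller than the Raman peaks
themselves, which then dominate the corrected spectrum. The artifact
criterion (negative excursions and first-difference spikes beyond 4 robust
SDs) assumes the corrected spectrum carries measurement noise; on
noiseless synthetic signals the spike rule can flag genuine sharp
features.

Whether correction should run on the full spectrum or per band is not
dictated by anything physical; the package corrects the full spectrum once
and extracts bands afterwards, so both bands see one consistent baseline.

## Classification

Tissue classes (0 = brain, 1 = glioma) are learned by gradient-boosted
trees on band intensities. Feature vectors are the conditioned
(Savitzky–Golay smoothed, window 11, order 3; L2-normalized) intensities,
re-normalized *within the band* — so features are invariant both to
overall scale and to whatever happens outside the band (e.g. residual
fluorescence near its apex, which varies with local dye concentration).
Defaults: depth 3, learning rate 0.1, up to 100 rounds with early stopping
on a stratified 20% validation split; probabilities above 0.5 are called
glioma, 0.5 or below brain. Stratified 5-fold cross-validation is
available where a single split would be too noisy.

Feature-importance profiles (per-wavenumber gain) from two instruments are
compared with a ±3.5 cm⁻¹ tolerance: the top-*k* overlap ratio uses greedy
nearest-neighbor matching (descending importance, ties toward the lower
wavenumber — deterministic by construction), and cosine similarity aligns
the second profile onto the first axis (nearest wavenumber within
tolerance, else 0). *k* defaults to 20 and is reported with the result.

## SNR segmentation and agreement

Fluorescence images are standardized per pixel against an
operator-designated healthy-tissue ROI, $\mathrm{SNR}_i = (S_i - \mu_B)/\sigma_B$,
and discretized with closed lower bounds: background (SNR < 1), region-n
for n ≤ SNR < n+1 (n = 1, 2, 3), region-4 for SNR ≥ 4. The half-open
reading is forced by region-4's "SNR ≥ 4" definition and makes the
region maps affine-invariant in the image gain/offset. SNR is computed
per pixel (not per region mean) — the per-point reading of the defining
formula.

Agreement between the dichotomized fluorescence rater (SNR ≥ t) and the
Raman rater uses unweighted Cohen's κ with the Fleiss–Cohen–Everitt
asymptotic SE (a multinomial bootstrap SE is provided as a cross-check;
the test suite holds them within 10% of each other). Sites are individual
spectra, not region-aggregated calls. Per-region concordance designates
regions ≥ 2 as glioma by default — the "suspicion map" reading — and is
configurable.

## Spatial mapping

Probability heatmaps run the full per-spectrum pipeline at every grid
point. When the spectral grid subsamples the image, maps are bilinearly
interpolated back to full resolution. Before the Raman boundary is
contoured, the probability field is Gaussian-smoothed (default SD 2 px in
the pipeline): per-spectrum prediction noise is spatially uncorrelated,
and without regularization it stochastically erodes the thresholded mask
exactly at the infiltrative margin where probabilities are intermediate.
Smoothing before contouring is standard segmentation practice and is
exposed as a parameter (`smooth_sigma`, default 0 in the low-level
function). Unsupervised structure is mapped with k-means (k ∈ {2, 3}
typical) on the same conditioned band vectors; the clustering algorithm is
a free choice and k-means is the documented default.

Margin quantification: masks are compared by area over-ratio
(area / truth area) and by the mean signed offset — for each truth-contour
pixel, the distance-transform distance to the compared mask's contour,
signed positive when the mask extends outward past the true margin. For
identical masks both statistics are exactly 1 and 0.

## What the synthetic generator emulates

* **Spectra.** Twelve pseudo-Voigt peaks (50/50 Gaussian/Lorentzian,
  FWHM 12 cm⁻¹ — the standard condensed-phase line shape) at the
  tissue-characteristic positions, with class contrasts in the
  biochemically expected directions: brain-elevated 963, 1261, 1430, 1647,
  2842/2856 cm⁻¹ (structural proteins, lipids/myelin); glioma-elevated
  997 (phenylalanine), 1207, 2940 cm⁻¹ (protein metabolism). Absolute
  amplitudes are free model choices — only directions are constrained —
  with 10% multiplicative log-normal jitter per peak and additive Gaussian
  noise (SD 0.05 of unit peak height). Axis: 400–3100 cm⁻¹ at 2 cm⁻¹.
* **ICG background.** One broad log-normal band peaking at 531 cm⁻¹ with
  a long high-wavenumber tail, height 20 (a.u.) at `icg_amp = 1` — the
  regime in which Raman recovery still works, standing in for ~10⁻⁹ M
  dye — and 200 at `icg_amp = 10`, where recovery collapses.
* **Phantoms.** A circular tumor with a stepped radial infiltration
  profile — 1 (core), 0.65 (inner margin band), 0.2 (inner halo), 0
  (outer halo and beyond) — matching the histological composition
  reported for the corresponding fluorescence regions. The fluorescence
  image is a smoothed four-step radial profile with per-pixel SNR targets
  ≈ 5 / 3.5 / 2.4 / 1.5 over core / margin / inner halo / outer halo, so
  the SNR = 3 contour tracks the true boundary and the SNR = 1 contour
  tracks the halo edge. Pixel noise is 1 σ_B in the background but
  0.3 σ_B over ICG-laden regions: σ_B is dominated by healthy-tissue
  autofluorescence heterogeneity, while the strong specific ICG signal has
  smaller relative fluctuation — without this the five regions would not
  be spatially coherent, as real system-software region maps are.
  Per-pixel spectra are brain/glioma mixtures weighted by infiltration,
  with spectral ICG contamination proportional to the local fluorescence.

What passing tests on these phantoms do **not** show: robustness to real
tissue optics (depth-dependent attenuation, scattering), to instrument
drift and cosmic rays, to non-circular infiltration geometry, or to ICG
pharmacokinetics. The generator is directionally faithful, not
radiometrically calibrated.

## Problem sizes and determinism

The shipped tests and the acceptance script use 64×64 phantoms with
spectra on a 2-px sub-lattice (1024 spectra per phantom), training sets of
100–500 spectra per class, and 50-spectrum fidelity cohorts — sizes at
which every stage's behavior is already stable and a full run takes about
two minutes. All stochastic stages are seeded; the pipeline records the
seed and a configuration hash in every report, and re-running a
configuration reproduces every number bit for bit.

## Known limitations

* The latent-variable reading of the baseline model (DCT projection for
  `w`) is one defensible construction; the baseline actually subtracted is
  the converged penalized solution, so this choice affects reporting only.
* Boosted trees extrapolate poorly: probabilities for tissue mixtures are
  monotone in infiltration but not calibrated fractions.
* The artifact detector needs genuine noise to estimate its thresholds.
* `over_ratio` statistics are area-based and assume a single dominant
  lesion (largest connected component).
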