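# ramanicg

Dual-modal tumor-margin analysis combining **ICG fluorescence imaging**
(fast, wide-field, but prone to overestimating tumor extent) with **Raman
spectroscopy** (slow, point-wise, but molecularly specific). The package is
aimed at researchers developing fluorescence-guided surgery workflows who
need to (a) recover Raman spectra buried under indocyanine-green (ICG)
emission, (b) classify tissue from the recovered spectra, and (c) quantify
how far dye-defined margins stray from molecular ones.

## What it computes

**Fluorescence baseline rejection.** The ICG emission under shared 785-nm
excitation appears in Raman-shift coordinates as a broad curve peaking near
531 cm⁻¹ that dwarfs the Raman peaks. The baseline *z* is estimated by
iteratively reweighted penalized least squares

    (W + λ DᵀD) z = W y,

where *D* is the second-order difference operator, λ the smoothness weight,
and the diagonal weights *W* are updated asymmetrically (points above the
running baseline — Raman peaks — get weight `asym_p` = 0.01). Residual
discontinuities after subtraction are repaired by piecewise-linear
interpolation between flanking valid points,
*y = y₁ + (x − x₁)(y₂ − y₁)/(x₂ − x₁)*.

**Band-wise tissue classification.** A gradient-boosted tree classifier
(XGBoost) on the fingerprint band (FP, 800–1800 cm⁻¹) or high-wave-number
band (HWN, 2800–3050 cm⁻¹), with sensitivity/specificity/accuracy from the
confusion matrix, per-spectrum glioma probabilities, gain-based feature
importance, and cross-instrument importance comparison (top-*k* overlap
ratio within ±3.5 cm⁻¹ and cosine similarity).

**SNR segmentation of fluorescence images.** Per-pixel
*SNRᵢ = (Sᵢ − μ_B)/σ_B* against a healthy-tissue background ROI,
discretized into background (SNR < 1) and regions 1–4 (region-4: SNR ≥ 4).

**Agreement statistics.** Cohen's κ with asymptotic (and bootstrap) SE,
κ sweeps over SNR dichotomization thresholds, per-region concordance, and
Spearman/Pearson correlations.

**Spatial margin mapping.** Per-pixel probability heatmaps, k-means cluster
maps, peak-intensity maps, boundary extraction and quantitative comparison
of fluorescence- and Raman-derived margins against ground truth (area
over-ratios, signed margin offsets).

**Synthetic data.** Because no real acquisitions ship with the package, a
first-class generator produces two-class (brain/glioma) spectra with
pseudo-Voigt peaks at the tissue-characteristic positions, concentration-
scaled ICG backgrounds, and co-registered 2-D phantoms whose fluorescent
halo extends beyond the true tumor mask — so every stage is testable
end-to-end.

## Worked example

```r
library(ramanicg)

# a glioma spectrum contaminated by ICG at the recoverable (1e-9 M-like) level
s <- make_spectrum(class_label = 1, icg_amp = 1, noise_sd = 0.05, seed = 1)
out <- epls_correct(s)
fidelity(out$corrected, spectrum(s$wavenumber, s$meta$raman))
#> [1] 0.89262

# band-wise classification of a simulated cohort
train <- make_dataset(150, icg_amp = 1, seed = 2)
prep  <- function(set) {
  ints <- apply(set$intensity, 2, function(y)
    condition(epls_correct(spectrum(set$wavenumber, y))$corrected)$intensity)
  spectrum_set(set$wavenumber, ints, labels = set$labels)
}
model <- train_classifier(prep(train), band = bands()$FP, seed = 2)
evaluate_classifier(model, prep(make_dataset(60, icg_amp = 1, seed = 3)))
#> <classifier_report: acc 1.000, sens 1.000, spec 1.000 (TP 60 FN 0 FP 0 TN 60)>

# the full search-and-confirm pipeline on a 64x64 phantom
report <- run_pipeline(pipeline_config(seed = 1))
report
#> == ramanicg run report ==
#> seed 1, config 4a5c0a90
#> classifier accuracy 1.000 (sens 1.000, spec 1.000)
#> best kappa threshold: 3 (kappa 0.867)
#> boundary over-ratios: fluor 1.625, raman 0.931
```

The report says: fluorescence (dichotomized at its best-agreeing SNR
threshold, 3) concurs with Raman calls at κ = 0.87; the fluorescence-positive
area is 1.63× the true tumor area while the Raman-derived margin stays
within ~7% of it — the quantitative form of "the dye overestimates, the
spectroscopy does not".

A thin CLI over the same functions is at `inst/cli/ramanicg.R`
(`simulate`, `phantom`, `correct`, `segment`, `run` subcommands).

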