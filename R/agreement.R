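#' Cohen's kappa for a 2x2 contingency table
#'
#' Chance-corrected agreement between two binary raters (here: fluorescence
#' dichotomized at an SNR threshold vs. Raman-predicted tissue class):
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginals. The standard error uses the
#' Fleiss-Cohen-Everitt asymptotic formula and the 95 percent confidence
#' interval is `kappa +/- 1.96 * SE`.
#'
#' @param tab 2x2 matrix of non-negative counts (rows: rater A, columns:
#'   rater B).
#' @return a `kappa_result`: list with `kappa`, `se`, `ci_low`, `ci_high`,
#'   `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("2x2 contingency table required")
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n < 1) stop("empty table")
  p <- tab / n
  prow <- rowSums(p); pcol <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(prow * pcol)
  if (isTRUE(all.equal(pe, 1)))
    stop("degenerate marginals (chance agreement = 1): kappa undefined")
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) large-sample variance
  A <- sum(diag(p) * (1 - (prow + pcol) * (1 - kappa))^2)
  B <- (1 - kappa)^2 *
    sum(p * outer(seq_len(2), seq_len(2),
                  Vectorize(function(i, j)
                    if (i == j) 0 else (pcol[i] + prow[j])^2)))
  C <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(A + B - C, 0) / (n * (1 - pe)^2))
  structure(list(kappa = kappa, se = se,
                 ci_low = kappa - 1.96 * se, ci_high = kappa + 1.96 * se,
                 p_o = po, p_e = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa %.3f (95%% CI %.3f to %.3f), n = %d>\n",
              x$kappa, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Bootstrap standard error of Cohen's kappa
#'
#' Multinomial resampling of the table cells; cross-check for the
#' asymptotic SE of [cohens_kappa()].
#'
#' @param tab 2x2 count matrix.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return bootstrap SE of kappa.
#' @export
kappa_bootstrap_se <- function(tab, n_boot = 10000, seed = 1) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  set.seed(seed)
  draws <- stats::rmultinom(n_boot, n, prob = as.vector(tab) / n)
  ks <- apply(draws, 2, function(v) {
    t2 <- matrix(v, 2, 2)
    p <- t2 / n
    po <- sum(diag(p))
    pe <- sum(rowSums(p) * colSums(p))
    if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  })
  stats::sd(ks, na.rm = TRUE)
}

#' Kappa across SNR dichotomization thresholds
#'
#' For each threshold `t`, the fluorescence rater calls a site positive
#' when its SNR is `>= t`; agreement with the Raman-predicted label is then
#' scored with [cohens_kappa()]. The threshold with maximal kappa is the
#' operating point at which the two modalities concur best.
#'
#' @param snr_values per-site SNR values.
#' @param raman_labels per-site Raman labels in \{0, 1\}, same length.
#' @param thresholds thresholds to sweep (default `1:4`).
#' @return a `kappa_sweep`: list with `results` (data.frame of threshold,
#'   kappa, se, ci_low, ci_high), `best_threshold` (argmax kappa) and the
#'   per-threshold `kappa_result`s.
#' @export
kappa_sweep <- function(snr_values, raman_labels, thresholds = 1:4) {
  if (length(snr_values) != length(raman_labels))
    stop("snr_values and raman_labels lengths differ")
  res <- lapply(thresholds, function(t) {
    fl <- as.integer(snr_values >= t)
    tab <- table(factor(fl, levels = c(0, 1)),
                 factor(raman_labels, levels = c(0, 1)))
    cohens_kappa(unclass(matrix(as.integer(tab), 2, 2)))
  })
  df <- data.frame(threshold = thresholds,
                   kappa = vapply(res, `[[`, 0, "kappa"),
                   se = vapply(res, `[[`, 0, "se"),
                   ci_low = vapply(res, `[[`, 0, "ci_low"),
                   ci_high = vapply(res, `[[`, 0, "ci_high"))
  structure(list(results = df,
                 best_threshold = thresholds[which.max(df$kappa)],
                 detail = res),
            class = "kappa_sweep")
}

#' @export
print.kappa_sweep <- function(x, ...) {
  print(x$results)
  cat("best threshold:", x$best_threshold, "\n")
  invisible(x)
}

#' Per-region concordance between fluorescence regions and Raman calls
#'
#' For every region, the fraction of sites whose Raman prediction matches
#' the region's designated class (by default regions >= 2 are designated
#' glioma, the "suspicion map" reading of SNR >= 2).
#'
#' @param region_labels per-site region id in \{0, ..., 4\}.
#' @param predictions per-site Raman labels in \{0, 1\}.
#' @param positive_regions region ids designated glioma (default `2:4`).
#' @return data.frame with `region`, `designated`, `n`, `concordance`.
#' @export
concordance <- function(region_labels, predictions, positive_regions = 2:4) {
  if (length(region_labels) != length(predictions))
    stop("aligned site vectors required")
  if (!all(region_labels %in% 0:4)) stop("unknown region id")
  regs <- sort(unique(region_labels))
  do.call(rbind, lapply(regs, function(g) {
    sel <- region_labels == g
    cls <- as.integer(g %in% positive_regions)
    data.frame(region = g, designated = cls, n = sum(sel),
               concordance = mean(predictions[sel] == cls))
  }))
}

#' Rank and linear correlation across regions
#'
#' Spearman rho and Pearson r (with two-sided p-values) between a region
#' ordinal (e.g. region id 1-4) and a per-region summary (e.g. mean
#' fluorescence or diagnostic rate).
#'
#' @param x per-region ordinal values (n >= 3).
#' @param y per-region response values, same length.
#' @return list with `spearman_rho`, `spearman_p`, `pearson_r`,
#'   `pearson_p`.
#' @export
rank_linear_correlations <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need aligned vectors with n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance input")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  pe <- stats::cor.test(x, y, method = "pearson")
  list(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value)
}
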