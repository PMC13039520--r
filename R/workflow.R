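#' Pipeline configuration
#'
#' Bundles per-stage configurations for the search-and-confirm pipeline:
#' the fluorescence image proposes suspicious regions (wide-field search),
#' targeted Raman sampling inside each region then provides molecular
#' confirmation.
#'
#' @param seed master seed; every stochastic stage derives from it.
#' @param phantom list of [make_phantom()] arguments.
#' @param epls an [epls_config()].
#' @param prep a [prep_config()].
#' @param classifier list: `n_train_per_class` (default 150), `band`
#'   (default FP), `params` for [train_classifier()].
#' @param agreement list: `thresholds` for [kappa_sweep()] (default 1:4),
#'   `positive_regions` for [concordance()] (default 2:4).
#' @param n_per_region Raman spectra sampled per fluorescence region
#'   (default 15, within the 10-20 per region practice).
#' @param raman_threshold probability threshold for the Raman boundary
#'   (default 0.5, the classification threshold).
#' @param fluor_threshold SNR threshold for the fluorescence boundary
#'   (default 1, the first fluorescent region).
#' @param boundary_smooth Gaussian pre-smoothing SD (pixels) applied to the
#'   probability map before the Raman boundary is extracted (default 2;
#'   see [extract_boundary()]).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1, phantom = list(), epls = epls_config(),
                            prep = prep_config(), classifier = list(),
                            agreement = list(), n_per_region = 15,
                            raman_threshold = 0.5, fluor_threshold = 1,
                            boundary_smooth = 2) {
  classifier <- utils::modifyList(
    list(n_train_per_class = 150, band = bands()$FP, params = list()),
    classifier)
  agreement <- utils::modifyList(
    list(thresholds = 1:4, positive_regions = 2:4), agreement)
  structure(list(seed = seed, phantom = phantom, epls = epls, prep = prep,
                 classifier = classifier, agreement = agreement,
                 n_per_region = n_per_region,
                 raman_threshold = raman_threshold,
                 fluor_threshold = fluor_threshold,
                 boundary_smooth = boundary_smooth),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the [pipeline_config()] arguments; nested sections `epls`
#' and `prep` are passed to [epls_config()] / [prep_config()]. Unknown
#' keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: ", ext)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$epls)) raw$epls <- do.call(epls_config, raw$epls)
  if (!is.null(raw$prep)) raw$prep <- do.call(prep_config, raw$prep)
  do.call(pipeline_config, raw)
}

# polynomial rolling hash of the serialized config (provenance only)
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 3))
  h <- 0
  m <- 2^31 - 1
  for (b in bytes) h <- (h * 257 + b) %% m
  sprintf("%08x", h)
}

#' Run the dual-modal search-and-confirm pipeline on a phantom
#'
#' Stages, in order: phantom generation, SNR segmentation of the
#' fluorescence image, per-region Raman sampling, fluorescence baseline
#' rejection and conditioning, classifier training (on an independently
#' simulated labeled set) and per-site prediction, agreement statistics
#' (kappa threshold sweep, per-region concordance, rank/linear
#' correlations of region means), and spatial mapping with boundary
#' comparison against ground truth.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a `run_report`: list with `segmentation` (region stats),
#'   `classifier` (a `classifier_report` on held-out data), `sites`
#'   (per-site table), `kappa` (a `kappa_sweep`), `concordance`,
#'   `correlations`, `boundaries` (a `boundary_comparison`) and
#'   `provenance` (seed, config hash, package version, timestamp).
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message("[ramanicg] ", ...)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ph <- stage("phantom", do.call(make_phantom,
                                 utils::modifyList(list(seed = cfg$seed),
                                                   cfg$phantom)))
  seg <- stage("segment", {
    sm <- snr_map(ph$fluor_image, ph$background_roi)
    labels <- bin_regions(sm$snr)
    list(snr = sm, labels = labels,
         stats = region_stats(labels, ph$fluor_image))
  })
  sites <- stage("sample-regions", {
    set.seed(cfg$seed + 1)
    reg_at_coords <- seg$labels[ph$grid$coords]
    idx <- unlist(lapply(1:4, function(g) {
      cand <- which(reg_at_coords == g)
      if (!length(cand)) return(integer())
      sample(cand, min(cfg$n_per_region, length(cand)))
    }))
    data.frame(index = idx,
               region = reg_at_coords[idx],
               snr = seg$snr$snr[ph$grid$coords[idx, , drop = FALSE]])
  })
  prepped <- stage("defluorescence+preprocess", {
    sub <- spectrum_set(ph$grid$set$wavenumber,
                        ph$grid$set$intensity[, sites$index, drop = FALSE])
    grid_pipeline(sub, cfg$epls, cfg$prep)
  })
  model <- stage("train", {
    train <- make_dataset(cfg$classifier$n_train_per_class,
                          icg_amp = ph$icg_amp, seed = cfg$seed + 2)
    train_classifier(grid_pipeline(train, cfg$epls, cfg$prep),
                     band = cfg$classifier$band,
                     params = cfg$classifier$params, seed = cfg$seed)
  })
  report <- stage("classify", {
    test <- make_dataset(max(50, cfg$classifier$n_train_per_class %/% 3),
                         icg_amp = ph$icg_amp, seed = cfg$seed + 3)
    evaluate_classifier(model, grid_pipeline(test, cfg$epls, cfg$prep))
  })
  sites$proba <- stage("predict-sites", predict_proba(model, prepped))
  sites$label <- predict_label(sites$proba)
  agree <- stage("agreement", {
    ks <- kappa_sweep(sites$snr, sites$label, cfg$agreement$thresholds)
    cc <- concordance(sites$region, sites$label,
                      cfg$agreement$positive_regions)
    rs <- seg$stats[seg$stats$region >= 1, ]
    corr <- rank_linear_correlations(rs$region, rs$mean)
    list(kappa = ks, concordance = cc, correlations = corr)
  })
  bounds <- stage("spatial-map", {
    prob <- classify_map(ph$grid, model, cfg$epls, cfg$prep)
    raman <- extract_boundary(prob, cfg$raman_threshold,
                              smooth_sigma = cfg$boundary_smooth)
    fluor <- extract_boundary(seg$snr$snr, cfg$fluor_threshold)
    list(prob_map = prob,
         comparison = compare_boundaries(ph$truth_mask, fluor$mask,
                                         raman$mask))
  })
  structure(list(segmentation = seg$stats,
                 classifier = report,
                 sites = sites,
                 kappa = agree$kappa,
                 concordance = agree$concordance,
                 correlations = agree$correlations,
                 boundaries = bounds$comparison,
                 prob_map = bounds$prob_map,
                 provenance = list(seed = cfg$seed,
                                   config_hash = config_hash(cfg),
                                   package_version =
                                     as.character(utils::packageVersion("ramanicg")),
                                   timestamp = format(Sys.time()))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== ramanicg run report ==\n")
  cat(sprintf("seed %d, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  cat(sprintf("classifier accuracy %.3f (sens %.3f, spec %.3f)\n",
              x$classifier$accuracy, x$classifier$sensitivity,
              x$classifier$specificity))
  cat(sprintf("best kappa threshold: %d (kappa %.3f)\n",
              x$kappa$best_threshold,
              max(x$kappa$results$kappa)))
  cat(sprintf("boundary over-ratios: fluor %.3f, raman %.3f\n",
              x$boundaries$over_ratio_fluor, x$boundaries$over_ratio_raman))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    provenance = report$provenance,
    segmentation = report$segmentation,
    classifier = list(confusion = as.list(report$classifier$confusion),
                      sensitivity = report$classifier$sensitivity,
                      specificity = report$classifier$specificity,
                      accuracy = report$classifier$accuracy),
    kappa = report$kappa$results,
    best_threshold = report$kappa$best_threshold,
    concordance = report$concordance,
    correlations = report$correlations,
    boundaries = unclass(report$boundaries))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
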