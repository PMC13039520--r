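#' Train a gradient-boosted tissue classifier on one spectral band
#'
#' Fits an XGBoost binary classifier (log-loss objective) on the band
#' intensities of a labeled [spectrum_set()] (class 0 = brain,
#' class 1 = glioma). Each wavenumber in the band is one feature. A
#' stratified validation split monitors log-loss for early stopping.
#' Training is deterministic for a fixed seed (single-threaded).
#'
#' @param set labeled, conditioned [spectrum_set()]; both classes present.
#' @param band a [band_window()]; features are the intensities inside it.
#' @param params list overriding the boosting defaults
#'   (`max_depth = 3`, `eta = 0.1`, `nrounds = 100`,
#'   `early_stopping_rounds = 10`, `val_fraction = 0.2`).
#' @param seed integer seed (controls the validation split and boosting).
#' @return a `raman_classifier`: list with the fitted `booster`, the band,
#'   the feature `wavenumber`s, `n_rounds` used and `loss_curve`
#'   (per-round train/validation log-loss).
#' @export
train_classifier <- function(set, band = bands()$FP, params = list(), seed = 1) {
  if (is.null(set$labels)) stop("labeled spectrum set required")
  if (length(unique(set$labels)) < 2) stop("both classes must be present")
  p <- utils::modifyList(list(max_depth = 3, eta = 0.1, nrounds = 100,
                              early_stopping_rounds = 10, val_fraction = 0.2),
                         params)
  bset <- extract_band(set, band)
  X <- band_features(bset)
  y <- bset$labels
  set.seed(seed)
  # stratified validation split
  val <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(p$val_fraction * length(idx))))
  }))
  tr <- setdiff(seq_along(y), val)
  dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
  dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val])
  xgb_params <- p[setdiff(names(p), c("nrounds", "early_stopping_rounds",
                                      "val_fraction"))]
  xgb_params <- utils::modifyList(
    list(objective = "binary:logistic", eval_metric = "logloss",
         nthread = 1, seed = seed), xgb_params)
  booster <- xgboost::xgb.train(
    params = xgb_params,
    data = dtrain, nrounds = p$nrounds,
    evals = list(train = dtrain, validation = dval),
    early_stopping_rounds = p$early_stopping_rounds, verbose = 0)
  att <- attributes(booster)
  n_rounds <- if (!is.null(att$early_stop)) att$early_stop$best_iteration
              else xgboost::xgb.get.num.boosted.rounds(booster)
  structure(list(booster = booster, band = band,
                 wavenumber = bset$wavenumber,
                 params = p, seed = seed,
                 n_rounds = n_rounds,
                 loss_curve = as.data.frame(att$evaluation_log)),
            class = "raman_classifier")
}

#' @export
print.raman_classifier <- function(x, ...) {
  cat(sprintf("<raman_classifier: band %s, %d features, %d rounds>\n",
              x$band$name, length(x$wavenumber), x$n_rounds))
  invisible(x)
}

# classifier feature matrix: band intensities, L2-renormalized per spectrum
# within the band so that features do not depend on signal outside it (e.g.
# residual fluorescence near its apex) or on overall intensity scale
band_features <- function(bset) {
  X <- t(bset$intensity)
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X <- X / nrm
  colnames(X) <- paste0("wn_", bset$wavenumber)
  X
}

#' Predicted glioma probability per spectrum
#'
#' @param model a `raman_classifier`.
#' @param set a [spectrum_set()] on an axis covering the model band.
#' @return numeric vector of class-1 (glioma) probabilities.
#' @export
predict_proba <- function(model, set) {
  bset <- extract_band(set, model$band)
  if (length(bset$wavenumber) != length(model$wavenumber) ||
      any(bset$wavenumber != model$wavenumber))
    stop("band axis mismatch between model and data; resample first")
  X <- band_features(bset)
  as.numeric(stats::predict(model$booster, xgboost::xgb.DMatrix(X)))
}

#' Dichotomize a glioma probability
#'
#' Probability strictly above 0.5 is called glioma (1); 0.5 or below is
#' assigned to brain (0).
#'
#' @param p probability in \[0, 1\] (vectorized).
#' @return integer label(s) in \{0, 1\}.
#' @export
predict_label <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probability outside [0, 1]")
  as.integer(p > 0.5)
}

#' Confusion-matrix metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/total, with class 1 (glioma) as positive.
#'
#' @param tp,fn,fp,tn confusion counts.
#' @return list with `confusion` (named counts), `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion matrix")
  list(confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / total)
}

#' Evaluate a classifier on a labeled test set
#'
#' @param model a `raman_classifier`.
#' @param test labeled [spectrum_set()].
#' @return a `classifier_report`: confusion counts, sensitivity,
#'   specificity, accuracy, per-spectrum glioma probabilities, rounds used
#'   and the training loss curve.
#' @export
evaluate_classifier <- function(model, test) {
  if (is.null(test$labels)) stop("labeled test set required")
  if (nspec(test) == 0) stop("empty test set")
  proba <- predict_proba(model, test)
  pred <- predict_label(proba)
  y <- test$labels
  m <- confusion_metrics(tp = sum(pred == 1 & y == 1),
                         fn = sum(pred == 0 & y == 1),
                         fp = sum(pred == 1 & y == 0),
                         tn = sum(pred == 0 & y == 0))
  structure(c(m, list(per_spectrum_proba = proba,
                      n_rounds = model$n_rounds,
                      loss_curve = model$loss_curve)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report: acc %.3f, sens %.3f, spec %.3f ",
                     "(TP %d FN %d FP %d TN %d)>\n"),
              x$accuracy, x$sensitivity, x$specificity,
              x$confusion["TP"], x$confusion["FN"], x$confusion["FP"],
              x$confusion["TN"]))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' @param set labeled [spectrum_set()].
#' @param band a [band_window()].
#' @param params,seed as in [train_classifier()].
#' @param folds number of folds (default 5).
#' @return list with per-fold reports and mean `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
cross_validate <- function(set, band = bands()$FP, params = list(),
                           seed = 1, folds = 5) {
  y <- set$labels
  if (is.null(y)) stop("labeled spectrum set required")
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  reports <- lapply(seq_len(folds), function(f) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    sub <- function(i) spectrum_set(set$wavenumber,
                                    set$intensity[, i, drop = FALSE],
                                    labels = y[i])
    m <- train_classifier(sub(tr), band, params, seed = seed + f)
    evaluate_classifier(m, sub(te))
  })
  list(folds = reports,
       sensitivity = mean(vapply(reports, `[[`, 0, "sensitivity")),
       specificity = mean(vapply(reports, `[[`, 0, "specificity")),
       accuracy = mean(vapply(reports, `[[`, 0, "accuracy")))
}

#' Per-wavenumber feature importance
#'
#' Gain-based importance of every band wavenumber in a fitted model;
#' wavenumbers never used by any tree get importance 0.
#'
#' @param model a `raman_classifier`.
#' @return an `importance_profile`: data.frame with `wavenumber` and
#'   non-negative `importance`, sorted by wavenumber.
#' @export
importance_profile <- function(model) {
  if (!inherits(model, "raman_classifier")) stop("fitted raman_classifier required")
  imp <- xgboost::xgb.importance(model = model$booster)
  sc <- stats::setNames(rep(0, length(model$wavenumber)),
                        paste0("wn_", model$wavenumber))
  sc[imp$Feature] <- imp$Gain
  structure(data.frame(wavenumber = model$wavenumber,
                       importance = as.numeric(sc)),
            class = c("importance_profile", "data.frame"))
}

#' Compare two feature-importance profiles across instruments
#'
#' Two devices measuring the same tissue should prioritize the same
#' vibrational features even if their axes are slightly offset. Two metrics
#' are computed under a wavenumber tolerance (default +/- 3.5 cm-1):
#' the overlap ratio of the top-`k` features (greedy nearest-neighbor
#' matching: a's top-k are processed in descending importance, each claims
#' its nearest unmatched b top-k feature within tolerance, ties broken
#' toward the lower wavenumber), and the cosine similarity of the two full
#' importance vectors after aligning b onto a's axis (nearest b wavenumber
#' within tolerance, else 0).
#'
#' @param a,b `importance_profile` objects (sorted by wavenumber).
#' @param tolerance matching tolerance in cm-1 (default 3.5).
#' @param k number of top features compared (default 20).
#' @return an `importance_comparison`: list with `overlap_ratio`,
#'   `cosine_similarity`, `tolerance`, `k`, and the matched pairs.
#' @export
compare_importance <- function(a, b, tolerance = 3.5, k = 20) {
  if (k > nrow(a) || k > nrow(b))
    stop("k exceeds profile length")
  top <- function(p) {
    ord <- order(-p$importance, p$wavenumber)
    p[ord[seq_len(k)], , drop = FALSE]
  }
  ta <- top(a); tb <- top(b)
  used <- rep(FALSE, k)
  pairs <- list()
  for (i in seq_len(k)) {
    dists <- abs(tb$wavenumber - ta$wavenumber[i])
    dists[used] <- Inf
    j <- which(dists <= tolerance)
    if (length(j)) {
      j <- j[order(dists[j], tb$wavenumber[j])][1]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        c(a_wn = ta$wavenumber[i], b_wn = tb$wavenumber[j])
    }
  }
  overlap <- length(pairs) / k
  # align b's full profile onto a's axis for the cosine
  b_aligned <- vapply(a$wavenumber, function(wn) {
    d <- abs(b$wavenumber - wn)
    j <- which.min(d)
    if (d[j] <= tolerance) b$importance[j] else 0
  }, numeric(1))
  na <- sqrt(sum(a$importance^2)); nb <- sqrt(sum(b_aligned^2))
  cosine <- if (na == 0 || nb == 0) 0 else
    sum(a$importance * b_aligned) / (na * nb)
  structure(list(overlap_ratio = overlap, cosine_similarity = cosine,
                 tolerance = tolerance, k = k,
                 pairs = do.call(rbind, pairs)),
            class = "importance_comparison")
}
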