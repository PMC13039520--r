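test_that("a separable problem is learned perfectly and deterministically", {
  set <- separable_set(n_per_class = 25, seed = 1)
  m <- train_classifier(set, bands()$FP, seed = 3)
  rep <- evaluate_classifier(m, set)
  expect_equal(rep$accuracy, 1.0)
  m2 <- train_classifier(set, bands()$FP, seed = 3)
  expect_identical(predict_proba(m, set), predict_proba(m2, set))
  # training log-loss is non-increasing over boosting rounds
  ll <- m$loss_curve$train_logloss
  expect_true(all(diff(ll) <= 1e-12))
  expect_error(train_classifier(spectrum_set(set$wavenumber, set$intensity,
                                             labels = rep(0L, nspec(set))),
                                bands()$FP), "both classes")
})

test_that("probability dichotomization assigns 0.5 to brain", {
  expect_equal(predict_label(0.6), 1L)
  expect_equal(predict_label(0.5), 0L)
  expect_equal(predict_label(0.0), 0L)
  expect_equal(predict_label(c(0.49, 0.51)), c(0L, 1L))
  expect_error(predict_label(1.2), "outside")
})

test_that("confusion metrics are exact functions of the counts", {
  m <- confusion_metrics(tp = 9, fn = 1, fp = 2, tn = 8)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  p <- confusion_metrics(10, 0, 0, 10)
  expect_equal(c(p$sensitivity, p$specificity, p$accuracy), c(1, 1, 1))
})

test_that("feature importance concentrates on the informative wavenumber", {
  set <- separable_set(n_per_class = 30, seed = 2, sep_wn = 1200)
  m <- train_classifier(set, bands()$FP, seed = 1)
  prof <- importance_profile(m)
  expect_true(all(prof$importance >= 0))
  expect_gt(sum(prof$importance), 0)
  expect_equal(prof$wavenumber[which.max(prof$importance)], 1200)
  expect_identical(importance_profile(m), prof)
  expect_error(importance_profile(list()), "raman_classifier")
})

test_that("importance comparison metrics behave at the extremes", {
  prof <- structure(data.frame(wavenumber = seq(800, 1800, 10),
                               importance = c(rep(0, 80), runif(21))),
                    class = c("importance_profile", "data.frame"))
  same <- compare_importance(prof, prof, k = 10)
  expect_equal(same$overlap_ratio, 1.0)
  expect_equal(same$cosine_similarity, 1.0)
  shifted <- prof
  shifted$wavenumber <- prof$wavenumber + 5  # every pair beyond 3.5 cm-1
  disp <- compare_importance(prof, shifted, k = 10)
  expect_equal(disp$overlap_ratio, 0)
  expect_error(compare_importance(prof, prof, k = 200), "exceeds")
})

test_that("greedy top-k matching agrees with the exhaustive-matching oracle", {
  mk <- function(wn, imp) structure(
    data.frame(wavenumber = wn, importance = imp),
    class = c("importance_profile", "data.frame"))
  # k = 4; exactly one pair within 3 cm-1, the rest displaced far
  a <- mk(c(1000, 1100, 1200, 1300), c(0.4, 0.3, 0.2, 0.1))
  b <- mk(c(1002, 1150, 1250, 1350), c(0.4, 0.3, 0.2, 0.1))
  got <- compare_importance(a, b, tolerance = 3.5, k = 4)
  # oracle: maximum bipartite matching by brute force over permutations
  brute <- function(awn, bwn, tol) {
    best <- 0
    for (perm in combinat_perms(length(bwn)))
      best <- max(best, sum(abs(awn - bwn[perm]) <= tol))
    best
  }
  expect_equal(got$overlap_ratio, brute(a$wavenumber, b$wavenumber, 3.5) / 4)
  # a denser case where greedy still attains the maximum matching
  a2 <- mk(c(1000, 1003, 1100, 1200), c(0.4, 0.3, 0.2, 0.1))
  b2 <- mk(c(1001, 1004, 1102, 1300), c(0.1, 0.2, 0.3, 0.4))
  got2 <- compare_importance(a2, b2, tolerance = 3.5, k = 4)
  expect_equal(got2$overlap_ratio,
               brute(a2$wavenumber, b2$wavenumber, 3.5) / 4)
  # overlap is symmetric in its arguments for these profiles
  expect_equal(compare_importance(b2, a2, tolerance = 3.5, k = 4)$overlap_ratio,
               got2$overlap_ratio)
})

test_that("shuffled labels drop test accuracy to chance", {
  train <- make_dataset(60, icg_amp = 0, noise_sd = 0.05, seed = 31)
  test <- make_dataset(40, icg_amp = 0, noise_sd = 0.05, seed = 32)
  set.seed(33)
  shuffled <- spectrum_set(train$wavenumber, train$intensity,
                           labels = sample(train$labels))
  m <- train_classifier(condition(shuffled), bands()$FP, seed = 33)
  rep <- evaluate_classifier(m, condition(test))
  # binomial 99.9% band around 0.5 at n = 80
  expect_lt(abs(rep$accuracy - 0.5), 3.3 * sqrt(0.25 / 80))
})

test_that("test accuracy does not increase as class contrast vanishes", {
  accs <- vapply(c(1, 0.25, 0), function(ct) {
    train <- make_dataset(80, icg_amp = 0, noise_sd = 0.05, seed = 41,
                          contrast = ct)
    test <- make_dataset(50, icg_amp = 0, noise_sd = 0.05, seed = 42,
                         contrast = ct)
    m <- train_classifier(condition(train), bands()$FP, seed = 41)
    evaluate_classifier(m, condition(test))$accuracy
  }, numeric(1))
  expect_gte(accs[1], accs[2] - 0.03)
  expect_gte(accs[2], accs[3] - 0.03)
  expect_lt(accs[3], 0.65)  # chance regime at zero contrast
  expect_gt(accs[1], 0.95)  # near-perfect at full contrast
})

test_that("validation metrics plateau after about 20 boosting rounds", {
  train <- make_dataset(150, icg_amp = 0, noise_sd = 0.05, seed = 51)
  m <- train_classifier(condition(train), bands()$FP, seed = 51,
                        params = list(nrounds = 40,
                                      early_stopping_rounds = 40))
  ll <- m$loss_curve$validation_logloss
  late <- ll[21:length(ll)]
  # steady state: per-round drift below 0.01 log-loss units after round 20
  expect_lt(max(abs(diff(late))), 0.01)
})

test_that("stratified cross-validation reports mean metrics", {
  set <- separable_set(n_per_class = 25, seed = 9)
  cv <- cross_validate(set, bands()$FP, seed = 2, folds = 3)
  expect_length(cv$folds, 3)
  expect_equal(cv$accuracy, mean(vapply(cv$folds, `[[`, 0, "accuracy")))
  expect_gt(cv$accuracy, 0.9)
})
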