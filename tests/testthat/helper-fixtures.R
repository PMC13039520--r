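# shared fixtures, built in code at test time

# correct + condition every spectrum of a set (the per-spectrum pipeline
# ahead of classification)
prep_set <- function(set, epls = epls_config(), prep = prep_config()) {
  ints <- apply(set$intensity, 2, function(y)
    condition(epls_correct(spectrum(set$wavenumber, y), epls)$corrected,
              prep)$intensity)
  spectrum_set(set$wavenumber, ints, labels = set$labels, group = set$group)
}

# tiny linearly separable two-class set: classes differ in one band feature
separable_set <- function(n_per_class = 20, seed = 1, sep_wn = 1000,
                          axis = seq(800, 1800, by = 10)) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n_per_class)
  ints <- sapply(labels, function(cl) {
    y <- stats::rnorm(length(axis), 0.5, 0.02)
    y[which.min(abs(axis - sep_wn))] <- if (cl == 0) 0.2 else 0.8
    y
  })
  spectrum_set(axis, ints, labels = labels)
}

# small phantom for fast spatial tests
small_phantom <- function(seed = 1, halo_width = 3, icg_amp = 1) {
  make_phantom(shape = c(32, 32), tumor_radius = 9, halo_width = halo_width,
               margin_px = 2, icg_amp = icg_amp, seed = seed,
               spectrum_step = 2)
}

# all permutations of seq_len(n) (tiny n; brute-force oracle helper)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# classifier trained on generator data after the standard pipeline
trained_model <- function(n_per_class = 100, band = bands()$FP, seed = 7,
                          icg_amp = 1) {
  train <- make_dataset(n_per_class, icg_amp = icg_amp, seed = seed)
  train_classifier(prep_set(train), band = band, seed = seed)
}
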