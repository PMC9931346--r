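# Small shared configurations for fast tests.

quick_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_patients = 30L, n_stays = 30L, K_true = 4L,
               noise_sd = 0.1, missing_rate = 0.2, outlier_rate = 0.01)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# tiny event frame builder
ev <- function(stay_id, time_hours, variable, value) {
  data.frame(stay_id = stay_id, time_hours = time_hours,
             variable = variable, value = value, stringsAsFactors = FALSE)
}

# brute-force per-variable inertia sums, written independently of the
# package implementation
brute_inertia <- function(X, labels) {
  ks <- sort(unique(labels))
  g <- colMeans(X)
  Tj <- Bj <- Wj <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    for (i in seq_len(nrow(X))) Tj[j] <- Tj[j] + (X[i, j] - g[j])^2
    for (k in ks) {
      idx <- which(labels == k)
      gk <- mean(X[idx, j])
      Bj[j] <- Bj[j] + length(idx) * (gk - g[j])^2
      for (i in idx) Wj[j] <- Wj[j] + (X[i, j] - gk)^2
    }
  }
  list(T = Tj, B = Bj, W = Wj)
}
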