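# shared fixture builders; everything is generated in code at test time

# a small deterministic epoch of random average-referenced data
random_epoch <- function(C = 4, Tn = 200, fs = 100, seed = 1) {
  set.seed(seed)
  eeg_epoch(matrix(rnorm(C * Tn), C, Tn), fs = fs)
}

# sinusoid epoch: one row per frequency (Hz); a single frequency gets a
# negated second row so the container's >= 2 channel contract holds
sine_epoch <- function(freqs, fs, dur_s, amp = 1) {
  t <- seq_len(round(fs * dur_s)) / fs
  m <- t(sapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  if (length(freqs) == 1L) m <- rbind(m, -m)
  eeg_epoch(m, channels = paste0("ch", seq_len(nrow(m))), fs = fs)
}

# independent oracle for the global dissimilarity (direct formula)
gd_oracle <- function(u, v) {
  u <- u - mean(u); v <- v - mean(v)
  gu <- sqrt(sum(u^2) / length(u)); gv <- sqrt(sum(v^2) / length(v))
  sqrt(mean((u / gu - v / gv)^2))
}

# independent oracle for GFP (direct term-by-term summation)
gfp_oracle <- function(v) {
  vbar <- mean(v)
  sqrt(sum((v - vbar)^2) / length(v))
}

# exhaustive sign-agnostic 2-partition optimum of the clustering objective:
# for every bipartition, the best templates are the dominant eigenvectors,
# so the objective is the sum of top eigenvalues over clusters
enumerate_k2_objective <- function(maps) {
  maps <- maps - rowMeans(maps)
  n <- nrow(maps)
  total <- sum(maps^2)
  best <- -Inf
  for (code in 1:(2^(n - 1) - 1)) {       # fix map 1 in cluster 1
    grp <- as.integer(intToBits(code))[seq_len(n)] + 1L
    if (length(unique(grp)) < 2L) next
    obj <- 0
    for (g in 1:2) {
      m <- maps[grp == g, , drop = FALSE]
      obj <- obj + eigen(crossprod(m), symmetric = TRUE,
                         only.values = TRUE)$values[1L]
    }
    if (obj > best) best <- obj
  }
  best / total
}

# small planted cohort used across recovery tests
small_cohort <- function(n_subjects = 3, snr = 5, epoch_length_s = 30,
                         seed = 11, k = 5,
                         mean_as = 120, mean_qs = 120) {
  tm <- make_templates(k, 19, seed = seed)
  mk <- function(mean_ms) synthetic_truth(
    tm, duration_law = list(name = "lognormal", mean_ms = mean_ms,
                            sd_ms = 40, min_ms = 30),
    snr = snr, n_subjects = n_subjects, epoch_length_s = epoch_length_s,
    seed = seed + 1)
  list(templates = tm, cohort = simulate_cohort(mk(mean_as), mk(mean_qs)))
}
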