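test_that("the default band table lists the five canonical bands", {
  bt <- band_table()
  expect_equal(nrow(bt), 5)
  expect_equal(bt$band, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(bt$median_hz, c(2.25, 6, 10.5, 19, 35))
  expect_true(all(bt$low_hz < bt$high_hz))
})

test_that("band decomposition passes in-band and attenuates out-of-band tones", {
  fs <- 100
  ep <- sine_epoch(2, fs = fs, dur_s = 60)
  bands <- band_decompose(ep)
  expect_length(bands, 5)
  expect_identical(names(bands), band_table()$band)
  mid <- seq(25 * fs, 35 * fs)
  t <- seq_len(n_samples(ep)) / fs
  # delta band keeps a 2 Hz tone within 5%
  expect_lt(max(abs(bands$delta$data[1, mid] - sin(2 * pi * 2 * t[mid]))), 0.05)
  # alpha band (8-13 Hz) attenuates it at least per the analytic high-pass
  # response of one 7th-order pass
  bound <- 1 / sqrt(1 + (8 / 2)^14)
  expect_lt(max(abs(bands$alpha$data[1, mid])), bound)
  # a band reaching Nyquist is rejected
  expect_error(band_decompose(eeg_epoch(matrix(rnorm(200), 2), fs = 60)),
               "Nyquist")
})

test_that("log-log fits recover exact lines and are unit invariant in slope", {
  bt <- band_table()
  y <- exp(-0.9 * log(bt$median_hz) + 2)
  fit <- loglog_fit(setNames(y, bt$band))
  expect_equal(attr(fit, "slope"), -0.9, tolerance = 1e-12)
  expect_equal(attr(fit, "intercept"), 2, tolerance = 1e-12)
  expect_equal(attr(fit, "r_squared"), 1, tolerance = 1e-12)

  # ms -> s rescaling shifts the intercept, not the slope
  fit_s <- loglog_fit(setNames(y / 1000, bt$band))
  expect_equal(attr(fit_s, "slope"), attr(fit, "slope"), tolerance = 1e-12)
  expect_equal(attr(fit_s, "intercept"), attr(fit, "intercept") - log(1000),
               tolerance = 1e-9)

  expect_warning(f2 <- loglog_fit(setNames(c(y[1:4], 0), bt$band)),
                 "non-positive")
  expect_equal(nrow(f2), 4)
  expect_error(suppressWarnings(loglog_fit(setNames(c(1, 2, 0, 0, 0), bt$band))),
               "3 usable")
})

test_that("Welch PSD satisfies Parseval for a pure tone and is flat for white noise", {
  fs <- 100
  ep <- sine_epoch(10, fs = fs, dur_s = 40)
  p <- psd_welch(ep, window_s = 4)
  p1 <- p[p$channel == "ch1", ]
  expect_equal(p1$freq_hz[which.max(p1$psd)], 10)
  df <- diff(p1$freq_hz[1:2])
  expect_equal(sum(p1$psd) * df, 0.5, tolerance = 0.05)   # tone variance

  set.seed(3)
  wn <- eeg_epoch(matrix(rnorm(2 * 8000), 2, 8000), fs = fs)
  pw <- psd_welch(wn, window_s = 2)
  p2 <- pw[pw$channel == "ch1" & pw$freq_hz > 2 & pw$freq_hz < 48, ]
  # white noise of unit variance: density 1/ (fs/2) = 0.02 everywhere
  expect_lt(max(abs(p2$psd - 0.02)) / 0.02, 0.5)
  expect_equal(mean(p2$psd), 0.02, tolerance = 0.05)
})

test_that("synthetic 1/f noise shows the planted log-log spectral slope", {
  set.seed(11)
  x <- neoms:::one_over_f_noise(20000, alpha = 1)
  ep <- eeg_epoch(matrix(c(x, -x), nrow = 2, byrow = TRUE), fs = 100)
  p <- psd_welch(ep, window_s = 10)
  p1 <- p[p$channel == "ch1" & p$freq_hz >= 0.5 & p$freq_hz <= 30, ]
  slope <- coef(lm(log(psd) ~ log(freq_hz), data = p1))[2]
  expect_equal(unname(slope), -1, tolerance = 0.15)
})

test_that("the per-band pipeline reports per-band templates, metrics and GEV", {
  fix <- small_cohort(n_subjects = 2, snr = 8, epoch_length_s = 20, seed = 55,
                      k = 3)
  bt <- band_table()[1:3, ]               # delta, theta, alpha keep runtime low
  bp <- band_pipeline(fix$cohort$epochs, k = 3, bands = bt,
                      n_restarts = 5, seed = 2)
  expect_identical(names(bp$bands), bt$band)
  for (b in bt$band) {
    expect_equal(nrow(bp$bands[[b]]$templates$maps), 3)   # honors configured k
    expect_identical(bp$bands[[b]]$templates$band, b)
  }
  # coverage still sums to 100 within each epoch and band
  sums <- bp$metrics |>
    dplyr::group_by(.data$band, .data$subject_id, .data$state) |>
    dplyr::summarise(s = sum(.data$coverage_pct), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-6))
  expect_true(all(bp$gev$gev >= 0 & bp$gev$gev <= 100))
})

test_that("band content drives band GEV: slow planted dynamics favor delta", {
  tm <- make_templates(3, 19, seed = 23)
  truth <- synthetic_truth(tm,
                           duration_law = list(name = "lognormal", mean_ms = 400,
                                               sd_ms = 100, min_ms = 200),
                           osc_freq = 3, snr = 8, epoch_length_s = 30,
                           n_subjects = 1, seed = 24)
  sim <- simulate_epoch(truth)
  gev_of_band <- function(b) {
    bt <- band_table()[band_table()$band == b, ]
    ep <- bandpass(sim$epoch, filter_spec(bt$low_hz, bt$high_hz))
    backfit_epoch(ep, tm)$gev
  }
  expect_gt(gev_of_band("delta"), gev_of_band("gamma"))
})
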