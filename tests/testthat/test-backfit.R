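test_that("a single-template epoch is labeled entirely with that template", {
  tm <- make_templates(3, 19, seed = 2)
  env <- abs(sin(pi * (1:500) / 50))          # repeating half-sine envelopes
  ep <- eeg_epoch(tcrossprod(tm$maps[2, ], env), channels = tm$channels,
                  fs = 100)
  lab <- backfit(ep, tm)
  expect_true(all(lab$labels == 2L))
  # polarity inversion leaves labels untouched
  ep_neg <- ep; ep_neg$data <- -ep$data
  expect_identical(backfit(ep_neg, tm)$labels, lab$labels)
  # and so does global amplitude rescaling
  ep_sc <- ep; ep_sc$data <- 7.3 * ep$data
  expect_identical(backfit(ep_sc, tm)$labels, lab$labels)
})

test_that("labels spread to the nearest peak with midpoint boundaries", {
  tm <- template_set(rbind(c(1, -1, 0, 0), c(0, 0, 1, -1)))
  # two clean peaks at samples 5 (template A) and 15 (template B)
  d <- matrix(0, 4, 20)
  env <- c(0.2, 0.6, 1, 0.6, 0.2)
  d[, 3:7] <- tcrossprod(c(1, -1, 0, 0), env)
  d[, 13:17] <- tcrossprod(c(0, 0, 1, -1), env)
  d <- d + 1e-3 * matrix(sin(1:80), 4, 20)    # break exact-zero GFP ties
  ep <- eeg_epoch(d, channels = tm$channels, fs = 100)
  lab <- backfit(ep, tm, peaks = c(5L, 15L))
  expect_identical(lab$labels, rep(c(1L, 2L), each = 10))
  seg <- lab$segments
  expect_identical(nrow(seg), 2L)
  expect_true(all(seg$truncated))             # both runs touch an epoch edge
})

test_that("backfit without peaks returns a flagged, unlabeled sequence", {
  tm <- make_templates(2, 4, geometry = "random", seed = 1)
  ep <- eeg_epoch(matrix(1e-12, 4, 10), channels = tm$channels, fs = 100)
  lab <- backfit(ep, tm, peaks = integer(0))
  expect_true(lab$no_peaks)
  expect_true(all(is.na(lab$labels)))
})

test_that("GEV is 100% for a noiseless single-template epoch and 0% for orthogonal maps", {
  tm <- make_templates(3, 19, seed = 4)
  env <- abs(sin(pi * (1:400) / 40))
  ep <- eeg_epoch(tcrossprod(tm$maps[1, ], env), channels = tm$channels, fs = 100)
  lab <- backfit(ep, tm)
  expect_equal(gev(ep, tm, lab)$gev, 100, tolerance = 1e-9)

  # force-label with an orthogonal template: explained variance collapses
  base <- qr.Q(qr(cbind(tm$maps[1, ], rnorm(19))))
  ortho <- base[, 2] - mean(base[, 2])
  ortho <- ortho - tm$maps[1, ] * sum(ortho * tm$maps[1, ]) / sum(tm$maps[1, ]^2)
  tm2 <- template_set(rbind(ortho, rnorm(19)), channels = tm$channels)
  lab2 <- lab; lab2$template_labels <- tm2$labels
  expect_lt(gev(ep, tm2, lab2)$gev, 1e-9)
})

test_that("GEV matches the direct-summation oracle on random data", {
  set.seed(8)
  tm <- make_templates(3, 6, geometry = "random", seed = 3)
  ep <- eeg_epoch(matrix(rnorm(6 * 60), 6, 60), channels = tm$channels, fs = 100)
  ep <- rereference_common_average(ep)
  lab <- backfit(ep, tm)
  got <- gev(ep, tm, lab, domain = "all_samples")

  g <- gfp(ep)
  num <- 0
  for (t in seq_len(60)) {
    r <- cor(ep$data[, t], tm$maps[lab$labels[t], ])
    num <- num + (g[t] * r)^2
  }
  expect_equal(got$gev, 100 * num / sum(g^2), tolerance = 1e-9)
  expect_equal(sum(got$per_template), got$gev, tolerance = 1e-12)
})

test_that("metrics reproduce the hand-computed three-segment example", {
  # A(300 ms) B(200 ms) A(500 ms) at 100 Hz
  labels <- rep(c(1L, 2L, 1L), c(30, 20, 50))
  lab <- neoms:::new_ms_labels(labels, 100, c("A", "B"))
  m <- ms_metrics(lab, exclude_truncated = FALSE)
  expect_equal(m$duration_ms, c(400, 200))
  expect_equal(m$coverage_pct, c(80, 20))
  expect_equal(m$occurrence_hz, c(2, 1))
  expect_equal(sum(m$coverage_pct), 100)
})

test_that("boundary-truncated runs are excluded from duration but not occurrence", {
  labels <- rep(1L, 1000)                      # 10 s of constant A at 100 Hz
  lab <- neoms:::new_ms_labels(labels, 100, c("A", "B"))
  m <- ms_metrics(lab)                         # truncation rule on
  expect_true(is.na(m$duration_ms[1]))         # single clipped run
  expect_equal(m$occurrence_hz[1], 0.1)
  expect_equal(m$coverage_pct[1], 100)
  m2 <- ms_metrics(lab, exclude_truncated = FALSE)
  expect_equal(m2$duration_ms[1], 10000)
  # absent template: occurrence and coverage 0, duration missing
  expect_true(is.na(m$duration_ms[2]))
  expect_equal(m$occurrence_hz[2], 0)
  expect_equal(m$coverage_pct[2], 0)
})

test_that("occurrence x duration conservation holds for random label sequences", {
  set.seed(33)
  for (i in 1:20) {
    labels <- sample.int(4, 300, replace = TRUE)
    lab <- neoms:::new_ms_labels(labels, 100, LETTERS[1:4])
    m <- ms_metrics(lab, exclude_truncated = FALSE)
    lhs <- sum(m$occurrence_hz * m$duration_ms, na.rm = TRUE)
    expect_equal(lhs, 1000, tolerance = 1e-6)  # fully labeled: 1000 ms/s
    expect_equal(sum(m$coverage_pct), 100, tolerance = 1e-6)
  }
})

test_that("peak-level backfit recovers planted labels on a noisy cohort", {
  cohort <- small_cohort(n_subjects = 2, snr = 5, epoch_length_s = 30, seed = 61)
  tm <- cohort$templates
  acc <- vapply(seq_along(cohort$cohort$epochs), function(i) {
    ep <- cohort$cohort$epochs[[i]]
    truth_lab <- cohort$cohort$true_labels[[i]]
    pk <- find_gfp_peaks(gfp(ep), fs = ep$fs, min_separation_ms = 10)
    lab <- backfit(ep, tm, peaks = pk)
    mean(lab$labels[pk] == truth_lab[pk])
  }, 0)
  expect_gte(mean(acc), 0.9)
})
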