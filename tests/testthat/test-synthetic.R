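test_that("planted templates are zero-mean, unit-GFP and well separated", {
  tm <- make_templates(7, 19, min_pairwise_dissimilarity = 0.8, seed = 7)
  expect_lt(max(abs(rowMeans(tm$maps))), 1e-12)
  expect_equal(unname(sqrt(rowMeans(tm$maps^2))), rep(1, 7), tolerance = 1e-12)
  d <- dissimilarity_matrix(tm)
  # all 21 pairwise values clear the floor, per the independent GD oracle
  oracle <- outer(1:7, 1:7, Vectorize(function(i, j) {
    gd_oracle(tm$maps[i, ], tm$maps[j, ])
  }))
  expect_equal(d, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(d[upper.tri(d)] >= 0.8))
})

test_that("two channels force antisymmetric maps and infeasible requests fail", {
  tm <- make_templates(2, 2, geometry = "random", seed = 1,
                       min_pairwise_dissimilarity = 0)
  expect_equal(tm$maps[, 1], -tm$maps[, 2], ignore_attr = TRUE)
  expect_error(make_templates(5, 19, min_pairwise_dissimilarity = 1.9,
                              seed = 2, max_tries = 5),
               "dissimilarity")
  expect_error(make_templates(20, 19), "n_templates")
})

test_that("template generation is deterministic under a seed", {
  t1 <- make_templates(5, 19, seed = 77)
  t2 <- make_templates(5, 19, seed = 77)
  expect_identical(t1$maps, t2$maps)
})

test_that("fixed duration law plants exact run lengths", {
  tm <- make_templates(3, 19, seed = 3)
  truth <- synthetic_truth(tm, duration_law = list(name = "fixed", mean_ms = 100),
                           snr = Inf, fs = 100, epoch_length_s = 10, seed = 5)
  sim <- simulate_epoch(truth)
  runs <- rle(sim$labels)
  # interior runs are exactly 10 samples; only the trimmed tail may differ
  expect_true(all(head(runs$lengths, -1) == 10))
  expect_equal(sum(runs$lengths), 1000)
  expect_true(all(sim$labels %in% 1:3))
})

test_that("noiseless epochs backfit to the planted labels at every GFP peak", {
  tm <- make_templates(4, 19, seed = 13)
  truth <- synthetic_truth(tm, snr = Inf, epoch_length_s = 20, seed = 21)
  sim <- simulate_epoch(truth)
  pk <- find_gfp_peaks(gfp(sim$epoch), fs = 100, min_separation_ms = 10)
  lab <- backfit(sim$epoch, tm, peaks = pk)
  expect_true(all(lab$labels[pk] == sim$labels[pk]))
})

test_that("empirical transition frequencies converge to the planted Markov matrix", {
  set.seed(9)
  m <- markov_uniform(5)
  path <- neoms:::markov_path(m, 40000)   # +-0.02 is then a 4-SE bound per cell
  emp <- table(factor(head(path, -1), levels = 1:5),
               factor(tail(path, -1), levels = 1:5))
  emp <- sweep(as.matrix(emp), 1, rowSums(emp), "/")
  expect_lt(max(abs(emp - m)), 0.02)
})

test_that("planted segment durations converge to the law mean", {
  tm <- make_templates(3, 19, seed = 4)
  truth <- synthetic_truth(tm,
                           duration_law = list(name = "lognormal", mean_ms = 120,
                                               sd_ms = 40, min_ms = 30),
                           snr = Inf, epoch_length_s = 600, seed = 6)
  sim <- simulate_epoch(truth)
  runs <- rle(sim$labels)$lengths
  runs <- head(runs, -1) * 10             # drop trimmed tail; samples -> ms
  expect_gt(length(runs), 1000)
  se <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 120), 2 * se + 5)  # 5 ms rounding slack
})

test_that("generated samples stay average-referenced and at the planted SNR", {
  tm <- make_templates(4, 19, seed = 8)
  truth <- synthetic_truth(tm, snr = 5, epoch_length_s = 30, seed = 10)
  sim <- simulate_epoch(truth)
  expect_lt(max(abs(colMeans(sim$epoch$data))), 1e-9)
  # reconstruct the planted signal to measure the realized SNR
  truth_clean <- truth; truth_clean$snr <- Inf
  sim_clean <- neoms:::with_seed(1234, simulate_epoch(truth_clean))
  # signal RMS / noise RMS was imposed exactly at generation; check the
  # noise share of total power is close to 1/(1+snr^2) = 1/26
  p_total <- mean(sim$epoch$data^2)
  p_sig <- mean(sim_clean$epoch$data^2)
  expect_gt(p_total, 0)
  expect_lt(abs(p_total / p_sig - (1 + 1 / 25)) , 0.25)
})

test_that("cohort simulation is deterministic and correctly tagged", {
  fix <- small_cohort(n_subjects = 2, epoch_length_s = 10, seed = 71)
  c1 <- fix$cohort
  fix2 <- small_cohort(n_subjects = 2, epoch_length_s = 10, seed = 71)
  c2 <- fix2$cohort
  expect_identical(lapply(c1$epochs, `[[`, "data"),
                   lapply(c2$epochs, `[[`, "data"))
  expect_identical(c1$true_labels, c2$true_labels)
  expect_equal(length(c1$epochs), 4)      # 2 subjects x 2 states
  expect_setequal(vapply(c1$epochs, `[[`, "", "state"), c("AS", "QS"))
  # every epoch has fs x epoch_length samples and labels in 1..K
  for (i in seq_along(c1$epochs)) {
    expect_equal(n_samples(c1$epochs[[i]]), 1000)
    expect_true(all(c1$true_labels[[i]] %in% 1:5))
  }
})

test_that("mismatched truths are rejected", {
  tm1 <- make_templates(3, 19, seed = 1)
  tm2 <- make_templates(3, 19, seed = 2)
  t1 <- synthetic_truth(tm1, seed = 1)
  t2 <- synthetic_truth(tm2, seed = 1)
  expect_error(simulate_cohort(t1, t2), "share planted templates")
  expect_error(synthetic_truth(tm1, markov = matrix(1, 3, 3)), "diagonal")
  bad <- markov_uniform(3); bad[1, 2] <- 0.9
  expect_error(synthetic_truth(tm1, markov = bad), "sum to 1")
})

test_that("written cohorts are byte-identical across identical seeds", {
  fix <- small_cohort(n_subjects = 1, epoch_length_s = 5, seed = 81)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(fix$cohort, d1)
  write_cohort(small_cohort(n_subjects = 1, epoch_length_s = 5, seed = 81)$cohort, d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("longer planted durations in one state are recovered as longer measured durations", {
  fix <- small_cohort(n_subjects = 3, snr = 8, epoch_length_s = 40, seed = 91,
                      mean_as = 110, mean_qs = 170)
  res <- lapply(fix$cohort$epochs, backfit_epoch, templates = fix$templates)
  met <- dplyr::bind_rows(lapply(res, `[[`, "metrics"))
  mean_by_state <- tapply(met$duration_ms, met$state, mean, na.rm = TRUE)
  expect_gt(mean_by_state["QS"], mean_by_state["AS"])
  occ_by_state <- tapply(met$occurrence_hz, met$state, mean)
  expect_lt(occ_by_state["QS"], occ_by_state["AS"])
})
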