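test_that("template_set enforces zero-mean unit-GFP maps", {
  m <- matrix(rnorm(3 * 8), 3, 8) + 5
  ts <- template_set(m)
  expect_equal(rowMeans(ts$maps), c(A = 0, B = 0, C = 0), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(ts$maps^2))), rep(1, 3), tolerance = 1e-12)
  expect_identical(ts$labels, c("A", "B", "C"))
})

test_that("modified k-means recovers orthogonal templates under sign flips", {
  set.seed(3)
  base <- qr.Q(qr(matrix(rnorm(12 * 4), 12, 4)))[, 1:4]   # orthonormal cols
  base <- t(base) - rowMeans(t(base))                     # 4 x 12, centered
  signs <- sample(c(-1, 1), 200, replace = TRUE)
  maps <- base[rep(1:4, each = 50), ] * signs
  fit <- modified_kmeans(maps, 4, n_restarts = 10, seed = 1)
  expect_equal(fit$explained_variance, 1, tolerance = 1e-9)
  mt <- match_templates(fit$templates$maps, base)
  expect_true(all(mt$abs_correlation > 1 - 1e-9))
})

test_that("k = 2 clustering attains the exhaustive sign-agnostic optimum", {
  set.seed(17)
  for (i in 1:50) {
    maps <- matrix(rnorm(8 * 6), 8, 6)
    fit <- modified_kmeans(maps, 2, n_restarts = 100, seed = i)
    oracle <- enumerate_k2_objective(maps)
    expect_equal(fit$explained_variance, oracle, tolerance = 1e-8)
  }
})

test_that("clustering is deterministic under a fixed seed and polarity invariant", {
  set.seed(9)
  maps <- matrix(rnorm(60 * 10), 60, 10)
  f1 <- modified_kmeans(maps, 3, n_restarts = 5, seed = 42)
  f2 <- modified_kmeans(maps, 3, n_restarts = 5, seed = 42)
  expect_identical(f1$templates$maps, f2$templates$maps)

  flip <- sample(c(-1, 1), 60, replace = TRUE)
  f3 <- modified_kmeans(maps * flip, 3, n_restarts = 5, seed = 42)
  agree <- abs(rowSums(f1$templates$maps * f3$templates$maps) /
                 ncol(maps))              # |cos| between matched rows
  expect_equal(unname(agree), rep(1, 3), tolerance = 1e-9)
})

test_that("explained variance is non-decreasing in k on fixed data", {
  set.seed(11)
  maps <- matrix(rnorm(120 * 8), 120, 8)
  ev <- vapply(3:10, function(k) {
    modified_kmeans(maps, k, n_restarts = 20, seed = k)$explained_variance
  }, 0)
  expect_true(all(diff(ev) > -1e-6))
})

test_that("clustering rejects infeasible requests", {
  maps <- matrix(rnorm(3 * 5), 3, 5)
  expect_error(modified_kmeans(maps, 4), "exceeds")
  expect_error(modified_kmeans(matrix(0, 5, 4), 2), "zero GFP")
})

test_that("KL dispersion is non-increasing and selection recovers planted k", {
  cohort <- small_cohort(n_subjects = 1, snr = 10, epoch_length_s = 30,
                         seed = 31, k = 5)
  pm <- peak_maps(cohort$cohort$epochs[[1]])$maps
  kl <- kl_select(pm, 3, 10, rule = "first_max", n_restarts = 10, seed = 8)
  expect_true(all(diff(kl$dispersion) < 1e-6))
  expect_identical(attr(kl, "chosen_k"), 5L)
  expect_true(all(kl$dispersion >= 0))
  # KL defined only at interior candidates
  expect_true(is.na(kl$kl[1]) && is.na(kl$kl[nrow(kl)]))
})

test_that("second-max rule falls back with a warning when only one maximum exists", {
  # two clean planted clusters give a single dominant KL maximum
  set.seed(12)
  base <- matrix(rnorm(2 * 12), 2, 12)
  maps <- base[rep(1:2, each = 40), ] + matrix(rnorm(80 * 12, sd = 0.05), 80)
  expect_warning(kl <- kl_select(maps, 2, 6, rule = "second_max",
                                 n_restarts = 8, seed = 2),
                 "falling back|no local maximum")
})

test_that("two-step clustering equals individual clustering for one subject", {
  cohort <- small_cohort(n_subjects = 1, snr = 8, epoch_length_s = 20,
                         seed = 41, k = 4)
  eps <- cohort$cohort$epochs[1]           # one subject, AS epoch
  two <- two_step_cluster(eps, 4, n_restarts = 10, seed = 3)
  ind <- modified_kmeans(peak_maps(eps[[1]])$maps, 4, n_restarts = 10, seed = 3)
  mt <- match_templates(two$group, ind$templates)
  expect_true(all(mt$abs_correlation > 0.999))
})

test_that("two-step clustering recovers planted templates across subjects", {
  cohort <- small_cohort(n_subjects = 3, snr = 5, epoch_length_s = 30, seed = 51)
  fit <- two_step_cluster(cohort$cohort$epochs, 5, n_restarts = 10, seed = 6)
  mt <- match_templates(fit$group, cohort$templates)
  expect_gte(mean(mt$abs_correlation), 0.95)
  # group templates keep the container invariants
  expect_lt(max(abs(rowMeans(fit$group$maps))), 1e-9)
  expect_equal(unname(sqrt(rowMeans(fit$group$maps^2))), rep(1, 5),
               tolerance = 1e-9)
  # labels ordered by descending share of attracted peak maps
  expect_true(all(diff(fit$peak_counts) <= 0))
})
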