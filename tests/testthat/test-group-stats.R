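# direct sums-of-squares oracle for the two-way within-subject design,
# written independently of the implementation
ss_oracle <- function(d) {
  n <- nlevels(d$subject); a <- nlevels(d$a); b <- nlevels(d$b)
  gm <- mean(d$y)
  cell <- function(...) tapply(d$y, list(...), mean)
  ss <- list(
    A = n * b * sum((cell(d$a) - gm)^2),
    B = n * a * sum((cell(d$b) - gm)^2)
  )
  mab <- cell(d$a, d$b); ma <- cell(d$a); mb <- cell(d$b); ms <- cell(d$subject)
  ss$AB <- n * sum((mab - outer(ma, rep(1, b)) - outer(rep(1, a), mb) + gm)^2)
  mas <- cell(d$a, d$subject)
  ss$AS <- b * sum((mas - outer(ma, rep(1, n)) - outer(rep(1, a), ms) + gm)^2)
  mbs <- cell(d$b, d$subject)
  ss$BS <- a * sum((mbs - outer(mb, rep(1, n)) - outer(rep(1, b), ms) + gm)^2)
  ss$total <- sum((d$y - gm)^2)
  ss$S <- a * b * sum((ms - gm)^2)
  ss$ABS <- ss$total - ss$S - ss$A - ss$B - ss$AB - ss$AS - ss$BS
  ss
}

fixture_2x3 <- function(seed = 1, n = 5, effect_a = 0, effect_b = 0) {
  set.seed(seed)
  d <- expand.grid(subject = factor(seq_len(n)), a = factor(c("AS", "QS")),
                   b = factor(c("A", "B", "C")))
  d$y <- rnorm(nrow(d)) + effect_a * (d$a == "QS") +
    effect_b * as.numeric(d$b) + rep(rnorm(n), 6)
  d
}

test_that("rm_anova_2way matches the direct sums-of-squares oracle", {
  d <- fixture_2x3(seed = 7, effect_a = 0.8, effect_b = 0.4)
  got <- rm_anova_2way(d, "y", "subject", "a", "b")
  ss <- ss_oracle(d)
  f_oracle <- c(
    (ss$A / 1) / (ss$AS / 4),
    (ss$B / 2) / (ss$BS / 8),
    (ss$AB / 2) / (ss$ABS / 8)
  )
  expect_equal(got$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(got$df1, c(1, 2, 2))
  expect_equal(got$df2, c(4, 8, 8))
  eta_oracle <- c(ss$A / (ss$A + ss$AS), ss$B / (ss$B + ss$BS),
                  ss$AB / (ss$AB + ss$ABS))
  expect_equal(got$partial_eta_sq, eta_oracle, tolerance = 1e-10)
})

test_that("rm_anova_2way agrees with aov error strata", {
  d <- fixture_2x3(seed = 3, n = 8, effect_a = 0.5)
  got <- rm_anova_2way(d, "y", "subject", "a", "b")
  fit <- summary(aov(y ~ a * b + Error(subject / (a * b)), data = d))
  f_aov <- c(fit[["Error: subject:a"]][[1]]["a", "F value"],
             fit[["Error: subject:b"]][[1]]["b", "F value"],
             fit[["Error: subject:a:b"]][[1]]["a:b", "F value"])
  expect_equal(got$statistic, unname(f_aov), tolerance = 1e-8)
})

test_that("epsilon behaves: df-1 effects are exempt, corrected = uncorrected at epsilon 1", {
  d <- fixture_2x3(seed = 5)
  got <- rm_anova_2way(d, "y", "subject", "a", "b")
  expect_equal(got$epsilon[1], 1)         # two-level factor: sphericity moot
  expect_true(all(got$epsilon > 0 & got$epsilon <= 1))
  expect_equal(got$df1_gg[1], got$df1[1])
  expect_equal(got$df2_gg[1], got$df2[1])
})

test_that("zero between-condition variance yields F = 0", {
  d <- expand.grid(subject = factor(1:5), a = factor(c("x", "y")),
                   b = factor(c("p", "q")))
  set.seed(2)
  subj_eff <- rnorm(5)
  d$y <- subj_eff[as.integer(d$subject)] +
    rnorm(20, sd = 0.2)[as.integer(interaction(d$subject, d$a, d$b))]
  # force every condition mean per subject equal: y depends on subject only
  d$y <- subj_eff[as.integer(d$subject)]
  expect_error(got <- rm_anova_2way(d, "y", "subject", "a", "b"), NA)
  expect_true(all(got$statistic == 0 | is.nan(got$statistic)))
})

test_that("rm_anova_2way rejects broken designs", {
  d <- fixture_2x3()
  expect_error(rm_anova_2way(d[-1, ], "y", "subject", "a", "b"), "complete")
  d2 <- d; d2$y[1] <- NA
  expect_error(rm_anova_2way(d2, "y", "subject", "a", "b"), "missing")
  expect_error(rm_anova_2way(d[d$subject %in% 1:2, ], "y", "subject", "a", "b"),
               "3 subjects")
})

test_that("paired post-hoc handles identity, multiplication, and capping", {
  d <- expand.grid(subject = factor(1:6), state = c("AS", "QS"),
                   template = c("A", "B"))
  set.seed(8)
  base <- rnorm(6)
  d$value <- rep(base, 4) + (d$state == "QS" & d$template == "A") * 2 +
    rnorm(24, sd = 0.1)
  res <- paired_posthoc(d, "value", "subject", "state", "template")
  expect_equal(res$p_adjusted, pmin(res$p_value * 2, 1))
  expect_true(all(res$p_adjusted >= res$p_value, na.rm = TRUE))

  # identical paired vectors: degenerate, reported as NA
  d$value <- rep(base, 4)
  res2 <- paired_posthoc(d, "value", "subject", "state", "template")
  expect_true(all(is.na(res2$p_value)))
})

test_that("BH adjustment reproduces the hand-worked staircase", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  p <- sort(runif(20))
  expect_true(all(diff(fdr_adjust(p)) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("one-sample t matches the closed form and flags degeneracy", {
  x <- c(0.12, 0.08, 0.11, 0.09, 0.1, 0.13, 0.07, 0.1, 0.12, 0.08)
  got <- one_sample_t(x)
  t_oracle <- mean(x) / (sd(x) / sqrt(length(x)))
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(t_oracle), 9), tolerance = 1e-12)

  sym <- c(-2, -1, 1, 2)
  got_sym <- one_sample_t(sym)
  expect_equal(got_sym$t, 0)
  expect_equal(got_sym$p_value, 1)

  expect_true(one_sample_t(rep(0.5, 5))$degenerate)
})
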