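#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Both factors are within-subject (e.g. sleep state and microstate
#' template). Sums of squares are computed by direct decomposition, each
#' effect tested against its own effect-by-subject interaction. Sphericity
#' is handled with the Greenhouse-Geisser epsilon estimated from the
#' covariance of orthonormally contrasted cell scores; effects with a
#' single numerator df have epsilon 1 (sphericity does not arise). Partial
#' eta squared is \eqn{SS_{effect} / (SS_{effect} + SS_{error})}.
#'
#' @param data data frame with one row per subject x cell.
#' @param value,subject,factor_a,factor_b column names (strings).
#' @return An `ms_anova` tibble: one row per effect (`factor_a`, `factor_b`,
#'   interaction) with `df1`, `df2`, `epsilon`, `df1_gg`, `df2_gg`,
#'   `statistic` (F), `p_value`, `partial_eta_sq`.
#' @export
#' @examples
#' d <- expand.grid(subject = 1:6, state = c("AS", "QS"), template = c("A", "B", "C"))
#' d$value <- rnorm(nrow(d)) + (d$state == "QS") * 0.5
#' rm_anova_2way(d, "value", "subject", "state", "template")
rm_anova_2way <- function(data, value = "value", subject = "subject",
                          factor_a = "state", factor_b = "template") {
  df <- data.frame(
    subject = factor(data[[subject]]),
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]]),
    y = as.numeric(data[[value]])
  )
  if (anyNA(df$y)) stop("missing cells in the ANOVA table (no imputation)", call. = FALSE)
  n <- nlevels(df$subject); a <- nlevels(df$a); b <- nlevels(df$b)
  if (n < 3L) stop("repeated-measures ANOVA needs at least 3 subjects", call. = FALSE)
  if (nrow(df) != n * a * b || anyDuplicated(df[c("subject", "a", "b")])) {
    stop("design must be complete and balanced: one value per subject x cell",
         call. = FALSE)
  }

  gm <- mean(df$y)
  m_s <- tapply(df$y, df$subject, mean)
  m_a <- tapply(df$y, df$a, mean)
  m_b <- tapply(df$y, df$b, mean)
  m_ab <- tapply(df$y, list(df$a, df$b), mean)
  m_as <- tapply(df$y, list(df$a, df$subject), mean)
  m_bs <- tapply(df$y, list(df$b, df$subject), mean)

  ss_total <- sum((df$y - gm)^2)
  ss_s <- a * b * sum((m_s - gm)^2)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  ss_as <- b * sum((sweep(sweep(m_as, 1, m_a), 2, m_s) + gm)^2)
  ss_bs <- a * sum((sweep(sweep(m_bs, 1, m_b), 2, m_s) + gm)^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs

  # subject x cell matrix (factor A slow, factor B fast) for GG epsilon
  df_o <- df[order(df$subject, df$a, df$b), ]
  Y <- matrix(df_o$y, nrow = n, ncol = a * b, byrow = TRUE)
  S <- stats::cov(Y)
  ortho <- function(k) {
    if (k < 2L) return(matrix(1, 1, 1))
    cm <- stats::contr.helmert(k)
    sweep(cm, 2, sqrt(colSums(cm^2)), "/")
  }
  ones <- function(k) matrix(1 / sqrt(k), k, 1)
  gg_eps <- function(M) {
    d <- ncol(M)
    if (d < 2L) return(1)
    E <- t(M) %*% S %*% M
    (sum(diag(E))^2) / (d * sum(E^2))
  }
  eps <- c(
    gg_eps(kronecker(ortho(a), ones(b))),
    gg_eps(kronecker(ones(a), ortho(b))),
    gg_eps(kronecker(ortho(a), ortho(b)))
  )

  eff <- tibble::tibble(
    effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_as, ss_bs, ss_abs),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    epsilon = eps
  )
  eff$statistic <- (eff$ss / eff$df1) / (eff$ss_error / eff$df2)
  eff$df1_gg <- eff$epsilon * eff$df1
  eff$df2_gg <- eff$epsilon * eff$df2
  eff$p_value <- stats::pf(eff$statistic, eff$df1_gg, eff$df2_gg, lower.tail = FALSE)
  eff$partial_eta_sq <- eff$ss / (eff$ss + eff$ss_error)
  structure(eff[, c("effect", "df1", "df2", "epsilon", "df1_gg", "df2_gg",
                    "statistic", "p_value", "partial_eta_sq")],
            class = c("ms_anova", class(eff)))
}

#' Paired post-hoc t-tests with multiplicity correction
#'
#' Runs a two-sided paired t-test per level of `by` comparing the two levels
#' of `condition`, then adjusts p values across the family (Bonferroni by
#' default, capped at 1; `"fdr"` for Benjamini-Hochberg).
#'
#' @param data data frame with one row per subject x condition x `by` level.
#' @param value,subject,condition,by column names (strings).
#' @param method `"bonferroni"` or `"fdr"`.
#' @return A tibble with one row per `by` level: `contrast`, `estimate`
#'   (mean difference, level 1 minus level 2), `t`, `df`, `p_value`,
#'   `p_adjusted`, `method`. Zero-variance differences yield `NA` tests.
#' @export
paired_posthoc <- function(data, value = "value", subject = "subject",
                           condition = "state", by = "template",
                           method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  lv <- levels(factor(data[[condition]]))
  if (length(lv) != 2L) stop("`condition` must have exactly 2 levels", call. = FALSE)
  rows <- lapply(split(data, data[[by]]), function(d) {
    d1 <- d[d[[condition]] == lv[1L], ]
    d2 <- d[d[[condition]] == lv[2L], ]
    d1 <- d1[order(d1[[subject]]), ]; d2 <- d2[order(d2[[subject]]), ]
    diffs <- d1[[value]] - d2[[value]]
    base <- tibble::tibble(contrast = sprintf("%s: %s - %s", d[[by]][1L], lv[1L], lv[2L]),
                           estimate = mean(diffs))
    if (length(diffs) >= 2L && stats::sd(diffs) > 0) {
      tt <- stats::t.test(diffs, mu = 0)
      base$t <- unname(tt$statistic); base$df <- unname(tt$parameter)
      base$p_value <- tt$p.value
    } else {
      base$t <- NA_real_; base$df <- NA_real_; base$p_value <- NA_real_
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value,
                                    method = if (method == "fdr") "BH" else "bonferroni")
  out$method <- method
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin, named wrapper over `p.adjust(method = "BH")` so the correction used
#' throughout the pipeline is explicit and testable in one place.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return Adjusted p values (same length/order).
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' One-sample t-test returning a tidy row
#'
#' @param values numeric vector (n >= 2).
#' @param null null-hypothesis mean.
#' @return One-row tibble: `estimate`, `t`, `df`, `p_value`, `degenerate`
#'   (`TRUE` when the values have zero variance, in which case the test
#'   columns are `NA`).
#' @export
one_sample_t <- function(values, null = 0) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(tibble::tibble(estimate = mean(values), t = NA_real_, df = NA_real_,
                          p_value = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = null)
  tibble::tibble(estimate = mean(values), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 degenerate = FALSE)
}
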