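#' Observed and expected microstate transition statistics
#'
#' Transitions are counted between consecutive segments (maximal runs) of
#' the label sequence, so self-transitions are structurally impossible. The
#' relative occurrence \eqn{P_X} is the share of segments labelled X. The
#' observed transition probability \eqn{P_{X\to Y}} is the share of all
#' transitions going X to Y; under the occurrence-driven null the expected
#' probability is \eqn{P^*_{X\to Y} = P_X P_Y / (1 - P_X)}.
#'
#' @param label_seq an `ms_labels` from [backfit()], or an integer vector of
#'   segment labels (in `1..k`).
#' @param k number of templates (inferred from `ms_labels`).
#' @return A list of class `transition_stats`: `occurrence` (\eqn{P_X}),
#'   `observed` and `expected` (k x k matrices, zero diagonal),
#'   `n_transitions`, `template_labels`.
#' @export
transition_stats <- function(label_seq, k = NULL) {
  if (inherits(label_seq, "ms_labels")) {
    segs <- label_seq$segments$label
    k <- length(label_seq$template_labels)
    tl <- label_seq$template_labels
  } else {
    segs <- as.integer(label_seq)
    if (is.null(k)) k <- max(segs)
    tl <- make_template_labels(k)
  }
  if (length(segs) < 2L) {
    stop("need at least 2 segments to count transitions", call. = FALSE)
  }
  p_occ <- tabulate(segs, nbins = k) / length(segs)

  from <- segs[-length(segs)]
  to <- segs[-1L]
  obs <- matrix(0, k, k, dimnames = list(tl, tl))
  counts <- table(factor(from, levels = seq_len(k)),
                  factor(to, levels = seq_len(k)))
  obs[] <- counts / sum(counts)

  expd <- outer(p_occ, p_occ) / (1 - p_occ)   # rows X: P_X P_Y / (1 - P_X)
  diag(expd) <- 0
  dimnames(expd) <- list(tl, tl)

  structure(list(occurrence = stats::setNames(p_occ, tl), observed = obs,
                 expected = expd, n_transitions = length(from),
                 template_labels = tl),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat(sprintf("<transition_stats> %d templates, %d transitions\n",
              length(x$occurrence), x$n_transitions))
  invisible(x)
}

#' Chi-square distance between observed and expected transition probabilities
#'
#' \eqn{D = \sum_{X \ne Y} (P_{X\to Y} - P^*_{X\to Y})^2 / P^*_{X\to Y}},
#' summed over all ordered pairs of distinct templates. Pairs with expected
#' probability 0 and observed 0 are skipped; expected 0 with observed > 0 is
#' an error (the null assigns that transition zero mass).
#'
#' @param observed,expected k x k matrices (diagonals ignored), e.g. from
#'   [transition_stats()], or a `transition_stats` object as `observed`.
#' @return The chi-square distance (a nonnegative scalar).
#' @export
chi_square_distance <- function(observed, expected = NULL) {
  if (inherits(observed, "transition_stats")) {
    expected <- observed$expected
    observed <- observed$observed
  }
  observed <- as.matrix(observed); expected <- as.matrix(expected)
  off <- row(observed) != col(observed)
  o <- observed[off]; e <- expected[off]
  if (any(e == 0 & o > 0)) {
    stop("observed transition with zero expected probability", call. = FALSE)
  }
  use <- e > 0
  sum((o[use] - e[use])^2 / e[use])
}

#' Randomization test for microstate syntax structure
#'
#' Tests whether group-mean observed transition probabilities differ from
#' the occurrence-driven expectation. The effect size is the chi-square
#' distance between the across-epoch mean observed and mean expected
#' matrices. Each randomization swaps, independently per epoch with
#' probability 1/2, the observed/expected labels, and recomputes the
#' distance; the p value is the share of random distances exceeding the
#' observed one (strictly, by default; `conservative = TRUE` uses
#' (r + 1) / (n + 1)).
#'
#' @param stats_list list of `transition_stats`, one per epoch.
#' @param n_reps number of randomizations.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param conservative use the (r + 1)/(n + 1) p-value variant.
#' @return A list of class `syntax_test`: `distance`, `p_value`, `n_reps`,
#'   `null_distances`.
#' @export
syntax_randomization_test <- function(stats_list, n_reps = 5000, seed = NULL,
                                      conservative = FALSE) {
  stopifnot(length(stats_list) >= 2L)
  if (n_reps < 100L) warning("fewer than 100 randomizations; p value will be coarse")
  obs_arr <- simplify2array(lapply(stats_list, `[[`, "observed"))
  exp_arr <- simplify2array(lapply(stats_list, `[[`, "expected"))
  n_ep <- length(stats_list)

  mean_obs <- apply(obs_arr, c(1, 2), mean)
  mean_exp <- apply(exp_arr, c(1, 2), mean)
  d_obs <- chi_square_distance(mean_obs, mean_exp)
  if (!is.finite(d_obs)) stop("non-finite observed chi-square distance", call. = FALSE)

  # vectorized over randomizations: flatten the k x k matrices to columns
  # and realize every epoch-swap pattern with one matrix product
  k <- nrow(mean_obs)
  O <- matrix(obs_arr, k * k, n_ep)
  E <- matrix(exp_arr, k * k, n_ep)
  off <- as.vector(row(mean_obs) != col(mean_obs))
  null_d <- with_seed(seed, {
    M <- matrix(stats::runif(n_ep * n_reps) < 0.5, n_ep, n_reps)
    mo <- (O %*% (1 - M) + E %*% M) / n_ep
    me <- (O %*% M + E %*% (1 - M)) / n_ep
    vapply(seq_len(n_reps), function(r) {
      o <- mo[off, r]; e <- me[off, r]
      use <- e > 0
      # a randomized "observed" transition with zero expected mass makes
      # the distance infinite; it counts as an exceedance (conservative)
      if (any(!use & o > 0)) return(Inf)
      sum((o[use] - e[use])^2 / e[use])
    }, 0)
  })

  # ties count as exceedances: on degenerate data (observed identical to
  # expected in every epoch) every randomized distance ties the observed
  # zero and the test must report no structure, not p = 0
  p <- if (conservative) (sum(null_d >= d_obs) + 1) / (n_reps + 1) else
    mean(null_d >= d_obs)
  structure(list(distance = d_obs, p_value = p, n_reps = n_reps,
                 null_distances = null_d),
            class = "syntax_test")
}

#' @export
print.syntax_test <- function(x, ...) {
  cat(sprintf("<syntax_test> chi-square distance D = %.4g, p = %.4g (%d reps)\n",
              x$distance, x$p_value, x$n_reps))
  invisible(x)
}

#' Directional predominance of microstate transitions
#'
#' For every unordered template pair \{X, Y\} (X before Y in label order)
#' and every epoch, the predominance is the difference between the observed
#' probabilities of the forward and reverse transitions,
#' \eqn{P_{X\to Y} - P_{Y\to X}}; it is antisymmetric in the pair. Across
#' epochs, each pair is tested against 0 with a two-sided one-sample t-test
#' and Benjamini-Hochberg FDR correction over the k(k-1)/2 pairs.
#'
#' @param stats_list list of `transition_stats`, one per epoch.
#' @param alpha significance level applied to the adjusted p values.
#' @return A tibble with one row per pair: `from`, `to`, `predominance`
#'   (mean across epochs), `t`, `df`, `p_value`, `p_adjusted`,
#'   `significant`; pairs with zero variance get `NA` test columns.
#' @export
directional_predominance <- function(stats_list, alpha = 0.05) {
  stopifnot(length(stats_list) >= 2L)
  tl <- stats_list[[1L]]$template_labels
  k <- length(tl)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- pairs[i, 1L]; y <- pairs[i, 2L]
    d <- vapply(stats_list, function(s) s$observed[x, y] - s$observed[y, x], 0)
    if (stats::sd(d) > 0) {
      tt <- stats::t.test(d, mu = 0)
      tibble::tibble(from = tl[x], to = tl[y], predominance = mean(d),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value)
    } else {
      tibble::tibble(from = tl[x], to = tl[y], predominance = mean(d),
                     t = NA_real_, df = NA_real_, p_value = NA_real_)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}
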