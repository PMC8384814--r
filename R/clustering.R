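#' Microstate template set
#'
#' An ordered set of K microstate template maps. Each map is average
#' referenced (zero mean across channels) and scaled to unit GFP; polarity
#' carries no meaning anywhere in the pipeline.
#'
#' @param maps K x C numeric matrix of template maps.
#' @param channels channel names (length C).
#' @param labels template labels; defaults to `"A"`, `"B"`, ... in row order.
#' @param level `"individual"` or `"group"`.
#' @param band frequency-band tag.
#' @param gev global explained variance (percent), if known.
#' @return A `template_set`.
#' @export
template_set <- function(maps, channels = colnames(maps), labels = NULL,
                         level = c("individual", "group"), band = "broad",
                         gev = NA_real_) {
  maps <- as.matrix(maps)
  level <- match.arg(level)
  if (nrow(maps) < 2L) stop("a template set needs K >= 2 maps", call. = FALSE)
  maps <- center_rows(maps)
  g <- sqrt(rowMeans(maps^2))
  if (any(g <= 0)) stop("template maps must have nonzero GFP", call. = FALSE)
  maps <- maps / g
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(maps)))
  if (is.null(labels)) labels <- make_template_labels(nrow(maps))
  dimnames(maps) <- list(labels, channels)
  structure(list(maps = maps, labels = labels, channels = channels,
                 level = level, band = band, gev = gev),
            class = "template_set")
}

make_template_labels <- function(k) {
  if (k <= 26L) LETTERS[seq_len(k)] else paste0("T", seq_len(k))
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d templates x %d channels (%s level, %s band)\n",
              nrow(x$maps), ncol(x$maps), x$level, x$band))
  if (!is.na(x$gev)) cat(sprintf("  GEV: %.2f%%\n", x$gev))
  invisible(x)
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' Clusters scalp maps into `k` classes ignoring polarity: a map belongs to
#' the template with the largest squared spatial correlation, and each
#' template is updated as the dominant eigenvector of the outer-product sum
#' of its assigned maps (the closed-form maximizer of the summed squared
#' correlations). The best of `n_restarts` random initializations by
#' explained variance is returned.
#'
#' @param maps n x C matrix of maps (rows are observations, e.g. GFP-peak
#'   topographies). Rows are re-centered to average reference.
#' @param k number of clusters (2 <= k <= n).
#' @param n_restarts random restarts.
#' @param max_iter iteration cap per restart.
#' @param tol convergence tolerance on the relative change in explained
#'   variance.
#' @param seed integer seed for reproducible initialization; `NULL` uses the
#'   current RNG stream.
#' @param polish run a Hartigan-style exact single-map exchange pass after
#'   convergence (each candidate move scored by the true objective via the
#'   cluster scatter eigenvalues). Escapes Lloyd fixed points whose basin
#'   random restarts cannot reach; on by default for small problems
#'   (`n <= 64`), where its cost is negligible.
#' @return A list with `templates` ([template_set()]), `assignment` (cluster
#'   index per map), `correlation` (signed spatial correlation of each map
#'   with its template), and `explained_variance` (GFP-weighted, in
#'   \[0, 1\]).
#' @export
modified_kmeans <- function(maps, k, n_restarts = 20, max_iter = 300,
                            tol = 1e-6, seed = NULL,
                            polish = nrow(maps) <= 64) {
  maps <- center_rows(as.matrix(maps))
  n <- nrow(maps)
  if (k > n) stop("k = ", k, " exceeds the number of maps (", n, ")", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  norms <- row_norms(maps)
  if (any(norms <= 0)) stop("maps with zero GFP cannot be clustered", call. = FALSE)
  Xn <- maps / norms                    # unit-norm for correlations
  total_ss <- sum(norms^2)

  # k-means++-style seeding in correlation geometry: each next seed map is
  # drawn with probability proportional to its unexplained variance under
  # the seeds chosen so far
  init_templates <- function() {
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    d2 <- 1 - (Xn %*% Xn[idx[1L], ])^2
    for (j in seq_len(k - 1L)) {
      w <- pmax(as.vector(d2), 0)
      idx[j + 1L] <- if (sum(w) > 0) sample.int(n, 1L, prob = w) else sample.int(n, 1L)
      d2 <- pmin(d2, 1 - (Xn %*% Xn[idx[j + 1L], ])^2)
    }
    Xn[idx, , drop = FALSE]
  }

  run_once <- function() {
    Tm <- init_templates()
    ev_old <- -Inf
    assign_idx <- rep(1L, n)
    for (iter in seq_len(max_iter)) {
      A <- Xn %*% t(Tm)                 # n x k correlations
      A2 <- A^2
      assign_idx <- max.col(A2, ties.method = "first")
      best_r2 <- A2[cbind(seq_len(n), assign_idx)]
      for (j in seq_len(k)) {
        members <- which(assign_idx == j)
        if (length(members) == 0L) {    # re-seed from the worst-fit map
          worst <- which.min(best_r2)
          members <- worst
          assign_idx[worst] <- j
          best_r2[worst] <- 1
        }
        S <- crossprod(maps[members, , drop = FALSE])
        e <- eigen(S, symmetric = TRUE)
        Tm[j, ] <- e$vectors[, 1L]
      }
      A <- Xn %*% t(Tm)
      best_r2 <- A[cbind(seq_len(n), assign_idx)]^2
      ev <- sum(best_r2 * norms^2) / total_ss
      if (is.finite(ev_old) && abs(ev - ev_old) <= tol * max(ev_old, .Machine$double.eps)) break
      ev_old <- ev
    }
    list(Tm = Tm, assignment = assign_idx, ev = ev,
         r = A[cbind(seq_len(n), assign_idx)])
  }

  # exact single-map exchange polish: objective contribution of a cluster
  # is the top eigenvalue of its scatter matrix
  lambda1 <- function(S) {
    if (all(S == 0)) 0 else eigen(S, symmetric = TRUE, only.values = TRUE)$values[1L]
  }
  polish_assignment <- function(assign_idx) {
    S <- lapply(seq_len(k), function(j) {
      crossprod(maps[assign_idx == j, , drop = FALSE])
    })
    lam <- vapply(S, lambda1, 0)
    for (sweep in 1:100) {
      improved <- FALSE
      for (i in seq_len(n)) {
        a <- assign_idx[i]
        if (sum(assign_idx == a) == 1L) next     # keep clusters nonempty
        xx <- tcrossprod(maps[i, ])
        lam_a_out <- lambda1(S[[a]] - xx)
        for (b in seq_len(k)[-a]) {
          lam_b_in <- lambda1(S[[b]] + xx)
          if (lam_a_out + lam_b_in > lam[a] + lam[b] + 1e-12) {
            S[[a]] <- S[[a]] - xx; S[[b]] <- S[[b]] + xx
            lam[a] <- lam_a_out; lam[b] <- lam_b_in
            assign_idx[i] <- b
            improved <- TRUE
            break
          }
        }
      }
      if (!improved) {
        # second-order exchange: swap one map of each of two clusters
        for (i in seq_len(n - 1L)) {
          a <- assign_idx[i]
          xi <- tcrossprod(maps[i, ])
          for (j in seq.int(i + 1L, n)) {
            b <- assign_idx[j]
            if (a == b) next
            xj <- tcrossprod(maps[j, ])
            la <- lambda1(S[[a]] - xi + xj)
            lb <- lambda1(S[[b]] - xj + xi)
            if (la + lb > lam[a] + lam[b] + 1e-12) {
              S[[a]] <- S[[a]] - xi + xj; S[[b]] <- S[[b]] - xj + xi
              lam[a] <- la; lam[b] <- lb
              assign_idx[i] <- b; assign_idx[j] <- a
              improved <- TRUE
              break
            }
          }
          if (improved) break
        }
      }
      if (!improved) break
    }
    assign_idx
  }
  finalize <- function(assign_idx) {
    Tm <- t(vapply(seq_len(k), function(j) {
      eigen(crossprod(maps[assign_idx == j, , drop = FALSE]),
            symmetric = TRUE)$vectors[, 1L]
    }, numeric(ncol(maps))))
    A <- Xn %*% t(Tm)
    r <- A[cbind(seq_len(n), assign_idx)]
    list(Tm = Tm, assignment = assign_idx, r = r,
         ev = sum(r^2 * norms^2) / total_ss)
  }

  best <- with_seed(seed, {
    res <- NULL
    for (s in seq_len(n_restarts)) {
      cand <- run_once()
      if (polish) {                       # polish every basin, not just the best
        pol <- finalize(polish_assignment(cand$assignment))
        if (pol$ev > cand$ev) cand <- pol
      }
      if (is.null(res) || cand$ev > res$ev) res <- cand
    }
    res
  })

  ts <- template_set(best$Tm, channels = colnames(maps), level = "individual")
  list(templates = ts, assignment = best$assignment,
       correlation = best$r, explained_variance = best$ev)
}

#' Krzanowski-Lai selection of the number of templates
#'
#' Runs [modified_kmeans()] for each candidate `k`, forms the within-cluster
#' dispersion \eqn{W(k) = \sum_i (1 - r_i^2)} over maps, and the KL index
#' \eqn{KL(k) = |DIFF(k) / DIFF(k+1)|} with
#' \eqn{DIFF(k) = (k-1)^{2/C} W(k-1) - k^{2/C} W(k)}. The chosen `k` is a
#' local maximum of the KL curve: the first along ascending `k`
#' (`rule = "first_max"`) or the second (`rule = "second_max"`). With fewer
#' than two local maxima the second-max rule falls back to the first with a
#' warning.
#'
#' @inheritParams modified_kmeans
#' @param k_min,k_max candidate range (inclusive).
#' @param rule `"second_max"` or `"first_max"`.
#' @param n_restarts restarts per candidate `k`.
#' @param min_ratio eligibility floor for a local maximum: since
#'   `KL(k)` is the ratio of successive dispersion improvements, values
#'   near 1 mean a featureless improvement profile whose small wiggles are
#'   sampling noise, not elbows; a local maximum must exceed this ratio to
#'   count. Default 2 (the improvement at `k` at least doubles that at
#'   `k + 1`).
#' @return A `kl_curve`: tibble of `k`, `dispersion`, `diff`, `kl` with
#'   attributes `chosen_k` and `rule`.
#' @export
kl_select <- function(maps, k_min = 3, k_max = 15,
                      rule = c("second_max", "first_max"),
                      n_restarts = 20, max_iter = 300, tol = 1e-6,
                      seed = NULL, min_ratio = 2) {
  rule <- match.arg(rule)
  maps <- center_rows(as.matrix(maps))
  C <- ncol(maps)
  if (nrow(maps) < k_max) stop("need at least k_max maps", call. = FALSE)
  # the dispersion grid extends two candidates below k_min so that the KL
  # index and its local maxima are defined across the whole requested range
  ks <- seq.int(max(1L, k_min - 2L), k_max)

  W <- with_seed(seed, vapply(ks, function(k) {
    if (k == 1L) {        # single template: dominant eigenvector fit
      Xn <- maps / row_norms(maps)
      v <- eigen(crossprod(maps), symmetric = TRUE)$vectors[, 1L]
      return(sum(1 - as.vector(Xn %*% v)^2))
    }
    fit <- modified_kmeans(maps, k, n_restarts = n_restarts,
                           max_iter = max_iter, tol = tol, seed = NULL)
    sum(1 - fit$correlation^2)
  }, 0))

  diffs <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-1L]) {
    diffs[i] <- (ks[i] - 1)^(2 / C) * W[i - 1L] - ks[i]^(2 / C) * W[i]
  }
  kl <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    if (i >= 2L && i < length(ks) && is.finite(diffs[i]) && diffs[i + 1L] != 0) {
      kl[i] <- abs(diffs[i] / diffs[i + 1L])
    }
  }

  # a local maximum must beat both neighbours, clear the elbow floor, and
  # lie in the requested range; points whose neighbours are undefined are
  # not eligible
  interior <- which(!is.na(kl))
  is_max <- vapply(interior, function(i) {
    (i - 1L) %in% interior && (i + 1L) %in% interior &&
      kl[i] > kl[i - 1L] && kl[i] > kl[i + 1L] && kl[i] > min_ratio &&
      ks[i] >= k_min
  }, TRUE)
  maxima <- ks[interior[is_max]]

  in_range <- interior[ks[interior] >= k_min]
  chosen <- if (length(maxima) == 0L) {
    warning("KL curve has no local maximum; choosing k at the largest KL value")
    ks[in_range[which.max(kl[in_range])]]
  } else if (rule == "first_max" || length(maxima) == 1L) {
    if (rule == "second_max" && length(maxima) == 1L) {
      warning("fewer than 2 KL local maxima; falling back to the first maximum")
    }
    maxima[1L]
  } else {
    maxima[2L]
  }

  out <- tibble::tibble(k = ks, dispersion = W, diff = diffs, kl = kl)
  structure(out, chosen_k = chosen, rule = rule,
            class = c("kl_curve", class(out)))
}

#' @export
print.kl_curve <- function(x, ...) {
  cat(sprintf("<kl_curve> chosen k = %d (%s rule)\n",
              attr(x, "chosen_k"), attr(x, "rule")))
  NextMethod()
}

#' Two-step clustering: individual then group templates
#'
#' Step 1 clusters each subject's pooled GFP-peak topographies with the
#' polarity-invariant [modified_kmeans()]; step 2 clusters the pooled
#' individual templates with the same algorithm to produce the group
#' template set. Group templates are labelled `A`, `B`, ... in order of
#' descending share of assigned GFP-peak maps (a coverage proxy on the
#' pooled data).
#'
#' @param epochs list of [eeg_epoch()] objects (one or more per subject).
#' @param k number of templates at both steps.
#' @param states which sleep states to include (`NULL` = all, pooled).
#' @param min_separation_ms GFP peak separation passed to [peak_maps()].
#' @inheritParams modified_kmeans
#' @return A list with `group` ([template_set()], level `"group"`),
#'   `individual` (named list of per-subject template sets), and
#'   `peak_counts` (maps assigned per group template).
#' @export
two_step_cluster <- function(epochs, k, states = NULL, min_separation_ms = 10,
                             n_restarts = 20, max_iter = 300, tol = 1e-6,
                             seed = NULL) {
  stopifnot(length(epochs) >= 1L)
  if (!is.null(states)) {
    epochs <- Filter(function(e) e$state %in% states, epochs)
    if (length(epochs) == 0L) stop("no epochs match the requested states", call. = FALSE)
  }
  subjects <- vapply(epochs, function(e) as.character(e$subject_id), "")
  channels <- epochs[[1L]]$channels
  band <- epochs[[1L]]$band

  with_seed(seed, {
    by_subject <- split(epochs, subjects)
    indiv <- lapply(by_subject, function(eps) {
      pm <- do.call(rbind, lapply(eps, function(e) {
        peak_maps(e, min_separation_ms = min_separation_ms)$maps
      }))
      modified_kmeans(pm, k, n_restarts = n_restarts, max_iter = max_iter,
                      tol = tol, seed = NULL)$templates
    })
    pooled_templates <- do.call(rbind, lapply(indiv, function(ts) ts$maps))
    fit <- modified_kmeans(pooled_templates, k, n_restarts = n_restarts,
                           max_iter = max_iter, tol = tol, seed = NULL)

    # order group templates by share of all GFP-peak maps they attract
    all_peaks <- do.call(rbind, lapply(epochs, function(e) {
      peak_maps(e, min_separation_ms = min_separation_ms)$maps
    }))
    r <- spatial_cor_matrix(all_peaks, fit$templates$maps)
    counts <- tabulate(max.col(r^2, ties.method = "first"), nbins = k)
    ord <- order(counts, decreasing = TRUE)
    group <- template_set(fit$templates$maps[ord, , drop = FALSE],
                          channels = channels, level = "group", band = band)
    list(group = group, individual = indiv,
         peak_counts = stats::setNames(counts[ord], group$labels))
  })
}
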