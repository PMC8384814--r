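#' Backfit microstate templates to an epoch
#'
#' Assigns each GFP peak the template with the highest absolute spatial
#' correlation (polarity ignored), then labels every other sample with the
#' label of its nearest peak (boundaries at the midpoint between consecutive
#' peaks; exact ties go to the earlier peak). Samples before the first and
#' after the last peak inherit that peak's label, but those runs are flagged
#' as boundary-truncated, because their true extent is clipped by the epoch
#' edges.
#'
#' @param epoch an [eeg_epoch()].
#' @param templates a [template_set()] sharing the epoch's channel order.
#' @param peaks optional precomputed GFP peak indices; detected via
#'   [find_gfp_peaks()] when `NULL`.
#' @param min_separation_ms passed to peak detection when `peaks` is `NULL`.
#' @return An `ms_labels` object: integer template index per sample (`NA`
#'   when unlabeled), with `fs`, template `labels`, and a `segments` tibble
#'   (`label`, `start`, `length`, `truncated`).
#' @export
backfit <- function(epoch, templates, peaks = NULL, min_separation_ms = 10) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(templates, "template_set"))
  if (!identical(epoch$channels, templates$channels)) {
    stop("epoch and template channel orders differ", call. = FALSE)
  }
  n <- ncol(epoch$data)
  if (is.null(peaks)) {
    peaks <- find_gfp_peaks(gfp(epoch), fs = epoch$fs,
                            min_separation_ms = min_separation_ms)
  }
  if (length(peaks) == 0L) {
    return(new_ms_labels(rep(NA_integer_, n), epoch$fs, templates$labels,
                         no_peaks = TRUE))
  }
  r <- spatial_cor_matrix(t(epoch$data[, peaks, drop = FALSE]), templates$maps)
  peak_lab <- max.col(r^2, ties.method = "first")

  # nearest-peak label spreading; midpoints split runs, ties to earlier peak
  labels <- integer(n)
  bounds <- c(0L, floor((peaks[-length(peaks)] + peaks[-1L]) / 2), n)
  for (i in seq_along(peaks)) {
    labels[(bounds[i] + 1L):bounds[i + 1L]] <- peak_lab[i]
  }
  new_ms_labels(labels, epoch$fs, templates$labels)
}

new_ms_labels <- function(labels, fs, template_labels, no_peaks = FALSE) {
  seg <- label_segments(labels)
  structure(list(labels = labels, fs = fs, template_labels = template_labels,
                 segments = seg, no_peaks = no_peaks),
            class = "ms_labels")
}

# run-length segments of a per-sample label vector (NA = unlabeled)
label_segments <- function(labels) {
  n <- length(labels)
  if (n == 0L || all(is.na(labels))) {
    return(tibble::tibble(label = integer(), start = integer(),
                          length = integer(), truncated = logical()))
  }
  r <- rle(labels)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  seg <- tibble::tibble(label = r$values, start = start, length = r$lengths)
  seg <- seg[!is.na(seg$label), , drop = FALSE]
  seg$truncated <- seg$start == 1L | (seg$start + seg$length - 1L) == n
  seg
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d samples @ %g Hz, %d segments (%d truncated)\n",
              length(x$labels), x$fs, nrow(x$segments), sum(x$segments$truncated)))
  invisible(x)
}

#' Global explained variance of a microstate labeling
#'
#' GEV is the GFP-weighted share of topographic variance captured by the
#' assigned templates:
#' \eqn{GEV = 100 \sum_t (GFP_t r_t)^2 / \sum_t GFP_t^2}, where \eqn{r_t} is
#' the spatial correlation between the sample map at \eqn{t} and its
#' assigned template. Summation runs over the GFP peaks by default
#' (consistent with peak-based fitting) or over all labeled samples.
#'
#' @param epoch an [eeg_epoch()].
#' @param templates a [template_set()].
#' @param label_seq an `ms_labels` from [backfit()].
#' @param domain `"peaks"` or `"all_samples"`.
#' @param peaks peak indices (recomputed when `NULL` and `domain = "peaks"`).
#' @param min_separation_ms passed to peak detection when `peaks` is `NULL`.
#' @return A list: `gev` (percent) and `per_template` (named vector summing
#'   to `gev`).
#' @export
gev <- function(epoch, templates, label_seq, domain = c("peaks", "all_samples"),
                peaks = NULL, min_separation_ms = 10) {
  domain <- match.arg(domain)
  stopifnot(inherits(label_seq, "ms_labels"))
  g <- gfp(epoch)
  if (domain == "peaks") {
    if (is.null(peaks)) {
      peaks <- find_gfp_peaks(g, fs = epoch$fs,
                              min_separation_ms = min_separation_ms)
    }
    idx <- peaks
  } else {
    idx <- seq_along(g)
  }
  idx <- idx[!is.na(label_seq$labels[idx])]
  k <- nrow(templates$maps)
  per <- stats::setNames(rep(0, k), templates$labels)
  if (length(idx) == 0L) return(list(gev = 0, per_template = per))
  lab <- label_seq$labels[idx]
  r <- spatial_cor_matrix(t(epoch$data[, idx, drop = FALSE]), templates$maps)
  r_assigned <- r[cbind(seq_along(idx), lab)]
  num <- (g[idx] * r_assigned)^2
  denom <- sum(g[idx]^2)
  for (j in seq_len(k)) per[j] <- 100 * sum(num[lab == j]) / denom
  list(gev = sum(per), per_template = per)
}

#' Microstate metrics: duration, occurrence, coverage
#'
#' For each template: mean duration (ms) of its runs, occurrence (runs
#' started per labeled second), and coverage (percent of labeled time).
#' Boundary-truncated runs (clipped by the epoch edges) are excluded from
#' the duration average by default, since their true length is unknown; they
#' still count toward occurrence and coverage. A template that never occurs
#' gets duration `NA`, occurrence 0, coverage 0. Coverage sums to 100
#' across templates.
#'
#' @param label_seq an `ms_labels` from [backfit()].
#' @param exclude_truncated drop boundary-truncated runs from the duration
#'   mean (default `TRUE`).
#' @param subject_id,state,band optional tags copied into the output.
#' @return A tibble with one row per template: `template`, `duration_ms`,
#'   `occurrence_hz`, `coverage_pct` (+ any tags).
#' @export
ms_metrics <- function(label_seq, exclude_truncated = TRUE,
                       subject_id = NULL, state = NULL, band = NULL) {
  stopifnot(inherits(label_seq, "ms_labels"))
  seg <- label_seq$segments
  fs <- label_seq$fs
  k <- length(label_seq$template_labels)
  labeled_s <- sum(!is.na(label_seq$labels)) / fs

  rows <- lapply(seq_len(k), function(j) {
    runs <- seg[seg$label == j, , drop = FALSE]
    dur_runs <- if (exclude_truncated) runs[!runs$truncated, , drop = FALSE] else runs
    tibble::tibble(
      template = label_seq$template_labels[j],
      duration_ms = if (nrow(dur_runs)) mean(dur_runs$length) / fs * 1000 else NA_real_,
      occurrence_hz = if (labeled_s > 0) nrow(runs) / labeled_s else 0,
      coverage_pct = if (labeled_s > 0) sum(runs$length) / fs / labeled_s * 100 else 0
    )
  })
  out <- dplyr::bind_rows(rows)
  tags <- tibble::tibble(.rows = nrow(out))
  if (!is.null(subject_id)) tags$subject_id <- subject_id
  if (!is.null(state)) tags$state <- state
  if (!is.null(band)) tags$band <- band
  dplyr::bind_cols(tags, out)
}

#' Backfit an epoch and return labeling, GEV and metrics together
#'
#' @inheritParams backfit
#' @inheritParams gev
#' @inheritParams ms_metrics
#' @return A list of class `backfit_result`: `labels` (`ms_labels`), `gev`
#'   (percent), `per_template_gev`, and `metrics` (tibble).
#' @export
backfit_epoch <- function(epoch, templates, min_separation_ms = 10,
                          domain = "peaks", exclude_truncated = TRUE) {
  peaks <- find_gfp_peaks(gfp(epoch), fs = epoch$fs,
                          min_separation_ms = min_separation_ms)
  lab <- backfit(epoch, templates, peaks = peaks)
  g <- gev(epoch, templates, lab, domain = domain, peaks = peaks)
  m <- ms_metrics(lab, exclude_truncated = exclude_truncated,
                  subject_id = epoch$subject_id, state = epoch$state,
                  band = epoch$band)
  structure(list(labels = lab, gev = g$gev, per_template_gev = g$per_template,
                 metrics = m),
            class = "backfit_result")
}

#' @export
print.backfit_result <- function(x, ...) {
  cat(sprintf("<backfit_result> GEV %.2f%%, %d segments\n",
              x$gev, nrow(x$labels$segments)))
  print(x$metrics)
  invisible(x)
}
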