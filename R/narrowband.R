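#' Canonical frequency-band table
#'
#' The five neonatal EEG bands with their midpoint ("median") frequencies
#' used for the scaling fits: delta 0.5-4, theta 4-8, alpha 8-13, beta
#' 13-25, gamma 25-45 Hz (midpoints 2.25, 6, 10.5, 19, 35 Hz).
#'
#' @return A tibble: `band`, `low_hz`, `high_hz`, `median_hz`.
#' @export
band_table <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(0.5, 4, 8, 13, 25),
    high_hz = c(4, 8, 13, 25, 45),
    median_hz = c(2.25, 6, 10.5, 19, 35)
  )
}

#' Filter an epoch into narrow frequency bands
#'
#' Each band is obtained with the same zero-phase 7th-order Butterworth
#' high-pass/low-pass cascade as the broad-band preprocessing, applied to
#' the (already preprocessed) signal. The band tag is set on each output.
#'
#' @param epoch an [eeg_epoch()].
#' @param bands a band table as from [band_table()].
#' @param order Butterworth order per stage.
#' @return Named list of band-filtered [eeg_epoch()] objects.
#' @export
band_decompose <- function(epoch, bands = band_table(), order = 7L) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (any(bands$high_hz >= epoch$fs / 2)) {
    stop("band upper edge at or above Nyquist (", epoch$fs / 2, " Hz)", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(bands)), function(i) {
    e <- bandpass(epoch, filter_spec(bands$low_hz[i], bands$high_hz[i], order))
    e$band <- bands$band[i]
    e
  })
  stats::setNames(out, bands$band)
}

#' Run the microstate pipeline per frequency band
#'
#' Filters every epoch into each band, re-runs two-step clustering on the
#' band-filtered signals (GFP peaks re-detected per band), backfits, and
#' collects metrics and GEV per band.
#'
#' @param epochs list of preprocessed [eeg_epoch()] objects.
#' @param k number of templates per band.
#' @param bands a band table as from [band_table()].
#' @param min_separation_ms GFP peak separation.
#' @param n_restarts,seed clustering controls.
#' @return A list of class `band_pipeline`: per band, `templates`
#'   ([template_set()]), `metrics` (tibble with `band` column), `gev`
#'   (per-epoch tibble); plus `metrics` and `gev` binding all bands.
#' @export
band_pipeline <- function(epochs, k, bands = band_table(),
                          min_separation_ms = 10, n_restarts = 20,
                          seed = NULL) {
  per_band <- with_seed(seed, lapply(seq_len(nrow(bands)), function(i) {
    b <- bands[i, ]
    filt <- lapply(epochs, function(e) {
      fe <- bandpass(e, filter_spec(b$low_hz, b$high_hz))
      fe$band <- b$band
      fe
    })
    fit <- two_step_cluster(filt, k, min_separation_ms = min_separation_ms,
                            n_restarts = n_restarts, seed = NULL)
    fit$group$band <- b$band
    res <- lapply(filt, backfit_epoch, templates = fit$group,
                  min_separation_ms = min_separation_ms)
    metrics <- dplyr::bind_rows(lapply(res, `[[`, "metrics"))
    gev_tbl <- tibble::tibble(
      band = b$band,
      subject_id = vapply(filt, function(e) as.character(e$subject_id), ""),
      state = vapply(filt, function(e) e$state, ""),
      gev = vapply(res, `[[`, 0, "gev")
    )
    list(band = b$band, templates = fit$group, metrics = metrics, gev = gev_tbl)
  }))
  names(per_band) <- bands$band
  structure(list(bands = per_band,
                 band_table = bands,
                 metrics = dplyr::bind_rows(lapply(per_band, `[[`, "metrics")),
                 gev = dplyr::bind_rows(lapply(per_band, `[[`, "gev"))),
            class = "band_pipeline")
}

#' Log-log scaling fit of a microstate metric across bands
#'
#' Ordinary least squares of `ln(metric)` on `ln(median band frequency)`.
#' Bands with non-positive metric means are excluded with a warning; at
#' least 3 usable bands are required.
#'
#' @param metric_means numeric vector of band-mean metric values, named by
#'   band or aligned with `bands`.
#' @param bands a band table as from [band_table()].
#' @param metric_name label stored in the result.
#' @return A `scaling_fit` (tibble of the fitted points with attributes):
#'   `slope`, `intercept`, `r_squared` accessible via [glance()].
#' @export
loglog_fit <- function(metric_means, bands = band_table(),
                       metric_name = "metric") {
  if (!is.null(names(metric_means))) {
    metric_means <- metric_means[bands$band]
  }
  stopifnot(length(metric_means) == nrow(bands))
  usable <- is.finite(metric_means) & metric_means > 0
  if (any(!usable)) {
    warning("excluding bands with non-positive metric means: ",
            paste(bands$band[!usable], collapse = ", "))
  }
  if (sum(usable) < 3L) stop("need at least 3 usable bands", call. = FALSE)
  x <- log(bands$median_hz[usable]); y <- log(metric_means[usable])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  r2 <- if (stats::var(y) > 0) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2) else 1
  pts <- tibble::tibble(band = bands$band[usable],
                        log_freq = x, log_metric = y)
  structure(pts, metric = metric_name, slope = slope, intercept = intercept,
            r_squared = r2, class = c("scaling_fit", class(pts)))
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s: slope %.3f, intercept %.3f, R^2 %.3f\n",
              attr(x, "metric"), attr(x, "slope"), attr(x, "intercept"),
              attr(x, "r_squared")))
  NextMethod()
}

#' Welch power spectral density
#'
#' Per-channel PSD by Welch's method: Hamming-windowed overlapping
#' segments, averaged one-sided periodograms, density scaling (µV²/Hz), so
#' integrating the PSD over frequency recovers the signal variance.
#'
#' @param epoch an [eeg_epoch()].
#' @param window_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return A tibble: `freq_hz`, `channel`, `psd` (µV²/Hz).
#' @export
psd_welch <- function(epoch, window_s = 4, overlap = 0.5) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  fs <- epoch$fs
  nper <- as.integer(round(window_s * fs))
  if (nper > ncol(epoch$data)) stop("window longer than the epoch", call. = FALSE)
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, ncol(epoch$data) - nper + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nper) / (nper + 1))   # Hamming
  scale <- fs * sum(w^2)
  n_freq <- nper %/% 2L + 1L
  freq <- (seq_len(n_freq) - 1L) * fs / nper

  rows <- lapply(seq_len(nrow(epoch$data)), function(ch) {
    acc <- numeric(n_freq)
    for (s in starts) {
      seg <- epoch$data[ch, s:(s + nper - 1L)]
      seg <- (seg - mean(seg)) * w
      p <- Mod(stats::fft(seg))^2 / scale
      p <- p[seq_len(n_freq)]
      p[2:(n_freq - 1L)] <- 2 * p[2:(n_freq - 1L)]   # one-sided
      acc <- acc + p
    }
    tibble::tibble(freq_hz = freq, channel = epoch$channels[ch],
                   psd = acc / length(starts))
  })
  dplyr::bind_rows(rows)
}
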