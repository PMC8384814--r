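#' Global field power
#'
#' GFP at each time sample is the population standard deviation of the
#' potentials across channels:
#' \eqn{GFP_t = \sqrt{\sum_j (v_{jt} - \bar v_t)^2 / C}}, with \eqn{C} the
#' number of channels. Peaks of the GFP mark the moments of highest
#' topographic signal-to-noise and anchor both clustering and backfitting.
#'
#' @param x an [eeg_epoch()] or a channels-by-samples numeric matrix.
#' @return Numeric vector of per-sample GFP values (µV).
#' @export
#' @examples
#' gfp(eeg_epoch(rbind(c(1, 2), c(-1, -2)), fs = 100))
gfp <- function(x) {
  d <- if (inherits(x, "eeg_epoch")) x$data else as.matrix(x)
  vbar <- colMeans(d)
  sqrt(colMeans(sweep(d, 2L, vbar)^2))
}

#' Find local GFP peaks
#'
#' Strict local maxima of a GFP trace, optionally thinned to a minimum
#' separation (highest peaks win) and a minimum topographic prominence.
#'
#' @param trace numeric vector of GFP values (or an [eeg_epoch()], in which
#'   case its GFP is computed first).
#' @param fs sampling rate in Hz (taken from the epoch if one is given).
#' @param min_separation_ms minimum distance between retained peaks;
#'   conflicts resolved in favour of the larger peak.
#' @param min_prominence minimum peak prominence (µV); `0` disables.
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
find_gfp_peaks <- function(trace, fs = NULL, min_separation_ms = 10,
                           min_prominence = 0) {
  if (inherits(trace, "eeg_epoch")) {
    fs <- trace$fs
    trace <- gfp(trace)
  }
  if (is.null(fs)) stop("`fs` is required when `trace` is a plain vector", call. = FALSE)
  n <- length(trace)
  if (n < 3L) return(integer(0))
  core <- trace[2:(n - 1L)]
  idx <- which(core > trace[1:(n - 2L)] & core > trace[3:n]) + 1L
  if (length(idx) == 0L) return(integer(0))

  if (min_prominence > 0 && length(idx) > 0L) {
    prom <- vapply(idx, function(i) peak_prominence(trace, i, idx), 0)
    idx <- idx[prom >= min_prominence]
  }
  min_sep <- max(1L, round(min_separation_ms / 1000 * fs))
  if (min_sep > 1L && length(idx) > 1L) {
    keep <- logical(length(idx))
    for (j in order(trace[idx], decreasing = TRUE)) {
      if (!any(keep & abs(idx - idx[j]) < min_sep)) keep[j] <- TRUE
    }
    idx <- sort(idx[keep])
  }
  idx
}

# prominence: height above the higher of the two key saddles, i.e. the
# minimum on the path towards the nearest higher peak (or trace end) per side
peak_prominence <- function(trace, i, peak_idx) {
  h <- trace[i]
  left_hi <- peak_idx[peak_idx < i & trace[peak_idx] > h]
  right_hi <- peak_idx[peak_idx > i & trace[peak_idx] > h]
  lo <- if (length(left_hi)) max(left_hi) else 1L
  hi <- if (length(right_hi)) min(right_hi) else length(trace)
  saddle <- max(min(trace[lo:i]), min(trace[i:hi]))
  h - saddle
}

#' Extract GFP-peak topographies from an epoch
#'
#' Convenience wrapper: detects GFP peaks and returns the scalp maps at the
#' peaks as a peaks-by-channels matrix (average-referenced columns assumed).
#' Samples marked bad by `epoch$keep_mask` are excluded.
#'
#' @inheritParams find_gfp_peaks
#' @param epoch an [eeg_epoch()].
#' @return List with `maps` (peaks x channels matrix) and `peaks` (indices).
#' @export
peak_maps <- function(epoch, min_separation_ms = 10, min_prominence = 0) {
  pk <- find_gfp_peaks(gfp(epoch), fs = epoch$fs,
                       min_separation_ms = min_separation_ms,
                       min_prominence = min_prominence)
  if (!is.null(epoch$keep_mask)) pk <- pk[epoch$keep_mask[pk]]
  list(maps = t(epoch$data[, pk, drop = FALSE]), peaks = pk)
}
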