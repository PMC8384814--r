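#' Band-pass filter specification
#'
#' Describes the zero-phase Butterworth chain used throughout the pipeline: a
#' cascade of separate high-pass and low-pass Butterworth filters, each run
#' forward and backward (non-causal, zero phase). The default matches the
#' broad-band preprocessing: 0.15-45 Hz, 7th order.
#'
#' @param low_cut high-pass cutoff in Hz (0 disables the high-pass stage).
#' @param high_cut low-pass cutoff in Hz (`Inf` disables the low-pass stage).
#' @param order filter order of each stage.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cut = 0.15, high_cut = 45, order = 7L) {
  if (!is.numeric(low_cut) || low_cut < 0) stop("`low_cut` must be >= 0", call. = FALSE)
  if (low_cut >= high_cut) stop("`low_cut` must be below `high_cut`", call. = FALSE)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), family = "butterworth",
                 mode = "forward-backward"),
            class = "filter_spec")
}

# Digital Butterworth as second-order sections via the analytic s-plane pole
# positions and a per-biquad bilinear transform. The transfer-function form
# is ill-conditioned at 7th order for cutoffs near 0.003 x Nyquist, so the
# filter is designed and applied section by section.
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must lie strictly between 0 and Nyquist (", fs / 2, " Hz)",
         call. = FALSE)
  }
  n <- as.integer(order)
  wc <- tan(pi * cutoff_hz / fs)            # prewarped analog cutoff
  k <- seq_len(n)
  p <- wc * exp(1i * pi * (2 * k + n - 1) / (2 * n))  # analog LP poles
  if (type == "high") p <- wc^2 / p         # s -> wc/s keeps |p| pattern
  zp <- (1 + p) / (1 - p)                   # bilinear (T = 2 convention)

  sos <- list()
  # complex pole pairs (conjugates come in order p_k, p_{n+1-k})
  i <- 1L
  while (i <= n %/% 2L) {
    pole <- zp[i]
    a1 <- -2 * Re(pole); a2 <- Mod(pole)^2
    if (type == "low") {
      g <- (1 + a1 + a2) / 4              # unit gain at z = 1
      b <- g * c(1, 2, 1)
    } else {
      g <- (1 - a1 + a2) / 4              # unit gain at z = -1
      b <- g * c(1, -2, 1)
    }
    sos[[i]] <- list(b = b, a = c(a1, a2))
    i <- i + 1L
  }
  if (n %% 2L == 1L) {
    pole <- Re(zp[(n + 1L) %/% 2L])
    if (type == "low") {
      sos[[length(sos) + 1L]] <- list(b = (1 - pole) / 2 * c(1, 1, 0),
                                      a = c(-pole, 0))
    } else {
      sos[[length(sos) + 1L]] <- list(b = (1 + pole) / 2 * c(1, -1, 0),
                                      a = c(-pole, 0))
    }
  }
  sos
}

# apply one biquad causally with steady-state initial conditions (the
# filter starts as if the input had been constant at x[1] forever): FIR
# part vectorized, AR part via stats::filter with matching init
biquad_filter <- function(x, sec) {
  nx <- length(x)
  u <- sec$b[1L] * x
  if (sec$b[2L] != 0) u <- u + sec$b[2L] * c(x[1L], x[-nx])
  if (sec$b[3L] != 0) u <- u + sec$b[3L] * c(x[1L], x[1L], x[-c(nx - 1L, nx)])
  dc_gain <- sum(sec$b) / (1 + sum(sec$a))
  y0 <- dc_gain * x[1L]
  as.numeric(stats::filter(u, -sec$a, method = "recursive", init = c(y0, y0)))
}

sosfilt <- function(x, sos) {
  for (sec in sos) x <- biquad_filter(x, sec)
  x
}

# forward-backward (zero-phase) pass with odd-reflection padding
sosfiltfilt <- function(x, sos, padlen) {
  nx <- length(x)
  padlen <- min(padlen, nx - 1L)
  if (padlen > 0L) {
    left <- 2 * x[1L] - x[(padlen + 1L):2L]
    right <- 2 * x[nx] - x[(nx - 1L):(nx - padlen)]
    x <- c(left, x, right)
  }
  y <- sosfilt(x, sos)
  y <- rev(sosfilt(rev(y), sos))
  if (padlen > 0L) y <- y[(padlen + 1L):(padlen + nx)]
  y
}

apply_zero_phase <- function(data, sos, order, pad_factor = 3L) {
  padlen <- pad_factor * as.integer(order) * length(sos)
  t(apply(data, 1L, sosfiltfilt, sos = sos, padlen = padlen))
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the high-pass stage then the low-pass stage of `spec`, each as a
#' Butterworth cascade of second-order sections run forward and backward
#' (zero phase, squared magnitude response). Edges are reflect-padded before
#' each pass to suppress startup transients.
#'
#' @param epoch an [eeg_epoch()].
#' @param spec a [filter_spec()].
#' @return The filtered [eeg_epoch()].
#' @export
#' @examples
#' ep <- eeg_epoch(matrix(rnorm(400), 4, 100), fs = 100)
#' filtered <- bandpass(ep, filter_spec(0.15, 45))
bandpass <- function(epoch, spec = filter_spec()) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(spec, "filter_spec"))
  if (is.finite(spec$high_cut) && spec$high_cut >= epoch$fs / 2) {
    stop("high cutoff at or above Nyquist (", epoch$fs / 2, " Hz)", call. = FALSE)
  }
  d <- epoch$data
  if (spec$low_cut > 0) {
    d <- apply_zero_phase(d, butter_sos(spec$order, spec$low_cut, epoch$fs, "high"),
                          spec$order)
  }
  if (is.finite(spec$high_cut)) {
    d <- apply_zero_phase(d, butter_sos(spec$order, spec$high_cut, epoch$fs, "low"),
                          spec$order)
  }
  out <- epoch
  out$data <- d
  rownames(out$data) <- epoch$channels
  out
}

#' Down-sample an EEG epoch
#'
#' Anti-alias low-pass (8th-order zero-phase Butterworth at 0.45 x the target
#' rate) followed by cubic-spline evaluation on the new sample grid. Only
#' down-sampling is supported; the pipeline never needs to up-sample.
#'
#' @param epoch an [eeg_epoch()].
#' @param target_fs target sampling rate in Hz.
#' @return The resampled [eeg_epoch()].
#' @export
resample_epoch <- function(epoch, target_fs) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (target_fs > epoch$fs) {
    stop("up-sampling is not supported (target ", target_fs, " > ", epoch$fs,
         " Hz)", call. = FALSE)
  }
  if (target_fs == epoch$fs) return(epoch)
  sos <- butter_sos(8L, 0.45 * target_fs, epoch$fs, "low")
  d <- apply_zero_phase(epoch$data, sos, 8L)
  t_old <- (seq_len(ncol(d)) - 1L) / epoch$fs
  n_new <- floor(ncol(d) * target_fs / epoch$fs)
  t_new <- (seq_len(n_new) - 1L) / target_fs
  out <- epoch
  out$data <- t(apply(d, 1L, function(x) stats::spline(t_old, x, xout = t_new)$y))
  rownames(out$data) <- epoch$channels
  out$fs <- target_fs
  out
}

#' Common-average re-referencing
#'
#' Subtracts, at every time sample, the mean potential across channels, so
#' each column of the data matrix has zero mean. Idempotent.
#'
#' @param epoch an [eeg_epoch()].
#' @return The re-referenced [eeg_epoch()].
#' @export
rereference_common_average <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  out <- epoch
  out$data <- sweep(epoch$data, 2L, colMeans(epoch$data))
  out
}

#' Full preprocessing chain
#'
#' Band-pass filter, down-sample, then re-reference to the common average —
#' the standard preparation of a raw epoch before microstate analysis. An
#' optional keep-mask drops pre-marked bad samples after preprocessing;
#' retained stretches are treated as independent (microstate runs do not
#' span the cut points), so the mask is returned alongside for downstream
#' segment-boundary handling.
#'
#' @param epoch an [eeg_epoch()].
#' @param spec a [filter_spec()].
#' @param target_fs target sampling rate (Hz); `NULL` keeps the native rate.
#' @param keep_mask optional logical vector (length = samples after
#'   resampling); `FALSE` samples are marked bad.
#' @return An [eeg_epoch()]; if `keep_mask` is given it is attached as
#'   `epoch$keep_mask`.
#' @export
preprocess <- function(epoch, spec = filter_spec(), target_fs = 100,
                       keep_mask = NULL) {
  out <- bandpass(epoch, spec)
  if (!is.null(target_fs)) out <- resample_epoch(out, target_fs)
  out <- rereference_common_average(out)
  if (!is.null(keep_mask)) {
    stopifnot(is.logical(keep_mask), length(keep_mask) == ncol(out$data))
    out$keep_mask <- keep_mask
  }
  out
}
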