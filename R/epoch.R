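#' EEG epoch container
#'
#' An `eeg_epoch` wraps a channels-by-samples matrix of scalp potentials in
#' microvolts together with its channel names, sampling rate and study tags
#' (subject, sleep state, frequency band). All pipeline stages consume and
#' return this container.
#'
#' @param data numeric matrix, channels x samples (µV).
#' @param channels character vector of channel names, one per row of `data`.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier (any scalar).
#' @param state sleep-state tag, typically `"AS"` or `"QS"`.
#' @param band frequency-band tag; `"broad"` for the full-band signal.
#'
#' @return An object of class `eeg_epoch`.
#' @export
#' @examples
#' ep <- eeg_epoch(matrix(rnorm(40), 4, 10), paste0("ch", 1:4), fs = 100)
#' n_channels(ep)
eeg_epoch <- function(data, channels = rownames(data), fs,
                      subject_id = NA, state = NA_character_,
                      band = "broad") {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(is.numeric(data), length(channels) == nrow(data))
  if (nrow(data) < 2L) stop("an EEG epoch needs at least 2 channels", call. = FALSE)
  if (ncol(data) < 2L) stop("an EEG epoch needs at least 2 samples", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("epoch data contain missing or non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  rownames(data) <- channels
  structure(
    list(data = data, channels = as.character(channels), fs = as.numeric(fs),
         subject_id = subject_id, state = state, band = band),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s  state: %s  band: %s\n",
              as.character(x$subject_id), x$state, x$band))
  invisible(x)
}

#' @rdname eeg_epoch
#' @param x an `eeg_epoch`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_epoch
#' @export
n_samples <- function(x) ncol(x$data)

#' Read an EEG epoch from disk
#'
#' Two formats are supported: European Data Format (`"edf"`, 16-bit) and a
#' plain-text matrix dialect (`"matrix"`): line 1 holds comma-separated
#' channel names, line 2 the sampling rate in Hz, followed by one row per
#' time sample with one whitespace-separated µV value per channel.
#'
#' @param path file path.
#' @param format `"edf"`, `"matrix"`, or `"auto"` (by file extension).
#' @inheritParams eeg_epoch
#' @return An [eeg_epoch()].
#' @export
read_epoch <- function(path, format = c("auto", "edf", "matrix"),
                       subject_id = NA, state = NA_character_, band = "broad") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  ep <- switch(format,
    edf = read_edf(path),
    matrix = read_epoch_matrix(path)
  )
  ep$subject_id <- subject_id
  ep$state <- state
  ep$band <- band
  ep
}

read_epoch_matrix <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L) stop("matrix file too short: ", path, call. = FALSE)
  channels <- trimws(strsplit(lines[1L], ",")[[1L]])
  fs <- suppressWarnings(as.numeric(trimws(lines[2L])))
  if (is.na(fs)) stop("matrix file has no parseable sampling rate: ", path, call. = FALSE)
  m <- as.matrix(utils::read.table(path, skip = 2L))
  if (ncol(m) != length(channels)) {
    stop("matrix file column count does not match the channel header", call. = FALSE)
  }
  eeg_epoch(t(m), channels = channels, fs = fs)
}

#' Write an EEG epoch to disk
#'
#' @inheritParams read_epoch
#' @param epoch an [eeg_epoch()].
#' @return `path`, invisibly.
#' @export
write_epoch <- function(epoch, path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  switch(format,
    edf = write_edf(epoch, path),
    matrix = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(paste(epoch$channels, collapse = ","), con)
      writeLines(format(epoch$fs), con)
      utils::write.table(t(epoch$data), con, row.names = FALSE,
                         col.names = FALSE)
    }
  )
  invisible(path)
}
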