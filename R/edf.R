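# Minimal European Data Format (EDF, 16-bit) reader/writer.
# One data record per second; physical units are µV. Covers plain EDF only
# (no EDF+ annotations), which is all the pipeline's fixtures need.

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd_str(8)                                  # version
  rd_str(80); rd_str(80); rd_str(8); rd_str(8)  # patient/recording ids, dates
  header_bytes <- as.integer(rd_str(8))
  rd_str(44)                                 # reserved
  n_records <- as.integer(rd_str(8))
  record_dur <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  if (is.na(ns) || ns < 1L) stop("EDF header unreadable: ", path, call. = FALSE)
  labels   <- vapply(seq_len(ns), function(i) rd_str(16), "")
  for (i in seq_len(ns)) rd_str(80)          # transducer
  units    <- vapply(seq_len(ns), function(i) rd_str(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8), ""))
  dig_min  <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8), ""))
  dig_max  <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8), ""))
  for (i in seq_len(ns)) rd_str(80)          # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd_str(8), ""))
  for (i in seq_len(ns)) rd_str(32)          # reserved
  if (length(unique(spr)) != 1L) {
    stop("EDF files with per-signal sampling rates are not supported", call. = FALSE)
  }
  seek(con, header_bytes)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1L])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2L,
                   signed = TRUE, endian = "little")
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        phys_min[s] + gain[s] * (d - dig_min[s])
    }
  }
  eeg_epoch(data, channels = labels, fs = spr[1L] / record_dur)
}

write_edf <- function(epoch, path) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  fs <- epoch$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  spr <- as.integer(round(fs))
  n_full <- ncol(epoch$data) %/% spr
  if (n_full < 1L) stop("epoch shorter than one EDF record (1 s)", call. = FALSE)
  data <- epoch$data[, seq_len(n_full * spr), drop = FALSE]
  ns <- nrow(data)

  rng <- max(abs(data), 1e-6)
  phys_min <- -rng; phys_max <- rng
  dig_min <- -32768; dig_max <- 32767
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  pad <- function(x, n) {
    x <- substr(as.character(x), 1L, n)
    sprintf(paste0("%-", n, "s"), x)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad(x, n)), con)
  header_bytes <- 256L + 256L * ns
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("", 44)
  wr(n_full, 8); wr("1", 8); wr(ns, 4)
  for (ch in epoch$channels) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", phys_min), 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", phys_max), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)

  # recover the *printed* physical range so reading is exactly inverse
  pmin_r <- as.numeric(sprintf("%.2f", phys_min))
  pmax_r <- as.numeric(sprintf("%.2f", phys_max))
  gain <- (pmax_r - pmin_r) / (dig_max - dig_min)
  for (r in seq_len(n_full)) {
    for (s in seq_len(ns)) {
      seg <- data[s, ((r - 1L) * spr + 1L):(r * spr)]
      d <- round((seg - pmin_r) / gain + dig_min)
      d <- pmin(pmax(d, dig_min), dig_max)
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# quantization step of the 16-bit EDF encoding used by write_edf()
edf_quantization_step <- function(epoch) {
  rng <- max(abs(epoch$data), 1e-6)
  pmax_r <- as.numeric(sprintf("%.2f", rng))
  2 * pmax_r / 65535
}
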