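#' Standard 19-channel 10-20 montage names
#' @return Character vector of 19 channel names.
#' @export
montage_10_20 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

#' Generate planted microstate template maps
#'
#' Draws random zero-mean, unit-GFP maps and retries until every template
#' pair is at least `min_pairwise_dissimilarity` apart in polarity-invariant
#' global dissimilarity (`min(GD(u, v), GD(u, -v))`; since that minimum
#' bounds the plain GD from below, the plain pairwise GD satisfies the floor
#' too). Well-separated planted templates make recovery experiments
#' meaningful.
#'
#' @param n_templates number of maps K (2 <= K <= C).
#' @param n_channels number of channels C.
#' @param geometry `"10-20"` (forces C = 19, named channels) or `"random"`.
#' @param min_pairwise_dissimilarity GD floor in \[0, sqrt(2)\].
#' @param seed integer seed.
#' @param max_tries resampling budget before giving up.
#' @return A [template_set()] of planted maps.
#' @export
make_templates <- function(n_templates, n_channels = 19,
                           geometry = c("10-20", "random"),
                           min_pairwise_dissimilarity = 0.8, seed = NULL,
                           max_tries = 500) {
  geometry <- match.arg(geometry)
  if (geometry == "10-20" && n_channels != 19) {
    stop("the 10-20 geometry has 19 channels", call. = FALSE)
  }
  if (n_templates < 2L || n_templates > n_channels) {
    stop("need 2 <= n_templates <= n_channels", call. = FALSE)
  }
  channels <- if (geometry == "10-20") montage_10_20() else
    paste0("ch", seq_len(n_channels))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      m <- matrix(stats::rnorm(n_templates * n_channels), n_templates)
      m <- center_rows(m)
      m <- m / sqrt(rowMeans(m^2))          # unit GFP
      d <- dissimilarity_matrix(m, m, polarity_invariant = TRUE)
      if (min(d[upper.tri(d)]) >= min_pairwise_dissimilarity) {
        return(template_set(m, channels = channels, level = "group"))
      }
    }
    stop("could not achieve the requested pairwise dissimilarity in ",
         max_tries, " tries", call. = FALSE)
  })
}

#' Ground truth of a simulated microstate cohort
#'
#' Bundles everything the generator needs: planted templates, the
#' first-order Markov syntax over them, the segment-duration law, the GFP
#' envelope amplitude, and the background-noise model (1/f^alpha spectrum,
#' exchangeable spatial correlation, signal-to-noise ratio as the ratio of
#' template-signal RMS to noise RMS).
#'
#' @param templates a [template_set()] of planted maps.
#' @param markov K x K row-stochastic transition matrix with zero diagonal;
#'   default uniform off-diagonal.
#' @param duration_law list: `name` (`"lognormal"` or `"fixed"`), `mean_ms`,
#'   `sd_ms` (lognormal only), `min_ms` (truncation floor, default 30).
#' @param amplitude peak segment GFP in µV.
#' @param snr template-signal RMS over noise RMS; `Inf` = noiseless.
#' @param noise_alpha spectral exponent of the 1/f^alpha background.
#' @param noise_spatial_cor exchangeable channel correlation of the noise
#'   before average-referencing.
#' @param osc_freq optional carrier frequency (Hz) multiplying the segment
#'   envelope; `NULL` gives the plain half-sine envelope.
#' @param random_polarity flip each segment's template sign with
#'   probability 1/2 (exercises polarity invariance).
#' @param fs sampling rate (Hz).
#' @param n_subjects,n_epochs,epoch_length_s cohort dimensions.
#' @param seed master seed for [simulate_cohort()].
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(templates,
                            markov = NULL,
                            duration_law = list(name = "lognormal",
                                                mean_ms = 120, sd_ms = 50,
                                                min_ms = 30),
                            amplitude = 10, snr = 5,
                            noise_alpha = 1, noise_spatial_cor = 0.3,
                            osc_freq = NULL, random_polarity = TRUE,
                            fs = 100, n_subjects = 10, n_epochs = 1,
                            epoch_length_s = 60, seed = 1) {
  stopifnot(inherits(templates, "template_set"))
  k <- nrow(templates$maps)
  if (is.null(markov)) markov <- markov_uniform(k)
  markov <- as.matrix(markov)
  if (!all(dim(markov) == k)) stop("markov matrix must be K x K", call. = FALSE)
  if (any(abs(diag(markov)) > 0)) stop("markov diagonal must be 0", call. = FALSE)
  if (any(abs(rowSums(markov) - 1) > 1e-12)) {
    stop("markov rows must sum to 1", call. = FALSE)
  }
  if (any(markov < 0)) stop("markov entries must be nonnegative", call. = FALSE)
  stopifnot(snr > 0, fs > 0, epoch_length_s > 0, amplitude > 0)
  structure(list(templates = templates, markov = markov,
                 duration_law = duration_law, amplitude = amplitude,
                 snr = snr, noise_alpha = noise_alpha,
                 noise_spatial_cor = noise_spatial_cor, osc_freq = osc_freq,
                 random_polarity = random_polarity, fs = fs,
                 n_subjects = n_subjects, n_epochs = n_epochs,
                 epoch_length_s = epoch_length_s, seed = seed),
            class = "synthetic_truth")
}

#' Occurrence-driven (null) and structured Markov matrices
#'
#' `markov_uniform(k)` is the uniform off-diagonal matrix.
#' `markov_null(p)` builds the occurrence-driven null
#' \eqn{q_{XY} = P_Y / (1 - P_X)} for X != Y, under which transitions carry
#' no syntax beyond occurrence. `markov_cyclic(k, p)` sends each state to
#' its successor (1 -> 2 -> ... -> k -> 1) with probability `p`, spreading
#' the rest uniformly — a strongly directional syntax.
#'
#' @param k number of states.
#' @param p occurrence probabilities (`markov_null`) or the cycle
#'   probability (`markov_cyclic`).
#' @return K x K row-stochastic matrix with zero diagonal.
#' @export
markov_uniform <- function(k) {
  m <- matrix(1 / (k - 1), k, k)
  diag(m) <- 0
  m
}

#' @rdname markov_uniform
#' @export
markov_null <- function(p) {
  k <- length(p)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  m <- outer(rep(1, k), p)
  diag(m) <- 0
  m / rowSums(m)
}

#' @rdname markov_uniform
#' @export
markov_cyclic <- function(k, p = 0.8) {
  m <- matrix((1 - p) / (k - 2), k, k)
  diag(m) <- 0
  for (i in seq_len(k)) m[i, i %% k + 1L] <- p
  m
}

# one segment-duration draw in samples
draw_durations <- function(n, law, fs) {
  min_ms <- law$min_ms %||% 30
  ms <- switch(law$name,
    fixed = rep(law$mean_ms, n),
    lognormal = {
      mu <- law$mean_ms; s <- law$sd_ms
      sdlog <- sqrt(log(1 + s^2 / mu^2))
      meanlog <- log(mu) - sdlog^2 / 2
      x <- stats::rlnorm(n, meanlog, sdlog)
      for (i in 1:20) {                     # truncated resampling
        bad <- x < min_ms
        if (!any(bad)) break
        x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
      }
      pmax(x, min_ms)
    },
    stop("unknown duration law: ", law$name, call. = FALSE)
  )
  pmax(1L, as.integer(round(ms / 1000 * fs)))
}

# sample a Markov state path of given length
markov_path <- function(markov, n) {
  k <- nrow(markov)
  s <- integer(n)
  s[1L] <- sample.int(k, 1L)
  for (i in seq_len(n - 1L)) {
    s[i + 1L] <- sample.int(k, 1L, prob = markov[s[i], ])
  }
  s
}

# zero-mean unit-variance 1/f^alpha noise via spectral shaping
one_over_f_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  X <- stats::fft(w)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))
  scale <- c(0, f[-1L]^(-alpha / 2))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Simulate one EEG epoch with planted microstate structure
#'
#' Concatenates microstate segments whose labels follow the planted Markov
#' chain and whose durations follow the planted law; each segment
#' contributes its template scaled by a half-sine GFP envelope (optionally
#' carrying an oscillation), with random polarity when enabled. Spatially
#' correlated 1/f^alpha noise, average-referenced so every sample keeps
#' zero channel mean, is added at the planted SNR.
#'
#' @param truth a [synthetic_truth()].
#' @param subject_id,state tags for the produced epoch.
#' @return A list: `epoch` ([eeg_epoch()]) and `labels` (planted per-sample
#'   template index).
#' @export
simulate_epoch <- function(truth, subject_id = 1, state = "AS") {
  stopifnot(inherits(truth, "synthetic_truth"))
  fs <- truth$fs
  n <- as.integer(round(fs * truth$epoch_length_s))
  tm <- truth$templates$maps                 # K x C, unit GFP, zero mean
  C <- ncol(tm)
  n_seg_guess <- ceiling(n / max(1, (truth$duration_law$min_ms %||% 30) / 1000 * fs)) + 8L

  path <- integer(0); durs <- integer(0)
  while (sum(durs) < n) {
    extra_path <- if (length(path)) {
      c(path, markov_path_from(truth$markov, path[length(path)], n_seg_guess))
    } else markov_path(truth$markov, n_seg_guess)
    extra_durs <- c(durs, draw_durations(n_seg_guess, truth$duration_law, fs))
    path <- extra_path; durs <- extra_durs
  }
  n_seg <- which(cumsum(durs) >= n)[1L]
  path <- path[seq_len(n_seg)]; durs <- durs[seq_len(n_seg)]
  durs[n_seg] <- n - sum(durs[-n_seg])       # trim the last segment

  signal <- matrix(0, C, n)
  labels <- integer(n)
  pos <- 0L
  for (i in seq_len(n_seg)) {
    L <- durs[i]
    idx <- pos + seq_len(L)
    env <- truth$amplitude * sin(pi * seq_len(L) / (L + 1))
    if (!is.null(truth$osc_freq)) {
      phase <- stats::runif(1, 0, 2 * pi)
      env <- env * cos(2 * pi * truth$osc_freq * (idx - 1L) / fs + phase)
    }
    sgn <- if (truth$random_polarity && stats::runif(1) < 0.5) -1 else 1
    signal[, idx] <- tcrossprod(tm[path[i], ], sgn * env)
    labels[idx] <- path[i]
    pos <- pos + L
  }

  if (is.finite(truth$snr)) {
    rho <- truth$noise_spatial_cor
    shared <- one_over_f_noise(n, truth$noise_alpha)
    noise <- t(vapply(seq_len(C), function(ch) {
      sqrt(1 - rho) * one_over_f_noise(n, truth$noise_alpha) +
        sqrt(rho) * shared
    }, numeric(n)))
    noise <- sweep(noise, 2L, colMeans(noise))   # zero-mean across channels
    rms_sig <- sqrt(mean(signal^2))
    rms_noi <- sqrt(mean(noise^2))
    if (rms_noi > 0 && rms_sig > 0) {
      noise <- noise * rms_sig / (truth$snr * rms_noi)
    }
    signal <- signal + noise
  }
  ep <- eeg_epoch(signal, channels = truth$templates$channels, fs = fs,
                  subject_id = subject_id, state = state)
  list(epoch = ep, labels = labels)
}

markov_path_from <- function(markov, start, n) {
  k <- nrow(markov)
  s <- integer(n)
  prev <- start
  for (i in seq_len(n)) {
    s[i] <- sample.int(k, 1L, prob = markov[prev, ])
    prev <- s[i]
  }
  s
}

#' Simulate a two-state cohort with planted ground truth
#'
#' Every subject contributes epochs in both sleep-like states; the two
#' states share templates (the planted study design) but may differ in
#' duration law, syntax, SNR, etc. All randomness derives from
#' `truth_as$seed`, so identical truths reproduce the cohort exactly.
#'
#' @param truth_as,truth_qs [synthetic_truth()] objects sharing templates
#'   and cohort dimensions.
#' @return A `synthetic_cohort` list: `epochs` (list of [eeg_epoch()]),
#'   `true_labels` (parallel list of planted label vectors), `truth_as`,
#'   `truth_qs`.
#' @export
simulate_cohort <- function(truth_as, truth_qs = truth_as) {
  stopifnot(inherits(truth_as, "synthetic_truth"),
            inherits(truth_qs, "synthetic_truth"))
  if (!isTRUE(all.equal(truth_as$templates$maps, truth_qs$templates$maps))) {
    stop("the two states must share planted templates", call. = FALSE)
  }
  if (truth_as$n_subjects != truth_qs$n_subjects) {
    stop("the two states must share the subject roster", call. = FALSE)
  }
  with_seed(truth_as$seed, {
    epochs <- list(); labels <- list()
    for (s in seq_len(truth_as$n_subjects)) {
      for (st in c("AS", "QS")) {
        truth <- if (st == "AS") truth_as else truth_qs
        for (e in seq_len(truth$n_epochs)) {
          sim <- simulate_epoch(truth, subject_id = s, state = st)
          epochs[[length(epochs) + 1L]] <- sim$epoch
          labels[[length(labels) + 1L]] <- sim$labels
        }
      }
    }
    structure(list(epochs = epochs, true_labels = labels,
                   truth_as = truth_as, truth_qs = truth_qs),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d epochs, %d subjects, %d planted templates\n",
              length(x$epochs), x$truth_as$n_subjects,
              nrow(x$truth_as$templates$maps)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Epochs go to EDF or matrix-dialect files, the ground truth (templates,
#' Markov matrix, laws, seeds) and per-epoch planted labels to a JSON
#' sidecar — enough to re-run recovery experiments from files alone.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @param format `"matrix"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") "edf" else "txt"
  files <- character(length(cohort$epochs))
  for (i in seq_along(cohort$epochs)) {
    ep <- cohort$epochs[[i]]
    files[i] <- sprintf("sub%02d_%s_ep%02d.%s", as.integer(ep$subject_id),
                        ep$state, i, ext)
    write_epoch(ep, file.path(dir, files[i]), format = format)
  }
  truth <- cohort$truth_as
  sidecar <- list(
    files = files,
    subject = vapply(cohort$epochs, function(e) as.integer(e$subject_id), 0L),
    state = vapply(cohort$epochs, function(e) e$state, ""),
    templates = truth$templates$maps,
    channels = truth$templates$channels,
    markov_as = cohort$truth_as$markov,
    markov_qs = cohort$truth_qs$markov,
    fs = truth$fs,
    seed = truth$seed,
    true_labels = cohort$true_labels
  )
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
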