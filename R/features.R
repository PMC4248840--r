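# Epoching and band-power feature extraction.
#
# Each 30 s epoch is transformed channel-wise by averaging the magnitude-
# squared spectra of consecutive non-overlapping 1024-sample segments
# (Welch-style, rectangular window, remainder samples discarded) and the
# averaged spectrum is summed over seven fixed frequency bands.  With the
# default 21 channels this yields 21 x 7 = 147 features per epoch.

DEFAULT_BANDS <- list(c(0, 4), c(4, 7), c(7, 12), c(12, 30),
                      c(30, 42), c(42, 84), c(84, 128))

#' Epoching and spectral-estimation configuration
#'
#' @param window_s epoch length in seconds (default 30 s).
#' @param step_s update interval between epoch starts (default 5 s, i.e.
#'   25 s overlap between consecutive epochs).
#' @param fft_len FFT transform length in samples (default 1024).
#' @param bands_hz ordered list of `c(low, high)` band edges in Hz; bands
#'   are half-open `[low, high)`, must be contiguous and non-overlapping,
#'   and the last edge may not exceed the Nyquist frequency.
#' @param rate_hz sampling rate the configuration is validated against.
#' @return object of class `epoching_config`.
#' @export
epoching_config <- function(window_s = 30, step_s = 5, fft_len = 1024,
                            bands_hz = DEFAULT_BANDS, rate_hz = 256) {
  stopifnot_scalar_number(window_s, "window_s", min = 1e-9)
  stopifnot_scalar_number(step_s, "step_s", min = 1e-9)
  if (step_s > window_s) abort_invalid("step_s must be <= window_s")
  stopifnot_scalar_number(fft_len, "fft_len", min = 2)
  lows <- vapply(bands_hz, `[`, numeric(1), 1)
  highs <- vapply(bands_hz, `[`, numeric(1), 2)
  if (any(highs <= lows)) abort_invalid("each band needs high > low")
  if (length(bands_hz) > 1 &&
      any(abs(lows[-1] - highs[-length(highs)]) > 1e-9)) {
    abort_invalid("bands must be contiguous and non-overlapping")
  }
  if (highs[length(highs)] > rate_hz / 2 + 1e-9) {
    abort_invalid("last band edge %g Hz exceeds Nyquist %g Hz",
                  highs[length(highs)], rate_hz / 2)
  }
  structure(list(window_s = window_s, step_s = step_s, fft_len = fft_len,
                 bands_hz = bands_hz, rate_hz = rate_hz),
            class = "epoching_config")
}

#' Epoch start times for a signal of given duration
#'
#' Epochs start at 0, `step_s`, 2`step_s`, ...; the count is
#' `floor((duration - window) / step) + 1`.  A duration shorter than one
#' window yields an empty vector (the caller decides whether that is
#' fatal).
#'
#' @param duration_s signal duration in seconds.
#' @param config [epoching_config()].
#' @return numeric vector of epoch start times in seconds.
#' @export
epoch_slices <- function(duration_s, config = epoching_config()) {
  if (duration_s < config$window_s - 1e-9) return(numeric(0))
  k <- floor((duration_s - config$window_s) / config$step_s + 1e-9)
  seq(0, by = config$step_s, length.out = k + 1)
}

band_bin_index <- function(config) {
  # Map one-sided FFT bins (0 .. fft_len/2) to band indices; Nyquist bin
  # is assigned to the last band.
  nfft <- config$fft_len
  freqs <- (0:(nfft %/% 2)) * config$rate_hz / nfft
  lows <- vapply(config$bands_hz, `[`, numeric(1), 1)
  highs <- vapply(config$bands_hz, `[`, numeric(1), 2)
  idx <- rep(NA_integer_, length(freqs))
  for (b in seq_along(lows)) {
    idx[freqs >= lows[b] - 1e-12 & freqs < highs[b] - 1e-12] <- b
  }
  idx[length(idx)] <- length(lows)          # Nyquist bin -> last band
  idx[freqs < lows[1]] <- NA_integer_       # below the first band (none
  idx                                       # with default 0 Hz edge)
}

#' Band powers of one epoch
#'
#' Splits the epoch into consecutive non-overlapping `fft_len`-sample
#' segments (remainder discarded), averages their magnitude-squared
#' spectra, and sums the averaged spectrum over the configured bands.
#' Powers are scaled so that the bands partition the epoch's mean squared
#' amplitude: the sum over bands equals the total power of the averaged
#' spectrum (Parseval over the band partition).
#'
#' @param epoch_samples channels x samples numeric matrix (microvolts).
#' @param config [epoching_config()].
#' @return channels x bands matrix of band powers (microvolt^2).
#' @export
band_powers <- function(epoch_samples, config = epoching_config()) {
  if (!is.matrix(epoch_samples)) {
    epoch_samples <- matrix(epoch_samples, nrow = 1)
  }
  nfft <- config$fft_len
  nsamp <- ncol(epoch_samples)
  if (nsamp < nfft) {
    abort_invalid("epoch has %d samples but fft_len is %d", nsamp, nfft)
  }
  nseg <- nsamp %/% nfft
  nch <- nrow(epoch_samples)
  half <- nfft %/% 2 + 1L
  # Stack all segments of all channels into one matrix for a single mvfft.
  segs <- matrix(0, nrow = nfft, ncol = nch * nseg)
  col <- 1L
  for (ch in seq_len(nch)) {
    for (s in seq_len(nseg)) {
      segs[, col] <- epoch_samples[ch, ((s - 1) * nfft + 1):(s * nfft)]
      col <- col + 1L
    }
  }
  spec <- Mod(stats::mvfft(segs))^2 / nfft^2   # two-sided, mean-power scale
  # Fold to one-sided: double everything except DC and Nyquist.
  one_sided <- spec[seq_len(half), , drop = FALSE]
  if (nfft %% 2 == 0) {
    mid <- 2:(half - 1)
  } else {
    mid <- 2:half
  }
  one_sided[mid, ] <- 2 * one_sided[mid, , drop = FALSE]
  # Average over the segments of each channel.
  avg <- matrix(0, nrow = half, ncol = nch)
  for (ch in seq_len(nch)) {
    cols <- ((ch - 1) * nseg + 1):(ch * nseg)
    avg[, ch] <- rowMeans(one_sided[, cols, drop = FALSE])
  }
  bidx <- band_bin_index(config)
  nb <- length(config$bands_hz)
  out <- matrix(0, nrow = nch, ncol = nb)
  keep <- !is.na(bidx)
  for (ch in seq_len(nch)) {
    out[ch, ] <- as.numeric(
      rowsum(avg[keep, ch], bidx[keep], reorder = TRUE))
  }
  rownames(out) <- rownames(epoch_samples)
  colnames(out) <- band_names(config)
  out
}

band_names <- function(config) {
  vapply(config$bands_hz,
         function(b) sprintf("%g-%gHz", b[1], b[2]), character(1))
}

#' Extract the epoch-by-feature matrix from a labelled recording
#'
#' Epochs are computed independently within each contiguous high- or
#' low-workload block so no epoch straddles a block boundary; transition
#' intervals are discarded.  Each epoch inherits its block's label.
#'
#' @param recording [eeg_recording()].
#' @param labels [label_track()] aligned to the recording.
#' @param config [epoching_config()].
#' @return object of class `feature_set`: list with `matrix`
#'   (epochs x channels*bands band powers), `epoch_start_s`, `labels`
#'   (per-epoch "high"/"low"), and `feature_names`.
#' @export
extract_features <- function(recording, labels,
                             config = epoching_config()) {
  if (!inherits(recording, "eeg_recording")) {
    abort_invalid("recording must be an eeg_recording")
  }
  if (!inherits(labels, "label_track")) {
    abort_invalid("labels must be a label_track")
  }
  rate <- recording$rate_hz
  iv <- labels$intervals
  iv <- iv[iv$state %in% c("high", "low"), , drop = FALSE]
  rows <- list(); starts <- c(); states <- c()
  for (i in seq_len(nrow(iv))) {
    dur <- iv$end_s[i] - iv$start_s[i]
    ep_starts <- epoch_slices(dur, config)
    for (t0 in ep_starts) {
      i0 <- round((iv$start_s[i] + t0) * rate) + 1L
      i1 <- i0 + round(config$window_s * rate) - 1L
      bp <- band_powers(recording$samples[, i0:i1, drop = FALSE], config)
      rows[[length(rows) + 1L]] <- as.numeric(t(bp))
      starts <- c(starts, iv$start_s[i] + t0)
      states <- c(states, iv$state[i])
    }
  }
  if (length(rows) == 0) {
    abort_invalid("no high/low block of at least %g s is present",
                  config$window_s)
  }
  mat <- do.call(rbind, rows)
  fnames <- as.character(outer(band_names(config), recording$channels,
                               function(b, ch) paste(ch, b, sep = "_")))
  colnames(mat) <- fnames
  o <- order(starts)
  structure(list(matrix = mat[o, , drop = FALSE],
                 epoch_start_s = starts[o],
                 labels = states[o],
                 feature_names = fnames),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d epochs x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

subset_features <- function(fs, rows) {
  structure(list(matrix = fs$matrix[rows, , drop = FALSE],
                 epoch_start_s = fs$epoch_start_s[rows],
                 labels = fs$labels[rows],
                 feature_names = fs$feature_names),
            class = "feature_set")
}

combine_features <- function(fs_list) {
  structure(list(matrix = do.call(rbind, lapply(fs_list, `[[`, "matrix")),
                 epoch_start_s = unlist(lapply(fs_list, `[[`,
                                               "epoch_start_s")),
                 labels = unlist(lapply(fs_list, `[[`, "labels")),
                 feature_names = fs_list[[1]]$feature_names),
            class = "feature_set")
}

#' Fit a per-feature z-normalizer on training rows only
#'
#' Statistics (mean, SD) come exclusively from the designated training
#' rows so prospective protocols never leak test information into the
#' normalization.
#'
#' @param features [extract_features()] output.
#' @param training_rows integer indices of the rows to fit on.
#' @return object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(features, training_rows = seq_len(nrow(features$matrix))) {
  if (length(training_rows) == 0) abort_invalid("training_rows is empty")
  x <- features$matrix[training_rows, , drop = FALSE]
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  bad <- which(!is.finite(sd) | sd <= 0)
  if (length(bad) > 0) {
    abort_invalid("zero-variance training feature: %s",
                  paste(colnames(x)[bad], collapse = ", "))
  }
  structure(list(mean = mu, sd = sd), class = "feature_normalizer")
}

#' Apply a fitted normalizer to a feature set
#'
#' @param normalizer [fit_normalizer()] output.
#' @param features [extract_features()] output (or any feature_set with
#'   matching columns).
#' @return the feature set with its matrix replaced by
#'   `(x - mean) / sd` per column.
#' @export
apply_normalizer <- function(normalizer, features) {
  x <- features$matrix
  if (ncol(x) != length(normalizer$mean)) {
    abort_invalid("feature count %d does not match normalizer (%d)",
                  ncol(x), length(normalizer$mean))
  }
  features$matrix <- sweep(sweep(x, 2, normalizer$mean, "-"),
                           2, normalizer$sd, "/")
  features
}
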