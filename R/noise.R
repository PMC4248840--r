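# Test-time noise injection: calibrated white Gaussian noise added to the
# raw recording, a parallel array of classifications over independent
# noise realizations combined by majority vote, and the clean-vs-noisy
# correlation study used to relate noise levels to electrode-quality
# correlation coefficients.

#' White-noise injection configuration
#'
#' The injected noise is white Gaussian with RMS amplitude `rms_uV`
#' (microvolts), bandwidth equal to the recording's Nyquist frequency
#' (white at the sampling rate), drawn independently per channel and per
#' sample.
#'
#' @param rms_uV target RMS amplitude of the additive noise.
#' @param seed noise seed.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(rms_uV = 10, seed = 1L) {
  if (!is.numeric(rms_uV) || length(rms_uV) != 1L || !is.finite(rms_uV) ||
      rms_uV < 0) {
    abort_invalid("rms_uV must be a finite scalar >= 0")
  }
  structure(list(rms_uV = rms_uV, seed = as.integer(seed)),
            class = "noise_config")
}

#' Ensemble (parallel classification) configuration
#'
#' @param n_members number of parallel classification repetitions
#'   (default 10 networks driven by independent noise streams).
#' @param tie_rule tie-breaking class; fixed to "high".
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 10L, tie_rule = "high") {
  if (n_members < 1) abort_invalid("n_members must be >= 1")
  if (!identical(tie_rule, "high")) {
    abort_invalid("tie_rule is fixed to 'high'")
  }
  structure(list(n_members = as.integer(n_members), tie_rule = tie_rule),
            class = "ensemble_config")
}

#' Add white Gaussian noise to a recording
#'
#' @param recording [eeg_recording()].
#' @param noise [noise_config()]; `rms_uV = 0` returns the input
#'   unchanged.
#' @return recording with independent zero-mean Gaussian noise of SD
#'   `rms_uV` added to every channel.
#' @export
add_noise <- function(recording, noise) {
  if (!inherits(noise, "noise_config")) {
    abort_invalid("noise must be a noise_config")
  }
  if (noise$rms_uV == 0) return(recording)
  dims <- dim(recording$samples)
  recording$samples <- recording$samples +
    with_seed(noise$seed,
              matrix(stats::rnorm(prod(dims), 0, noise$rms_uV),
                     nrow = dims[1], ncol = dims[2]))
  recording
}

#' Majority vote over ensemble members
#'
#' @param member_classes list (one element per member) of equal-length
#'   class vectors, or a members x epochs character matrix.
#' @return per-epoch modal class; an exact tie returns "high".
#' @export
majority_vote <- function(member_classes) {
  if (is.list(member_classes)) {
    if (length(member_classes) == 0) abort_invalid("no ensemble members")
    member_classes <- do.call(rbind, member_classes)
  }
  if (!is.matrix(member_classes) || nrow(member_classes) == 0) {
    abort_invalid("no ensemble members")
  }
  high_votes <- colSums(member_classes == "high")
  n <- nrow(member_classes)
  ifelse(high_votes >= n / 2, "high", "low")
}

#' Noise-injection ensemble prediction
#'
#' Implements testing-with-noise: the network is trained on noise-free
#' features, and at prediction time each of the `n_members` parallel
#' classifications sees the raw recording corrupted by an independent
#' white-noise realization (features re-extracted per member).  Per-epoch
#' classes are combined by majority vote with ties going to "high".
#' Member seeds are derived deterministically from `noise$seed` and the
#' session identity.
#'
#' @param net trained [train_workload_net()] (noise-free training).
#' @param recording,labels the test session.
#' @param epoching [epoching_config()].
#' @param noise [noise_config()] (master seed + RMS level).
#' @param ensemble [ensemble_config()].
#' @return per-epoch class vector (same epochs as
#'   `extract_features(recording, labels, epoching)`).
#' @export
ensemble_predict <- function(net, recording, labels,
                             epoching = epoching_config(),
                             noise = noise_config(),
                             ensemble = ensemble_config()) {
  votes <- vector("list", ensemble$n_members)
  for (m in seq_len(ensemble$n_members)) {
    member_noise <- noise_config(
      noise$rms_uV,
      seed = derive_seed(noise$seed, m,
                         recording$day_index, recording$session_index))
    noisy <- add_noise(recording, member_noise)
    feats <- extract_features(noisy, labels, epoching)
    votes[[m]] <- predict(net, feats)
  }
  majority_vote(votes)
}

#' Clean-vs-noisy correlation as a function of section length
#'
#' Splits one channel of the recording into consecutive non-overlapping
#' sections of each requested length, adds an independent white-noise
#' realization, and computes the Pearson correlation between the clean
#' and noisy trace per section.  For stationary signals the expected
#' correlation is the attenuation factor
#' `1 / sqrt(1 + rms_noise^2 / rms_signal^2)`; short sections
#' systematically underestimate the median and inflate the spread.
#'
#' @param recording [eeg_recording()].
#' @param noise [noise_config()].
#' @param section_lengths_s section durations in seconds.
#' @param channel channel label or index to analyze (default the first
#'   channel).
#' @return data.frame with one row per section length: `section_s`,
#'   `n_sections`, `min`, `median`, `max` correlation.
#' @export
correlation_vs_section_length <- function(recording, noise,
                                          section_lengths_s,
                                          channel = 1L) {
  if (is.character(channel)) channel <- match(channel, recording$channels)
  clean <- recording$samples[channel, ]
  duration <- length(clean) / recording$rate_hz
  if (any(section_lengths_s > duration + 1e-9)) {
    abort_invalid("section length %g s exceeds recording duration %g s",
                  max(section_lengths_s), duration)
  }
  noisy <- add_noise(recording, noise)$samples[channel, ]
  out <- lapply(section_lengths_s, function(len) {
    nsamp <- round(len * recording$rate_hz)
    nsec <- length(clean) %/% nsamp
    rs <- vapply(seq_len(nsec), function(i) {
      idx <- ((i - 1) * nsamp + 1):(i * nsamp)
      if (noise$rms_uV == 0) 1.0 else stats::cor(clean[idx], noisy[idx])
    }, numeric(1))
    data.frame(section_s = len, n_sections = nsec,
               min = min(rs), median = stats::median(rs), max = max(rs))
  })
  do.call(rbind, out)
}
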