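# Synthetic multi-subject EEG studies: 1/f background, band-limited
# oscillatory components whose RMS is modulated by the workload state,
# blink-like transients, and slow session-to-session drift.

DEFAULT_CHANNELS <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                      "T3", "T5", "C3", "Cz", "C4", "T4", "T6",
                      "P3", "Pz", "P4", "O1", "O2", "EOGv", "EOGh")

WORKLOAD_STATES <- c("high", "low", "transition")

#' Default scalp topography surrogate for the oscillatory components
#'
#' Builds a channels x components weight matrix: the theta component is
#' frontal-weighted, the alpha component posterior/occipital-weighted, and
#' EOG channels receive small residual weights of every component.
#'
#' @param channel_labels character vector of channel names.
#' @param component_names names of the band components.
#' @return numeric matrix, one row per channel, one column per component.
#' @export
default_channel_mixing <- function(channel_labels = DEFAULT_CHANNELS,
                                   component_names = c("theta", "alpha")) {
  weight_for <- function(lab, comp) {
    frontal <- grepl("^(Fp|F)", lab) && !grepl("^EOG", lab)
    central <- grepl("^(C|T3|T4)", lab)
    posterior <- grepl("^(P|O|T5|T6)", lab)
    eog <- grepl("^EOG", lab)
    if (comp == "theta") {
      if (eog) 0.2 else if (frontal) 1.0 else if (central) 0.6 else 0.4
    } else if (comp == "alpha") {
      if (eog) 0.2 else if (grepl("^O", lab)) 1.0
      else if (posterior) 0.8 else if (central) 0.5 else 0.3
    } else {
      if (eog) 0.2 else 0.5
    }
  }
  m <- sapply(component_names, function(comp)
    vapply(channel_labels, weight_for, numeric(1), comp = comp))
  m <- matrix(m, nrow = length(channel_labels),
              dimnames = list(channel_labels, component_names))
  m
}

#' Signal-model parameters for the synthetic EEG generator
#'
#' The generator superimposes, per channel: (i) a 1/f^k Gaussian background,
#' (ii) band-pass-filtered oscillatory components whose RMS amplitude is
#' multiplied by a component-specific workload gain during high-workload
#' blocks, and (iii) optional blink-like transients concentrated in the EOG
#' and frontal channels.
#'
#' Defaults encode the classic workload signature: under high workload,
#' theta (4-7 Hz) activity increases and alpha (7-12 Hz) activity is
#' suppressed.
#'
#' @param background_exponent spectral slope k of the 1/f^k background PSD.
#' @param background_rms_uV target background RMS per channel, microvolts.
#' @param band_components data.frame with columns `name`, `center_hz`,
#'   `bandwidth_hz`, `rms_uV` (baseline source RMS at unit mixing weight)
#'   and `workload_gain` (multiplicative RMS factor in the high state).
#' @param blink_rate_hz mean rate of blink transients (0 disables them).
#' @param blink_amp_uV peak blink amplitude in the EOG channels.
#' @param channel_mixing channels x components weight matrix; `NULL` uses
#'   [default_channel_mixing()] for the channels supplied at generation.
#' @return object of class `signal_model_params`.
#' @export
signal_model_params <- function(background_exponent = 1.5,
                                background_rms_uV = 31,
                                band_components = data.frame(
                                  name = c("theta", "alpha"),
                                  center_hz = c(5.5, 9.5),
                                  bandwidth_hz = c(3, 5),
                                  rms_uV = c(8, 10),
                                  workload_gain = c(1.6, 0.7)),
                                blink_rate_hz = 0.2,
                                blink_amp_uV = 150,
                                channel_mixing = NULL) {
  stopifnot_scalar_number(background_rms_uV, "background_rms_uV", min = 0)
  stopifnot_scalar_number(background_exponent, "background_exponent", min = 0)
  stopifnot_scalar_number(blink_rate_hz, "blink_rate_hz", min = 0)
  stopifnot_scalar_number(blink_amp_uV, "blink_amp_uV", min = 0)
  bc <- band_components
  need <- c("name", "center_hz", "bandwidth_hz", "rms_uV", "workload_gain")
  if (!is.data.frame(bc) || !all(need %in% names(bc))) {
    abort_invalid("band_components must be a data.frame with columns %s",
                  paste(need, collapse = ", "))
  }
  if (any(bc$rms_uV < 0)) abort_invalid("component RMS values must be >= 0")
  if (any(bc$workload_gain <= 0)) abort_invalid("workload gains must be > 0")
  if (nrow(bc) > 0 && all(bc$workload_gain == 1) && any(bc$rms_uV > 0)) {
    abort_invalid(
      "at least one band component must have workload_gain != 1; otherwise high and low states are indistinguishable by construction")
  }
  if (!is.null(channel_mixing)) {
    if (!is.matrix(channel_mixing) || ncol(channel_mixing) != nrow(bc)) {
      abort_invalid("channel_mixing needs one column per band component")
    }
  }
  structure(list(background_exponent = background_exponent,
                 background_rms_uV = background_rms_uV,
                 band_components = bc,
                 blink_rate_hz = blink_rate_hz,
                 blink_amp_uV = blink_amp_uV,
                 channel_mixing = channel_mixing),
            class = "signal_model_params")
}

#' Temporal drift parameters
#'
#' Controls the nonstationarity of the oscillatory components across a
#' study.  Component RMS multipliers evolve as a cumulative log-normal
#' random walk: a `session_drift_sd` step between consecutive sessions of a
#' day and a `day_drift_sd` step between days, so spectral statistics
#' wander further apart as the time gap grows and cross-session classifier
#' transfer degrades.  All zeros reproduces a stationary study.
#'
#' @param session_drift_sd SD of the log-multiplier step per session.
#' @param day_drift_sd SD of the log-multiplier step per day.
#' @param within_session_slope fractional linear change of component RMS
#'   over the course of one session (0 = flat).
#' @return object of class `drift_params`.
#' @export
drift_params <- function(session_drift_sd = 0.15,
                         day_drift_sd = 0.3,
                         within_session_slope = 0) {
  stopifnot_scalar_number(session_drift_sd, "session_drift_sd", min = 0)
  stopifnot_scalar_number(day_drift_sd, "day_drift_sd", min = 0)
  stopifnot_scalar_number(abs(within_session_slope), "within_session_slope",
                          min = 0)
  structure(list(session_drift_sd = session_drift_sd,
                 day_drift_sd = day_drift_sd,
                 within_session_slope = within_session_slope),
            class = "drift_params")
}

default_block_plan <- function() {
  data.frame(state = c("transition", "high", "transition", "low",
                       "transition"),
             duration_s = c(60, 300, 120, 300, 120))
}

#' Study schedule: subjects, days, sessions and the within-session plan
#'
#' The default mirrors a multi-day workload-monitoring study: 8 subjects,
#' 5 days, 3 sessions per day; each 15 min session contains one 5 min
#' high-workload and one 5 min low-workload block, separated by transition
#' blocks of at least 60 s which are excluded from analysis.
#'
#' @param n_subjects,days,sessions_per_day study dimensions.
#' @param session_length_s session duration in seconds.
#' @param block_plan data.frame with columns `state` (high/low/transition)
#'   and `duration_s`; durations must sum to `session_length_s` and
#'   workload blocks must be separated by >= 60 s of transition.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param channel_labels ordered channel names (EEG first, then EOG).
#' @param session_spacing_s nominal time between session starts on a day.
#' @param day_spacing_s nominal time between days.
#' @return object of class `study_schedule`.
#' @export
study_schedule <- function(n_subjects = 8, days = 5, sessions_per_day = 3,
                           session_length_s = 900,
                           block_plan = default_block_plan(),
                           sampling_rate_hz = 256,
                           channel_labels = DEFAULT_CHANNELS,
                           session_spacing_s = 1800,
                           day_spacing_s = 86400) {
  for (nm in c("n_subjects", "days", "sessions_per_day")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      abort_invalid("'%s' must be a positive integer", nm)
    }
  }
  stopifnot_scalar_number(session_length_s, "session_length_s", min = 1)
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", min = 1)
  if (!is.data.frame(block_plan) ||
      !all(c("state", "duration_s") %in% names(block_plan))) {
    abort_invalid("block_plan must have columns 'state' and 'duration_s'")
  }
  if (!all(block_plan$state %in% WORKLOAD_STATES)) {
    abort_invalid("block states must be one of %s",
                  paste(WORKLOAD_STATES, collapse = "/"))
  }
  if (abs(sum(block_plan$duration_s) - session_length_s) > 1e-9) {
    abort_invalid("block durations sum to %g s but session_length_s is %g s",
                  sum(block_plan$duration_s), session_length_s)
  }
  # Workload blocks must be separated by >= 60 s of transition.
  st <- block_plan$state
  dur <- block_plan$duration_s
  work_idx <- which(st != "transition")
  if (length(work_idx) > 1) {
    for (i in seq_len(length(work_idx) - 1)) {
      a <- work_idx[i]; b <- work_idx[i + 1]
      gap <- if (b == a + 1) 0 else sum(dur[(a + 1):(b - 1)])
      if (gap < 60) {
        abort_invalid(
          "workload blocks %d and %d are separated by %g s of transition (< 60 s)",
          a, b, gap)
      }
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 days = as.integer(days),
                 sessions_per_day = as.integer(sessions_per_day),
                 session_length_s = session_length_s,
                 block_plan = block_plan,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_labels = channel_labels,
                 session_spacing_s = session_spacing_s,
                 day_spacing_s = day_spacing_s),
            class = "study_schedule")
}

#' Construct an EEG recording object
#'
#' @param samples channels x time numeric matrix, microvolts.
#' @param rate_hz sampling rate.
#' @param channels channel labels, one per row of `samples`.
#' @param subject_id,day_index,session_index session identity.
#' @param start_offset_s nominal session start time within the study.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate_hz, channels,
                          subject_id = 1L, day_index = 1L,
                          session_index = 1L, start_offset_s = 0) {
  if (!is.matrix(samples)) abort_invalid("samples must be a matrix")
  if (nrow(samples) != length(channels)) {
    abort_invalid("channel count (%d) does not match label count (%d)",
                  nrow(samples), length(channels))
  }
  if (!all(is.finite(samples))) abort_invalid("samples must be finite")
  stopifnot_scalar_number(rate_hz, "rate_hz", min = 1e-9)
  rownames(samples) <- channels
  structure(list(samples = samples, rate_hz = rate_hz,
                 channels = as.character(channels),
                 subject_id = subject_id, day_index = as.integer(day_index),
                 session_index = as.integer(session_index),
                 start_offset_s = start_offset_s),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s day %d session %d: %d ch x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$day_index, x$session_index,
    nrow(x$samples), ncol(x$samples), x$rate_hz,
    ncol(x$samples) / x$rate_hz))
  invisible(x)
}

#' Construct a label track of workload intervals
#'
#' Intervals use the half-open convention `[start_s, end_s)` and must be
#' non-overlapping and ordered.
#'
#' @param intervals data.frame with columns `start_s`, `end_s`, `state`.
#' @return object of class `label_track`.
#' @export
label_track <- function(intervals) {
  need <- c("start_s", "end_s", "state")
  if (!is.data.frame(intervals) || !all(need %in% names(intervals))) {
    abort_invalid("intervals must have columns start_s, end_s, state")
  }
  if (nrow(intervals) > 0) {
    if (!all(intervals$state %in% WORKLOAD_STATES)) {
      abort_invalid("interval states must be one of %s",
                    paste(WORKLOAD_STATES, collapse = "/"))
    }
    o <- order(intervals$start_s)
    intervals <- intervals[o, , drop = FALSE]
    if (any(intervals$end_s <= intervals$start_s)) {
      abort_invalid("intervals must have end_s > start_s")
    }
    if (nrow(intervals) > 1) {
      bad <- which(intervals$start_s[-1] <
                     intervals$end_s[-nrow(intervals)] - 1e-9)
      if (length(bad) > 0) {
        abort_invalid("intervals %d and %d overlap ([%g,%g) vs [%g,%g))",
                      bad[1], bad[1] + 1,
                      intervals$start_s[bad[1]], intervals$end_s[bad[1]],
                      intervals$start_s[bad[1] + 1],
                      intervals$end_s[bad[1] + 1])
      }
    }
  }
  rownames(intervals) <- NULL
  structure(list(intervals = intervals), class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track> %d intervals, %.1f s total\n",
              nrow(x$intervals),
              if (nrow(x$intervals)) max(x$intervals$end_s) else 0))
  invisible(x)
}

block_labels <- function(schedule) {
  bp <- schedule$block_plan
  ends <- cumsum(bp$duration_s)
  starts <- c(0, ends[-length(ends)])
  label_track(data.frame(start_s = starts, end_s = ends, state = bp$state))
}

# 1/f^k Gaussian background via frequency-domain shaping.  The PSD follows
# f^-k exactly above `f_floor`; below it the shaping is clamped so the
# variance stays finite.  Output is rescaled to the target RMS.
one_over_f_noise <- function(n, rate_hz, exponent, rms, f_floor = 0.5) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rate_hz / n   # symmetric frequency of each bin
  scale <- pmax(f, f_floor)^(-exponent / 2)
  scale[1] <- 0                       # remove DC
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y * (rms / stats::sd(y))
}

# Band-limited unit-RMS source: white noise through a 4th-order zero-phase
# Butterworth band-pass.
band_source <- function(n, rate_hz, center_hz, bandwidth_hz) {
  lo <- max(center_hz - bandwidth_hz / 2, 0.01)
  hi <- min(center_hz + bandwidth_hz / 2, rate_hz / 2 * 0.999)
  bf <- signal::butter(4, c(lo, hi) / (rate_hz / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

# Per-sample workload gain envelope for one component: `gain` inside high
# blocks, 1 inside low blocks, linear interpolation across transitions.
gain_envelope <- function(schedule, gain) {
  rate <- schedule$sampling_rate_hz
  bp <- schedule$block_plan
  n <- round(schedule$session_length_s * rate)
  ends <- round(cumsum(bp$duration_s) * rate)
  starts <- c(0L, ends[-length(ends)]) + 1L
  state_gain <- ifelse(bp$state == "high", gain,
                       ifelse(bp$state == "low", 1, NA))
  env <- numeric(n)
  for (i in seq_len(nrow(bp))) {
    idx <- starts[i]:ends[i]
    if (!is.na(state_gain[i])) {
      env[idx] <- state_gain[i]
    } else {
      prev <- if (i > 1) state_gain[i - 1] else NA
      nxt <- if (i < nrow(bp)) state_gain[i + 1] else NA
      from <- if (is.na(prev)) if (is.na(nxt)) 1 else nxt else prev
      to <- if (is.na(nxt)) if (is.na(prev)) 1 else prev else nxt
      env[idx] <- seq(from, to, length.out = length(idx))
    }
  }
  env
}

blink_mixing_weights <- function(channel_labels) {
  # EOG channels carry blinks at 10x the weight of EEG channels.
  ifelse(grepl("^EOG", channel_labels), 1.0, 0.1)
}

#' Generate one synthetic EEG session
#'
#' @param model [signal_model_params()].
#' @param schedule [study_schedule()] (its block plan defines this session).
#' @param drift_state per-component RMS multipliers (default all 1).
#' @param seed integer seed; output is fully determined by (inputs, seed).
#' @param subject_id,day_index,session_index,start_offset_s identity fields
#'   copied into the recording.
#' @param within_session_slope fractional linear RMS change over the
#'   session applied to all band components.
#' @return list with elements `recording` ([eeg_recording()]) and
#'   `labels` ([label_track()]).
#' @export
generate_session <- function(model, schedule, drift_state = NULL, seed = 1L,
                             subject_id = 1L, day_index = 1L,
                             session_index = 1L, start_offset_s = 0,
                             within_session_slope = 0) {
  if (!inherits(model, "signal_model_params")) {
    abort_invalid("model must be signal_model_params")
  }
  if (!inherits(schedule, "study_schedule")) {
    abort_invalid("schedule must be a study_schedule")
  }
  rate <- schedule$sampling_rate_hz
  n <- round(schedule$session_length_s * rate)
  chans <- schedule$channel_labels
  ncomp <- nrow(model$band_components)
  mixing <- model$channel_mixing
  if (is.null(mixing)) {
    mixing <- default_channel_mixing(chans, model$band_components$name)
  }
  if (nrow(mixing) != length(chans)) {
    abort_invalid("channel_mixing has %d rows but schedule has %d channels",
                  nrow(mixing), length(chans))
  }
  if (is.null(drift_state)) drift_state <- rep(1, ncomp)
  if (length(drift_state) != ncomp) {
    abort_invalid("drift_state needs one multiplier per band component")
  }

  samples <- with_seed(seed, {
    out <- matrix(0, nrow = length(chans), ncol = n)
    for (i in seq_along(chans)) {
      out[i, ] <- one_over_f_noise(n, rate, model$background_exponent,
                                   model$background_rms_uV)
    }
    slope_env <- if (within_session_slope == 0) 1 else {
      1 + within_session_slope * (seq_len(n) / n - 0.5)
    }
    for (ci in seq_len(ncomp)) {
      comp <- model$band_components[ci, ]
      if (comp$rms_uV == 0) next
      src <- band_source(n, rate, comp$center_hz, comp$bandwidth_hz)
      env <- comp$rms_uV * drift_state[ci] *
        gain_envelope(schedule, comp$workload_gain) * slope_env
      modulated <- src * env
      out <- out + mixing[, ci, drop = FALSE] %*% matrix(modulated, nrow = 1)
    }
    if (model$blink_rate_hz > 0 && model$blink_amp_uV > 0) {
      n_blinks <- stats::rpois(1, model$blink_rate_hz *
                                 schedule$session_length_s)
      if (n_blinks > 0) {
        times <- sort(stats::runif(n_blinks, 0, schedule$session_length_s))
        w <- blink_mixing_weights(chans)
        pulse_t <- seq(-0.3, 0.3, by = 1 / rate)
        pulse <- exp(-(pulse_t / 0.08)^2)   # ~200 ms blink-like deflection
        trace <- numeric(n)
        for (t0 in times) {
          i0 <- round(t0 * rate)
          idx <- i0 + seq_along(pulse)
          keep <- idx >= 1 & idx <= n
          trace[idx[keep]] <- trace[idx[keep]] + pulse[keep]
        }
        out <- out + (model$blink_amp_uV * w) %*% matrix(trace, nrow = 1)
      }
    }
    out
  })

  list(recording = eeg_recording(samples, rate, chans, subject_id,
                                 day_index, session_index, start_offset_s),
       labels = block_labels(schedule))
}

#' Generate a full multi-subject synthetic study
#'
#' Sessions are generated per subject/day/session with component RMS
#' multipliers following a cumulative log-normal walk (see
#' [drift_params()]).  Per-subject and per-session seeds are derived
#' deterministically from the master seed, so the study is reproducible
#' from `(model, schedule, drift, seed)` alone.
#'
#' @param model [signal_model_params()].
#' @param schedule [study_schedule()].
#' @param drift [drift_params()].
#' @param seed master seed.
#' @return object of class `eeg_study`: a list of sessions, each a list
#'   with `recording` and `labels`, ordered by subject, day, session.
#' @export
generate_study <- function(model, schedule, drift = drift_params(0, 0, 0),
                           seed = 1L) {
  if (!inherits(drift, "drift_params")) {
    abort_invalid("drift must be drift_params")
  }
  ncomp <- nrow(model$band_components)
  sessions <- list()
  for (s in seq_len(schedule$n_subjects)) {
    subj_seed <- derive_seed(seed, s)
    log_mult <- rep(0, ncomp)
    for (d in seq_len(schedule$days)) {
      if (d > 1 && drift$day_drift_sd > 0) {
        log_mult <- log_mult + with_seed(derive_seed(subj_seed, d, 0),
                                         stats::rnorm(ncomp, 0,
                                                      drift$day_drift_sd))
      }
      for (k in seq_len(schedule$sessions_per_day)) {
        if (k > 1 && drift$session_drift_sd > 0) {
          log_mult <- log_mult + with_seed(derive_seed(subj_seed, d, k),
                                           stats::rnorm(ncomp, 0,
                                                        drift$session_drift_sd))
        }
        offset <- (d - 1) * schedule$day_spacing_s +
          (k - 1) * schedule$session_spacing_s
        sess <- generate_session(
          model, schedule, drift_state = exp(log_mult),
          seed = derive_seed(subj_seed, d, k, 7919),
          subject_id = s, day_index = d, session_index = k,
          start_offset_s = offset,
          within_session_slope = drift$within_session_slope)
        sessions[[length(sessions) + 1L]] <- sess
      }
    }
  }
  structure(sessions, class = "eeg_study",
            schedule = schedule, model = model, drift = drift, seed = seed)
}

#' @export
print.eeg_study <- function(x, ...) {
  sc <- attr(x, "schedule")
  cat(sprintf("<eeg_study> %d sessions (%d subjects x %d days x %d/day)\n",
              length(x), sc$n_subjects, sc$days, sc$sessions_per_day))
  invisible(x)
}
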