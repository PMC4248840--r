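# Evaluation protocols: same-session temporal performance, cross-session
# transfer at minutes/hours/days scales, leave-one-out cross-validation,
# the chance-level resampler, and the binomial statistics for paired
# noise-vs-no-noise run comparisons.
#
# All temporal protocols are causal by construction: networks are trained
# on epochs from the start of a session and tested only on epochs (or
# sessions) strictly later in time.

#' Protocol configuration
#'
#' @param train_epochs_per_class epochs per class taken from the start of
#'   each class block for training (default 20, i.e. 125 s at the default
#'   epoching).
#' @param test_window_epochs sliding test-window length in epochs
#'   (default 11, i.e. 80 s).
#' @param test_window_step_epochs step between consecutive test windows.
#' @param rms_levels noise RMS levels (microvolts) for noise sweeps.
#' @param n_chance_runs resampling runs for the chance-level estimate.
#' @param chance_seed seed for the chance resampler.
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(train_epochs_per_class = 20L,
                            test_window_epochs = 11L,
                            test_window_step_epochs = 1L,
                            rms_levels = c(0, 5, 10, 20),
                            n_chance_runs = 1000L,
                            chance_seed = 1L) {
  for (nm in c("train_epochs_per_class", "test_window_epochs",
               "test_window_step_epochs", "n_chance_runs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      abort_invalid("'%s' must be >= 1", nm)
    }
  }
  structure(list(train_epochs_per_class = as.integer(train_epochs_per_class),
                 test_window_epochs = as.integer(test_window_epochs),
                 test_window_step_epochs = as.integer(test_window_step_epochs),
                 rms_levels = rms_levels,
                 n_chance_runs = as.integer(n_chance_runs),
                 chance_seed = as.integer(chance_seed)),
            class = "protocol_config")
}

# Row indices of the first `n_train` epochs of each class (training
# vectors) and the remaining per-class test rows, preserving time order.
session_training_split <- function(features, protocol = protocol_config()) {
  n_train <- protocol$train_epochs_per_class
  split <- list(train = integer(0), test = list())
  for (cl in NET_CLASSES) {
    idx <- which(features$labels == cl)
    if (length(idx) < n_train + protocol$test_window_epochs) {
      abort_invalid(
        "class '%s' has %d epochs; need >= %d (%d training + %d test window)",
        cl, length(idx), n_train + protocol$test_window_epochs,
        n_train, protocol$test_window_epochs)
    }
    split$train <- c(split$train, idx[seq_len(n_train)])
    split$test[[cl]] <- idx[-seq_len(n_train)]
  }
  split$train <- sort(split$train)
  split
}

#' Train a network on the opening epochs of one session
#'
#' Uses the first `train_epochs_per_class` epochs of each class block
#' (the session's training segment); the rest of the session remains
#' untouched as prospective test data.
#'
#' @param features session [extract_features()] output.
#' @param protocol [protocol_config()].
#' @param net_cfg [net_config()].
#' @return [train_workload_net()] result.
#' @export
train_session_net <- function(features, protocol = protocol_config(),
                              net_cfg = net_config()) {
  split <- session_training_split(features, protocol)
  train_workload_net(subset_features(features, split$train), net_cfg)
}

#' Same-session temporal evaluation
#'
#' Trains a network on the first `train_epochs_per_class` epochs of each
#' class block and evaluates sliding `test_window_epochs`-epoch windows
#' over the remaining epochs of each class stream, indexed by the time
#' gap between the end of the training data and the end of the test
#' window.  Window accuracies are pooled across the class streams by gap.
#'
#' @param recording,labels the session (or pass `features`).
#' @param epoching [epoching_config()].
#' @param protocol [protocol_config()].
#' @param net_cfg [net_config()].
#' @param features optional precomputed [extract_features()] output.
#' @param predict_fun optional `function(feature_set)` returning classes,
#'   substituted for the trained network (e.g. an oracle classifier in
#'   tests).
#' @return list with `windows` (per-window data.frame: class, gap_s,
#'   accuracy), `curve` (per-gap mean accuracy and mean absolute
#'   deviation), `overall` (mean over windows), `net`, `train_end_s`.
#' @export
same_session_protocol <- function(recording = NULL, labels = NULL,
                                  epoching = epoching_config(),
                                  protocol = protocol_config(),
                                  net_cfg = net_config(),
                                  features = NULL,
                                  predict_fun = NULL) {
  if (is.null(features)) {
    features <- extract_features(recording, labels, epoching)
  }
  split <- session_training_split(features, protocol)
  net <- NULL
  if (is.null(predict_fun)) {
    net <- train_workload_net(subset_features(features, split$train),
                              net_cfg)
    predict_fun <- function(fs) predict(net, fs)
  }
  win <- protocol$test_window_epochs
  step <- protocol$test_window_step_epochs
  rows <- list()
  for (cl in NET_CLASSES) {
    test_idx <- split$test[[cl]]
    # End of this class's training data: last training epoch + window.
    train_cl <- which(features$labels == cl)[
      seq_len(protocol$train_epochs_per_class)]
    train_end <- max(features$epoch_start_s[train_cl]) + epoching$window_s
    preds <- predict_fun(subset_features(features, test_idx))
    correct <- preds == features$labels[test_idx]
    w0 <- seq(1, length(test_idx) - win + 1, by = step)
    for (s0 in w0) {
      wi <- s0:(s0 + win - 1)
      gap <- features$epoch_start_s[test_idx[wi[win]]] +
        epoching$window_s - train_end
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, gap_s = gap, accuracy = mean(correct[wi]))
    }
  }
  windows <- do.call(rbind, rows)
  curve <- do.call(rbind, lapply(split(windows, windows$gap_s), function(d) {
    data.frame(gap_s = d$gap_s[1], mean_acc = mean(d$accuracy),
               mad = mean(abs(d$accuracy - mean(d$accuracy))),
               n = nrow(d))
  }))
  curve <- curve[order(curve$gap_s), ]
  rownames(curve) <- NULL
  train_end_s <- max(features$epoch_start_s[split$train]) +
    epoching$window_s
  list(windows = windows, curve = curve,
       overall = mean(windows$accuracy), net = net,
       train_end_s = train_end_s)
}

#' Extract features for every session of a study
#'
#' @param study [generate_study()] output (or any list of sessions with
#'   `recording` and `labels`).
#' @param epoching [epoching_config()].
#' @return list of [extract_features()] outputs, same order as `study`.
#' @export
study_features <- function(study, epoching = epoching_config()) {
  lapply(study, function(s)
    extract_features(s$recording, s$labels, epoching))
}

session_meta <- function(study) {
  do.call(rbind, lapply(seq_along(study), function(i) {
    r <- study[[i]]$recording
    data.frame(index = i, subject = r$subject_id, day = r$day_index,
               session = r$session_index, offset_s = r$start_offset_s)
  }))
}

#' Train-test session pairings for cross-session transfer
#'
#' Pure schedule arithmetic, testable without generating any signal:
#' \describe{
#'   \item{minutes}{first session of each day tested on the second
#'     session of that day;}
#'   \item{hours}{first session of each day tested on the last session of
#'     that day;}
#'   \item{days}{the very first session tested on every later session.}
#' }
#' Pairings are subject-specific and strictly prospective.
#'
#' @param meta data.frame with columns `index`, `subject`, `day`,
#'   `session`, `offset_s` (see [cross_session_protocol()]), or a
#'   [study_schedule()] from which the nominal structure is expanded.
#' @param scale one of "minutes", "hours", "days".
#' @return data.frame with columns `subject`, `train_index`,
#'   `test_index`, `gap_s`.
#' @export
cross_session_pairs <- function(meta, scale = c("minutes", "hours", "days")) {
  scale <- match.arg(scale)
  if (inherits(meta, "study_schedule")) meta <- schedule_meta(meta)
  pairs <- list()
  for (subj in unique(meta$subject)) {
    ms <- meta[meta$subject == subj, , drop = FALSE]
    ms <- ms[order(ms$offset_s), , drop = FALSE]
    if (scale %in% c("minutes", "hours")) {
      for (d in sort(unique(ms$day))) {
        day_rows <- ms[ms$day == d, , drop = FALSE]
        if (nrow(day_rows) < 2) {
          abort_invalid("subject %s day %d has %d session(s); %s scale needs >= 2",
                        subj, d, nrow(day_rows), scale)
        }
        tr <- day_rows[1, ]
        te <- if (scale == "minutes") day_rows[2, ] else
          day_rows[nrow(day_rows), ]
        pairs[[length(pairs) + 1L]] <- data.frame(
          subject = subj, train_index = tr$index, test_index = te$index,
          gap_s = te$offset_s - tr$offset_s)
      }
    } else {
      tr <- ms[1, ]
      if (nrow(ms) < 2) {
        abort_invalid("subject %s has a single session; days scale needs >= 2",
                      subj)
      }
      for (i in 2:nrow(ms)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          subject = subj, train_index = tr$index,
          test_index = ms$index[i], gap_s = ms$offset_s[i] - tr$offset_s)
      }
    }
  }
  do.call(rbind, pairs)
}

schedule_meta <- function(schedule) {
  rows <- list()
  i <- 0L
  for (s in seq_len(schedule$n_subjects)) {
    for (d in seq_len(schedule$days)) {
      for (k in seq_len(schedule$sessions_per_day)) {
        i <- i + 1L
        rows[[i]] <- data.frame(
          index = i, subject = s, day = d, session = k,
          offset_s = (d - 1) * schedule$day_spacing_s +
            (k - 1) * schedule$session_spacing_s)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cross-session transfer evaluation
#'
#' Re-uses networks trained on the opening training segment of one
#' session (as in [same_session_protocol()]) to classify every epoch of a
#' later session of the same subject.  The test session is not split: all
#' its high/low epochs are test data.
#'
#' @param study session list ([generate_study()] output).
#' @param scale "minutes", "hours" or "days" (see
#'   [cross_session_pairs()]).
#' @param epoching,protocol,net_cfg configurations.
#' @param features_list optional precomputed [study_features()] output.
#' @param nets optional list of pre-trained nets indexed by session
#'   number (entries for non-training sessions may be NULL); missing nets
#'   are trained on demand.
#' @return data.frame with one row per train/test session pair:
#'   `subject`, train/test day and session indices, `gap_s`, `accuracy`.
#' @export
cross_session_protocol <- function(study,
                                   scale = c("minutes", "hours", "days"),
                                   epoching = epoching_config(),
                                   protocol = protocol_config(),
                                   net_cfg = net_config(),
                                   features_list = NULL,
                                   nets = NULL) {
  scale <- match.arg(scale)
  if (is.null(features_list)) features_list <- study_features(study, epoching)
  meta <- session_meta(study)
  pairs <- cross_session_pairs(meta, scale)
  if (is.null(nets)) nets <- vector("list", length(study))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    tr <- pairs$train_index[i]; te <- pairs$test_index[i]
    if (is.null(nets[[tr]])) {
      nets[[tr]] <- train_session_net(features_list[[tr]], protocol, net_cfg)
    }
    preds <- predict(nets[[tr]], features_list[[te]])
    acc <- accuracy(preds, features_list[[te]]$labels)
    out[[i]] <- data.frame(
      subject = pairs$subject[i],
      train_day = meta$day[tr], train_session = meta$session[tr],
      test_day = meta$day[te], test_session = meta$session[te],
      gap_s = pairs$gap_s[i], accuracy = acc)
  }
  res <- do.call(rbind, out)
  attr(res, "nets") <- nets
  res
}

#' Leave-one-out cross-validated average performance
#'
#' For each subject and each held-out session: train on the features of
#' all the subject's other sessions, test on every epoch of the held-out
#' session.  This is the time-independent (non-causal) average protocol.
#'
#' @param study session list.
#' @param epoching,net_cfg configurations.
#' @param features_list optional precomputed [study_features()] output.
#' @return list with `folds` (per-fold data.frame), `per_subject` mean
#'   accuracies, and `overall` (mean of per-subject means).
#' @export
loocv_protocol <- function(study, epoching = epoching_config(),
                           net_cfg = net_config(),
                           features_list = NULL) {
  if (is.null(features_list)) features_list <- study_features(study, epoching)
  meta <- session_meta(study)
  folds <- list()
  for (subj in unique(meta$subject)) {
    idx <- meta$index[meta$subject == subj]
    if (length(idx) < 2) {
      abort_invalid("subject %s has a single session; leave-one-out needs >= 2",
                    subj)
    }
    for (held in idx) {
      train_fs <- combine_features(features_list[setdiff(idx, held)])
      net <- train_workload_net(train_fs, net_cfg)
      preds <- predict(net, features_list[[held]])
      folds[[length(folds) + 1L]] <- data.frame(
        subject = subj, held_out = held,
        accuracy = accuracy(preds, features_list[[held]]$labels))
    }
  }
  folds <- do.call(rbind, folds)
  per_subject <- tapply(folds$accuracy, folds$subject, mean)
  list(folds = folds, per_subject = per_subject,
       overall = mean(per_subject))
}

#' Per-session test-epoch structure of a schedule
#'
#' Expands a schedule into the per-session true-label vectors the
#' protocols would see (one "high"/"low" entry per analyzable epoch),
#' without generating any signal.  This is the input to the chance-level
#' resampler.
#'
#' @param schedule [study_schedule()].
#' @param epoching [epoching_config()].
#' @return list with one character vector of epoch labels per session.
#' @export
study_test_structure <- function(schedule = study_schedule(),
                                 epoching = epoching_config()) {
  bp <- schedule$block_plan
  session_labels <- unlist(lapply(seq_len(nrow(bp)), function(i) {
    if (bp$state[i] == "transition") return(character(0))
    k <- length(epoch_slices(bp$duration_s[i], epoching))
    rep(bp$state[i], k)
  }))
  n_sessions <- schedule$n_subjects * schedule$days *
    schedule$sessions_per_day
  rep(list(session_labels), n_sessions)
}

#' Chance-level accuracy by resampling a random classifier
#'
#' Replaces the network's output with a uniform random classifier (each
#' epoch equally likely to be called high or low regardless of the true
#' class balance) and analyzes it exactly like the real pipeline:
#' per-session accuracy, averaged over sessions within a run, then
#' summarized over runs.
#'
#' @param test_structure list of per-session true-label vectors (see
#'   [study_test_structure()]).
#' @param n_runs number of resampling runs (default 1000).
#' @param seed resampling seed.
#' @return list with `mean_acc` (mean over runs), `max_acc` (best run)
#'   and `per_run` accuracies.
#' @export
chance_resample <- function(test_structure, n_runs = 1000L, seed = 1L) {
  if (length(test_structure) == 0 ||
      sum(lengths(test_structure)) == 0) {
    abort_invalid("test_structure contains no epochs")
  }
  if (n_runs < 1) abort_invalid("n_runs must be >= 1")
  truth <- unlist(test_structure)
  session_id <- rep(seq_along(test_structure), lengths(test_structure))
  n_epochs <- length(truth)
  truth_high <- truth == "high"
  per_run <- with_seed(seed, vapply(seq_len(n_runs), function(run) {
    calls_high <- stats::runif(n_epochs) < 0.5
    correct <- calls_high == truth_high
    mean(tapply(correct, session_id, mean))
  }, numeric(1)))
  list(mean_acc = mean(per_run), max_acc = max(per_run), per_run = per_run)
}

#' Probability that all runs succeed under a binomial model
#'
#' Under a Binomial(n, p) model for the number of noise-enhanced runs
#' beating the no-noise baseline, the probability that all `n_runs` runs
#' succeed is `p^n_runs`.
#'
#' @param n_runs number of independent runs.
#' @param p per-run success probability.
#' @return `p^n_runs`.
#' @export
binomial_all_success_prob <- function(n_runs, p) {
  if (n_runs < 1) abort_invalid("n_runs must be >= 1")
  if (!is.numeric(p) || p < 0 || p > 1) {
    abort_invalid("p must be in [0, 1]")
  }
  p^n_runs
}

#' Exact (Clopper-Pearson) lower confidence bound for a proportion
#'
#' Lower limit of the exact two-sided confidence interval obtained by
#' inverting the binomial tail probability (the beta quantile form).  For
#' `successes == trials == n` this equals `(alpha/2)^(1/n)` with
#' `alpha = 1 - confidence`.
#'
#' @param successes,trials observed counts.
#' @param confidence two-sided confidence level (default 0.95).
#' @return lower bound of the interval.
#' @export
exact_binomial_ci_lower <- function(successes, trials, confidence = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    abort_invalid("need 0 <= successes <= trials with trials >= 1")
  }
  if (confidence <= 0 || confidence >= 1) {
    abort_invalid("confidence must be in (0, 1)")
  }
  if (successes == 0) return(0)
  alpha <- 1 - confidence
  stats::qbeta(alpha / 2, successes, trials - successes + 1)
}

#' Paired noise-vs-no-noise run comparison
#'
#' Computes the no-noise baseline accuracy of the supplied nets on their
#' test sessions, then performs `n_runs` independent runs of the
#' noise-injection ensemble (fresh noise realizations per run) and counts
#' the runs whose accuracy strictly exceeds the baseline.
#'
#' @param nets list of trained nets, one per test session (recycled if
#'   length 1).
#' @param sessions list of test sessions, each a list with `recording`
#'   and `labels`.
#' @param epoching [epoching_config()].
#' @param rms_uV noise RMS for the noisy runs.
#' @param n_runs number of independent ensemble runs (default 10).
#' @param seed master seed; run r of session i uses an independently
#'   derived noise seed.
#' @param ensemble [ensemble_config()].
#' @return list with `no_noise_acc`, `run_accs` (length `n_runs`), and
#'   `successes` (runs strictly better than baseline).
#' @export
compare_noise_runs <- function(nets, sessions,
                               epoching = epoching_config(),
                               rms_uV = 5, n_runs = 10L, seed = 1L,
                               ensemble = ensemble_config()) {
  if (length(nets) == 1L) nets <- rep(nets, length(sessions))
  if (length(nets) != length(sessions)) {
    abort_invalid("need one net per test session (or a single net)")
  }
  feats <- lapply(sessions, function(s)
    extract_features(s$recording, s$labels, epoching))
  base_accs <- vapply(seq_along(sessions), function(i) {
    accuracy(predict(nets[[i]], feats[[i]]), feats[[i]]$labels)
  }, numeric(1))
  no_noise_acc <- mean(base_accs)
  run_accs <- vapply(seq_len(n_runs), function(r) {
    accs <- vapply(seq_along(sessions), function(i) {
      preds <- ensemble_predict(
        nets[[i]], sessions[[i]]$recording, sessions[[i]]$labels,
        epoching, noise_config(rms_uV, seed = derive_seed(seed, r, i)),
        ensemble)
      accuracy(preds, feats[[i]]$labels)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  list(no_noise_acc = no_noise_acc, run_accs = run_accs,
       successes = sum(run_accs > no_noise_acc))
}
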