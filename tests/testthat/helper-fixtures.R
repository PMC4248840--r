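# Shared fixtures, built in code.  The heavyweight ones (a full 21-channel
# session with extracted features and a trained net) are memoized so the
# whole suite pays for them once.

.fixtures <- new.env(parent = emptyenv())

# A short two-block session schedule: high/low blocks of `block_s` seconds
# separated by a 60 s transition.
short_schedule <- function(block_s = 200, n_subjects = 1, days = 1,
                           sessions_per_day = 1,
                           channel_labels = NULL, ...) {
  args <- list(
    n_subjects = n_subjects, days = days,
    sessions_per_day = sessions_per_day,
    session_length_s = 2 * block_s + 60,
    block_plan = data.frame(
      state = c("high", "transition", "low"),
      duration_s = c(block_s, 60, block_s)), ...)
  if (!is.null(channel_labels)) args$channel_labels <- channel_labels
  do.call(study_schedule, args)
}

# Three-channel schedule for tests that only need a light signal.
light_schedule <- function(block_s = 30, ...) {
  short_schedule(block_s = block_s,
                 channel_labels = c("Fz", "Pz", "O1"), ...)
}

# Memoized 21-channel session (200 s blocks), its features and a net
# trained on the session's opening epochs.
fixture_session <- function() {
  if (is.null(.fixtures$sess)) {
    sched <- short_schedule()
    sess <- generate_session(signal_model_params(), sched, seed = 101)
    feats <- extract_features(sess$recording, sess$labels)
    .fixtures$sched <- sched
    .fixtures$sess <- sess
    .fixtures$feats <- feats
    .fixtures$net <- train_session_net(feats)
  }
  .fixtures
}

# Synthetic two-cluster feature set: class means separated by `sep`
# within-cluster standard deviations along every informative dimension.
make_cluster_features <- function(n_per_class = 20, sep = 10, p = 12,
                                  n_informative = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), nrow = n)
  labels <- rep(c("high", "low"), each = n_per_class)
  shift <- c(rep(sep / 2, n_informative), rep(0, p - n_informative))
  x <- x + outer(ifelse(labels == "high", 1, -1), shift)
  colnames(x) <- paste0("f", seq_len(p))
  structure(list(matrix = x,
                 epoch_start_s = seq(0, by = 5, length.out = n),
                 labels = labels,
                 feature_names = colnames(x)),
            class = "feature_set")
}
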