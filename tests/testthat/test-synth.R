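test_that("session generation is deterministic and dimensioned by the schedule", {
  sched <- light_schedule()
  model <- signal_model_params(blink_rate_hz = 0)
  a <- generate_session(model, sched, seed = 7)
  b <- generate_session(model, sched, seed = 7)
  c <- generate_session(model, sched, seed = 8)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_false(identical(a$recording$samples, c$recording$samples))
  expect_equal(ncol(a$recording$samples),
               sched$session_length_s * sched$sampling_rate_hz)
  expect_equal(nrow(a$recording$samples), length(sched$channel_labels))
  iv <- a$labels$intervals
  expect_equal(max(iv$end_s), sched$session_length_s)
  expect_setequal(iv$state, c("high", "transition", "low"))
})

test_that("schedule invariants are enforced with structured errors", {
  expect_error(
    study_schedule(session_length_s = 100,
                   block_plan = data.frame(state = "high",
                                           duration_s = 90)),
    "sum", class = "workloadbci_invalid")
  expect_error(
    study_schedule(session_length_s = 230,
                   block_plan = data.frame(
                     state = c("high", "transition", "low"),
                     duration_s = c(100, 30, 100))),
    "60 s", class = "workloadbci_invalid")
  # all-equal workload gains make the classes indistinguishable
  expect_error(
    signal_model_params(band_components = data.frame(
      name = "a", center_hz = 10, bandwidth_hz = 4, rms_uV = 5,
      workload_gain = 1)),
    "indistinguishable", class = "workloadbci_invalid")
  expect_error(
    signal_model_params(band_components = data.frame(
      name = "a", center_hz = 10, bandwidth_hz = 4, rms_uV = 5,
      workload_gain = -2)),
    "> 0", class = "workloadbci_invalid")
})

test_that("background-only recording matches the target RMS on every channel", {
  sched <- light_schedule(block_s = 60)
  model <- signal_model_params(
    background_rms_uV = 30, blink_rate_hz = 0,
    band_components = data.frame(name = "a", center_hz = 10,
                                 bandwidth_hz = 4, rms_uV = 0,
                                 workload_gain = 0.5))
  sess <- generate_session(model, sched, seed = 3)
  rms <- apply(sess$recording$samples, 1, sd)
  expect_true(all(abs(rms - 30) / 30 < 0.05))
})

test_that("workload gain scales band power by gain squared", {
  # alpha gain 0.5 in the high state: alpha-band power in high blocks
  # should be ~0.25x the low blocks (power goes as RMS^2).
  sched <- short_schedule(block_s = 300,
                          channel_labels = c("Fz", "Pz", "O1"))
  model <- signal_model_params(
    background_rms_uV = 0, blink_rate_hz = 0,
    band_components = data.frame(name = "alpha", center_hz = 9.5,
                                 bandwidth_hz = 5, rms_uV = 10,
                                 workload_gain = 0.5))
  sess <- generate_session(model, sched, seed = 5)
  fs <- extract_features(sess$recording, sess$labels)
  alpha_cols <- grep("7-12Hz", colnames(fs$matrix))
  ratio <- mean(fs$matrix[fs$labels == "high", alpha_cols]) /
    mean(fs$matrix[fs$labels == "low", alpha_cols])
  expect_lt(abs(ratio - 0.25) / 0.25, 0.15)
})

test_that("background spectrum has the configured 1/f slope over 1-100 Hz", {
  sched <- study_schedule(
    n_subjects = 1, days = 1, sessions_per_day = 1,
    session_length_s = 256,
    block_plan = data.frame(state = "low", duration_s = 256),
    channel_labels = "Cz")
  for (k in c(1, 1.5)) {
    model <- signal_model_params(
      background_exponent = k, background_rms_uV = 30, blink_rate_hz = 0,
      band_components = data.frame(name = "a", center_hz = 10,
                                   bandwidth_hz = 4, rms_uV = 0,
                                   workload_gain = 0.5),
      channel_mixing = matrix(0, 1, 1))
    x <- generate_session(model, sched, seed = 11)$recording$samples[1, ]
    nfft <- 4096
    nseg <- length(x) %/% nfft
    P <- rowMeans(vapply(seq_len(nseg), function(i)
      Mod(stats::fft(x[((i - 1) * nfft + 1):(i * nfft)]))[1:(nfft / 2)]^2,
      numeric(nfft / 2)))
    f <- (0:(nfft / 2 - 1)) * 256 / nfft
    sel <- f >= 1 & f <= 100
    slope <- unname(coef(lm(log(P[sel]) ~ log(f[sel])))[2])
    expect_lt(abs(slope - (-k)), 0.3)
  }
})

test_that("blink transients land on EOG channels at 10x the EEG weight", {
  sched <- short_schedule(block_s = 30,
                          channel_labels = c("Cz", "EOGv"))
  base <- signal_model_params(blink_rate_hz = 0)
  blinky <- signal_model_params(blink_rate_hz = 1, blink_amp_uV = 200)
  a <- generate_session(base, sched, seed = 21)$recording$samples
  b <- generate_session(blinky, sched, seed = 21)$recording$samples
  blink_part <- b - a   # same seed: background/components identical draws
  expect_gt(max(abs(blink_part["EOGv", ])), 0)
  expect_equal(max(abs(blink_part["EOGv", ])) /
                 max(abs(blink_part["Cz", ])), 10)
})

test_that("study generation enumerates subjects x days x sessions deterministically", {
  sched <- light_schedule(block_s = 30, n_subjects = 2, days = 2,
                          sessions_per_day = 2)
  model <- signal_model_params(blink_rate_hz = 0)
  st <- generate_study(model, sched, drift_params(0, 0, 0), seed = 9)
  expect_length(st, 8)
  meta <- do.call(rbind, lapply(st, function(s)
    data.frame(sub = s$recording$subject_id, day = s$recording$day_index,
               ses = s$recording$session_index)))
  expect_equal(nrow(unique(meta)), 8)
  st2 <- generate_study(model, sched, drift_params(0, 0, 0), seed = 9)
  expect_identical(st[[5]]$recording$samples, st2[[5]]$recording$samples)
  # subjects get different signals
  expect_false(identical(st[[1]]$recording$samples,
                         st[[5]]$recording$samples))
})

test_that("zero-drift studies show no feature trend across sessions", {
  # 20 replicate mini-studies; per replicate, regress the per-session mean
  # log total power on session index and test at alpha = 0.01.  Under
  # stationarity the rejection count over 20 replicates stays small.
  sched <- light_schedule(block_s = 30, days = 2, sessions_per_day = 3)
  model <- signal_model_params(blink_rate_hz = 0)
  rejections <- 0L
  for (rep in 1:20) {
    st <- generate_study(model, sched, drift_params(0, 0, 0), seed = rep)
    m <- vapply(seq_along(st), function(i) {
      fs <- extract_features(st[[i]]$recording, st[[i]]$labels)
      mean(log(rowSums(fs$matrix)))
    }, numeric(1))
    p <- summary(lm(m ~ seq_along(m)))$coefficients[2, 4]
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 3)
})
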