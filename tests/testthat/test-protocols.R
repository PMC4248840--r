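test_that("same-session training and test windows have the stated spans", {
  fx <- fixture_session()
  fs <- fx$feats
  split <- workloadbci:::session_training_split(fs)
  expect_length(split$train, 40)
  for (cl in c("high", "low")) {
    tr <- intersect(split$train, which(fs$labels == cl))
    expect_length(tr, 20)
    # 20 epochs at 5 s steps + 30 s window span 125 s of signal
    span <- max(fs$epoch_start_s[tr]) - min(fs$epoch_start_s[tr]) + 30
    expect_equal(span, 125)
  }
  ss <- same_session_protocol(features = fs,
                              predict_fun = function(f) f$labels)
  # an 11-epoch window spans 80 s
  win_rows <- ss$windows
  expect_equal(unique(diff(sort(unique(win_rows$gap_s)))), 5)
  expect_true(all(win_rows$accuracy == 1))   # oracle classifier
  expect_equal(ss$overall, 1)
  expect_true(all(ss$curve$mean_acc == 1 & ss$curve$mad == 0))
  # causality: every test window ends after the training data
  expect_true(all(win_rows$gap_s > 0))
})

test_that("insufficient epochs per class are reported by block", {
  fx <- fixture_session()
  few <- workloadbci:::subset_features(fx$feats, 1:45)
  expect_error(same_session_protocol(features = few), "class",
               class = "workloadbci_invalid")
})

test_that("cross-session pairings follow the minutes/hours/days definitions", {
  sched <- study_schedule()   # 8 subjects x 5 days x 3 sessions
  for (scale in c("minutes", "hours")) {
    p <- cross_session_pairs(sched, scale)
    expect_equal(nrow(p), 8 * 5)
    expect_true(all(p$gap_s > 0))
  }
  p_min <- cross_session_pairs(sched, "minutes")
  p_hr <- cross_session_pairs(sched, "hours")
  expect_true(all(p_hr$gap_s >= p_min$gap_s))
  # days: the very first session against all 14 later sessions
  p_days <- cross_session_pairs(sched, "days")
  expect_equal(as.integer(table(p_days$subject)), rep(14, 8))
  expect_true(all(p_days$gap_s > 0))
  one <- study_schedule(sessions_per_day = 1, session_length_s = 660,
                        block_plan = data.frame(
                          state = c("high", "transition", "low"),
                          duration_s = c(300, 60, 300)))
  expect_error(cross_session_pairs(one, "minutes"),
               class = "workloadbci_invalid")
})

test_that("testing a copy of the training session reproduces its accuracy", {
  fx <- fixture_session()
  sess <- fx$sess
  copy <- sess
  copy$recording$session_index <- 2L
  copy$recording$start_offset_s <- 1800
  study <- list(sess, copy)
  cs <- cross_session_protocol(study, "minutes")
  net <- attr(cs, "nets")[[1]]
  expect_equal(nrow(cs), 1)
  expect_equal(cs$accuracy,
               accuracy(predict(net, fx$feats), fx$feats$labels))
})

test_that("leave-one-out folds cover each session once and copies tie", {
  fx <- fixture_session()
  base <- fx$sess
  study <- lapply(1:3, function(k) {
    s <- base
    s$recording$session_index <- k
    s$recording$start_offset_s <- (k - 1) * 1800
    s
  })
  lo <- loocv_protocol(study, net_cfg = net_config(n_restarts = 2))
  expect_equal(nrow(lo$folds), 3)
  expect_equal(sort(lo$folds$held_out), 1:3)
  # identical sessions: identical training sets per fold -> equal accuracy
  expect_equal(length(unique(lo$folds$accuracy)), 1)
  expect_error(loocv_protocol(study[1]), class = "workloadbci_invalid")
})

test_that("chance resampling behaves like a fair coin analyzed per session", {
  # single epoch, single run: reproducible and in {0, 1}
  one <- chance_resample(list("high"), n_runs = 1, seed = 5)
  expect_true(one$mean_acc %in% c(0, 1))
  expect_identical(one, chance_resample(list("high"), 1, seed = 5))
  # all-high labels, fair coin: converges to 50%
  st <- rep(list(rep("high", 100)), 5)
  ch <- chance_resample(st, n_runs = 1000, seed = 2)
  se <- 0.5 / sqrt(1000 * 500)
  expect_lt(abs(ch$mean_acc - 0.5), 5 * se)
  # per-run spread matches the binomial standard error
  expect_lt(abs(sd(ch$per_run) - 0.5 / sqrt(500)) / (0.5 / sqrt(500)),
            0.2)
  expect_gte(ch$max_acc, ch$mean_acc)
  expect_error(chance_resample(list(), 10), class = "workloadbci_invalid")
})

test_that("binomial run statistics match their closed forms", {
  expect_equal(binomial_all_success_prob(10, 0.5), 0.5^10)
  expect_equal(binomial_all_success_prob(1, 0.5), 0.5)
  expect_equal(binomial_all_success_prob(10, 1), 1)
  expect_error(binomial_all_success_prob(10, 1.2),
               class = "workloadbci_invalid")

  expect_equal(exact_binomial_ci_lower(0, 10, 0.95), 0)
  # all-successes case equals (alpha/2)^(1/n)
  for (n in 1:20) {
    expect_equal(exact_binomial_ci_lower(n, n, 0.95), 0.025^(1 / n),
                 tolerance = 1e-10)
  }
  # general case agrees with the exact binomial test
  bt <- binom.test(7, 10, conf.level = 0.9)$conf.int[1]
  expect_equal(exact_binomial_ci_lower(7, 10, 0.9), bt,
               tolerance = 1e-10)
  expect_error(exact_binomial_ci_lower(11, 10),
               class = "workloadbci_invalid")
})

test_that("noise-run comparison is internally consistent and seeded", {
  fx <- fixture_session()
  sessions <- list(list(recording = fx$sess$recording,
                        labels = fx$sess$labels))
  cmp0 <- compare_noise_runs(list(fx$net), sessions, rms_uV = 0,
                             n_runs = 2, seed = 1,
                             ensemble = ensemble_config(n_members = 2))
  expect_true(all(cmp0$run_accs == cmp0$no_noise_acc))
  expect_equal(cmp0$successes, 0)

  cmp <- compare_noise_runs(list(fx$net), sessions, rms_uV = 2,
                            n_runs = 2, seed = 1,
                            ensemble = ensemble_config(n_members = 2))
  expect_equal(cmp$successes, sum(cmp$run_accs > cmp$no_noise_acc))
  cmp2 <- compare_noise_runs(list(fx$net), sessions, rms_uV = 2,
                             n_runs = 2, seed = 1,
                             ensemble = ensemble_config(n_members = 2))
  expect_identical(cmp, cmp2)
})
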