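stationary_channel <- function(duration_s, rms = 31, seed = 11) {
  # single-channel stationary recording: pure 1/f background, no
  # oscillatory components, no blinks
  sched <- study_schedule(
    n_subjects = 1, days = 1, sessions_per_day = 1,
    session_length_s = duration_s,
    block_plan = data.frame(state = "low", duration_s = duration_s),
    channel_labels = "C3")
  model <- signal_model_params(
    background_rms_uV = rms, blink_rate_hz = 0,
    band_components = data.frame(name = "a", center_hz = 10,
                                 bandwidth_hz = 4, rms_uV = 0,
                                 workload_gain = 0.5),
    channel_mixing = matrix(0, 1, 1))
  generate_session(model, sched, seed = seed)$recording
}

test_that("added noise is calibrated, independent across channels, and seeded", {
  fx <- fixture_session()
  rec <- fx$sess$recording
  expect_identical(add_noise(rec, noise_config(0))$samples, rec$samples)

  noisy <- add_noise(rec, noise_config(10, seed = 3))
  diff <- noisy$samples - rec$samples
  sec60 <- 1:(60 * 256)
  rms <- apply(diff[, sec60], 1, sd)
  expect_true(all(abs(rms - 10) / 10 < 0.02))
  cm <- cor(t(diff[1:6, sec60]))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
  # deterministic given seed
  noisy2 <- add_noise(rec, noise_config(10, seed = 3))
  expect_identical(noisy$samples, noisy2$samples)
  expect_error(noise_config(-1), class = "workloadbci_invalid")
})

test_that("majority vote picks the modal class with ties going high", {
  v <- function(nh, nl) c(rep("high", nh), rep("low", nl))
  expect_equal(majority_vote(lapply(1:10, function(i)
    if (i <= 6) "high" else "low")), "high")
  m <- rbind(v(6, 4), deparse.level = 0)
  expect_equal(majority_vote(matrix(v(6, 4), ncol = 1)), rep("high", 1))
  expect_equal(majority_vote(matrix(c(v(5, 5), v(0, 10), v(2, 8)),
                                    nrow = 10)),
               c("high", "low", "low"))
  expect_error(majority_vote(list()), class = "workloadbci_invalid")
})

test_that("the zero-noise ensemble equals the single network exactly", {
  fx <- fixture_session()
  single <- predict(fx$net, fx$feats)
  ens <- ensemble_predict(fx$net, fx$sess$recording, fx$sess$labels,
                          noise = noise_config(0),
                          ensemble = ensemble_config(n_members = 3))
  expect_identical(ens, single)
})

test_that("a one-member ensemble equals prediction on one noisy copy", {
  fx <- fixture_session()
  noise <- noise_config(5, seed = 9)
  ens <- ensemble_predict(fx$net, fx$sess$recording, fx$sess$labels,
                          noise = noise,
                          ensemble = ensemble_config(n_members = 1))
  member_seed <- workloadbci:::derive_seed(
    9, 1, fx$sess$recording$day_index, fx$sess$recording$session_index)
  noisy <- add_noise(fx$sess$recording, noise_config(5, seed = member_seed))
  manual <- predict(fx$net,
                    extract_features(noisy, fx$sess$labels))
  expect_identical(ens, manual)
})

test_that("ensemble output is stable across master seeds on separable data", {
  fx <- fixture_session()
  p1 <- ensemble_predict(fx$net, fx$sess$recording, fx$sess$labels,
                         noise = noise_config(5, seed = 1),
                         ensemble = ensemble_config(n_members = 5))
  p2 <- ensemble_predict(fx$net, fx$sess$recording, fx$sess$labels,
                         noise = noise_config(5, seed = 2),
                         ensemble = ensemble_config(n_members = 5))
  expect_gte(mean(p1 == p2), 0.9)
})

test_that("clean-vs-noisy correlation matches the additive-noise attenuation", {
  rec <- stationary_channel(1800, rms = 31)
  cc <- correlation_vs_section_length(rec, noise_config(15, seed = 5),
                                      c(600))
  expected <- 1 / sqrt(1 + 15^2 / 31^2)   # ~0.900
  expect_lt(abs(cc$median - expected), 0.02)

  cc0 <- correlation_vs_section_length(rec, noise_config(0), c(10, 600))
  expect_true(all(cc0$min == 1 & cc0$max == 1))
  expect_error(
    correlation_vs_section_length(rec, noise_config(5), 4000),
    class = "workloadbci_invalid")
})

test_that("short sections underestimate the median correlation", {
  worse <- 0L
  for (rep in 1:20) {
    rec <- stationary_channel(64, rms = 31, seed = rep + 50)
    cc <- correlation_vs_section_length(rec, noise_config(15, seed = rep),
                                        c(1, 64))
    if (cc$median[1] <= cc$median[2]) worse <- worse + 1L
  }
  expect_gte(worse, 15)   # consistent tendency, not a per-draw guarantee
})

test_that("median correlation rises monotonically as noise shrinks", {
  rec <- stationary_channel(300, rms = 31, seed = 123)
  meds <- vapply(c(20, 10, 5, 0), function(r)
    correlation_vs_section_length(rec, noise_config(r, seed = 4),
                                  60)$median,
    numeric(1))
  expect_false(is.unsorted(meds))
  expect_equal(meds[4], 1)
})
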