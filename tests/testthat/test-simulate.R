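test_that("identical seeds give bit-identical sessions", {
  cfg <- simulation_config(sampling_rate_hz = 250, n_trials = 6,
                           n_channels = 2, rng_seed = 7)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_session(simulation_config(sampling_rate_hz = 250,
                                           n_trials = 6, n_channels = 2,
                                           rng_seed = 8))
  expect_false(identical(s1$recording$data, s3$recording$data))
})

test_that("event table honours the Sternberg timing", {
  s <- quick_session(3, n_trials = 25)
  ev <- s$events
  gap12 <- ev$onset2_s - ev$onset1_s - 0.7
  gap23 <- ev$onset3_s - ev$onset2_s - 0.7
  expect_true(all(gap12 >= 0.275 & gap12 <= 0.350))
  expect_true(all(gap23 >= 0.275 & gap23 <= 0.350))
  # 2 s maintenance between last letter offset and probe
  expect_equal(ev$probe_onset_s - (ev$onset3_s + 0.7), rep(2, 25))
  expect_true(all(diff(t(cbind(ev$onset1_s, ev$onset2_s, ev$onset3_s,
                               ev$probe_onset_s))) > 0))
  # letters within a trial are distinct
  expect_true(all(apply(cbind(ev$letter1, ev$letter2, ev$letter3), 1,
                        function(l) !anyDuplicated(l))))
})

test_that("16-letter set yields 120 unordered pairs", {
  s <- quick_session(5, n_trials = 20)
  letters_seen <- unique(c(s$events$letter1, s$events$letter2,
                           s$events$letter3))
  expect_true(all(letters_seen %in% LETTERS[1:16]))
  expect_equal(choose(length(LETTERS[1:16]), 2), 120)
})

test_that("null configuration plants nothing and refuses phase read-back", {
  s <- quick_session(11, n_trials = 6, phase_concentration = 0,
                     tuned_gamma_gain = 1)
  expect_false(any(s$truth$channels$selective))
  expect_false(s$truth$phase_code_planted)
  expect_error(planted_phase_profile(s$truth, 1), "no phase code")
})

test_that("planted phase centres read back and increase with position", {
  s <- quick_session(11, n_trials = 6)
  phases <- vapply(1:3, planted_phase_profile, numeric(1), truth = s$truth)
  expect_equal(phases[1], s$truth$config$position_phase_centers_rad[1])
  expect_true(all(diff(phases) > 0))
})

test_that("maintenance burst phases are uniform when no phase code is planted", {
  ps <- vapply(1:8, function(seed) {
    s <- quick_session(100 + seed, n_trials = 40, phase_concentration = 0)
    ph <- s$truth$bursts$phase[s$truth$bursts$period == "maintenance"]
    expect_gt(length(ph), 400)
    thetaseq:::rayleigh_test(ph)
  }, numeric(1))
  expect_true(mean(ps > 0.01) >= 0.95)
})

test_that("maintenance burst phases concentrate on the planted centre", {
  s <- quick_session(13, n_trials = 40, phase_concentration = 6,
                     tuned_positions = rep(2L, 40))
  b <- s$truth$bursts
  ph <- b$phase[b$coupled]
  ctr <- planted_phase_profile(s$truth, 2)
  expect_lt(thetaseq:::circ_dist(thetaseq:::circ_mean(ph), ctr), 0.15)
  expect_lt(thetaseq:::rayleigh_test(ph), 1e-6)
})

test_that("tuned-letter encoding band power is elevated by about the gain", {
  gain <- 6
  s <- quick_session(17, n_trials = 60, n_channels = 1, tuned_gamma_gain = gain)
  fs <- s$recording$sampling_rate_hz
  bp <- Mod(thetaseq:::band_analytic(s$recording$data[1, ], fs,
                                     c(75, 120)))^2
  ev <- s$events
  tuned <- s$truth$channels$tuned_letter[1]
  lists <- cbind(ev$letter1, ev$letter2, ev$letter3)
  ons <- cbind(ev$onset1_s, ev$onset2_s, ev$onset3_s)
  pw <- function(on) mean(bp[round((on + 0.15) * fs):round((on + 0.55) * fs)])
  vals <- matrix(vapply(seq_len(nrow(ev)), function(t) {
    vapply(1:3, function(p) pw(ons[t, p]), numeric(1))
  }, numeric(3)), nrow = 3)
  is_tuned <- t(lists == tuned)
  ratio <- mean(vals[is_tuned]) / mean(vals[!is_tuned])
  expect_gt(ratio, gain * 0.5)
  expect_lt(ratio, gain * 2)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(letter_set = c("A", "B", "C")),
               "at least 4")
  expect_error(simulation_config(theta_amp_encoding = 12),
               "encoding < baseline < maintenance")
  expect_error(simulation_config(gamma_band_hz = c(75, 130)),
               "Nyquist")
  expect_error(simulation_config(tuned_gamma_gain = 0.5), ">= 1")
  expect_error(simulation_config(
    position_phase_centers_rad = c(2, 1, 3)), "strictly increasing")
})

test_that("sessions round-trip through the plain-text container", {
  s <- quick_session(19, n_trials = 5, n_channels = 2)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$recording$sampling_rate_hz, 250)
  expect_equal(dim(s2$recording$data), dim(s$recording$data))
  # TSV stores 7 significant digits
  expect_lt(max(abs(s2$recording$data - s$recording$data)) /
              stats::sd(s$recording$data), 1e-4)
  expect_equal(s2$events$letter1, s$events$letter1)
  expect_equal(s2$events$rt_s, s$events$rt_s, tolerance = 1e-6)
  expect_equal(s2$truth$phase_code_planted, s$truth$phase_code_planted)
})
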