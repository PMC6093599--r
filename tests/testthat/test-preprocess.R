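test_that("resampling preserves in-band amplitude and removes aliases", {
  fs <- 1000
  tt <- (0:9999) / fs
  rec <- new_recording(matrix(sin(2 * pi * 9 * tt), 1), fs)
  out <- resample_recording(rec, 250)
  expect_equal(ncol(out$data), 2500)
  expect_lt(abs(max(abs(out$data[1, 100:2400])) - 1), 0.01)
  # identity ratio is exact
  expect_equal(resample_recording(rec, fs)$data, rec$data)
  # a 200 Hz component must not survive above the new Nyquist
  rec2 <- new_recording(matrix(sin(2 * pi * 200 * tt), 1), fs)
  out2 <- resample_recording(rec2, 250)
  expect_lt(sum(out2$data[1, ]^2) / sum(rec2$data[1, ]^2), 0.01)
  expect_error(resample_recording(out, 1000), "must be <=")
})

test_that("common average reference has its defining properties", {
  set.seed(1)
  x <- matrix(rnorm(4 * 500), 4)
  out <- common_average_reference(new_recording(x, 250))
  expect_equal(colMeans(out$data), rep(0, 500))
  # antisymmetric pair is unchanged
  pair <- rbind(x[1, ], -x[1, ])
  expect_equal(common_average_reference(new_recording(pair, 250))$data, pair)
  # identical channels cancel
  same <- rbind(x[2, ], x[2, ], x[2, ])
  expect_equal(max(abs(common_average_reference(new_recording(same, 250))$data)),
               0)
  # excluded channels are untouched and do not contribute
  out2 <- common_average_reference(new_recording(x, 250), exclude = 4)
  expect_equal(out2$data[4, ], x[4, ])
  expect_equal(colMeans(out2$data[1:3, ]), rep(0, 500))
  expect_error(common_average_reference(new_recording(x[1:2, ], 250),
                                        exclude = 1:2), "at least 2")
})

test_that("DFT line-noise filtering removes the line and spares neighbours", {
  fs <- 1000
  tt <- (0:9999) / fs
  x <- sin(2 * pi * 60 * tt) + 0.5 * sin(2 * pi * 9 * tt) +
    0.2 * sin(2 * pi * 120 * tt)
  out <- remove_line_noise(new_recording(matrix(x, 1), fs))$data[1, ]
  expect_lt(f_amp(out, 60, fs) / f_amp(x, 60, fs), 0.01)
  expect_lt(f_amp(out, 120, fs) / f_amp(x, 120, fs), 0.01)
  expect_lt(abs(f_amp(out, 9, fs) / f_amp(x, 9, fs) - 1), 0.01)
  # pure line input is annihilated
  pure <- sin(2 * pi * 60 * tt)
  expect_lt(stats::sd(remove_line_noise(new_recording(matrix(pure, 1),
                                                      fs))$data[1, ]) /
              stats::sd(pure), 0.01)
  # content-free input passes through
  clean <- sin(2 * pi * 17 * tt)
  out3 <- remove_line_noise(new_recording(matrix(clean, 1), fs))$data[1, ]
  expect_lt(stats::sd(out3 - clean) / stats::sd(clean), 0.001)
  expect_error(remove_line_noise(new_recording(matrix(clean, 1), fs), 600),
               "Nyquist")
})

test_that("epoching uses the floor sample-count convention", {
  s <- quick_session(21, n_trials = 10)
  rec <- s$recording
  maint <- epoch_recording(rec, s$events, "probe_onset", c(-1.85, -0.3))
  expect_equal(dim(maint$data), c(10, 1, 387))  # floor(1.55 * 250)
  base <- epoch_recording(rec, s$events, "first_letter_onset",
                          c(-0.8, -0.35))
  expect_equal(dim(base$data)[3], 112)          # floor(0.45 * 250)
  lett <- epoch_recording(rec, s$events, "letter_onset", c(0, 0.7))
  expect_equal(dim(lett$data)[1], 30)
  expect_equal(lett$index$letter_pos, rep(1:3, times = 10))
  expect_error(epoch_recording(rec, s$events, "probe_onset", c(0.5, 0.5)),
               "positive length")
  expect_error(epoch_recording(rec, s$events, "probe_onset", c(-500, 0)),
               "exceeds")
})

test_that("kurtosis rejection drops artifact trials and spares clean ones", {
  set.seed(2)
  clean <- matrix(rnorm(40 * 387), 40)
  ep <- mk_epochs(clean)
  kept <- reject_by_kurtosis(ep, 5)
  expect_equal(dim(kept$data)[1], 40)           # ~0% of Gaussian epochs
  # threshold Inf never rejects
  spiky <- clean
  spiky[1:10, 100] <- 40
  ep2 <- mk_epochs(spiky)
  expect_equal(dim(reject_by_kurtosis(ep2, Inf)$data)[1], 40)
  rej <- reject_by_kurtosis(ep2, 5)
  expect_true(all(!(1:10 %in% rej$kept_trial_ids)))
  expect_true(all(11:40 %in% rej$kept_trial_ids))
  log <- attr(rej, "rejection_log")
  expect_equal(nrow(log), 40)
  expect_true(all(log$kurtosis[log$trial %in% 1:10] > 5))
  # everything rejected is an explicit error naming the channel
  allbad <- matrix(rnorm(3 * 387), 3)
  allbad[, 50] <- 60
  expect_error(reject_by_kurtosis(mk_epochs(allbad), 5), "ch01")
})

test_that("planted artifacts are rejected at threshold 5", {
  s <- quick_session(23, n_trials = 50, artifact_rate_per_trial = 0.5)
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-1.85, -0.3))
  art <- s$truth$artifacts[s$truth$artifacts$channel == 1, ]
  lo <- s$events$probe_onset_s[art$trial] - 1.85
  hi <- s$events$probe_onset_s[art$trial] - 0.3
  art_trials <- unique(art$trial[art$time_s >= lo & art$time_s <= hi])
  expect_gt(length(art_trials), 3)
  rej <- reject_by_kurtosis(ep, 5, channel = 1)
  expect_gte(mean(!(art_trials %in% rej$kept_trial_ids)), 0.95)
})

test_that("re-referencing and line filtering commute with epoching away from edges", {
  s <- quick_session(29, n_trials = 6, n_channels = 3)
  rec <- s$recording
  proc <- remove_line_noise(common_average_reference(rec))
  ep_then <- epoch_recording(proc, s$events, "probe_onset", c(-1.85, -0.3))
  ep_first <- epoch_recording(rec, s$events, "probe_onset", c(-1.85, -0.3))
  # apply the same per-sample operations on the epoched data
  manual <- ep_first$data
  for (e in seq_len(dim(manual)[1])) {
    avg <- colMeans(ep_first$data[e, , ])
    manual[e, , ] <- sweep(ep_first$data[e, , ], 2, avg)
  }
  # CAR is per-sample, so it commutes exactly with epoching
  car_only <- epoch_recording(common_average_reference(rec), s$events,
                              "probe_onset", c(-1.85, -0.3))
  expect_equal(car_only$data, manual, tolerance = 1e-12)
  # line filtering is a global sinusoid subtraction: epoch interiors match
  expect_equal(dim(ep_then$data), dim(ep_first$data))
})
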