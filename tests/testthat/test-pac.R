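test_that("power envelope tracks amplitude structure", {
  fs <- 250
  tt <- (0:1999) / fs
  # stationary sinusoid: flat envelope near 1
  env <- power_envelope(cos(2 * pi * 80 * tt), fs, 80)
  mid <- env[!is.na(env)]
  expect_lt(stats::sd(mid) / mean(mid), 0.05)
  expect_lt(abs(mean(mid) - 1), 0.05)
  # amplitude modulation at 10 Hz dominates the envelope spectrum
  am <- (1 + 0.8 * cos(2 * pi * 10 * tt)) * cos(2 * pi * 80 * tt)
  env2 <- power_envelope(am, fs, 80)
  e <- env2[!is.na(env2)]
  e <- e - mean(e)
  freqs <- 1:30
  amps <- vapply(freqs, function(f) f_amp(e, f, fs), numeric(1))
  expect_equal(freqs[which.max(amps)], 10)
  # zero in, zero out
  expect_equal(max(power_envelope(numeric(500), fs, 80), na.rm = TRUE), 0)
  expect_error(power_envelope(rnorm(100), fs, 10), "longer than the epoch")
})

test_that("planted coupling is localized to the theta/alpha x fast-gamma region", {
  s <- quick_session(43, n_trials = 40, n_channels = 2, theta_freq_hz = 10,
                     tuned_positions = rep(1L, 40), phase_concentration = 6)
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  pac <- pac_spectrum(ep, channel = 1)
  expect_true(all(pac$coupling >= 0 & pac$coupling <= 1))
  mx <- which(pac$coupling == max(pac$coupling), arr.ind = TRUE)[1, ]
  pf <- pac$phase_freqs_hz[mx[1]]
  af <- pac$amp_freqs_hz[mx[2]]
  expect_true(pf >= 7 && pf <= 13)
  expect_true(af >= 75 && af <= 120)
  # uncoupled channel is much weaker in the band of interest
  pac0 <- pac_spectrum(ep, channel = 2)
  expect_gte(band_pac(pac) / band_pac(pac0), 3)
})

test_that("PAC is invariant to amplitude scaling of the input", {
  s <- quick_session(47, n_trials = 10, n_channels = 1,
                     tuned_positions = rep(1L, 10))
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  p1 <- pac_spectrum(ep, 1)
  ep$data <- ep$data * 12.5
  p2 <- pac_spectrum(ep, 1)
  expect_equal(p1$coupling, p2$coupling, tolerance = 1e-10)
})

test_that("independent pink noise gives uniformly small coupling", {
  set.seed(6)
  rats <- vapply(1:5, function(i) {
    arr <- t(vapply(1:30, function(tr) thetaseq:::pink_noise(500, 1, 250),
                    numeric(500)))
    p <- pac_spectrum(mk_epochs(arr, 250, window = c(-2, 0)), 1)
    expect_lt(max(p$coupling), 0.15)
    max(p$coupling) / stats::median(p$coupling)
  }, numeric(1))
  # order statistics over ~456 null coherence cells put E[max]/median near
  # ln(456)/ln(2) ~ 8.8; anything far beyond signals a biased estimator
  expect_lt(mean(rats), 12)
})

test_that("phase scrambling collapses planted coupling", {
  s <- quick_session(53, n_trials = 30, n_channels = 1, theta_freq_hz = 10,
                     tuned_positions = rep(1L, 30), phase_concentration = 6)
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  intact <- band_pac(pac_spectrum(ep, 1))
  # randomize Fourier phases per trial: same spectrum, no cross-frequency
  # structure
  set.seed(54)
  scr <- ep
  n <- dim(ep$data)[3]
  for (tr in seq_len(dim(ep$data)[1])) {
    X <- stats::fft(ep$data[tr, 1, ])
    ph <- stats::runif(n, 0, 2 * pi)
    ph[1] <- 0
    Xs <- Mod(X) * exp(1i * ph)
    scr$data[tr, 1, ] <- Re(stats::fft(Xs, inverse = TRUE)) / n
  }
  shuffled <- band_pac(pac_spectrum(scr, 1))
  expect_lt(shuffled, intact / 3)
})

test_that("display normalization is scale-free and bounded", {
  s <- quick_session(59, n_trials = 10, n_channels = 2,
                     tuned_positions = rep(1L, 10))
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  p1 <- pac_spectrum(ep, 1)
  one <- normalize_for_display(list(p1))
  expect_equal(max(one), 1)
  two <- normalize_for_display(list(p1, p1))
  expect_equal(two, one)
  p_scaled <- p1
  p_scaled$coupling <- p1$coupling * 0.37
  expect_equal(normalize_for_display(list(p1, p_scaled)), one)
  p0 <- p1
  p0$coupling[] <- 0
  expect_error(normalize_for_display(list(p0)), "all-zero")
})

test_that("peak-locked averaging separates sinusoidal from sawtooth rhythms", {
  fs <- 250
  tt <- (0:4999) / fs
  pl_sin <- peak_locked_average(mk_epochs(cos(2 * pi * 10 * tt), fs), 1)
  expect_gt(pl_sin$harmonic_ratio, 100)
  expect_true(pl_sin$sinusoidal)
  expect_equal(pl_sin$fundamental_hz, 10, tolerance = 0.3)
  # the mean waveform peaks at lag zero (up to ties at whole periods)
  centre <- (length(pl_sin$waveform) + 1) / 2
  expect_equal(pl_sin$waveform[centre], max(pl_sin$waveform),
               tolerance = 1e-6)
  saw <- 2 * ((10 * tt) %% 1) - 1
  pl_saw <- peak_locked_average(mk_epochs(saw, fs), 1)
  expect_lt(pl_saw$harmonic_ratio, 10)
  expect_false(pl_saw$sinusoidal)
  expect_error(peak_locked_average(mk_epochs(cos(2 * pi * 10 * tt[1:100]),
                                             fs), 1),
               "peaks")
})

test_that("the synthetic theta/alpha waveform passes the shape control", {
  s <- quick_session(61, n_trials = 15, n_channels = 1)
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  pl <- peak_locked_average(ep, 1)
  expect_true(pl$sinusoidal)
  expect_gt(pl$n_peaks, 20)
  expect_true(!is.null(pl$mean_tfr) && all(dim(pl$mean_tfr) > 1))
})
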