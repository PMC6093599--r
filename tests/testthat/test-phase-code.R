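test_that("instantaneous phase follows the cosine-peak convention", {
  fs <- 250
  tt <- (0:999) / fs
  pp <- instantaneous_phase_and_power(cos(2 * pi * 10 * tt), fs)
  # phase ~0 at signal maxima (away from epoch edges)
  peaks <- which(diff(sign(diff(cos(2 * pi * 10 * tt)))) == -2) + 1
  peaks <- peaks[peaks > 50 & peaks < 950]
  devs <- pmin(pp$phase[peaks], 2 * pi - pp$phase[peaks])
  expect_lt(max(devs), 0.15)
  # phase advances ~2*pi per cycle (100 ms at 10 Hz)
  inc <- diff(pp$phase[100:900]) %% (2 * pi)
  expect_equal(mean(inc), 2 * pi * 10 / fs, tolerance = 0.02)
})

test_that("constant-amplitude gamma yields constant smoothed power", {
  fs <- 250
  tt <- (0:999) / fs
  pp <- instantaneous_phase_and_power(cos(2 * pi * 90 * tt), fs)
  mid <- pp$power[100:900]
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.05)
  expect_error(instantaneous_phase_and_power(rnorm(50), fs), "300 ms")
})

test_that("template fits match brute-force enumeration exactly", {
  base <- rep(1:3, each = 6)
  tf <- template_fit(base)
  expect_equal(tf$max_fit, 18L)
  expect_equal(tf$rotation, 0L)
  expect_equal(template_fit(rep(1L, 18))$max_fit, 6L)
  set.seed(14)
  for (i in 1:1000) {
    labels <- sample(1:3, 18, replace = TRUE)
    tf <- template_fit(labels)
    expect_identical(tf$max_fit, brute_force_template_fit(labels))
    # rotation-mean identity and pigeonhole bounds
    expect_equal(mean(tf$fits), 6)
    expect_gte(tf$max_fit, 6L)
    expect_lte(tf$max_fit, 18L)
  }
  expect_error(template_fit(rep(1:2, 8)), "divisible")
  expect_error(template_fit(c(rep(1L, 17), 5L)), "values in 1:3")
})

test_that("the maximum fit is invariant to global label rotation", {
  set.seed(15)
  for (i in 1:50) {
    labels <- sample(1:3, 18, replace = TRUE)
    k <- sample(17, 1)
    rotated <- c(labels[(k + 1):18], labels[1:k])
    expect_identical(template_fit(labels)$max_fit,
                     template_fit(rotated)$max_fit)
  }
})

test_that("profile deviations cancel across positions and labels take the argmax", {
  pos <- rep(1:3, length.out = 30)
  s <- quick_session(63, n_trials = 30, tuned_positions = pos,
                     phase_concentration = 5)
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  tp <- tibble::tibble(channel = 1, trial = 1:30, position = pos)
  pr <- phase_bin_profile(ep, tp, analysis_window = c(-1.85, -0.3))
  expect_equal(colSums(pr$deviation_by_position), rep(0, 18),
               tolerance = 1e-12)
  expect_equal(pr$labels,
               apply(pr$power_by_position, 2, which.max))
  expect_equal(length(pr$bin_edges), 19)
  expect_equal(diff(pr$bin_edges), rep(2 * pi / 18, 18))
})

test_that("labels form ordered contiguous runs when phases are planted on bin centres", {
  centres <- ((c(3, 9, 15) - 0.5) * 2 * pi / 18)
  pos <- rep(1:3, length.out = 45)
  s <- quick_session(67, n_trials = 45, tuned_positions = pos,
                     phase_concentration = 10,
                     position_phase_centers_rad = centres)
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  tp <- tibble::tibble(channel = 1, trial = 1:45, position = pos)
  pr <- phase_bin_profile(ep, tp, analysis_window = c(-1.85, -0.3))
  # a rotation of the ideal 6/6/6 template fits nearly everywhere
  expect_gte(template_fit(pr$labels)$max_fit, 15)
})

test_that("a null phase code gives a flat profile", {
  pos <- rep(1:3, length.out = 60)
  s <- quick_session(71, n_trials = 60, phase_concentration = 0,
                     tuned_positions = pos)
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  tp <- tibble::tibble(channel = 1, trial = 1:60, position = pos)
  pr <- phase_bin_profile(ep, tp, analysis_window = c(-1.85, -0.3))
  overall <- colMeans(pr$power_by_position)
  expect_lt(max(overall) / min(overall), 1.2)
})

test_that("a strongly planted code is recovered with a significant ordering", {
  pos <- rep(1:3, length.out = 60)
  centres <- c(pi / 6, pi / 6 + 2 * pi / 3, pi / 6 + 4 * pi / 3)
  eps <- list(); tps <- list()
  for (site in 1:2) {
    s <- quick_session(73 + site, n_trials = 60, tuned_positions = pos,
                       phase_concentration = 4,
                       position_phase_centers_rad = centres)
    eps[[site]] <- epoch_recording(s$recording, s$events, "probe_onset",
                                   c(-2, 0))
    tps[[site]] <- tibble::tibble(channel = site, trial = 1:60,
                                  position = pos)
  }
  res <- serial_order_permutation_test(
    combine_site_epochs(eps), dplyr::bind_rows(tps),
    n_shuffles = 500, seed = 75, analysis_window = c(-1.85, -0.3))
  expect_lte(res$p_value, 0.01)
  expect_gte(res$observed_fit, 14)
  est <- estimate_preferred_phase(res$profile)
  err <- vapply(1:3, function(p) thetaseq:::circ_dist(est[p], centres[p]),
                numeric(1))
  expect_lt(max(err), 2 * pi / 18)
  # p equals the proportion of surrogates at or above the observed fit
  expect_equal(res$p_value,
               mean(res$surrogate_fits >= res$observed_fit))
  expect_error(serial_order_permutation_test(
    combine_site_epochs(eps), dplyr::bind_rows(tps), n_shuffles = 50),
    "at least 100")
})

test_that("a position without qualifying trials is an error", {
  pos <- rep(c(1L, 2L), length.out = 20)
  s <- quick_session(79, n_trials = 20, tuned_positions = pos)
  ep <- epoch_recording(s$recording, s$events, "probe_onset", c(-2, 0))
  tp <- tibble::tibble(channel = 1, trial = 1:20, position = pos)
  expect_error(phase_bin_profile(ep, tp), "zero qualifying trials")
})
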