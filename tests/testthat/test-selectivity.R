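test_that("MI matches an independent brute-force computation to 1e-12", {
  set.seed(8)
  gens <- list(function(n) rnorm(n), function(n) rlnorm(n, 0, 2),
               function(n) sample(0:5, n, replace = TRUE),
               function(n) runif(n, -1, 1))
  for (i in 1:100) {
    g <- gens[[(i %% 4) + 1]]
    x <- g(sample(5:40, 1))
    y <- g(sample(5:40, 1))
    expect_equal(mutual_information(x, y), brute_force_mi(x, y),
                 tolerance = 1e-12)
  }
})

test_that("perfectly separated balanced groups give exactly 1 bit", {
  x <- runif(20, 0, 1)
  y <- runif(20, 10, 11)
  expect_equal(mutual_information(x, y), 1)
})

test_that("null MI for heavy-tailed power values stays below 0.08 bits at n = 200", {
  set.seed(9)
  v <- replicate(100, mutual_information(rlnorm(200, 0, 2.5),
                                         rlnorm(200, 0, 2.5)))
  expect_lte(mean(v), 0.08)
})

test_that("MI is exactly invariant under affine rescaling", {
  set.seed(10)
  x <- rlnorm(30); y <- rlnorm(25, 0.5)
  m0 <- mutual_information(x, y)
  expect_identical(m0, mutual_information(3.2 * x + 7, 3.2 * y + 7))
  expect_identical(m0, mutual_information(-2 * x, -2 * y))
  # constant input occupies one bin: MI defined as 0
  expect_equal(mutual_information(rep(2, 10), rep(2, 12)), 0)
})

test_that("the pair permutation test behaves at its extremes", {
  # observed MI = 0 (constant pooled values): every permutation ties, p = 1
  expect_equal(pair_permutation_test(rep(1, 10), rep(1, 10),
                                     n_perm = 100)$p_raw, 1)
  # perfectly separated clusters: p at the Monte-Carlo floor
  set.seed(11)
  r <- pair_permutation_test(runif(20, 0, 1), runif(20, 10, 11),
                             n_perm = 1000)
  expect_lte(r$p_raw, 0.01)
  expect_equal(r$method, "monte_carlo")
  # small groups take the exact-enumeration path
  r2 <- pair_permutation_test(rnorm(7), rnorm(7), n_perm = 100)
  expect_equal(r2$method, "exact")
  expect_equal(r2$n_perm_used, choose(14, 7))
  expect_error(pair_permutation_test(rnorm(5), rnorm(5), n_perm = 50),
               "at least 100")
})

test_that("the permutation p-value is calibrated for exchangeable inputs", {
  set.seed(12)
  ps <- replicate(100, pair_permutation_test(rlnorm(20, 0, 1.5),
                                             rlnorm(20, 0, 1.5),
                                             n_perm = 300)$p_raw)
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.12)
  expect_gt(stats::median(ps), 0.2)
})

test_that("detection evaluates 120 pairs and flags the planted channel", {
  s <- simulate_session(simulation_config(
    sampling_rate_hz = 250, n_trials = 160, n_channels = 4,
    selective_channels = 1L, artifact_rate_per_trial = 0, rng_seed = 2))
  rec <- preprocess_recording(s$recording)
  tab <- letter_band_power(rec, s$events)
  sel <- detect_selective_sites(tab, n_perm = 40000, seed = 52)
  pairs <- attr(sel, "all_pair_mis")
  expect_equal(as.integer(table(pairs$channel)), rep(120L, 4))
  expect_equal(sel$n_pairs, rep(120L, 4))
  tuned <- s$truth$channels$tuned_letter[1]
  expect_true(sel$selective[1])
  expect_true(tuned %in% c(sel$letter_x[1], sel$letter_y[1]))
  expect_equal(sel$tuned[1], tuned)
  expect_equal(sel$p_corrected,
               pmin(1, sel$p_raw * 4 * sel$n_pairs))
})

test_that("null sessions produce no selective channels", {
  s <- simulate_session(simulation_config(
    sampling_rate_hz = 250, n_trials = 64, n_channels = 4,
    tuned_gamma_gain = 1, phase_concentration = 0,
    artifact_rate_per_trial = 0, rng_seed = 61))
  tab <- letter_band_power(s$recording, s$events, kurtosis_threshold = Inf)
  sel <- detect_selective_sites(tab, n_perm = 500, seed = 62)
  expect_equal(sum(sel$selective), 0L)
})

test_that("detection strength grows with gain and trial count", {
  z_of <- function(gain, n_trials, seed) {
    s <- simulate_session(simulation_config(
      sampling_rate_hz = 250, n_trials = n_trials, n_channels = 1,
      tuned_gamma_gain = gain, artifact_rate_per_trial = 0,
      rng_seed = seed))
    tab <- letter_band_power(s$recording, s$events,
                             kurtosis_threshold = Inf)
    tuned <- s$truth$config$tuned_letters[1]
    sub <- tab[tab$channel == 1, ]
    sub$block <- paste(sub$trial, sub$position)
    others <- setdiff(sort(unique(sub$letter)), tuned)[1:5]
    set.seed(seed)
    mean(vapply(others, function(l) {
      a <- sub[sub$letter == tuned, ]
      b <- sub[sub$letter == l, ]
      thetaseq:::mi_permutation_z(a$power, b$power, a$block, b$block,
                                  256, 150)["z"]
    }, numeric(1)))
  }
  grid <- expand.grid(gain = c(1, 4, 10), trials = c(48, 96))
  grid$z <- mapply(function(g, n) mean(c(z_of(g, n, 71), z_of(g, n, 72))),
                   grid$gain, grid$trials)
  for (n in unique(grid$trials)) {
    zz <- grid$z[grid$trials == n]
    expect_true(all(diff(zz) > 0))   # increasing in gain
  }
  # increasing in trials at the strongest gain
  z10 <- grid$z[grid$gain == 10]
  expect_gt(z10[2], z10[1])
})

test_that("maintenance trial subsets follow the tuned/untuned rules", {
  ev <- tibble::tibble(
    trial = 1:5,
    letter1 = c("Q", "Q", "S", "T", "Z"),
    letter2 = c("R", "Z", "R", "U", "U"),
    letter3 = c("S", "S", "T", "V", "V"))
  subs <- maintenance_trial_subsets(ev, "Q", "Z")
  expect_true(1 %in% subs$tuned_trials)       # Q present, Z absent
  expect_false(2 %in% subs$tuned_trials)      # Z co-present excludes
  expect_false(2 %in% subs$untuned_trials)    # Q co-present excludes
  expect_equal(length(intersect(subs$tuned_trials, subs$untuned_trials)), 0)
  # tuned letter never shown: empty subset warns
  expect_warning(s2 <- maintenance_trial_subsets(ev, "X", "Z"), "empty")
  expect_equal(length(s2$tuned_trials), 0)
  expect_error(maintenance_trial_subsets(ev, "Q", "Q"), "differ")
})
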