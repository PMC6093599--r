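#' Continuous multichannel recording
#'
#' Thin container for a channels-by-samples matrix with its sampling rate and
#' channel labels.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sampling_rate_hz sampling rate, Hz.
#' @param channel_labels character vector, one label per channel.
#' @return A `ts_recording` object.
#' @export
new_recording <- function(data, sampling_rate_hz, channel_labels = NULL) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (any(!is.finite(data))) stop("recording contains non-finite samples")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  stopifnot(length(channel_labels) == nrow(data), sampling_rate_hz > 0)
  structure(list(data = data,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_labels = channel_labels),
            class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              ncol(x$data) / x$sampling_rate_hz))
  invisible(x)
}

# Add a Hanning-windowed tone packet (band-limited burst) in place.
add_burst <- function(sig, fs, t_center, f_carrier, n_cycles, amp, phi = NULL) {
  len <- max(5L, as.integer(round(n_cycles / f_carrier * fs)))
  if (len %% 2L == 0L) len <- len + 1L   # odd length: centred on t_center
  i0 <- as.integer(round(t_center * fs)) - len %/% 2L
  idx <- seq.int(i0, i0 + len - 1L)
  keep <- idx >= 1L & idx <= length(sig)
  if (!any(keep)) return(sig)
  if (is.null(phi)) phi <- stats::runif(1, 0, 2 * pi)
  tt <- (idx - 1L) / fs
  w <- hann_taper(len)
  sig[idx[keep]] <- sig[idx[keep]] +
    amp * w[keep] * cos(2 * pi * f_carrier * (tt[keep] - t_center) + phi)
  sig
}

# Sharp biphasic transient emulating an epileptiform discharge.
add_artifact <- function(sig, fs, t_center, amp) {
  half <- as.integer(round(0.04 * fs))
  i0 <- as.integer(round(t_center * fs)) - half
  idx <- seq.int(i0, i0 + 2L * half)
  keep <- idx >= 1L & idx <= length(sig)
  if (!any(keep)) return(sig)
  tt <- (idx - 1L) / fs - t_center
  shape <- exp(-(tt / 0.003)^2) - 0.35 * exp(-((tt - 0.012) / 0.007)^2)
  sig[idx[keep]] <- sig[idx[keep]] + amp * shape[keep]
  sig
}

# Draw the per-trial letter triples, honouring the schedule and any forced
# tuned-letter positions.
draw_letters <- function(cfg) {
  n <- cfg$n_trials
  if (cfg$letter_schedule == "balanced") {
    deck <- character(0)
    while (length(deck) < 3 * n) deck <- c(deck, sample(cfg$letter_set))
    letters_mat <- matrix(deck[seq_len(3 * n)], nrow = n, byrow = TRUE)
    # a letter may repeat within a trial across deck boundaries; redraw those
    for (t in seq_len(n)) {
      while (anyDuplicated(letters_mat[t, ])) {
        letters_mat[t, ] <- sample(cfg$letter_set, 3)
      }
    }
  } else {
    letters_mat <- t(replicate(n, sample(cfg$letter_set, 3)))
  }
  if (!is.null(cfg$tuned_positions)) {
    tuned <- cfg$tuned_letters[1]
    for (t in seq_len(n)) {
      p <- cfg$tuned_positions[t]
      if (is.na(p)) {
        # tuned letter must be absent
        while (tuned %in% letters_mat[t, ]) {
          letters_mat[t, ] <- sample(setdiff(cfg$letter_set, tuned), 3)
        }
      } else {
        if (!tuned %in% letters_mat[t, ]) {
          letters_mat[t, p] <- tuned
        } else {
          cur <- match(tuned, letters_mat[t, ])
          letters_mat[t, c(cur, p)] <- letters_mat[t, c(p, cur)]
        }
      }
    }
  }
  letters_mat
}

#' Simulate a synthetic Sternberg working-memory session
#'
#' Generates a continuous multichannel recording with the statistical
#' structure the downstream analysis assumes: pink-noise background, a
#' theta/alpha rhythm whose amplitude falls during encoding and rises during
#' the 2 s retention interval, Hanning-windowed band-limited gamma bursts
#' (elevated for the tuned letter at selective channels during encoding),
#' maintenance bursts whose theta/alpha phase is drawn from a von Mises
#' distribution centred on the tuned letter's list-position phase, and rare
#' high-kurtosis epileptiform transients. Every planted effect is switchable
#' through the configuration, and all planted parameters are returned as
#' ground truth.
#'
#' @param config a [simulation_config()] object.
#' @return A `ts_session` list with elements `recording` ([new_recording()]),
#'   `events` (one-row-per-trial tibble: letters, onsets, probe, response
#'   time, correctness) and `truth` (a `ts_truth` list of planted parameters:
#'   per-channel selectivity, per-trial tuned-letter positions, every burst
#'   with its theta phase, artifact times, and the generating config).
#' @examples
#' s <- simulate_session(simulation_config(n_trials = 4, n_channels = 2,
#'                                         rng_seed = 7))
#' s$recording
#' s$events
#' @export
simulate_session <- function(config) {
  cfg <- validate_config(config)
  set.seed(cfg$rng_seed)
  fs <- cfg$sampling_rate_hz
  n_tr <- cfg$n_trials
  f_th <- cfg$theta_freq_hz

  # --- trial timeline ------------------------------------------------------
  isi <- matrix(stats::runif(2 * n_tr, 0.275, 0.350), ncol = 2)
  rt <- pmax(0.4, stats::rnorm(n_tr, 2.0, 0.4))
  letters_mat <- draw_letters(cfg)
  onset1 <- numeric(n_tr)
  t_cursor <- 0
  for (t in seq_len(n_tr)) {
    onset1[t] <- t_cursor + 1.0           # 1 s pre-trial baseline padding
    probe_t <- onset1[t] + 0.7 + isi[t, 1] + 0.7 + isi[t, 2] + 0.7 + 2.0
    t_cursor <- probe_t + 0.7 + 1.5
  }
  onset2 <- onset1 + 0.7 + isi[, 1]
  onset3 <- onset2 + 0.7 + isi[, 2]
  probe_onset <- onset3 + 0.7 + 2.0
  in_list <- stats::runif(n_tr) < 0.5
  probe_letter <- character(n_tr)
  for (t in seq_len(n_tr)) {
    probe_letter[t] <- if (in_list[t]) sample(letters_mat[t, ], 1) else
      sample(setdiff(cfg$letter_set, letters_mat[t, ]), 1)
  }
  correct <- stats::runif(n_tr) < 0.94
  events <- tibble::tibble(
    trial = seq_len(n_tr),
    letter1 = letters_mat[, 1], letter2 = letters_mat[, 2],
    letter3 = letters_mat[, 3],
    onset1_s = onset1, onset2_s = onset2, onset3_s = onset3,
    probe_onset_s = probe_onset, probe_letter = probe_letter,
    rt_s = rt, correct = correct)

  dur <- t_cursor + 1.0
  n_samp <- as.integer(ceiling(dur * fs))
  tt <- (seq_len(n_samp) - 1) / fs

  # --- theta/alpha amplitude schedule (shared across channels) -------------
  amp_env <- rep(cfg$theta_amp_baseline, n_samp)
  for (t in seq_len(n_tr)) {
    enc <- tt >= onset1[t] & tt < onset3[t] + 0.7
    mnt <- tt >= onset3[t] + 0.7 & tt < probe_onset[t]
    amp_env[enc] <- cfg$theta_amp_encoding
    amp_env[mnt] <- cfg$theta_amp_maintenance
  }
  amp_env <- smooth_series(amp_env, hann_kernel(0.1, fs))
  # each channel carries the rhythm at its own phase offset: cortical
  # theta/alpha is spatially heterogeneous, and a rhythm common to all
  # channels would be annihilated by the common average reference
  theta_offset <- stats::runif(cfg$n_channels, 0, 2 * pi)

  # --- per-channel signal assembly -----------------------------------------
  sel_idx <- cfg$selective_channels
  tuned_of <- stats::setNames(rep(NA_character_, cfg$n_channels), NULL)
  tuned_of[sel_idx] <- cfg$tuned_letters
  data <- matrix(0, nrow = cfg$n_channels, ncol = n_samp)
  bursts <- list()
  kappa <- cfg$phase_concentration

  for (ch in seq_len(cfg$n_channels)) {
    theta_sig <- amp_env * cos(2 * pi * f_th * tt + theta_offset[ch])
    noise <- cfg$noise_sd_uv * pink_noise(n_samp, cfg$noise_exponent, fs)
    # background band power of this channel, used to scale tuned responses
    # so that tuned-letter encoding band power is ~tuned_gamma_gain times
    # the background level
    n_band <- stats::var(Re(band_analytic(noise[seq_len(min(n_samp,
                                                            2^15))],
                                          fs, cfg$gamma_band_hz)))
    sig <- noise + theta_sig
    resp_len <- as.integer(round(0.54 * fs))
    resp_env <- tukey_env(resp_len, as.integer(round(0.05 * fs)))
    rows <- list()
    for (t in seq_len(n_tr)) {
      ons <- c(onset1[t], onset2[t], onset3[t])
      for (p in 1:3) {
        # background encoding bursts, identical for every letter
        lam <- cfg$gamma_burst_rate_per_theta_cycle * 0.7 * f_th
        nb <- stats::rpois(1, lam)
        if (nb > 0) {
          t_c <- stats::runif(nb, ons[p] + 0.03, ons[p] + 0.67)
          for (b in seq_len(nb)) {
            fc <- stats::runif(1, cfg$gamma_band_hz[1], cfg$gamma_band_hz[2])
            nc <- stats::runif(1, cfg$burst_cycles[1], cfg$burst_cycles[2])
            sig <- add_burst(sig, fs, t_c[b], fc, nc, cfg$gamma_burst_amp_uv)
          }
        }
        # sustained induced gamma response to the tuned letter: evoked band
        # power (tuned_gamma_gain - 1) x background, with heavy-tailed
        # (lognormal) trial-to-trial power as in real broadband gamma
        is_tuned <- !is.na(tuned_of[ch]) && letters_mat[t, p] == tuned_of[ch]
        if (is_tuned && cfg$tuned_gamma_gain > 1) {
          sdl <- cfg$response_power_sdlog
          g <- stats::rlnorm(1, -sdl^2, sdl)   # E[g^2] = 1
          a <- sqrt((cfg$tuned_gamma_gain - 1) * n_band) * g
          i0 <- as.integer(round((ons[p] + 0.08) * fs)) + 1L
          idx <- seq.int(i0, i0 + resp_len - 1L)
          keep <- idx >= 1L & idx <= n_samp
          resp <- a * resp_env * band_noise(resp_len, fs, cfg$gamma_band_hz)
          sig[idx[keep]] <- sig[idx[keep]] + resp[keep]
        }
      }
      # maintenance bursts: one candidate per theta cycle in the retention
      ret0 <- onset3[t] + 0.7
      ret1 <- probe_onset[t]
      cycles <- seq.int(ceiling(ret0 * f_th) - 1L, floor(ret1 * f_th))
      tuned_pos <- if (!is.na(tuned_of[ch])) {
        m <- match(tuned_of[ch], letters_mat[t, ])
        if (is.na(m)) NA_integer_ else m
      } else NA_integer_
      coupled <- !is.na(tuned_pos) && kappa > 0
      p_burst <- min(1, cfg$maintenance_burst_rate_per_theta_cycle)
      go <- stats::runif(length(cycles)) < p_burst
      if (any(go)) {
        phis <- if (coupled) {
          rvonmises(sum(go), cfg$position_phase_centers_rad[tuned_pos], kappa)
        } else {
          stats::runif(sum(go), 0, 2 * pi)
        }
        # burst centre where this channel's theta phase equals phi:
        # 2*pi*f*t + offset = phi (mod 2*pi)
        t_cs <- (cycles[go] +
                   ((phis - theta_offset[ch]) %% (2 * pi)) / (2 * pi)) / f_th
        inside <- t_cs > ret0 + 0.02 & t_cs < ret1 - 0.02
        t_cs <- t_cs[inside]; phis <- phis[inside]
        for (b in seq_along(t_cs)) {
          fc <- stats::runif(1, cfg$gamma_band_hz[1], cfg$gamma_band_hz[2])
          nc <- stats::runif(1, cfg$burst_cycles[1], cfg$burst_cycles[2])
          sig <- add_burst(sig, fs, t_cs[b], fc, nc, cfg$gamma_burst_amp_uv)
        }
        if (length(t_cs)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            channel = ch, trial = t, period = "maintenance",
            position = if (coupled) tuned_pos else NA_integer_,
            coupled = coupled, time_s = t_cs, phase = phis)
        }
      }
    }
    data[ch, ] <- sig
    if (length(rows)) bursts[[length(bursts) + 1L]] <- dplyr::bind_rows(rows)
  }
  bursts <- if (length(bursts)) dplyr::bind_rows(bursts) else
    tibble::tibble(channel = integer(), trial = integer(),
                   period = character(), position = integer(),
                   coupled = logical(), time_s = numeric(), phase = numeric())

  # --- artifacts ------------------------------------------------------------
  art_rows <- list()
  for (t in seq_len(n_tr)) {
    na <- stats::rpois(1, cfg$artifact_rate_per_trial)
    if (na == 0) next
    for (a in seq_len(na)) {
      ch <- sample.int(cfg$n_channels, 1)
      t_c <- stats::runif(1, onset1[t] - 0.9, probe_onset[t] + 0.5)
      data[ch, ] <- add_artifact(data[ch, ], fs, t_c, cfg$artifact_amp_uv)
      art_rows[[length(art_rows) + 1L]] <-
        tibble::tibble(trial = t, channel = ch, time_s = t_c)
    }
  }
  artifacts <- if (length(art_rows)) dplyr::bind_rows(art_rows) else
    tibble::tibble(trial = integer(), channel = integer(), time_s = numeric())

  selective_effect <- cfg$tuned_gamma_gain > 1
  truth <- structure(list(
    config = cfg,
    channels = tibble::tibble(
      channel = seq_len(cfg$n_channels),
      label = sprintf("ch%02d", seq_len(cfg$n_channels)),
      selective = seq_len(cfg$n_channels) %in% sel_idx & selective_effect,
      tuned_letter = ifelse(seq_len(cfg$n_channels) %in% sel_idx &
                              selective_effect, tuned_of, NA_character_)),
    tuned_positions = tidyr::crossing(channel = sel_idx,
                                      trial = seq_len(n_tr)) |>
      dplyr::mutate(position = purrr::map2_int(
        .data$channel, .data$trial,
        function(c0, t0) {
          m <- match(tuned_of[c0], letters_mat[t0, ])
          if (is.na(m)) NA_integer_ else as.integer(m)
        })),
    bursts = bursts,
    artifacts = artifacts,
    position_phase_centers_rad = cfg$position_phase_centers_rad,
    phase_code_planted = kappa > 0 && length(sel_idx) > 0),
    class = "ts_truth")

  structure(list(
    recording = new_recording(data, fs,
                              sprintf("ch%02d", seq_len(cfg$n_channels))),
    events = events,
    truth = truth), class = "ts_session")
}

#' Read back a planted preferred phase
#'
#' Returns the planted preferred theta/alpha phase (radians) of maintenance
#' gamma bursts for a given list position, for use as the recovery target
#' when validating the phase-code estimator.
#'
#' @param truth the `truth` element of a [simulate_session()] result.
#' @param position list position, 1..3.
#' @return phase in `[0, 2*pi)`.
#' @export
planted_phase_profile <- function(truth, position) {
  stopifnot(inherits(truth, "ts_truth"), position %in% 1:3)
  if (!isTRUE(truth$phase_code_planted)) {
    stop("no phase code was planted in this session (phase_concentration = 0 ",
         "or no selective channels)")
  }
  truth$position_phase_centers_rad[position]
}

#' @export
print.ts_session <- function(x, ...) {
  cat("<ts_session>\n")
  print(x$recording)
  cat(sprintf("  %d trials; %d selective channel(s); phase code %s\n",
              nrow(x$events), sum(x$truth$channels$selective),
              if (x$truth$phase_code_planted) "planted" else "absent"))
  invisible(x)
}
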