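#' Configuration for a synthetic Sternberg session
#'
#' Builds and validates the full parameter set of the synthetic-session
#' generator. The defaults are the study conditions the analysis assumes:
#' 1000 Hz acquisition later resampled to 250 Hz, three 700 ms letters with
#' 275--350 ms inter-stimulus jitter, a 2 s retention interval, a ~9 Hz
#' theta/alpha rhythm whose amplitude drops during encoding and rises during
#' maintenance, letter-dependent broadband gamma elevation at designated
#' selective channels, and maintenance gamma bursts whose theta/alpha phase
#' follows the tuned letter's list position.
#'
#' @param sampling_rate_hz acquisition rate in Hz (resampled to
#'   `resample_target_hz` by the preprocessing stage).
#' @param resample_target_hz analysis rate in Hz; the gamma band must lie
#'   below its Nyquist frequency.
#' @param n_channels number of recorded channels.
#' @param selective_channels integer indices of letter-selective channels.
#' @param tuned_letters optional character vector, one tuned letter per
#'   selective channel; defaults to distinct letters from `letter_set`.
#' @param letter_set distinct stimulus symbols (>= 4; default 16 letters).
#' @param n_trials number of trials.
#' @param theta_freq_hz theta/alpha frequency in Hz.
#' @param theta_amp_baseline,theta_amp_encoding,theta_amp_maintenance
#'   theta/alpha amplitudes (microvolts) in the three task periods; must
#'   satisfy encoding < baseline < maintenance.
#' @param gamma_band_hz length-2 band (Hz) of the burst carriers.
#' @param gamma_burst_rate_per_theta_cycle expected encoding bursts per
#'   theta cycle.
#' @param maintenance_burst_rate_per_theta_cycle expected maintenance bursts
#'   per theta cycle.
#' @param gamma_burst_amp_uv burst amplitude, microvolts.
#' @param burst_cycles length-2 range of burst durations in carrier cycles.
#' @param tuned_gamma_gain multiplicative encoding-period power elevation for
#'   the tuned letter at its selective channel (>= 1; 1 = no selectivity).
#' @param response_power_sdlog lognormal sd (log scale) of the single-trial
#'   tuned-response power; broadband gamma responses are heavy-tailed across
#'   trials.
#' @param position_phase_centers_rad preferred maintenance burst phase for
#'   list positions P1..P3, strictly increasing in [0, 2*pi) when a phase
#'   code is planted. The default places successive positions one slow-gamma
#'   (~50 Hz) subcycle apart within the theta/alpha cycle, as in
#'   nested-oscillation accounts of multi-item working memory; phases spread
#'   evenly over the whole cycle would cancel in trial-averaged
#'   phase-amplitude coupling.
#' @param phase_concentration von Mises concentration of maintenance burst
#'   phases around the position centre (0 = no phase code).
#' @param noise_exponent pink-noise 1/f^a slope.
#' @param noise_sd_uv pink-noise standard deviation, microvolts.
#' @param artifact_rate_per_trial expected high-kurtosis transients per trial.
#' @param artifact_amp_uv transient amplitude, microvolts.
#' @param letter_schedule `"balanced"` cycles shuffled decks so letters
#'   appear near-equally often; `"random"` samples letters independently.
#' @param tuned_positions optional integer vector (length `n_trials`, values
#'   in 1:3 or NA) forcing the list position of the tuned letter per trial;
#'   only valid with a single selective channel.
#' @param rng_seed integer seed; identical configs give identical sessions.
#'
#' @return A validated `ts_config` list.
#' @seealso [simulate_session()]
#' @export
simulation_config <- function(sampling_rate_hz = 1000,
                              resample_target_hz = 250,
                              n_channels = 4,
                              selective_channels = 1L,
                              tuned_letters = NULL,
                              letter_set = LETTERS[1:16],
                              n_trials = 60,
                              theta_freq_hz = 9,
                              theta_amp_baseline = 10,
                              theta_amp_encoding = 5,
                              theta_amp_maintenance = 15,
                              gamma_band_hz = c(75, 120),
                              gamma_burst_rate_per_theta_cycle = 0.4,
                              maintenance_burst_rate_per_theta_cycle = 1,
                              gamma_burst_amp_uv = 5,
                              burst_cycles = c(2, 3),
                              tuned_gamma_gain = 10,
                              response_power_sdlog = 0.8,
                              position_phase_centers_rad = 1.2 +
                                c(0, 1.13, 2.26),
                              phase_concentration = 4,
                              noise_exponent = 1,
                              noise_sd_uv = 10,
                              artifact_rate_per_trial = 0.05,
                              artifact_amp_uv = 300,
                              letter_schedule = c("balanced", "random"),
                              tuned_positions = NULL,
                              rng_seed = 1L) {
  letter_schedule <- match.arg(letter_schedule)
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    resample_target_hz = resample_target_hz,
    n_channels = as.integer(n_channels),
    selective_channels = as.integer(selective_channels),
    tuned_letters = tuned_letters,
    letter_set = as.character(letter_set),
    n_trials = as.integer(n_trials),
    theta_freq_hz = theta_freq_hz,
    theta_amp_baseline = theta_amp_baseline,
    theta_amp_encoding = theta_amp_encoding,
    theta_amp_maintenance = theta_amp_maintenance,
    gamma_band_hz = gamma_band_hz,
    gamma_burst_rate_per_theta_cycle = gamma_burst_rate_per_theta_cycle,
    maintenance_burst_rate_per_theta_cycle = maintenance_burst_rate_per_theta_cycle,
    gamma_burst_amp_uv = gamma_burst_amp_uv,
    burst_cycles = burst_cycles,
    tuned_gamma_gain = tuned_gamma_gain,
    response_power_sdlog = response_power_sdlog,
    position_phase_centers_rad = position_phase_centers_rad,
    phase_concentration = phase_concentration,
    noise_exponent = noise_exponent,
    noise_sd_uv = noise_sd_uv,
    artifact_rate_per_trial = artifact_rate_per_trial,
    artifact_amp_uv = artifact_amp_uv,
    letter_schedule = letter_schedule,
    tuned_positions = tuned_positions,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$sampling_rate_hz > 0, cfg$resample_target_hz > 0,
            cfg$n_channels >= 1, cfg$n_trials >= 1)
  if (length(unique(cfg$letter_set)) < 4) {
    stop("letter_set must contain at least 4 distinct symbols")
  }
  cfg$letter_set <- unique(cfg$letter_set)
  amps <- c(cfg$theta_amp_baseline, cfg$theta_amp_encoding,
            cfg$theta_amp_maintenance, cfg$gamma_burst_amp_uv,
            cfg$noise_sd_uv, cfg$artifact_amp_uv)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (!(cfg$theta_amp_encoding < cfg$theta_amp_baseline &&
        cfg$theta_amp_baseline < cfg$theta_amp_maintenance)) {
    stop("theta amplitudes must satisfy encoding < baseline < maintenance")
  }
  if (cfg$gamma_band_hz[2] >= cfg$resample_target_hz / 2) {
    stop("gamma band upper edge (", cfg$gamma_band_hz[2],
         " Hz) must lie below the post-resampling Nyquist frequency (",
         cfg$resample_target_hz / 2, " Hz)")
  }
  if (cfg$tuned_gamma_gain < 1) stop("tuned_gamma_gain must be >= 1")
  if (cfg$phase_concentration < 0) stop("phase_concentration must be >= 0")
  ctr <- cfg$position_phase_centers_rad
  if (length(ctr) != 3 || any(ctr < 0) || any(ctr >= 2 * pi)) {
    stop("position_phase_centers_rad must be three values in [0, 2*pi)")
  }
  if (cfg$phase_concentration > 0 && any(diff(ctr) <= 0)) {
    stop("position_phase_centers_rad must be strictly increasing when a phase code is planted")
  }
  if (any(cfg$selective_channels < 1) ||
      any(cfg$selective_channels > cfg$n_channels)) {
    stop("selective_channels out of range")
  }
  n_sel <- length(cfg$selective_channels)
  if (is.null(cfg$tuned_letters)) {
    cfg$tuned_letters <- cfg$letter_set[seq_len(n_sel)]
  }
  if (length(cfg$tuned_letters) != n_sel ||
      !all(cfg$tuned_letters %in% cfg$letter_set)) {
    stop("tuned_letters must supply one letter from letter_set per selective channel")
  }
  if (!is.null(cfg$tuned_positions)) {
    if (n_sel != 1) {
      stop("tuned_positions is only supported with a single selective channel")
    }
    if (length(cfg$tuned_positions) != cfg$n_trials ||
        !all(is.na(cfg$tuned_positions) | cfg$tuned_positions %in% 1:3)) {
      stop("tuned_positions must have length n_trials with values in 1:3 or NA")
    }
  }
  structure(cfg, class = "ts_config")
}

#' @export
print.ts_config <- function(x, ...) {
  cat("<ts_config> synthetic Sternberg session\n")
  cat(sprintf("  %d channels @ %g Hz, %d trials, %d letters\n",
              x$n_channels, x$sampling_rate_hz, x$n_trials,
              length(x$letter_set)))
  cat(sprintf("  selective channels: %s (tuned: %s), gain %g\n",
              paste(x$selective_channels, collapse = ","),
              paste(x$tuned_letters, collapse = ","), x$tuned_gamma_gain))
  cat(sprintf("  theta %g Hz; gamma %g-%g Hz; phase concentration %g\n",
              x$theta_freq_hz, x$gamma_band_hz[1], x$gamma_band_hz[2],
              x$phase_concentration))
  invisible(x)
}
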