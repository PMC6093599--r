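# Sliding-window FFT time-frequency analysis with the two window schemes:
# frequency-adaptive 3-cycle windows for 1-30 Hz and a fixed 100 ms window
# for the 30-125 Hz range, both Hanning-tapered, both stepped at 50 ms.

#' Sliding-window FFT time-frequency power
#'
#' Power is the squared magnitude of the Hanning-tapered windowed Fourier
#' coefficient at each requested frequency, evaluated at 50 ms step centres.
#' Low frequencies (`low_freqs`) use frequency-adaptive windows of
#' `low_cycles` cycles (dT = cycles/f); high frequencies (`high_freqs`) use a
#' fixed `high_window_s` window. Coefficients are normalized by the taper sum
#' and doubled so that a unit-amplitude sinusoid yields power 1 regardless of
#' window length. Windows that would extend beyond the epoch are dropped
#' (power `NA` at those centres), not zero-padded.
#'
#' @param epochs a `ts_epochs` object.
#' @param low_freqs frequencies (Hz) analysed with the adaptive scheme
#'   (default 1--30 Hz in 1 Hz steps).
#' @param high_freqs frequencies (Hz) analysed with the fixed window
#'   (default 35--125 Hz in 5 Hz steps; at 30 Hz the two schemes coincide,
#'   so 30 Hz is carried by the adaptive scheme).
#' @param step_s window-centre step, s.
#' @param high_window_s fixed window length for `high_freqs`, s.
#' @param low_cycles window length in cycles for `low_freqs`.
#' @return A `ts_tfr`: `power` (epochs x channels x freqs x times, amplitude^2
#'   units), `freqs_hz`, `times_s` (window centres relative to the epoch
#'   anchor), `index`, `window_scheme`, `baseline_power` (NULL until
#'   [baseline_correct()]).
#' @export
compute_tfr <- function(epochs,
                        low_freqs = 1:30,
                        high_freqs = seq(35, 125, by = 5),
                        step_s = 0.05,
                        high_window_s = 0.1,
                        low_cycles = 3) {
  stopifnot(inherits(epochs, "ts_epochs"))
  fs <- epochs$sampling_rate_hz
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  freqs <- c(low_freqs, high_freqs)
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("frequencies must be strictly increasing across the two schemes")
  }
  if (any(freqs > fs / 2)) stop("frequencies must not exceed Nyquist")
  win_len <- function(f, scheme) {
    dT <- if (scheme == "low") low_cycles / f else high_window_s
    max(3L, as.integer(floor(dT * fs)))
  }
  scheme <- c(rep("low", length(low_freqs)), rep("high", length(high_freqs)))
  lens <- mapply(win_len, freqs, scheme)
  feasible <- lens <= n_samp
  if (!any(feasible)) stop("epoch shorter than the shortest analysis window")
  if (!all(feasible)) {
    warning(sum(!feasible), " low frequencies dropped: ",
            "epoch too short for their ", low_cycles, "-cycle windows")
    freqs <- freqs[feasible]; lens <- lens[feasible]
    scheme <- scheme[feasible]
  }
  centers <- seq(0, (n_samp - 1) / fs, by = step_s)
  n_t <- length(centers)
  power <- array(NA_real_, dim = c(n_ep, n_ch, length(freqs), n_t))
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_samp)  # samples x (ep*ch)
  for (k in seq_along(freqs)) {
    L <- lens[k]
    h <- hann_taper(L)
    kern <- h * exp(-2i * pi * freqs[k] * seq(0, L - 1) / fs) * (2 / sum(h))
    c_samp <- as.integer(round(centers * fs)) + 1L
    starts <- c_samp - L %/% 2L
    ok <- starts >= 1L & (starts + L - 1L) <= n_samp
    for (j in which(ok)) {
      seg <- flat[starts[j]:(starts[j] + L - 1L), , drop = FALSE]
      coef <- crossprod(seg, kern)   # (ep*ch) x 1 complex
      power[, , k, j] <- matrix(Mod(coef)^2, nrow = n_ep)
    }
  }
  structure(list(
    power = power,
    freqs_hz = freqs,
    times_s = epochs$window[1] + centers,
    index = epochs$index,
    channel_labels = epochs$channel_labels,
    sampling_rate_hz = fs,
    window_scheme = paste(c(
      if (length(low_freqs)) sprintf("low: %d-cycle Hanning (%g-%g Hz)",
                                     low_cycles, min(low_freqs), max(low_freqs)),
      if (length(high_freqs)) sprintf("high: %g ms Hanning (%g-%g Hz)",
                                      high_window_s * 1000, min(high_freqs),
                                      max(high_freqs)),
      sprintf("step %g ms", step_s * 1000)), collapse = "; "),
    baseline_power = NULL), class = "ts_tfr")
}

#' @export
print.ts_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<ts_tfr> %d epochs x %d channels x %d freqs x %d times\n  %s\n",
              d[1], d[2], d[3], d[4], x$window_scheme))
  if (!is.null(x$baseline_power)) cat("  baseline-corrected\n")
  invisible(x)
}

#' Baseline-correct a time-frequency result
#'
#' The baseline power is the time-averaged power of the matching baseline
#' epoch (matched by trial id), per epoch, channel and frequency. With
#' `mode = "subtract"` it is subtracted; with `mode = "percent"` power is
#' divided by it (relative power).
#'
#' @param tfr a `ts_tfr` of the analysis window.
#' @param baseline a `ts_tfr` computed on baseline epochs of the same
#'   channels and frequencies (one epoch per trial).
#' @param mode `"subtract"` or `"percent"`.
#' @return The corrected `ts_tfr` with `baseline_power` filled in.
#' @export
baseline_correct <- function(tfr, baseline, mode = c("subtract", "percent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tfr, "ts_tfr"), inherits(baseline, "ts_tfr"))
  if (!isTRUE(all.equal(tfr$freqs_hz, baseline$freqs_hz)) ||
      dim(tfr$power)[2] != dim(baseline$power)[2]) {
    stop("baseline must match the analysis TFR in channels and frequencies")
  }
  base_mean <- apply(baseline$power, c(1, 2, 3), mean, na.rm = TRUE)
  map <- match(tfr$index$trial, baseline$index$trial)
  if (any(is.na(map))) stop("baseline is missing trials present in the TFR")
  out <- tfr
  d <- dim(tfr$power)
  bp <- base_mean[map, , , drop = FALSE]
  if (mode == "percent" && any(bp == 0, na.rm = TRUE)) {
    stop("zero baseline power: percent mode undefined")
  }
  for (j in seq_len(d[4])) {
    slice <- array(tfr$power[, , , j], dim = d[1:3])
    out$power[, , , j] <- if (mode == "subtract") slice - bp else slice / bp
  }
  out$baseline_power <- bp
  attr(out, "baseline_mode") <- mode
  out
}

#' Average power over a frequency band and time window
#'
#' @param tfr a `ts_tfr`.
#' @param band_hz length-2 band (inclusive), Hz.
#' @param window_s length-2 time window (inclusive, anchor-relative), s;
#'   `NULL` uses all time points.
#' @param per_time if `FALSE` (default), average over the time window to one
#'   scalar per epoch x channel; if `TRUE`, keep one band-mean value per
#'   window centre (column `time_s` added).
#' @return A tibble with one row per epoch x channel (x time point when
#'   `per_time`): `epoch`, `trial`, `letter_pos`, `channel`, `power`.
#' @export
band_power <- function(tfr, band_hz, window_s = NULL, per_time = FALSE) {
  stopifnot(inherits(tfr, "ts_tfr"), length(band_hz) == 2)
  fsel <- which(tfr$freqs_hz >= band_hz[1] & tfr$freqs_hz <= band_hz[2])
  tsel <- if (is.null(window_s)) seq_along(tfr$times_s) else {
    which(tfr$times_s >= window_s[1] & tfr$times_s <= window_s[2])
  }
  if (!length(fsel) || !length(tsel)) {
    stop("empty frequency-band or time-window selection")
  }
  sub <- tfr$power[, , fsel, tsel, drop = FALSE]
  d <- dim(sub)
  if (per_time) {
    pw <- apply(sub, c(1, 2, 4), mean, na.rm = TRUE)
    out <- tidyr::expand_grid(time_s = tfr$times_s[tsel],
                              channel = seq_len(d[2]),
                              epoch = tfr$index$epoch)
    out$trial <- tfr$index$trial[match(out$epoch, tfr$index$epoch)]
    out$letter_pos <- tfr$index$letter_pos[match(out$epoch,
                                                 tfr$index$epoch)]
    out$power <- as.vector(pw)
    out <- out[is.finite(out$power),
               c("epoch", "trial", "letter_pos", "channel", "time_s",
                 "power")]
    return(out)
  }
  pw <- apply(sub, c(1, 2), mean, na.rm = TRUE)
  tibble::tibble(
    epoch = rep(tfr$index$epoch, times = d[2]),
    trial = rep(tfr$index$trial, times = d[2]),
    letter_pos = rep(tfr$index$letter_pos, times = d[2]),
    channel = rep(seq_len(d[2]), each = d[1]),
    power = as.vector(pw))
}

#' Encoding-period letter band power table
#'
#' Pipeline convenience producing the input of
#' [detect_selective_sites()]: baseline-corrected gamma band power per
#' letter presentation and channel. Letter-anchored epochs are decomposed
#' with the fixed-window scheme; band power over `enc_window` is corrected
#' by the trial's baseline-window power; epochs whose excess kurtosis
#' exceeds `kurtosis_threshold` on the analysed channel are dropped.
#'
#' @param recording a preprocessed `ts_recording`.
#' @param events the event tibble.
#' @param band_hz gamma band used for selectivity, Hz.
#' @param enc_window letter-relative analysis window, s.
#' @param baseline_window window relative to first-letter onset, s.
#' @param kurtosis_threshold excess-kurtosis rejection threshold; `Inf`
#'   disables rejection.
#' @param baseline_mode passed to [baseline_correct()].
#' @param resolution `"sample"` (default) keeps one value per 50 ms window
#'   centre inside `enc_window` (the rows of one presentation form a block
#'   for label permutation); `"trial"` averages to one scalar per
#'   presentation.
#' @return Tibble: `trial`, `channel`, `letter`, `position`, `power` (and
#'   `time_s` for sample resolution).
#' @export
letter_band_power <- function(recording, events,
                              band_hz = c(70, 100),
                              enc_window = c(0.2, 0.5),
                              baseline_window = c(-0.8, -0.35),
                              kurtosis_threshold = 5,
                              baseline_mode = "subtract",
                              resolution = c("sample", "trial")) {
  resolution <- match.arg(resolution)
  freqs <- seq(floor(band_hz[1] / 5) * 5, ceiling(band_hz[2] / 5) * 5, by = 5)
  ep_letter <- epoch_recording(recording, events, "letter_onset", c(0, 0.7))
  ep_base <- epoch_recording(recording, events, "first_letter_onset",
                             baseline_window)
  tfr_letter <- compute_tfr(ep_letter, low_freqs = numeric(0),
                            high_freqs = freqs)
  tfr_base <- compute_tfr(ep_base, low_freqs = numeric(0),
                          high_freqs = freqs)
  tfr_corr <- baseline_correct(tfr_letter, tfr_base, mode = baseline_mode)
  tab <- band_power(tfr_corr, band_hz, enc_window,
                    per_time = resolution == "sample")
  letters_long <- tibble::tibble(
    trial = rep(events$trial, times = 3),
    position = rep(1:3, each = nrow(events)),
    letter = c(events$letter1, events$letter2, events$letter3))
  tab <- dplyr::left_join(
    dplyr::rename(tab, position = "letter_pos"), letters_long,
    by = c("trial", "position"))
  if (is.finite(kurtosis_threshold)) {
    d <- dim(ep_letter$data)
    kurt <- vapply(seq_len(d[1]), function(e) {
      vapply(seq_len(d[2]), function(ch) excess_kurtosis(ep_letter$data[e, ch, ]),
             numeric(1))
    }, numeric(d[2]))
    kurt_tbl <- tibble::tibble(
      epoch = rep(seq_len(d[1]), each = d[2]),
      channel = rep(seq_len(d[2]), times = d[1]),
      kurtosis = as.vector(kurt))
    tab <- dplyr::left_join(tab, kurt_tbl, by = c("epoch", "channel"))
    tab <- dplyr::filter(tab, .data$kurtosis <= kurtosis_threshold)
    tab$kurtosis <- NULL
  }
  keep <- c("trial", "channel", "letter", "position",
            if (resolution == "sample") "time_s", "power")
  dplyr::select(tab, dplyr::all_of(keep))
}
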