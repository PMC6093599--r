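# Phase-amplitude coupling as magnitude-squared coherence between the raw
# maintenance signal and the high-frequency power envelope, estimated over
# three overlapping 1 s retention segments and averaged over segments and
# trials; plus the peak-locked waveform-shape control.

#' High-frequency power envelope
#'
#' The power envelope at `center_freq_hz` is the squared magnitude of the
#' Fourier coefficient of a frequency-dependent sliding window (6 cycles
#' long, Hanning-tapered), evaluated at every sample where the window fits
#' entirely inside the epoch (per-sample stepping). Amplitude-normalized so
#' a unit sinusoid at the centre frequency has envelope 1.
#'
#' @param x numeric vector (one epoch, one channel).
#' @param fs sampling rate, Hz.
#' @param center_freq_hz envelope centre frequency, Hz.
#' @param n_cycles window length in cycles.
#' @return Numeric vector of `length(x)`; `NA` where the window does not fit.
#' @export
power_envelope <- function(x, fs, center_freq_hz, n_cycles = 6) {
  L <- as.integer(floor(n_cycles / center_freq_hz * fs))
  if (L > length(x)) stop("6-cycle window (", L,
                          " samples) longer than the epoch")
  if (L < 3) stop("window too short at this frequency/sampling rate")
  h <- hann_taper(L)
  cs <- h * cos(2 * pi * center_freq_hz * seq(0, L - 1) / fs)
  sn <- h * sin(2 * pi * center_freq_hz * seq(0, L - 1) / fs)
  cr <- stats::convolve(x, rev(cs), type = "filter")
  ci <- stats::convolve(x, rev(sn), type = "filter")
  env_valid <- (cr^2 + ci^2) * (2 / sum(h))^2
  out <- rep(NA_real_, length(x))
  offset <- (L - 1L) %/% 2L
  out[seq.int(offset + 1L, offset + length(env_valid))] <- env_valid
  out
}

#' Phase-amplitude coupling spectrum of maintenance epochs
#'
#' For every (phase frequency, amplitude frequency) pair, the coupling is
#' the magnitude-squared coherence between the raw segment signal and the
#' amplitude frequency's power envelope at the phase frequency: cross- and
#' auto-spectra (Hanning-tapered segment DFTs; envelopes mean-subtracted per
#' segment) are averaged over the three 1 s retention segments (50% overlap)
#' of every trial before forming the coherence, which is therefore bounded
#' in `[0, 1]` and invariant to overall amplitude scaling.
#'
#' @param epochs maintenance `ts_epochs` covering the retention interval
#'   (probe-anchored, e.g. window `c(-2, 0)`).
#' @param channel channel index to analyse.
#' @param phase_freqs phase-frequency axis, Hz.
#' @param amp_freqs amplitude-frequency axis, Hz (10--125 Hz in 5 Hz steps).
#' @param segment_centers_s segment centres in seconds after retention
#'   onset; segments are `segment_length_s` long and clipped to the samples
#'   where the envelope exists.
#' @param segment_length_s segment length, s.
#' @param n_cycles envelope window length in cycles.
#' @return A `ts_pac`: `coupling` (phase_freqs x amp_freqs matrix in
#'   `[0, 1]`), `phase_freqs_hz`, `amp_freqs_hz`, `n_segments`, `n_trials`.
#' @export
pac_spectrum <- function(epochs, channel = 1,
                         phase_freqs = 2:20,
                         amp_freqs = seq(10, 125, by = 5),
                         segment_centers_s = c(0.5, 1.0, 1.5),
                         segment_length_s = 1,
                         n_cycles = 6) {
  stopifnot(inherits(epochs, "ts_epochs"))
  fs <- epochs$sampling_rate_hz
  d <- dim(epochs$data)
  n_tr <- d[1]; n_samp <- d[3]
  if (any(amp_freqs > fs / 2) || any(phase_freqs >= fs / 2)) {
    stop("frequencies must lie within the Nyquist range")
  }
  n_seg_total <- n_tr * length(segment_centers_s)
  if (n_seg_total < 8) stop("at least 8 trial-segments are required")
  n_pf <- length(phase_freqs); n_af <- length(amp_freqs)
  Sxy <- matrix(0i, n_pf, n_af)
  Sxx <- matrix(0, n_pf, n_af)
  See <- matrix(0, n_pf, n_af)
  basis_cache <- new.env(parent = emptyenv())
  seg_basis <- function(len) {
    key <- as.character(len)
    if (!is.null(basis_cache[[key]])) return(basis_cache[[key]])
    h <- hann_taper(len)
    B <- exp(-2i * pi * outer(phase_freqs, seq(0, len - 1) / fs))
    B <- sweep(B, 2, h, `*`)
    basis_cache[[key]] <- B
    B
  }
  clipped <- FALSE
  for (tr in seq_len(n_tr)) {
    x <- epochs$data[tr, channel, ]
    if (stats::sd(x) == 0) stop("degenerate (zero-variance) segment in trial ", tr)
    for (ai in seq_len(n_af)) {
      env <- power_envelope(x, fs, amp_freqs[ai], n_cycles)
      valid <- which(!is.na(env))
      for (cs in segment_centers_s) {
        i0 <- as.integer(round((cs - segment_length_s / 2) * fs)) + 1L
        i1 <- as.integer(round((cs + segment_length_s / 2) * fs))
        idx <- intersect(seq.int(max(i0, 1L), min(i1, n_samp)), valid)
        if (length(idx) < i1 - i0 + 1L) clipped <- TRUE
        if (length(idx) < 0.25 * segment_length_s * fs) next
        B <- seg_basis(length(idx))
        e <- env[idx] - mean(env[idx])
        X <- B %*% x[idx]
        E <- B %*% e
        Sxy[, ai] <- Sxy[, ai] + X * Conj(E)
        Sxx[, ai] <- Sxx[, ai] + Mod(X)^2
        See[, ai] <- See[, ai] + Mod(E)^2
      }
    }
  }
  coupling <- Mod(Sxy)^2 / (Sxx * See)
  coupling[!is.finite(coupling)] <- 0
  dimnames(coupling) <- list(phase_freqs, amp_freqs)
  structure(list(coupling = coupling,
                 phase_freqs_hz = phase_freqs,
                 amp_freqs_hz = amp_freqs,
                 n_segments = length(segment_centers_s),
                 n_trials = n_tr,
                 channel = channel,
                 segments_clipped = clipped), class = "ts_pac")
}

#' @export
print.ts_pac <- function(x, ...) {
  cat(sprintf(
    "<ts_pac> %d phase x %d amplitude frequencies, %d trials x %d segments\n",
    length(x$phase_freqs_hz), length(x$amp_freqs_hz), x$n_trials,
    x$n_segments))
  mx <- which(x$coupling == max(x$coupling), arr.ind = TRUE)[1, ]
  cat(sprintf("  max coupling %.3f at %s Hz phase x %s Hz amplitude\n",
              max(x$coupling), rownames(x$coupling)[mx[1]],
              colnames(x$coupling)[mx[2]]))
  invisible(x)
}

#' Band-averaged PAC
#'
#' Mean of the coupling entries inside the phase-band by amplitude-band
#' rectangle (inclusive edges).
#'
#' @param spectrum a `ts_pac`.
#' @param phase_band,amp_band length-2 bands in Hz.
#' @return Scalar mean coupling.
#' @export
band_pac <- function(spectrum, phase_band = c(7, 13), amp_band = c(75, 120)) {
  stopifnot(inherits(spectrum, "ts_pac"))
  pf <- spectrum$phase_freqs_hz >= phase_band[1] &
    spectrum$phase_freqs_hz <= phase_band[2]
  af <- spectrum$amp_freqs_hz >= amp_band[1] &
    spectrum$amp_freqs_hz <= amp_band[2]
  if (!any(pf) || !any(af)) stop("empty frequency rectangle")
  mean(spectrum$coupling[pf, af])
}

#' Normalize PAC spectra for display and average over sites
#'
#' Each electrode's spectrum is divided by its own maximum before the
#' spectra are averaged, so sites with different absolute coupling scales
#' contribute equally to the grand average.
#'
#' @param spectra list of `ts_pac` objects with identical axes.
#' @return Matrix of the averaged normalized coupling (entries in `[0, 1]`).
#' @export
normalize_for_display <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  mats <- lapply(spectra, function(s) {
    stopifnot(inherits(s, "ts_pac"))
    m <- max(s$coupling)
    if (m <= 0) stop("all-zero PAC spectrum cannot be normalized")
    s$coupling / m
  })
  Reduce(`+`, mats) / length(mats)
}

#' Peak-locked average waveform-shape control
#'
#' Detects positive peaks of the 7--13 Hz band-passed signal, extracts
#' `+/- half_width_s` snippets of the unfiltered data around each peak,
#' averages them, and quantifies sinusoidality as the ratio of the mean
#' waveform's spectral power at its fundamental frequency to the summed
#' power at the second and third harmonics. Nonsinusoidal (sharp-edged or
#' sawtooth-like) rhythms, which can produce spurious phase-amplitude
#' coupling through their harmonics, give small ratios.
#'
#' @param epochs a `ts_epochs`.
#' @param channel channel to analyse.
#' @param band peak-detection band, Hz.
#' @param half_width_s snippet half width, s.
#' @param min_peaks minimum number of detected peaks required.
#' @param ratio_threshold harmonic ratio above which the waveform is deemed
#'   sinusoidal.
#' @return A `ts_peaklock`: `waveform` (mean snippet), `times_s`, `n_peaks`,
#'   `fundamental_hz`, `harmonic_ratio`, `sinusoidal`, `mean_tfr`
#'   (freqs x times mean time-frequency power of the snippets) and
#'   `tfr_freqs_hz`/`tfr_times_s`.
#' @export
peak_locked_average <- function(epochs, channel = 1, band = c(7, 13),
                                half_width_s = 0.15, min_peaks = 20,
                                ratio_threshold = 10) {
  stopifnot(inherits(epochs, "ts_epochs"))
  fs <- epochs$sampling_rate_hz
  d <- dim(epochs$data)
  half <- as.integer(round(half_width_s * fs))
  min_sep <- as.integer(floor(fs / band[2]))
  snippets <- list()
  for (tr in seq_len(d[1])) {
    x <- epochs$data[tr, channel, ]
    filt <- Re(band_analytic(x, fs, band))
    n <- length(filt)
    cand <- which(filt[2:(n - 1)] > filt[1:(n - 2)] &
                    filt[2:(n - 1)] >= filt[3:n] &
                    filt[2:(n - 1)] > 0) + 1L
    if (!length(cand)) next
    # enforce minimum separation, keeping the larger peak
    cand <- cand[order(filt[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (p in cand) {
      if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
    }
    kept <- kept[kept - half >= 1 & kept + half <= n]
    for (p in kept) {
      snippets[[length(snippets) + 1L]] <- x[(p - half):(p + half)]
    }
  }
  if (!length(snippets)) stop("no theta/alpha peaks found")
  if (length(snippets) < min_peaks) {
    stop("only ", length(snippets), " peaks found; at least ", min_peaks,
         " are required")
  }
  wf <- Reduce(`+`, snippets) / length(snippets)
  times <- seq(-half, half) / fs
  # fundamental: maximum Hanning-DFT amplitude of the mean waveform in band
  h <- hann_taper(length(wf))
  dft_power <- function(f) {
    Mod(sum(wf * h * exp(-2i * pi * f * seq_along(wf) / fs)) * 2 / sum(h))^2
  }
  grid <- seq(band[1], band[2], by = 0.25)
  p_grid <- vapply(grid, dft_power, numeric(1))
  f0 <- grid[which.max(p_grid)]
  ratio <- dft_power(f0) / (dft_power(2 * f0) + dft_power(3 * f0))
  # mean time-frequency power of the snippets (gamma range)
  snip_arr <- array(0, dim = c(length(snippets), 1, length(wf)))
  for (i in seq_along(snippets)) snip_arr[i, 1, ] <- snippets[[i]]
  snip_ep <- structure(list(
    data = snip_arr, sampling_rate_hz = fs,
    window = c(-half_width_s, half_width_s), anchor = "probe_onset",
    channel_labels = epochs$channel_labels[channel],
    index = tibble::tibble(epoch = seq_along(snippets),
                           trial = seq_along(snippets),
                           letter_pos = NA_integer_),
    kept_trial_ids = seq_along(snippets)), class = "ts_epochs")
  tfr <- compute_tfr(snip_ep, low_freqs = numeric(0),
                     high_freqs = seq(30, min(125, floor(fs / 2)), by = 5))
  mean_tfr <- apply(tfr$power[, 1, , , drop = FALSE], c(3, 4), mean,
                    na.rm = TRUE)
  structure(list(waveform = wf, times_s = times,
                 n_peaks = length(snippets),
                 fundamental_hz = f0,
                 harmonic_ratio = ratio,
                 sinusoidal = ratio > ratio_threshold,
                 ratio_threshold = ratio_threshold,
                 mean_tfr = mean_tfr,
                 tfr_freqs_hz = tfr$freqs_hz,
                 tfr_times_s = tfr$times_s), class = "ts_peaklock")
}

#' @export
print.ts_peaklock <- function(x, ...) {
  cat(sprintf(
    "<ts_peaklock> %d peaks; fundamental %.2f Hz; harmonic ratio %.1f (%s)\n",
    x$n_peaks, x$fundamental_hz, x$harmonic_ratio,
    if (x$sinusoidal) "sinusoidal" else "nonsinusoidal"))
  invisible(x)
}
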