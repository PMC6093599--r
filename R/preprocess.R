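# Preprocessing: resample -> common-average reference -> DFT line-noise
# removal -> epoching -> kurtosis-based artifact rejection. The stage order
# is fixed; preprocess_recording() applies and logs it.

# Zero-phase FIR filtering: symmetric (linear-phase) taps applied centred,
# with reflection padding so edges keep unit gain.
fir_zerophase <- function(x, h) {
  m <- length(h)
  stopifnot(m %% 2L == 1L)
  half <- (m - 1L) %/% 2L
  n <- length(x)
  xp <- c(rev(x[seq.int(2L, half + 1L)]), x,
          rev(x[seq.int(n - half, n - 1L)]))
  y <- stats::filter(xp, h, sides = 2)
  as.numeric(y[seq.int(half + 1L, half + n)])
}

#' Resample a recording with anti-aliasing
#'
#' Rational-ratio polyphase resampling: the signal is upsampled by the
#' numerator of the rate ratio, filtered with a zero-phase FIR low-pass at
#' 90% of the lower Nyquist frequency, and decimated by the denominator.
#' Event times are expressed in seconds and are therefore unaffected.
#'
#' @param recording a [new_recording()] object.
#' @param target_hz new sampling rate; must not exceed the current rate.
#' @param order FIR anti-aliasing filter order (even).
#' @return A resampled `ts_recording`.
#' @export
resample_recording <- function(recording, target_hz, order = 160) {
  stopifnot(inherits(recording, "ts_recording"))
  fs <- recording$sampling_rate_hz
  if (target_hz > fs) stop("target_hz must be <= the original sampling rate")
  if (any(!is.finite(recording$data))) stop("non-finite samples in recording")
  if (target_hz == fs) return(recording)
  den <- 1e6
  num <- round(target_hz / fs * den)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d0 <- g(num, den)
  p <- as.integer(num / d0); q <- as.integer(den / d0)
  cutoff <- 0.9 / max(p, q)           # normalized to the upsampled Nyquist
  h <- signal::fir1(order, cutoff) * p
  out <- t(apply(recording$data, 1, function(x) {
    if (p > 1L) {
      up <- numeric(length(x) * p)
      up[seq.int(1L, length(up), by = p)] <- x
      x <- up
    }
    fir_zerophase(x, h)[seq.int(1L, length(x) * 1L, by = q)]
  }))
  new_recording(out, target_hz, recording$channel_labels)
}

#' Re-reference to the common average
#'
#' Subtracts, sample-wise, the mean over all included channels from every
#' included channel. Excluded (bad) channels are left untouched and do not
#' contribute to the average.
#'
#' @param recording a `ts_recording`.
#' @param exclude integer indices of channels to exclude.
#' @return A re-referenced `ts_recording`.
#' @export
common_average_reference <- function(recording, exclude = integer(0)) {
  stopifnot(inherits(recording, "ts_recording"))
  incl <- setdiff(seq_len(nrow(recording$data)), exclude)
  if (length(incl) < 2) stop("common average requires at least 2 included channels")
  avg <- colMeans(recording$data[incl, , drop = FALSE])
  out <- recording$data
  out[incl, ] <- sweep(out[incl, , drop = FALSE], 2, avg)
  new_recording(out, recording$sampling_rate_hz, recording$channel_labels)
}

#' Remove line noise by DFT filtering
#'
#' For each listed frequency, the sine and cosine amplitudes over the whole
#' continuous recording are estimated by least squares and subtracted
#' (a DFT-based notch). Fitting over the full recording rather than per
#' epoch avoids epoch-edge bias.
#'
#' @param recording a `ts_recording`.
#' @param freqs_hz frequencies to remove (default 60 and 120 Hz).
#' @return A `ts_recording` with the listed components removed.
#' @export
remove_line_noise <- function(recording, freqs_hz = c(60, 120)) {
  stopifnot(inherits(recording, "ts_recording"))
  fs <- recording$sampling_rate_hz
  if (any(freqs_hz >= fs / 2)) {
    stop("line frequencies must lie below the Nyquist frequency ", fs / 2, " Hz")
  }
  n <- ncol(recording$data)
  tt <- (seq_len(n) - 1) / fs
  out <- recording$data
  for (f in freqs_hz) {
    basis <- cbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt))
    coefs <- qr.solve(crossprod(basis), crossprod(basis, t(out)))
    out <- out - t(basis %*% coefs)
  }
  new_recording(out, fs, recording$channel_labels)
}

#' Epoch a recording around task events
#'
#' Cuts fixed-length windows relative to an anchor event. The window is
#' half-open `[start, end)`; epoch length is `floor((end - start) * fs)`
#' samples. With `anchor = "letter_onset"` one epoch is produced per letter
#' presentation (three per trial) and the epoch index records the list
#' position.
#'
#' @param recording a `ts_recording`.
#' @param events the per-trial event tibble of [simulate_session()].
#' @param anchor `"first_letter_onset"`, `"letter_onset"` or `"probe_onset"`.
#' @param window length-2 numeric, window start/end in seconds relative to
#'   the anchor.
#' @return A `ts_epochs` object: `data` (epochs x channels x samples array),
#'   `sampling_rate_hz`, `window`, `anchor`, `index` (tibble with `epoch`,
#'   `trial`, and `letter_pos` for letter-anchored windows) and
#'   `kept_trial_ids`.
#' @export
epoch_recording <- function(recording, events,
                            anchor = c("first_letter_onset", "letter_onset",
                                       "probe_onset"),
                            window) {
  stopifnot(inherits(recording, "ts_recording"), length(window) == 2)
  anchor <- match.arg(anchor)
  if (window[2] <= window[1]) stop("epoch window must have positive length")
  fs <- recording$sampling_rate_hz
  n_samp <- as.integer(floor((window[2] - window[1]) * fs))
  if (n_samp < 1) stop("epoch window shorter than one sample")
  anchors <- switch(anchor,
    first_letter_onset = tibble::tibble(trial = events$trial,
                                        t0 = events$onset1_s,
                                        letter_pos = NA_integer_),
    probe_onset = tibble::tibble(trial = events$trial,
                                 t0 = events$probe_onset_s,
                                 letter_pos = NA_integer_),
    letter_onset = tibble::tibble(
      trial = rep(events$trial, each = 3),
      t0 = as.vector(rbind(events$onset1_s, events$onset2_s,
                           events$onset3_s)),
      letter_pos = rep(1:3, times = nrow(events))))
  starts <- as.integer(floor((anchors$t0 + window[1]) * fs)) + 1L
  if (any(starts < 1) || any(starts + n_samp - 1L > ncol(recording$data))) {
    stop("epoch window exceeds the recorded extent")
  }
  n_ep <- nrow(anchors)
  n_ch <- nrow(recording$data)
  arr <- array(NA_real_, dim = c(n_ep, n_ch, n_samp))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- recording$data[, starts[e]:(starts[e] + n_samp - 1L),
                                 drop = FALSE]
  }
  structure(list(
    data = arr,
    sampling_rate_hz = fs,
    window = window,
    anchor = anchor,
    channel_labels = recording$channel_labels,
    index = tibble::tibble(epoch = seq_len(n_ep), trial = anchors$trial,
                           letter_pos = anchors$letter_pos),
    kept_trial_ids = unique(anchors$trial)),
    class = "ts_epochs")
}

#' @export
print.ts_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ts_epochs> %d epochs x %d channels x %d samples @ %g Hz\n  anchor %s, window [%g, %g) s, %d trials kept\n",
    d[1], d[2], d[3], x$sampling_rate_hz, x$anchor, x$window[1], x$window[2],
    length(x$kept_trial_ids)))
  invisible(x)
}

#' Reject epochs by excess kurtosis
#'
#' Drops every epoch whose excess kurtosis (normal distribution gives 0) on
#' the channel under analysis exceeds the threshold; epileptiform transients
#' produce heavy-tailed segments with kurtosis well above typical thresholds.
#'
#' @param epochs a `ts_epochs` object.
#' @param threshold excess-kurtosis threshold (> 0; 5 is the conventional
#'   choice for intracranial recordings).
#' @param channel channel index whose kurtosis governs rejection; `NULL`
#'   (default) rejects an epoch if any channel exceeds the threshold.
#' @return The `ts_epochs` with offending epochs removed; the per-epoch
#'   kurtosis log is attached as attribute `rejection_log` (tibble: epoch,
#'   trial, channel, kurtosis, rejected).
#' @export
reject_by_kurtosis <- function(epochs, threshold = 5, channel = NULL) {
  stopifnot(inherits(epochs, "ts_epochs"), threshold > 0)
  d <- dim(epochs$data)
  chans <- if (is.null(channel)) seq_len(d[2]) else as.integer(channel)
  kurt <- vapply(seq_len(d[1]), function(e) {
    vapply(chans, function(ch) excess_kurtosis(epochs$data[e, ch, ]),
           numeric(1))
  }, numeric(length(chans)))
  kurt <- matrix(kurt, nrow = length(chans))
  bad <- apply(kurt > threshold, 2, any)
  log <- tibble::tibble(
    epoch = rep(seq_len(d[1]), each = length(chans)),
    trial = rep(epochs$index$trial, each = length(chans)),
    channel = rep(chans, times = d[1]),
    kurtosis = as.vector(kurt),
    rejected = rep(bad, each = length(chans)))
  if (all(bad)) {
    stop("all epochs rejected by kurtosis on channel(s) ",
         paste(epochs$channel_labels[chans], collapse = ", "))
  }
  keep <- which(!bad)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$index <- epochs$index[keep, ]
  out$index$epoch <- seq_along(keep)
  out$kept_trial_ids <- unique(out$index$trial)
  attr(out, "rejection_log") <- log
  out
}

#' Run the fixed preprocessing chain
#'
#' Applies, in a fixed logged order: resampling, common-average reference,
#' DFT line-noise removal. Epoching and kurtosis rejection are then applied
#' per analysis window by the caller (the analysis windows differ between
#' stages).
#'
#' @param recording a `ts_recording`.
#' @param target_hz analysis sampling rate (default 250 Hz).
#' @param line_freqs_hz line frequencies to remove.
#' @param exclude_channels channels excluded from the common average.
#' @return A preprocessed `ts_recording` with attribute `preprocess_log`.
#' @export
preprocess_recording <- function(recording, target_hz = 250,
                                 line_freqs_hz = c(60, 120),
                                 exclude_channels = integer(0)) {
  out <- resample_recording(recording, target_hz)
  out <- common_average_reference(out, exclude = exclude_channels)
  out <- remove_line_noise(out, line_freqs_hz)
  attr(out, "preprocess_log") <- sprintf(
    "resample(%g Hz) -> common_average_reference(exclude: %s) -> remove_line_noise(%s Hz)",
    target_hz,
    if (length(exclude_channels)) paste(exclude_channels, collapse = ",") else "none",
    paste(line_freqs_hz, collapse = ","))
  out
}
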