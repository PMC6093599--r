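# Shared fixtures, all generated in code.

# Wrap a numeric vector or trials x samples matrix as a single-channel
# epoch set.
mk_epochs <- function(x, fs = 250, window = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n_tr <- nrow(x); n <- ncol(x)
  if (is.null(window)) window <- c(0, n / fs)
  structure(list(
    data = array(x, dim = c(n_tr, 1, n)),
    sampling_rate_hz = fs,
    window = window,
    anchor = "probe_onset",
    channel_labels = "ch01",
    index = tibble::tibble(epoch = seq_len(n_tr), trial = seq_len(n_tr),
                           letter_pos = NA_integer_),
    kept_trial_ids = seq_len(n_tr)), class = "ts_epochs")
}

# Small fast session: low rate, no artifacts unless asked.
quick_session <- function(seed, n_trials = 30, n_channels = 1, ...) {
  args <- utils::modifyList(
    list(sampling_rate_hz = 250, n_trials = n_trials,
         n_channels = n_channels, artifact_rate_per_trial = 0,
         rng_seed = seed),
    list(...))
  simulate_session(do.call(simulation_config, args))
}

# Independent brute-force plug-in MI oracle: explicit double loop over the
# joint histogram, never sharing code with the implementation.
brute_force_mi <- function(x, y, n_bins = 256) {
  pooled <- c(x, y)
  lab <- c(rep(0, length(x)), rep(1, length(y)))
  rng <- range(pooled)
  if (diff(rng) == 0) bin <- rep(1, length(pooled)) else {
    bin <- pmin(floor((pooled - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1,
                n_bins)
  }
  n <- length(pooled)
  h <- 0
  for (b in unique(bin)) {
    p <- sum(bin == b) / n
    h <- h - p * log2(p)
  }
  h_cond <- 0
  for (l in 0:1) {
    pl <- sum(lab == l) / n
    if (pl == 0) next
    hb <- 0
    for (b in unique(bin[lab == l])) {
      p <- sum(bin == b & lab == l) / sum(lab == l)
      hb <- hb - p * log2(p)
    }
    h_cond <- h_cond + pl * hb
  }
  max(0, h - h_cond)
}

# Independent brute-force template fit: build every rotated template
# explicitly and count matches.
brute_force_template_fit <- function(labels) {
  n <- length(labels)
  base <- rep(1:3, each = n / 3)
  best <- -1
  for (r in 0:(n - 1)) {
    tmpl <- integer(n)
    for (k in seq_len(n)) {
      tmpl[((k - 1 + r) %% n) + 1] <- base[k]
    }
    fit <- sum(tmpl == labels)
    if (fit > best) best <- fit
  }
  best
}

# Fourier amplitude of a real series at one frequency.
f_amp <- function(x, f, fs) {
  n <- length(x)
  Mod(sum(x * exp(-2i * pi * f * (0:(n - 1)) / fs))) * 2 / n
}
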