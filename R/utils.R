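# Low-level numerical helpers shared across modules.

#' Hanning taper of length n (endpoints zero)
#' @noRd
hann_taper <- function(n) {
  if (n < 1) stop("taper length must be >= 1")
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Unit-sum Hanning smoothing kernel spanning `width_s` seconds
#' @noRd
hann_kernel <- function(width_s, fs) {
  n <- max(3L, as.integer(round(width_s * fs)))
  if (n %% 2L == 0L) n <- n + 1L   # odd length: exactly centred smoothing
  k <- hann_taper(n)
  k / sum(k)
}

#' Smooth a series with a unit-sum kernel; edges renormalized so that a
#' constant input maps to itself everywhere.
#' @noRd
smooth_series <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  if (m >= n) return(rep(mean(x), n))
  out <- as.numeric(stats::filter(x, kernel, sides = 2))
  # renormalized partial kernels at the edges
  half_l <- (m - 1L) %/% 2L
  half_r <- m - 1L - half_l
  for (i in which(is.na(out))) {
    lo <- max(1L, i - half_r)
    hi <- min(n, i + half_l)
    k <- kernel[(lo - i + half_r + 1L):(hi - i + half_r + 1L)]
    out[i] <- sum(x[lo:hi] * k) / sum(k)
  }
  out
}

#' 1/f^alpha ("pink") noise by spectral shaping, unit variance
#' @noRd
pink_noise <- function(n, exponent = 1, fs = 1) {
  if (n < 4) return(stats::rnorm(n))
  n_req <- n
  # pad to a highly composite length: mixed-radix FFT degrades badly on
  # lengths with large prime factors
  n <- stats::nextn(n, c(2, 3, 5))
  n_half <- n %/% 2L
  f <- seq_len(n_half) * fs / n
  amp <- f^(-exponent / 2)
  re <- stats::rnorm(n_half)
  im <- stats::rnorm(n_half)
  spec <- complex(real = re, imaginary = im) * amp
  full <- complex(length.out = n)
  full[2:(n_half + 1L)] <- spec
  # Hermitian symmetry for a real signal
  if (n %% 2L == 0L) {
    full[n_half + 1L] <- complex(real = re[n_half] * amp[n_half])
    if (n_half > 1L) full[(n_half + 2L):n] <- Conj(spec[(n_half - 1L):1L])
  } else {
    full[(n_half + 2L):n] <- Conj(spec[n_half:1L])
  }
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n_req)] / n
  as.numeric(scale(x))
}

#' Von Mises sampler (Best & Fisher rejection scheme); kappa = 0 is uniform
#' @noRd
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Circular mean of angles (radians), optionally weighted; result in [0, 2pi)
#' @noRd
circ_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  z <- sum(w * exp(1i * theta))
  if (Mod(z) < .Machine$double.eps) return(NA_real_)
  Arg(z) %% (2 * pi)
}

#' Absolute circular distance between two angles, in [0, pi]
#' @noRd
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Rayleigh test for circular uniformity (returns p-value)
#' @noRd
rayleigh_test <- function(theta) {
  n <- length(theta)
  r_bar <- Mod(mean(exp(1i * theta)))
  z <- n * r_bar^2
  # Standard small-sample corrected approximation
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  min(max(p, 0), 1)
}

#' Band-limited analytic signal via frequency-domain construction.
#'
#' Computes the analytic signal of the `band` Hz component of a real series:
#' the FFT is multiplied by a band indicator with raised-cosine edges of
#' `taper_hz`, negative frequencies are zeroed (positives doubled), and the
#' inverse transform yields a complex series whose argument is instantaneous
#' phase (0 at the positive peak of a cosine) and whose squared modulus is
#' instantaneous power. Exactly zero-phase by construction.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param band length-2 numeric, band edges in Hz (0 < lo < hi < fs/2).
#' @param taper_hz width of the raised-cosine band edges, Hz.
#' @return complex vector of the same length as `x`.
#' @keywords internal
band_analytic <- function(x, fs, band, taper_hz = 1) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  if (band[2] >= fs / 2) {
    stop("band upper edge ", band[2], " Hz must lie below the Nyquist frequency ",
         fs / 2, " Hz")
  }
  if (any(!is.finite(x))) stop("non-finite samples in input")
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  w <- numeric(n)
  pos <- f <= fs / 2
  fp <- f[pos]
  lo <- band[1]; hi <- band[2]
  ramp_lo <- max(lo - taper_hz, 0)
  ramp_hi <- min(hi + taper_hz, fs / 2)
  wp <- numeric(length(fp))
  wp[fp >= lo & fp <= hi] <- 1
  sel <- fp > ramp_lo & fp < lo
  wp[sel] <- 0.5 * (1 - cos(pi * (fp[sel] - ramp_lo) / (lo - ramp_lo)))
  sel <- fp > hi & fp < ramp_hi
  wp[sel] <- 0.5 * (1 + cos(pi * (fp[sel] - hi) / (ramp_hi - hi)))
  w[pos] <- wp * 2
  w[1] <- 0
  stats::fft(X * w, inverse = TRUE) / n
}

#' Unit-RMS band-limited Gaussian noise
#' @noRd
band_noise <- function(n, fs, band) {
  pad <- stats::nextn(n + 16L, c(2, 3, 5))
  x <- Re(band_analytic(stats::rnorm(pad), fs, band))[seq_len(n)]
  x / stats::sd(x)
}

#' Plateau envelope with raised-cosine ramps
#' @noRd
tukey_env <- function(n, ramp) {
  env <- rep(1, n)
  r <- min(ramp, n %/% 2)
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- up
    env[seq.int(n - r + 1L, n)] <- rev(up)
  }
  env
}

#' Excess kurtosis (normal -> 0), the convention used for artifact rejection
#' @noRd
excess_kurtosis <- function(x) {
  e1071::kurtosis(x, type = 1)
}

#' Derive a bounded child seed from a master seed and a stage index
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483647)
}
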