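# Letter-selective site detection: plug-in mutual information between binned
# encoding-period gamma power and a binary letter label, permutation null,
# Bonferroni correction over electrodes x letter pairs, tuned/untuned
# assignment, and maintenance trial subsetting.

# Observed MI and its permutation z-score (binning held fixed, labels
# permuted at block level).
mi_permutation_z <- function(x, y, bx, by, n_bins, n_perm) {
  pooled <- c(x, y)
  bins <- equal_width_bins(pooled, n_bins)
  blocks <- c(paste0("x.", bx), paste0("y.", by))
  ub <- unique(blocks)
  vb <- match(blocks, ub)
  lab0 <- ifelse(startsWith(ub, "x."), 0L, 1L)
  mi <- mi_from_bins(bins, lab0[vb], n_bins)
  null <- vapply(seq_len(n_perm), function(i) {
    mi_from_bins(bins, sample(lab0)[vb], n_bins)
  }, numeric(1))
  s <- stats::sd(null)
  c(mi = mi, z = if (s > 0) (mi - mean(null)) / s else 0)
}

# Bin pooled values into n_bins equal-width bins over their observed range.
equal_width_bins <- function(pooled, n_bins) {
  rng <- range(pooled)
  if (diff(rng) == 0) return(rep(1L, length(pooled)))
  b <- floor((pooled - rng[1]) / diff(rng) * n_bins) + 1L
  pmin(b, n_bins)
}

# MI (bits) between precomputed bin assignments and a 0/1 label vector.
mi_from_bins <- function(bins, labels, n_bins) {
  n <- length(bins)
  joint <- tabulate(bins + n_bins * labels, nbins = 2L * n_bins)
  pj <- joint[joint > 0] / n
  marg_b <- tabulate(bins, nbins = n_bins)
  pb <- marg_b[marg_b > 0] / n
  n1 <- sum(labels)
  pl <- c(n - n1, n1) / n
  pl <- pl[pl > 0]
  h_b <- -sum(pb * log2(pb))
  h_l <- -sum(pl * log2(pl))
  h_j <- -sum(pj * log2(pj))
  # MI = H(bins) - H(bins | label) = H(bins) + H(label) - H(bins, label)
  max(0, h_b + h_l - h_j)
}

#' Mutual information between gamma power and a binary letter label
#'
#' Plug-in mutual information, in bits, between the pooled power values
#' (binned into `n_bins` equal-width bins over the pooled min--max range) and
#' the letter label (0 for the first letter's trials, 1 for the second's).
#' Zero-probability bins contribute nothing to the entropies; a constant
#' pooled input occupies a single bin and yields MI 0.
#'
#' @param gamma_power_x,gamma_power_y baseline-corrected gamma power values
#'   for the two letters.
#' @param n_bins number of equal-width power bins.
#' @return MI in bits (in `[0, 1]` for binary labels).
#' @export
mutual_information <- function(gamma_power_x, gamma_power_y, n_bins = 256) {
  if (!length(gamma_power_x) || !length(gamma_power_y)) {
    stop("both inputs must be non-empty")
  }
  pooled <- c(gamma_power_x, gamma_power_y)
  if (any(!is.finite(pooled))) stop("non-finite power values")
  bins <- equal_width_bins(pooled, n_bins)
  labels <- c(rep(0L, length(gamma_power_x)), rep(1L, length(gamma_power_y)))
  mi_from_bins(bins, labels, n_bins)
}

#' Permutation test for a letter pair's mutual information
#'
#' The null distribution is built by permuting which observations carry
#' label 0 versus 1 (label counts fixed; the binning, which depends only on
#' the pooled values, is unchanged). When the inputs carry block identifiers
#' (`block_x`/`block_y`, e.g. one block per letter presentation contributing
#' several time-resolved power samples), whole blocks are relabelled, which
#' preserves the within-presentation dependence of the samples. When the
#' total number of distinct label assignments is at most `exact_max`, all of
#' them are enumerated and the p-value is the exact fraction of permuted MI
#' values greater than or equal to the observed MI. Otherwise `n_perm`
#' Monte-Carlo permutations are drawn and the add-one rule
#' p = (#\{MI_perm >= MI_obs\} + 1) / (n_perm + 1) keeps the test valid.
#'
#' @inheritParams mutual_information
#' @param n_perm number of Monte-Carlo permutations (>= 100).
#' @param exact_max enumeration is used when the number of block label
#'   assignments is at most this.
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @param block_x,block_y optional block identifiers (same lengths as the
#'   power vectors); labels are permuted at block level.
#' @return A list: `p_raw`, `mi_obs`, `method` ("exact" or "monte_carlo"),
#'   `n_perm_used`.
#' @export
pair_permutation_test <- function(gamma_power_x, gamma_power_y,
                                  n_perm = 10000, n_bins = 256,
                                  exact_max = 10000, seed = NULL,
                                  block_x = NULL, block_y = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  nx <- length(gamma_power_x); ny <- length(gamma_power_y)
  if (is.null(block_x)) block_x <- paste0("x", seq_len(nx))
  if (is.null(block_y)) block_y <- paste0("y", seq_len(ny))
  stopifnot(length(block_x) == nx, length(block_y) == ny)
  pooled <- c(gamma_power_x, gamma_power_y)
  if (any(!is.finite(pooled))) stop("non-finite power values")
  bins <- equal_width_bins(pooled, n_bins)
  # value -> block mapping; labels are attached to blocks
  blocks <- c(paste0("x.", block_x), paste0("y.", block_y))
  ublocks <- unique(blocks)
  val_block <- match(blocks, ublocks)
  block_lab0 <- ifelse(startsWith(ublocks, "x."), 0L, 1L)
  nbx <- sum(block_lab0 == 0L)
  nb <- length(ublocks)
  mi_obs <- mi_from_bins(bins, block_lab0[val_block], n_bins)
  n_comb <- choose(nb, nbx)
  if (n_comb <= exact_max) {
    combs <- utils::combn(nb, nbx)
    null <- apply(combs, 2, function(ix) {
      lab <- rep(1L, nb); lab[ix] <- 0L
      mi_from_bins(bins, lab[val_block], n_bins)
    })
    p <- mean(null >= mi_obs)
    method <- "exact"; n_used <- n_comb
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      mi_from_bins(bins, sample(block_lab0)[val_block], n_bins)
    }, numeric(1))
    p <- (sum(null >= mi_obs) + 1) / (n_perm + 1)
    method <- "monte_carlo"; n_used <- n_perm
  }
  list(p_raw = p, mi_obs = mi_obs, method = method, n_perm_used = n_used)
}

#' Detect letter-selective channels
#'
#' For every channel, evaluates the mutual information of every unordered
#' letter pair (letters with at least `min_trials` presentations each),
#' selects the best pair, runs the full permutation test on it, and
#' Bonferroni-corrects its p-value for the number of channels times the
#' number of pairs. A channel is selective when the corrected p falls below
#' `alpha`. Of the best pair, the letter with the higher mean gamma power is
#' the tuned letter, the other the untuned one.
#'
#' Because the plug-in MI bias depends on each pair's own pooled binning,
#' raw MI values are not comparable across pairs; the best pair is therefore
#' chosen by the permutation z-score (observed MI standardized against a
#' screening permutation null with the binning held fixed), which is
#' bias-matched by construction. Ties are broken by lexicographic letter
#' order.
#'
#' @param power_table tibble with columns `trial`, `channel`, `letter`,
#'   `power` and (at sample resolution) `position`/`time_s`, e.g. from
#'   [letter_band_power()]. Multiple rows of one presentation (trial x
#'   position) form a block: MI pools all values, the permutation relabels
#'   presentations.
#' @param alpha family-wise significance level.
#' @param n_bins power bins for the MI estimate.
#' @param n_perm Monte-Carlo permutations for the best pair's test.
#' @param n_perm_screen screening permutations per pair for the z-score.
#' @param min_trials minimum presentations per letter for eligibility.
#' @param seed integer seed for the permutation draws.
#' @return A `ts_selectivity` tibble, one row per channel: `channel`,
#'   `letter_x`, `letter_y` (best pair), `mi_bits`, `z`, `p_raw`,
#'   `p_corrected`, `selective`, `tuned`, `untuned`, `n_pairs`. The full
#'   pair table (with per-pair MI and z) is attached as attribute
#'   `all_pair_mis`.
#' @export
detect_selective_sites <- function(power_table, alpha = 0.05, n_bins = 256,
                                   n_perm = 10000, n_perm_screen = 400,
                                   min_trials = 8, seed = NULL) {
  stopifnot(all(c("trial", "channel", "letter", "power") %in%
                  names(power_table)))
  if (!is.null(seed)) set.seed(seed)
  channels <- sort(unique(power_table$channel))
  if (!"position" %in% names(power_table)) power_table$position <- 1L
  all_rows <- list(); res_rows <- list()
  for (ch in channels) {
    sub <- power_table[power_table$channel == ch, ]
    sub$block <- paste(sub$trial, sub$position, sep = ".")
    pres <- unique(sub[, c("letter", "block")])
    counts <- table(pres$letter)
    eligible <- sort(names(counts)[counts >= min_trials])
    if (length(eligible) < 2) {
      stop("channel ", ch, ": fewer than 2 letters with >= ", min_trials,
           " trials")
    }
    pairs <- utils::combn(eligible, 2)
    screen <- apply(pairs, 2, function(pr) {
      sx <- sub[sub$letter == pr[1], ]
      sy <- sub[sub$letter == pr[2], ]
      mi_permutation_z(sx$power, sy$power, sx$block, sy$block,
                       n_bins = n_bins, n_perm = n_perm_screen)
    })
    all_rows[[length(all_rows) + 1L]] <- tibble::tibble(
      channel = ch, letter_x = pairs[1, ], letter_y = pairs[2, ],
      mi_bits = screen["mi", ], z = screen["z", ],
      n_x = as.integer(counts[pairs[1, ]]),
      n_y = as.integer(counts[pairs[2, ]]))
    best <- which.max(screen["z", ])  # lexicographic pair order: first max
    sx <- sub[sub$letter == pairs[1, best], ]
    sy <- sub[sub$letter == pairs[2, best], ]
    px <- sx$power; py <- sy$power
    perm <- pair_permutation_test(px, py, n_perm = n_perm, n_bins = n_bins,
                                  block_x = sx$block, block_y = sy$block)
    tuned_first <- mean(px) >= mean(py)
    res_rows[[length(res_rows) + 1L]] <- tibble::tibble(
      channel = ch,
      letter_x = pairs[1, best], letter_y = pairs[2, best],
      mi_bits = screen["mi", best], z = screen["z", best],
      p_raw = perm$p_raw,
      n_pairs = ncol(pairs),
      tuned = if (tuned_first) pairs[1, best] else pairs[2, best],
      untuned = if (tuned_first) pairs[2, best] else pairs[1, best])
  }
  res <- dplyr::bind_rows(res_rows)
  res$p_corrected <- pmin(1, res$p_raw * length(channels) * res$n_pairs)
  res$selective <- res$p_corrected < alpha
  res <- dplyr::select(res, "channel", "letter_x", "letter_y", "mi_bits",
                       "z", "p_raw", "p_corrected", "selective", "tuned",
                       "untuned", "n_pairs")
  attr(res, "all_pair_mis") <- dplyr::bind_rows(all_rows)
  class(res) <- c("ts_selectivity", class(res))
  res
}

#' Maintenance trial subsets for a tuned/untuned letter pair
#'
#' Tuned trials are those whose memorized list contains the tuned letter but
#' not the untuned one; untuned trials contain the untuned letter but not
#' the tuned one. The two subsets are disjoint by construction.
#'
#' @param events the event tibble.
#' @param tuned,untuned the channel's tuned and untuned letters.
#' @return A list with integer vectors `tuned_trials` and `untuned_trials`.
#' @export
maintenance_trial_subsets <- function(events, tuned, untuned) {
  if (identical(tuned, untuned)) stop("tuned and untuned letters must differ")
  lists <- cbind(events$letter1, events$letter2, events$letter3)
  has_t <- apply(lists, 1, function(l) tuned %in% l)
  has_u <- apply(lists, 1, function(l) untuned %in% l)
  out <- list(tuned_trials = events$trial[has_t & !has_u],
              untuned_trials = events$trial[has_u & !has_t])
  if (!length(out$tuned_trials)) {
    warning("tuned-letter trial subset is empty")
  }
  if (!length(out$untuned_trials)) {
    warning("untuned-letter trial subset is empty")
  }
  out
}
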