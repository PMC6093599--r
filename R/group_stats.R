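# Site-level comparisons: paired/two-sample two-tailed t tests with paired
# Cohen's d, and the reaction-time median-split control.

#' Paired two-tailed t test with effect size
#'
#' Standard paired t statistic with two-tailed p and paired Cohen's d
#' (mean of the differences over their standard deviation). When every
#' difference is zero the degenerate result (statistic 0, p 1, d 0) is
#' reported instead of an error.
#'
#' @param values_a,values_b per-site values, equal length, n >= 2.
#' @param contrast descriptive label.
#' @return A `ts_comparison` list: `statistic`, `p_two_tailed`,
#'   `effect_size_d`, `n`, `contrast`, `paired`.
#' @export
paired_t <- function(values_a, values_b, contrast = "a_vs_b") {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  diffs <- values_a - values_b
  if (all(diffs == 0)) {
    return(structure(list(statistic = 0, p_two_tailed = 1,
                          effect_size_d = 0, n = length(diffs),
                          contrast = contrast, paired = TRUE),
                     class = "ts_comparison"))
  }
  if (stats::sd(diffs) == 0) stop("zero difference variance with nonzero mean")
  tt <- stats::t.test(values_a, values_b, paired = TRUE,
                      alternative = "two.sided")
  structure(list(statistic = unname(tt$statistic),
                 p_two_tailed = tt$p.value,
                 effect_size_d = mean(diffs) / stats::sd(diffs),
                 n = length(diffs),
                 contrast = contrast, paired = TRUE),
            class = "ts_comparison")
}

#' Two-sample (unpaired) two-tailed t test with effect size
#'
#' Welch two-sample t test; the effect size is Cohen's d with the pooled
#' standard deviation.
#'
#' @param values_a,values_b values for the two groups (n >= 2 each).
#' @param contrast descriptive label.
#' @return A `ts_comparison` list.
#' @export
two_sample_t <- function(values_a, values_b, contrast = "a_vs_b") {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  tt <- stats::t.test(values_a, values_b, alternative = "two.sided")
  na <- length(values_a); nb <- length(values_b)
  sp <- sqrt(((na - 1) * stats::var(values_a) +
                (nb - 1) * stats::var(values_b)) / (na + nb - 2))
  structure(list(statistic = unname(tt$statistic),
                 p_two_tailed = tt$p.value,
                 effect_size_d = if (sp > 0) (mean(values_a) - mean(values_b)) / sp else 0,
                 n = na + nb,
                 contrast = contrast, paired = FALSE),
            class = "ts_comparison")
}

#' @export
print.ts_comparison <- function(x, ...) {
  cat(sprintf(
    "<ts_comparison> %s: t = %.3f, two-tailed p = %.4g, d = %.2f, n = %d%s\n",
    x$contrast, x$statistic, x$p_two_tailed, x$effect_size_d, x$n,
    if (x$paired) " (paired)" else ""))
  invisible(x)
}

#' Reaction-time median-split control
#'
#' Splits trials at the median reaction time (ties assigned to the fast
#' half), averages the per-trial PAC values of each half within each site,
#' and compares fast versus slow halves across sites with a paired t test.
#' A planted-coupling generator whose reaction times are independent of the
#' signal should show no difference.
#'
#' @param events the event tibble (`trial`, `rt_s`).
#' @param pac_by_trial tibble with columns `site`, `trial`, `pac`: a
#'   per-trial band-averaged PAC value per site.
#' @param min_per_half minimum trials required in each half.
#' @return A `ts_rt_split` list: `comparison` (fast vs slow
#'   `ts_comparison`), `per_site` tibble (`site`, `fast`, `slow`),
#'   `median_rt_s`, `fast_trials`, `slow_trials`.
#' @export
rt_median_split <- function(events, pac_by_trial, min_per_half = 8) {
  stopifnot(all(c("site", "trial", "pac") %in% names(pac_by_trial)))
  rts <- events$rt_s
  if (stats::sd(rts) == 0) stop("constant reaction times: median split undefined")
  med <- stats::median(rts)
  fast <- events$trial[rts <= med]   # ties at the median go to the fast half
  slow <- events$trial[rts > med]
  if (length(fast) < min_per_half || length(slow) < min_per_half) {
    stop("fewer than ", min_per_half, " trials in a median-split half")
  }
  per_site <- pac_by_trial |>
    dplyr::mutate(half = ifelse(.data$trial %in% fast, "fast", "slow")) |>
    dplyr::group_by(.data$site, .data$half) |>
    dplyr::summarise(pac = mean(.data$pac), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "half", values_from = "pac")
  cmp <- paired_t(per_site$fast, per_site$slow, contrast = "fast_vs_slow_rt")
  structure(list(comparison = cmp, per_site = per_site,
                 median_rt_s = med, fast_trials = fast, slow_trials = slow),
            class = "ts_rt_split")
}

#' @export
print.ts_rt_split <- function(x, ...) {
  cat(sprintf("<ts_rt_split> median RT %.3f s; %d fast / %d slow trials\n",
              x$median_rt_s, length(x$fast_trials), length(x$slow_trials)))
  print(x$comparison)
  invisible(x)
}
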