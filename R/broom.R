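# broom-style tidiers for the fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selectivity result
#'
#' @param x a `ts_selectivity`.
#' @param all_pairs if `TRUE`, return the full pair-by-pair MI table instead
#'   of the per-channel summary.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.ts_selectivity <- function(x, all_pairs = FALSE, ...) {
  if (all_pairs) return(attr(x, "all_pair_mis"))
  tibble::as_tibble(unclass(x)[names(x)])
}

#' Tidy a serial-order test: one row per surrogate fit value
#'
#' @param x a `ts_order_test`.
#' @param ... unused.
#' @return Tibble with `fit` and `n` (surrogate counts).
#' @export
tidy.ts_order_test <- function(x, ...) {
  tb <- table(x$surrogate_fits)
  tibble::tibble(fit = as.integer(names(tb)), n = as.integer(tb))
}

#' One-row summary of a serial-order test
#'
#' @param x a `ts_order_test`.
#' @param ... unused.
#' @return One-row tibble: `observed_fit`, `best_template_rotation`,
#'   `p_value`, `n_shuffles`, `n_sites`.
#' @export
glance.ts_order_test <- function(x, ...) {
  tibble::tibble(observed_fit = x$observed_fit,
                 best_template_rotation = x$best_template_rotation,
                 p_value = x$p_value,
                 n_shuffles = x$n_shuffles,
                 n_sites = x$profile$n_sites)
}

#' Tidy a comparison result
#'
#' @param x a `ts_comparison`.
#' @param ... unused.
#' @return One-row tibble.
#' @export
tidy.ts_comparison <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, statistic = x$statistic,
                 p_two_tailed = x$p_two_tailed,
                 effect_size_d = x$effect_size_d, n = x$n,
                 paired = x$paired)
}

#' Tidy a phase-bin profile: one row per position x bin
#'
#' @param x a `ts_phase_profile`.
#' @param ... unused.
#' @return Tibble with `position`, `bin`, `phase_rad`, `power`, `deviation`,
#'   `label`.
#' @export
tidy.ts_phase_profile <- function(x, ...) {
  df <- tidyr::expand_grid(position = 1:3, bin = seq_len(x$n_bins))
  df$phase_rad <- x$bin_centers[df$bin]
  df$power <- as.vector(t(x$power_by_position))
  df$deviation <- as.vector(t(x$deviation_by_position))
  df$label <- x$labels[df$bin]
  df
}
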