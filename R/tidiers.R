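#' Tidy a permutation contrast
#'
#' @param x a `permutation_contrast`.
#' @param ... unused.
#' @return One-row tibble: `contrast`, `effect`, `p_value`, `n`, `n_perm`.
#' @export
tidy.permutation_contrast <- function(x, ...) {
  tibble::tibble(contrast = paste(x$levels[2], "-", x$levels[1]),
                 effect = x$effect, p_value = x$p_value,
                 n = x$n, n_perm = x$n_perm)
}

#' @rdname tidy.permutation_contrast
#' @export
glance.permutation_contrast <- function(x, ...) {
  tibble::tibble(effect = x$effect, p_value = x$p_value, n = x$n,
                 n_perm = x$n_perm,
                 null_sd = sd(x$perm_effects))
}

#' Tidy a fitted growth spline
#'
#' @param x a `growth_spline` from [fit_growth_spline()].
#' @param ... unused.
#' @return `tidy()`: per-day fitted values over the observed range;
#'   `glance()`: one-row fit summary (n, effective df, GCV score, range).
#' @export
tidy.growth_spline <- function(x, ...) {
  doy <- seq(x$doy_range[1], x$doy_range[2], by = 1)
  tibble::tibble(doy = doy, fitted = predict(x, doy = doy))
}

#' @rdname tidy.growth_spline
#' @export
glance.growth_spline <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_days = x$n_days,
                 edf = sum(x$fit$edf), gcv = x$fit$gcv.ubre,
                 doy_min = x$doy_range[1], doy_max = x$doy_range[2])
}
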