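#' Tidy an autocorrelation result
#'
#' @param x A `cg_acf`.
#' @param ... Unused.
#' @return A tibble with `lag` and `c`.
#' @method tidy cg_acf
#' @export
tidy.cg_acf <- function(x, ...) {
  tibble::tibble(lag = x$lag, c = x$c)
}

#' One-row summary of an autocorrelation result
#'
#' @param x A `cg_acf`.
#' @param ... Unused.
#' @return A tibble with `kind`, `n_lags`, `tau_e`, `tau` (NA when the
#'   correlation has not decayed below 1/e).
#' @method glance cg_acf
#' @export
glance.cg_acf <- function(x, ...) {
  ct <- tryCatch(correlation_time(x),
                 error = function(e) tibble::tibble(tau_e = NA_real_, tau = NA_real_))
  tibble::tibble(kind = attr(x, "kind"), n_lags = nrow(x),
                 tau_e = ct$tau_e, tau = ct$tau)
}

#' Tidy an exponential effective-cohesiveness fit
#'
#' @param x A `cg_expfit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @method tidy cg_expfit
#' @export
tidy.cg_expfit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' One-row summary of an exponential fit
#'
#' @param x A `cg_expfit`.
#' @param ... Unused.
#' @return A tibble with `a`, `b`, `sigma` (residual standard deviation),
#'   `n`.
#' @method glance cg_expfit
#' @export
glance.cg_expfit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b,
                 sigma = sqrt(mean(x$residuals^2)),
                 n = length(x$residuals))
}

#' Tidy a monotone patterning regression
#'
#' @param x A `cg_scd_regression`.
#' @param ... Unused.
#' @return The fit table: `scd`, `ratio`, `fitted`, `smoothed`.
#' @method tidy cg_scd_regression
#' @export
tidy.cg_scd_regression <- function(x, ...) x$data

#' Tidy an ensemble summary
#'
#' Long-format view of a `cg_ensemble_summary`: one row per observable
#' with its value and standard error.
#'
#' @param x A `cg_ensemble_summary`.
#' @param ... Unused.
#' @return A tibble with `observable`, `value`, `se`.
#' @method tidy cg_ensemble_summary
#' @export
tidy.cg_ensemble_summary <- function(x, ...) {
  obs <- c("mean_re2", "mean_rg2", "mean_delta", "rk",
           "ratio_re2_rg2", "ratio_rg_rk")
  ses <- c("se_re2", "se_rg2", "se_delta", "se_rk",
           "se_ratio_re2_rg2", "se_ratio_rg_rk")
  tibble::tibble(
    observable = obs,
    value = as.numeric(x[1, obs]),
    se = as.numeric(x[1, ses])
  )
}
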