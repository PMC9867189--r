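#' Homopolymer reference curve
#'
#' A monotone reference mapping from cohesiveness to an observable
#' (typically the mean squared radius of gyration, or the Rg/Rk ratio) used
#' to assign an equivalent-homopolymer cohesiveness to heterogeneous
#' sequences. Values that violate monotonicity at noise level are
#' isotonized before the curve is inverted.
#'
#' @param eps Cohesiveness grid, kT (strictly increasing).
#' @param values Observable means at each grid point.
#' @param se Optional standard errors.
#' @param observable Name of the observable (for labelling).
#' @return A `cg_reference_curve` tibble: `eps`, `value` (isotonized),
#'   `raw_value`, `se`.
#' @export
reference_curve <- function(eps, values, se = NULL, observable = "rg2") {
  stopifnot(length(eps) == length(values), !is.unsorted(eps, strictly = TRUE))
  decreasing <- values[length(values)] < values[1]
  iso <- if (decreasing) -stats::isoreg(eps, -values)$yf else stats::isoreg(eps, values)$yf
  out <- tibble::tibble(eps = eps, value = iso, raw_value = values,
                        se = se %||% NA_real_)
  structure(out, class = c("cg_reference_curve", class(out)),
            observable = observable, decreasing = decreasing)
}

#' Equivalent-homopolymer cohesiveness
#'
#' Inverts a homopolymer [reference_curve()] at the observed value by
#' piecewise-linear interpolation: the returned `eps_h` is the homopolymer
#' cohesiveness that produces the same observable value.
#'
#' @param value Observed value(s) of the curve's observable.
#' @param curve A [reference_curve()].
#' @return Numeric `eps_h`, kT.
#' @export
effective_epsilon <- function(value, curve) {
  stopifnot(inherits(curve, "cg_reference_curve"))
  lo <- min(curve$value)
  hi <- max(curve$value)
  if (any(value < lo | value > hi)) {
    stop(sprintf("value outside the covered range [%.4g, %.4g]", lo, hi))
  }
  # approx() needs increasing x; flatten exact ties from isotonization
  v <- curve$value
  e <- curve$eps
  if (attr(curve, "decreasing")) { v <- rev(v); e <- rev(e) }
  stats::approx(v, e, xout = value, ties = "ordered")$y
}

#' Fit the exponential effective-cohesiveness form
#'
#' Least-squares fit of \eqn{\epsilon_h = (e^{a\epsilon} - 1)/b} to the
#' mapping from sequence cohesiveness to equivalent-homopolymer
#' cohesiveness, valid for the points before the inflection of the
#' coil-to-globule transition (the caller selects the points).
#'
#' @param eps Sequence cohesiveness values, kT (>= 3 points).
#' @param eps_h Equivalent-homopolymer values from [effective_epsilon()].
#' @return A `cg_expfit` object: list with `a`, `b`, `fitted`, `residuals`
#'   and the underlying `nls` fit. In the small-`a` limit the form is
#'   linear with slope `a/b`.
#' @export
fit_exponential_form <- function(eps, eps_h) {
  stopifnot(length(eps) == length(eps_h))
  if (length(eps) < 3) stop("need at least 3 points to fit (e^(a*eps)-1)/b")
  slope <- stats::coef(stats::lm(eps_h ~ eps + 0))[[1]]
  start <- list(a = 0.5, b = max(0.5 / max(slope, 1e-6), 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(eps_h ~ (exp(a * eps) - 1) / b,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("exponential-form fit did not converge: ", conditionMessage(e),
           "; residual scale of linear baseline: ",
           signif(stats::sd(eps_h - slope * eps), 3))
    }
  )
  co <- stats::coef(fit)
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 eps = eps, eps_h = eps_h, fit = fit),
            class = "cg_expfit")
}

#' @export
print.cg_expfit <- function(x, ...) {
  cat(sprintf("<cg_expfit> eps_h = (exp(a*eps)-1)/b with a = %.4g, b = %.4g (RMS residual %.3g)\n",
              x$a, x$b, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Monotone regression of a dimension ratio on sequence patterning
#'
#' Isotonic (monotone) regression of e.g. Rg/Rk against SCD via the
#' pool-adjacent-violators algorithm, followed by a fixed-bandwidth moving
#' average, yielding a smooth evaluable mapping patterning score ->
#' observable. Composing its inverse interpolation with a homopolymer
#' [reference_curve()] maps a patterning score directly to an equivalent
#' homopolymer cohesiveness.
#'
#' @param scd Patterning scores (any monotone direction).
#' @param ratio Observable values (e.g. Rg/Rk) at each score.
#' @param smooth_window Moving-average window in points (default 3; 1
#'   disables smoothing).
#' @return A `cg_scd_regression` object with `$data` (tibble `scd`,
#'   `ratio`, `fitted`, `smoothed`) and `$predict(scd)` for interpolation.
#' @export
scd_regression <- function(scd, ratio, smooth_window = 3) {
  stopifnot(length(scd) == length(ratio))
  if (length(scd) < 4) stop("need at least 4 (scd, ratio) pairs")
  ord <- order(scd)
  x <- scd[ord]
  y <- ratio[ord]
  increasing <- stats::cor(x, y, method = "spearman") >= 0
  fitted <- if (increasing) stats::isoreg(x, y)$yf else -stats::isoreg(x, -y)$yf
  sm <- if (smooth_window > 1) {
    stats::filter(fitted, rep(1 / smooth_window, smooth_window), sides = 2)
  } else {
    fitted
  }
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- fitted[is.na(sm)] # window truncation at the edges
  data <- tibble::tibble(scd = x, ratio = y, fitted = fitted, smoothed = sm)
  predict_fun <- function(new_scd) {
    stats::approx(x, sm, xout = new_scd, rule = 2, ties = "ordered")$y
  }
  structure(list(data = data, predict = predict_fun,
                 increasing = increasing),
            class = "cg_scd_regression")
}

#' @export
print.cg_scd_regression <- function(x, ...) {
  cat("<cg_scd_regression> ", nrow(x$data), " points, ",
      if (x$increasing) "increasing" else "decreasing", " fit\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Map a patterning score to an equivalent homopolymer cohesiveness
#'
#' Composes [scd_regression()] (score -> observable) with a homopolymer
#' [reference_curve()] of the same observable (observable -> eps_h).
#'
#' @param scd Patterning score(s).
#' @param regression A [scd_regression()] fit.
#' @param curve A [reference_curve()] for the same observable.
#' @return Numeric `eps_h` values.
#' @export
scd_to_epsilon <- function(scd, regression, curve) {
  stopifnot(inherits(regression, "cg_scd_regression"))
  effective_epsilon(regression$predict(scd), curve)
}
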