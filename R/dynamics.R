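#' Autocorrelation function of an observable series
#'
#' For a 3-column matrix (a vector observable such as the end-to-end
#' vector) computes the dot-product autocorrelation
#' \eqn{c(t) = \langle \vec R_e(t)\cdot\vec R_e(0)\rangle / \langle R_e^2\rangle}
#' with no mean subtraction — the "rotation" correlation. For a numeric
#' vector (a scalar observable such as the end-to-end distance) computes
#' the mean-subtracted, variance-normalised autocorrelation — the
#' "reconfiguration" correlation. The default estimator is FFT-based
#' (circular convolution with zero padding, lag-wise normalised by the
#' number of contributing pairs) and agrees with the direct
#' \eqn{O(n^2)} sum to numerical precision; `method = "direct"` computes
#' the sum explicitly.
#'
#' @param series Numeric vector (scalar series) or n x 3 matrix (vector
#'   series), uniformly spaced in time.
#' @param dt Time between samples, simulation units (default 1, i.e. lags
#'   in sample units).
#' @param max_lag Largest lag (in samples) to report; defaults to n/2.
#' @param method `"fft"` or `"direct"`.
#' @return A `cg_acf` object: tibble with `lag` (time units) and `c`
#'   (normalised autocorrelation), plus attributes `kind` ("vector" or
#'   "scalar") and `dt`.
#' @export
autocorrelation <- function(series, dt = 1, max_lag = NULL,
                            method = c("fft", "direct")) {
  method <- match.arg(method)
  if (is.matrix(series)) {
    stopifnot(ncol(series) == 3)
    kind <- "vector"
    cols <- series
  } else {
    kind <- "scalar"
    v <- stats::var(series) * (length(series) - 1) / length(series)
    if (v <= 0) stop("zero-variance scalar series: reconfiguration correlation undefined")
    cols <- matrix(series - mean(series), ncol = 1)
  }
  n <- nrow(cols)
  if (n < 2) stop("series too short")
  if (is.null(max_lag)) max_lag <- n %/% 2
  max_lag <- min(max_lag, n - 1)

  raw <- if (method == "fft") {
    m <- 2^ceiling(log2(2 * n))
    acc <- numeric(max_lag + 1)
    for (k in seq_len(ncol(cols))) {
      f <- stats::fft(c(cols[, k], numeric(m - n)))
      s <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
      acc <- acc + s[1:(max_lag + 1)]
    }
    acc / (n - 0:max_lag)
  } else {
    vapply(0:max_lag, function(L) {
      idx <- 1:(n - L)
      mean(rowSums(cols[idx, , drop = FALSE] * cols[idx + L, , drop = FALSE]))
    }, 0)
  }
  cvals <- raw / raw[1]
  out <- tibble::tibble(lag = (0:max_lag) * dt, c = cvals)
  structure(out, class = c("cg_acf", class(out)), kind = kind, dt = dt)
}

#' Average autocorrelation functions over replicas
#'
#' Averages the normalised correlation values of several [autocorrelation()]
#' results on their common lag grid (correlations are averaged first; any
#' correlation time is computed from the average).
#'
#' @param acfs List of `cg_acf` objects with identical `dt`.
#' @return A `cg_acf` on the common (shortest) lag grid.
#' @export
average_acf <- function(acfs) {
  stopifnot(length(acfs) >= 1)
  nmin <- min(vapply(acfs, nrow, 0L))
  cbar <- rowMeans(vapply(acfs, function(a) a$c[seq_len(nmin)], numeric(nmin)))
  out <- tibble::tibble(lag = acfs[[1]]$lag[seq_len(nmin)], c = cbar)
  structure(out, class = class(acfs[[1]]),
            kind = attr(acfs[[1]], "kind"), dt = attr(acfs[[1]], "dt"))
}

#' Integrated correlation time
#'
#' \eqn{\tau = \int_0^{3\tau_e} c(t)\,dt} by the trapezoidal rule, where
#' \eqn{\tau_e} is the time of the first crossing of \eqn{e^{-1}}, located
#' by linear interpolation between the bracketing lags. The truncation at
#' \eqn{3\tau_e} suppresses the noisy tail of the estimated correlation
#' function.
#'
#' @param cr A `cg_acf` (or tibble with `lag` and `c`).
#' @return A one-row tibble: `tau_e` (e-folding time) and `tau`
#'   (integrated correlation time), simulation time units.
#' @export
correlation_time <- function(cr) {
  lag <- cr$lag
  cv <- cr$c
  target <- exp(-1)
  below <- which(cv < target)
  if (length(below) == 0) stop("correlation has not decayed below 1/e; extend the run")
  i <- below[1]
  if (i == 1) stop("correlation below 1/e at lag 0; series too coarse")
  # linear interpolation between bracketing lags
  tau_e <- lag[i - 1] + (target - cv[i - 1]) * (lag[i] - lag[i - 1]) /
    (cv[i] - cv[i - 1])
  t_cut <- 3 * tau_e
  keep <- lag <= t_cut
  lag_k <- lag[keep]
  c_k <- cv[keep]
  if (max(lag_k) < t_cut && sum(!keep) > 0) {
    j <- sum(keep)
    c_cut <- cv[j] + (cv[j + 1] - cv[j]) * (t_cut - lag[j]) / (lag[j + 1] - lag[j])
    lag_k <- c(lag_k, t_cut)
    c_k <- c(c_k, c_cut)
  }
  tau <- sum(diff(lag_k) * (utils::head(c_k, -1) + utils::tail(c_k, -1)) / 2)
  tibble::tibble(tau_e = tau_e, tau = tau)
}

#' End-to-end relaxation profile across a cohesiveness grid
#'
#' For each cohesiveness value runs the model and reports the chain
#' dimensions together with the rotation time (integrated correlation time
#' of the end-to-end vector) and the reconfiguration time (of the
#' end-to-end distance). Correlation functions are averaged over replicas
#' before integrating.
#'
#' @param seq Sequence (any [as_cg_sequence()] input).
#' @param eps_grid Numeric vector of cohesiveness values, kT.
#' @param config Base [simulation_config()]; its force field is reused
#'   with `eps` replaced per grid point.
#' @return A tibble: `eps`, `mean_rg2`, `se_rg2`, `mean_re2`,
#'   `tau_rotation`, `tau_reconfiguration`, `tau_e_rotation`.
#' @export
relaxation_profile <- function(seq, eps_grid, config = simulation_config()) {
  seq <- as_cg_sequence(seq)
  purrr::map_dfr(eps_grid, function(e) {
    cfg <- config
    cfg$forcefield$eps <- e
    cfg$seed <- config$seed + round(1000 * e)
    traj <- run_simulation(seq, cfg)
    dt_obs <- cfg$dt * cfg$obs_stride
    by_run <- split(traj$obs, traj$obs$run)
    acf_vec <- average_acf(lapply(by_run, function(o) {
      autocorrelation(as.matrix(o[, c("re_x", "re_y", "re_z")]), dt = dt_obs)
    }))
    acf_sca <- average_acf(lapply(by_run, function(o) {
      autocorrelation(o$re, dt = dt_obs)
    }))
    ct_vec <- correlation_time(acf_vec)
    ct_sca <- tryCatch(correlation_time(acf_sca),
                       error = function(e) tibble::tibble(tau_e = NA_real_, tau = NA_real_))
    tibble::tibble(
      eps = e,
      mean_rg2 = mean(traj$obs$rg2),
      se_rg2 = block_se(traj$obs$rg2),
      mean_re2 = mean(traj$obs$re^2),
      tau_rotation = ct_vec$tau,
      tau_e_rotation = ct_vec$tau_e,
      tau_reconfiguration = ct_sca$tau
    )
  })
}

#' Shape diagnostics of the end-to-end distance distribution
#'
#' Histogram of pooled end-to-end distances (bin width 0.5 by default),
#' its variance, and the number of local maxima of the histogram after
#' Gaussian kernel smoothing with bandwidth of one bin — multimodality of
#' p(Re) signals bistable end-to-end conformations.
#'
#' @param re Numeric vector of end-to-end distances (or a `cg_trajectory`,
#'   whose pooled `$obs$re` is used).
#' @param bin Histogram bin width (default 0.5).
#' @param smooth_bandwidth Gaussian smoothing bandwidth in units of bins
#'   (default 1).
#' @param min_prominence Peaks smaller than this fraction of the maximum
#'   smoothed density are ignored (default 0.05), so sampling noise in the
#'   tails does not count as multimodality.
#' @return A list: `histogram` (tibble `re_mid`, `prob`, `smoothed`),
#'   `variance`, `n_peaks`, `peak_positions`.
#' @export
end_distance_shape <- function(re, bin = 0.5, smooth_bandwidth = 1,
                               min_prominence = 0.05) {
  if (inherits(re, "cg_trajectory")) re <- re$obs$re
  stopifnot(length(re) > 1)
  v <- stats::var(re)
  edges <- seq(0, max(re) + bin, by = bin)
  h <- graphics::hist(re, breaks = edges, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  nb <- length(prob)
  # Gaussian kernel smoothing on the bin grid
  w <- stats::dnorm(seq(-4 * smooth_bandwidth, 4 * smooth_bandwidth),
                    sd = smooth_bandwidth)
  w <- w / sum(w)
  half <- (length(w) - 1) / 2
  padded <- c(rep(0, half), prob, rep(0, half))
  sm <- vapply(seq_len(nb), function(i) sum(padded[i:(i + 2 * half)] * w), 0)
  peaks <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) == -2)
  peaks <- peaks[sm[peaks] >= min_prominence * max(sm)]
  if (v == 0) peaks <- peaks[1] # degenerate series: a single spike
  list(
    histogram = tibble::tibble(re_mid = h$mids, prob = prob, smoothed = sm),
    variance = v,
    n_peaks = length(peaks),
    peak_positions = h$mids[peaks]
  )
}
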