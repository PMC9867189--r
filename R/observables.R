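#' Static observables of a single conformation
#'
#' End-to-end distance, gyration tensor eigenvalues, radius of gyration,
#' asphericity and the reciprocal-distance sum used by the Kirkwood
#' estimator.
#'
#' The gyration tensor is \eqn{S_{xy} = (1/N)\sum_i (R_{i,x}-R_{c,x})
#' (R_{i,y}-R_{c,y})}; its eigenvalues \eqn{\lambda_x \ge \lambda_y \ge
#' \lambda_z} sum to \eqn{R_g^2}, and the asphericity is
#' \eqn{\delta = 1 - 3(\lambda_x\lambda_y + \lambda_y\lambda_z +
#' \lambda_z\lambda_x)/(\lambda_x+\lambda_y+\lambda_z)^2} (0 for a sphere,
#' 1 for a rigid rod). A fully degenerate conformation (all beads
#' coincident) has `rg2 = 0` and `delta = NA`; such frames are excluded
#' from ensemble averages.
#'
#' @param positions N x 3 coordinate matrix (N >= 2).
#' @return A one-row tibble: `re`, `rg2`, `lambda_x`, `lambda_y`,
#'   `lambda_z`, `delta`, `inv_dist_sum` (\eqn{\sum_{i \ne j} 1/r_{ij}}
#'   over ordered pairs).
#' @export
frame_observables <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 beads")
  centred <- sweep(positions, 2, colMeans(positions))
  S <- crossprod(centred) / n
  lam <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  rg2 <- sum(lam)
  delta <- if (rg2 > 0) 1 - 3 * (lam[1] * lam[2] + lam[2] * lam[3] + lam[3] * lam[1]) / rg2^2 else NA_real_
  d <- stats::dist(positions)
  tibble::tibble(
    re = sqrt(sum((positions[1, ] - positions[n, ])^2)),
    rg2 = rg2,
    lambda_x = lam[1], lambda_y = lam[2], lambda_z = lam[3],
    delta = delta,
    inv_dist_sum = 2 * sum(1 / d)
  )
}

# iterate frame_observables over the stored frames of a trajectory
#' Per-frame observables of a trajectory
#'
#' Applies [frame_observables()] to every stored coordinate frame of a
#' [run_simulation()] trajectory.
#'
#' @param traj A `cg_trajectory`.
#' @return A tibble with one row per frame: `run`, `frame`, and the
#'   [frame_observables()] columns.
#' @export
traj_observables <- function(traj) {
  stopifnot(inherits(traj, "cg_trajectory"))
  purrr::map_dfr(seq_along(traj$frames), function(k) {
    fr <- traj$frames[[k]]
    nf <- dim(fr)[3]
    rows <- purrr::map_dfr(seq_len(nf), function(f) frame_observables(fr[, , f]))
    dplyr::bind_cols(tibble::tibble(run = k, frame = seq_len(nf)), rows)
  })
}

block_se <- function(x, n_blocks = 10) {
  x <- x[is.finite(x)]
  if (length(x) < 2 * n_blocks) n_blocks <- max(2, length(x) %/% 2)
  idx <- cut(seq_along(x), breaks = n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(length(bm))
}

#' Ensemble summary of a trajectory
#'
#' Means with block standard errors of the squared end-to-end distance,
#' squared radius of gyration, asphericity, the Kirkwood hydrodynamic
#' radius and the dimension ratios. `re2` and `rg2` use the densely
#' recorded observable series; asphericity and the Kirkwood radius use the
#' stored coordinate frames. Block errors are computed from contiguous
#' blocks within each replica so they account for temporal correlation.
#'
#' @param traj A `cg_trajectory`.
#' @param n_blocks Blocks per replica for the error estimate (default 10).
#' @return A one-row `cg_ensemble_summary` tibble: `name`, `eps`, `hydro`,
#'   `n`, `mean_re2`, `se_re2`, `mean_rg2`, `se_rg2`, `mean_delta`,
#'   `se_delta`, `rk`, `se_rk`, `ratio_re2_rg2`, `se_ratio_re2_rg2`,
#'   `ratio_rg_rk`, `se_ratio_rg_rk`.
#' @export
ensemble_summary <- function(traj, n_blocks = 10) {
  stopifnot(inherits(traj, "cg_trajectory"))
  obs <- traj$obs
  fobs <- traj_observables(traj)
  n <- length(traj$meta$sequence)

  per_run_blocks <- function(data, col) {
    unlist(lapply(split(data[[col]], data$run), function(x) {
      x <- x[is.finite(x)]
      nb <- min(n_blocks, max(1, length(x) %/% 2))
      idx <- cut(seq_along(x), breaks = nb, labels = FALSE)
      tapply(x, idx, mean)
    }), use.names = FALSE)
  }
  se_of <- function(bm) if (length(bm) > 1) stats::sd(bm) / sqrt(length(bm)) else NA_real_

  re2 <- obs$re^2
  b_re2 <- per_run_blocks(dplyr::mutate(obs, re2 = re2), "re2")
  b_rg2 <- per_run_blocks(obs, "rg2")
  b_delta <- per_run_blocks(fobs, "delta")
  b_inv <- per_run_blocks(fobs, "inv_dist_sum")

  mean_re2 <- mean(re2)
  mean_rg2 <- mean(obs$rg2)
  mean_delta <- mean(fobs$delta, na.rm = TRUE)
  rk <- n^2 / mean(fobs$inv_dist_sum)
  ratio <- mean_re2 / mean_rg2
  rg_rk <- sqrt(mean(fobs$rg2)) / rk

  # block-level ratios (paired blocks) for correlated-ratio errors
  nb <- min(length(b_re2), length(b_rg2))
  b_ratio <- b_re2[seq_len(nb)] / b_rg2[seq_len(nb)]
  nb2 <- min(length(b_inv), length(per_run_blocks(fobs, "rg2")))
  b_rg2f <- per_run_blocks(fobs, "rg2")
  b_rgrk <- sqrt(b_rg2f[seq_len(nb2)]) * b_inv[seq_len(nb2)] / n^2

  out <- tibble::tibble(
    name = traj$meta$name,
    eps = traj$meta$config$forcefield$eps,
    hydro = traj$meta$config$hydrodynamics,
    n = n,
    mean_re2 = mean_re2, se_re2 = se_of(b_re2),
    mean_rg2 = mean_rg2, se_rg2 = se_of(b_rg2),
    mean_delta = mean_delta, se_delta = se_of(b_delta),
    rk = rk, se_rk = se_of(n^2 / b_inv),
    ratio_re2_rg2 = ratio, se_ratio_re2_rg2 = se_of(b_ratio),
    ratio_rg_rk = rg_rk, se_ratio_rg_rk = se_of(b_rgrk)
  )
  class(out) <- c("cg_ensemble_summary", class(out))
  out
}

#' Kirkwood approximation to the hydrodynamic radius
#'
#' \deqn{R_k = \left[\frac{1}{N^2}\sum_{i\ne j}\langle 1/r_{ij}\rangle\right]^{-1}.}
#' The reciprocal distances are averaged over frames first and the double
#' sum inverted afterwards (the order matters). Frames with coincident
#' beads are excluded with a count.
#'
#' @param traj A `cg_trajectory`, or a tibble with an `inv_dist_sum` column
#'   (plus `run`) such as [traj_observables()] output.
#' @param n Number of beads (taken from the trajectory when available).
#' @return A one-row tibble: `rk`, `se`, `n_frames`, `n_excluded`.
#' @export
kirkwood_radius <- function(traj, n = NULL) {
  if (inherits(traj, "cg_trajectory")) {
    n <- length(traj$meta$sequence)
    fobs <- traj_observables(traj)
  } else {
    fobs <- traj
    if (is.null(n)) stop("n is required when passing a frame table")
  }
  bad <- !is.finite(fobs$inv_dist_sum)
  fobs <- fobs[!bad, ]
  if (nrow(fobs) == 0) stop("no usable frames")
  rk <- n^2 / mean(fobs$inv_dist_sum)
  se <- block_se(n^2 / fobs$inv_dist_sum) # delta-method scale; conservative
  tibble::tibble(rk = rk, se = se, n_frames = nrow(fobs),
                 n_excluded = sum(bad))
}

#' Hydrodynamic radius from centre-of-mass diffusion
#'
#' Fits the diffusion coefficient of the polymer centre of mass from the
#' linear regime of its mean-squared displacement and converts it through
#' the Stokes-Einstein relation. In simulation units a bead of radius `a0`
#' has diffusion coefficient 1/2, so \eqn{R_h = a_0/(2 D_e)}.
#'
#' @param traj A `cg_trajectory` (meaningful with hydrodynamics on).
#' @param fit_fraction Fit window as a fraction of the maximum lag,
#'   default `c(0.1, 1)` (the upper decade of available lags).
#' @param a0 Reference bead radius (default 3/4).
#' @return A one-row tibble: `De`, `rh`, `msd_exponent` (log-log slope of
#'   the MSD in the fit window, as a linearity diagnostic).
#' @export
com_diffusion_rh <- function(traj, fit_fraction = c(0.1, 1), a0 = 0.75) {
  stopifnot(inherits(traj, "cg_trajectory"))
  dt_frame <- traj$meta$config$dt * traj$meta$config$frame_stride
  msd_runs <- lapply(traj$frames, function(fr) {
    nf <- dim(fr)[3]
    com <- t(apply(fr, 3, colMeans))
    max_lag <- max(1, nf %/% 4)
    lags <- unique(round(exp(seq(0, log(max_lag), length.out = 40))))
    msd <- vapply(lags, function(L) {
      d <- com[(1 + L):nf, , drop = FALSE] - com[1:(nf - L), , drop = FALSE]
      mean(rowSums(d^2))
    }, 0)
    list(lags = lags, msd = msd)
  })
  lags <- msd_runs[[1]]$lags
  msd <- Reduce(`+`, lapply(msd_runs, `[[`, "msd")) / length(msd_runs)
  tmax <- max(lags) * dt_frame
  tt <- lags * dt_frame
  in_win <- tt >= fit_fraction[1] * tmax & tt <= fit_fraction[2] * tmax
  if (sum(in_win) < 3) stop("fit window contains fewer than 3 lags")
  slope_loglog <- stats::coef(stats::lm(log(msd[in_win]) ~ log(tt[in_win])))[2]
  if (slope_loglog < 0.8) {
    stop(sprintf(paste0("centre-of-mass MSD is sub-linear in the fit window ",
                        "(log-log slope %.2f); extend the run"), slope_loglog))
  }
  De <- unname(stats::coef(stats::lm(msd[in_win] ~ tt[in_win]))[2]) / 6
  tibble::tibble(De = De, rh = a0 / (2 * De),
                 msd_exponent = unname(slope_loglog))
}

#' Distance density of two uniform points in a ball
#'
#' The reference conditional end-to-end model: given a radius of gyration,
#' the end-to-end distance is modelled as the distance between two
#' independent uniform points inside a ball of radius
#' \eqn{R^* = \sqrt{5} R_g} (the radius for which the ball's second moment
#' matches \eqn{\langle R_e^2 \rangle = 6 R_g^2}). The closed-form density
#' is \eqn{p(d) = 3d^2/R^{*3} - 9d^3/(4R^{*4}) + 3d^5/(16R^{*6})} on
#' \eqn{[0, 2R^*]}.
#'
#' @param re End-to-end distance(s), >= 0.
#' @param rg Radius of gyration (> 0) conditioning the sub-ensemble.
#' @return Probability density values.
#' @export
sanchez_haran_pdf <- function(re, rg) {
  stopifnot(rg > 0, all(re >= 0))
  R <- sqrt(5) * rg
  d <- re
  p <- 3 * d^2 / R^3 - 9 * d^3 / (4 * R^4) + 3 * d^5 / (16 * R^6)
  ifelse(d <= 2 * R, pmax(p, 0), 0)
}

#' Conditional end-to-end distributions p(Re | Rg)
#'
#' Pools frames (typically across several cohesiveness values), bins the
#' radius of gyration at width `rg_bin`, and within each bin forms a
#' normalised histogram of the end-to-end distance at width `re_bin`.
#'
#' @param data A tibble with `re` and `rg2` (or `rg`) columns — e.g.
#'   pooled `$obs` tables or [traj_observables()] output — or a
#'   `cg_trajectory`.
#' @param rg_bin,re_bin Bin widths in simulation units (default 0.5).
#' @param min_frames Bins with fewer frames are flagged low-confidence
#'   (default 100).
#' @return A tibble: `rg_mid`, `re_mid`, `prob` (sums to 1 within each Rg
#'   bin), `n_frames`, `low_confidence`.
#' @export
conditional_distribution <- function(data, rg_bin = 0.5, re_bin = 0.5,
                                     min_frames = 100) {
  if (inherits(data, "cg_trajectory")) data <- data$obs
  rg <- if ("rg" %in% names(data)) data$rg else sqrt(data$rg2)
  df <- tibble::tibble(re = data$re, rg = rg)
  df$rg_mid <- (floor(df$rg / rg_bin) + 0.5) * rg_bin
  df$re_mid <- (floor(df$re / re_bin) + 0.5) * re_bin
  df |>
    dplyr::count(.data$rg_mid, .data$re_mid, name = "count") |>
    dplyr::group_by(.data$rg_mid) |>
    dplyr::mutate(
      n_frames = sum(.data$count),
      prob = .data$count / .data$n_frames,
      low_confidence = .data$n_frames < min_frames
    ) |>
    dplyr::ungroup() |>
    dplyr::select("rg_mid", "re_mid", "prob", "n_frames", "low_confidence")
}
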