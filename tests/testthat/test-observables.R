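test_that("frame observables match hand-computed references", {
  # rigid rod: delta = 1
  rod <- cbind(0:9, 0, 0)
  fo <- frame_observables(rod)
  expect_equal(fo$delta, 1, tolerance = 1e-12)
  expect_equal(fo$re, 9)

  # right triangle: eigenvalues 1/3, 1/9, 0 and delta 7/16
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ft <- frame_observables(tri)
  expect_equal(c(ft$lambda_x, ft$lambda_y, ft$lambda_z), c(1 / 3, 1 / 9, 0),
               tolerance = 1e-12)
  expect_equal(ft$rg2, 4 / 9, tolerance = 1e-12)
  expect_equal(ft$delta, 7 / 16, tolerance = 1e-12)
  expect_equal(ft$rg2, ft$lambda_x + ft$lambda_y + ft$lambda_z)

  # degenerate frame: rg2 = 0, delta undefined
  degen <- matrix(1, 4, 3)
  fd <- frame_observables(degen)
  expect_equal(fd$rg2, 0)
  expect_true(is.na(fd$delta))

  expect_error(frame_observables(matrix(0, 1, 3)), "at least 2")
})

test_that("Kirkwood radius matches direct evaluation on rigid configurations", {
  # three collinear beads at 0, 1, 2: Rk = 9/5
  coll <- cbind(0:2, 0, 0)
  fo <- frame_observables(coll)
  expect_equal(fo$inv_dist_sum, 5)
  tab <- tibble::tibble(run = 1, inv_dist_sum = rep(5, 10), rg2 = fo$rg2)
  expect_equal(kirkwood_radius(tab, n = 3)$rk, 9 / 5)
})

test_that("ideal chain ensembles reproduce random-walk closed forms", {
  n <- 60
  chains <- ideal_chain_ensemble(n, 4000, seed = 5)
  expect_identical(ideal_chain_ensemble(5, 3, seed = 9),
                   ideal_chain_ensemble(5, 3, seed = 9))
  st <- ensemble_statistics(chains, kirkwood = FALSE)
  b2 <- 1.35^2
  se_re2 <- stats::sd(vapply(chains, function(p) sum((p[1, ] - p[n, ])^2), 0)) /
    sqrt(length(chains))
  expect_lt(abs(st$mean_re2 - (n - 1) * b2), 3 * se_re2)
  expect_equal(st$ratio_re2_rg2, 6 * n / (n + 1), tolerance = 0.05)
})

test_that("ball point pairs match the uniform-sphere closed forms", {
  R <- 2.5
  bp <- ball_point_ensemble(R, 2e5, seed = 11)
  expect_true(all(rowSums(bp$p1^2) <= R^2))
  d <- sqrt(rowSums((bp$p1 - bp$p2)^2))
  rg2_ball <- 3 / 5 * R^2
  expect_equal(mean(d^2) / rg2_ball, 2, tolerance = 0.01)
  expect_equal(mean(1 / d), 6 / (5 * R), tolerance = 0.01)
})

test_that("ball-model density integrates to the stated moments", {
  rg <- 1.7
  p <- function(d) sanchez_haran_pdf(d, rg)
  norm <- stats::integrate(p, 0, 2 * sqrt(5) * rg, abs.tol = 1e-10)$value
  expect_equal(norm, 1, tolerance = 1e-8)
  m2 <- stats::integrate(function(d) d^2 * p(d), 0, 2 * sqrt(5) * rg)$value
  expect_equal(m2, 6 * rg^2, tolerance = 1e-7)
  m1 <- stats::integrate(function(d) d * p(d), 0, 2 * sqrt(5) * rg)$value
  expect_equal(m1, 36 * sqrt(5) * rg / 35, tolerance = 1e-7)
  expect_equal(sanchez_haran_pdf(2 * sqrt(5) * rg + 0.1, rg), 0)
})

test_that("conditional distributions are normalised within each Rg bin", {
  set.seed(2)
  df <- tibble::tibble(re = abs(rnorm(5000, 5, 2)), rg2 = runif(5000, 4, 16))
  cond <- conditional_distribution(df, min_frames = 100)
  sums <- tapply(cond$prob, cond$rg_mid, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(any(cond$low_confidence) || all(table(cond$rg_mid) > 0))
})

test_that("centre-of-mass diffusion recovers the single-bead radius", {
  cfg <- simulation_config(dt = 0.002, frame_stride = 10, obs_stride = 1e9)
  set.seed(17)
  res <- bd_run(matrix(0, 1, 3), "P", cfg, n_steps = 1e6, n_equil = 0)
  traj <- as_traj(res, "P", cfg)
  # short-lag window: the MSD of a free bead is exactly linear, and short
  # lags have far more independent origins, so the slope error stays small
  out <- com_diffusion_rh(traj, fit_fraction = c(2e-5, 2e-3))
  expect_equal(out$rh, 0.75, tolerance = 0.05)
  expect_equal(out$De, 0.5, tolerance = 0.05)
})

test_that("a bonded dimer with hydrodynamics has Rh between a0 and 2a0", {
  cfg <- simulation_config(dt = 0.001, frame_stride = 10, obs_stride = 1e9,
                           hydrodynamics = "rpy")
  set.seed(23)
  res <- bd_run(init_saw(2, seed = 2), "PP", cfg, n_steps = 3e5, n_equil = 1e4)
  traj <- as_traj(res, "PP", cfg)
  out <- com_diffusion_rh(traj, fit_fraction = c(5e-4, 0.05))
  expect_gt(out$rh, 0.75)
  expect_lt(out$rh, 1.5)
})

test_that("ensemble summary is internally consistent", {
  cfg <- simulation_config(n_steps = 2e5, n_equil = 5e4, n_runs = 2, seed = 19,
                           frame_stride = 2000, obs_stride = 100)
  traj <- run_simulation("(H)20", cfg)
  s <- ensemble_summary(traj)
  expect_equal(s$ratio_re2_rg2, s$mean_re2 / s$mean_rg2)
  expect_gt(s$se_rg2, 0)
  long <- tidy(s)
  expect_equal(nrow(long), 6)
  expect_equal(long$value[long$observable == "rk"], s$rk)
})
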