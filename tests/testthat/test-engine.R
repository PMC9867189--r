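test_that("self-avoiding walk initial conditions honour bond and exclusion", {
  p2 <- init_saw(2, seed = 1)
  expect_equal(sqrt(sum((p2[1, ] - p2[2, ])^2)), 1.35, tolerance = 1e-12)

  expect_identical(init_saw(100, seed = 9), init_saw(100, seed = 9))

  for (s in 1:20) {
    p <- init_saw(50, seed = s)
    bonds <- sqrt(rowSums((p[-1, ] - p[-50, ])^2))
    expect_equal(bonds, rep(1.35, 49), tolerance = 1e-9)
    d <- as.matrix(stats::dist(p))
    d[cbind(1:49, 2:50)] <- Inf
    d[cbind(2:50, 1:49)] <- Inf
    diag(d) <- Inf
    expect_gte(min(d), 1.5)
  }
  expect_error(init_saw(1), "at least 2")
})

test_that("simulations are bitwise reproducible from the master seed", {
  cfg <- simulation_config(n_steps = 5e3, n_equil = 1e3, n_runs = 2, seed = 77,
                           frame_stride = 500, obs_stride = 100)
  t1 <- run_simulation("(HP)10", cfg)
  t2 <- run_simulation("(HP)10", cfg)
  expect_identical(t1$obs, t2$obs)
  expect_identical(t1$frames, t2$frames)
  # different seeds decorrelate
  cfg$seed <- 78
  t3 <- run_simulation("(HP)10", cfg)
  expect_false(identical(t1$obs$re, t3$obs$re))
})

test_that("frame bookkeeping matches the stride contract", {
  cfg <- simulation_config(n_steps = 1e3 + 1, n_equil = 1e3, n_runs = 1,
                           seed = 4, frame_stride = 100, obs_stride = 100)
  traj <- run_simulation("(H)10", cfg)
  expect_equal(dim(traj$frames[[1]])[3], 1) # ceil(1/100)
  cfg2 <- simulation_config(n_steps = 2e3, n_equil = 1e3, seed = 4,
                            frame_stride = 100, obs_stride = 250)
  traj2 <- run_simulation("(H)10", cfg2)
  expect_equal(dim(traj2$frames[[1]])[3], 10)
  expect_equal(nrow(traj2$obs), 4)
  # all stored bonds below L_max
  fr <- traj2$frames[[1]]
  bonds <- apply(fr, 3, function(p) max(sqrt(rowSums((p[-1, ] - p[-10, ])^2))))
  expect_true(all(bonds < 3))
})

test_that("a proposed overstretching step is rejected, not propagated", {
  # a short FENE (L_max = 1.5 with a 0.5 contact) makes noise-driven
  # overstretch proposals occur at a countable rate; the run must reject
  # them and keep every recorded bond below L_max
  ff <- forcefield(B0 = 0.5, L_max = 1.5)
  cfg <- simulation_config(dt = 0.001, n_steps = 1e5, n_equil = 0, seed = 2,
                           frame_stride = 200, obs_stride = 200,
                           forcefield = ff, max_reject = 10000)
  set.seed(5)
  pos0 <- cbind(c(0, 0.45), 0, 0)
  res <- bd_run(pos0, cg_sequence(c("P", "P")), cfg, 1e5, 0)
  expect_gt(res$n_reject, 0)
  expect_true(all(abs(res$obs[, 2]) < 1.5))

  # with an even shorter bond and a coarse step the restoring drift itself
  # overshoots and no redraw can save the move: the engine must refuse to
  # continue rather than propagate an invalid state
  ff2 <- forcefield(B0 = 0.5, L_max = 1.2)
  cfg2 <- simulation_config(dt = 0.004, n_steps = 4000, n_equil = 0, seed = 2,
                            frame_stride = 10, obs_stride = 10,
                            forcefield = ff2, max_reject = 2000)
  set.seed(5)
  expect_error(bd_run(pos0, cg_sequence(c("P", "P")), cfg2, 4000, 0),
               "reduce dt")
})

test_that("two-bead bond length samples the Boltzmann density", {
  cfg <- simulation_config(dt = 0.001, frame_stride = 1e9, obs_stride = 2)
  set.seed(31)
  res <- bd_run(init_saw(2, seed = 3), "PP", cfg, n_steps = 4e5, n_equil = 2e4)
  R <- sqrt(res$obs[, 2]^2 + res$obs[, 3]^2 + res$obs[, 4]^2)
  u <- function(r) -9 * log(1 - (r / 3)^2) +
    ifelse(r < 1.5, (1.5 / r)^8 - (4 / 3) * (1.5 / r)^6 + 1 / 3, 0)
  rs <- seq(5e-4, 2.9995, by = 1e-3)
  w <- rs^2 * exp(-u(rs))
  cdf <- cumsum(w) / sum(w)
  ks <- max(abs(stats::ecdf(R)(rs + 5e-4) - cdf))
  expect_lt(ks, 0.02)
})

test_that("three-bead moments match exact Boltzmann quadrature", {
  # independent oracle: integrate over the two bond lengths and the
  # inter-bond angle with the Boltzmann weight of the same potential
  core <- function(r) (1.5 / r)^8 - (4 / 3) * (1.5 / r)^6 + 1 / 3
  pair_u <- function(r) ifelse(r < 1.5, core(r), 0)
  fene_u <- function(r) -9 * log(1 - (r / 3)^2)
  r <- seq(0.02, 2.98, length.out = 160)
  g <- seq(1e-4, pi - 1e-4, length.out = 160)
  grid <- expand.grid(r1 = r, r2 = r, g = g)
  r13 <- sqrt(grid$r1^2 + grid$r2^2 - 2 * grid$r1 * grid$r2 * cos(grid$g))
  w <- grid$r1^2 * grid$r2^2 * sin(grid$g) *
    exp(-(fene_u(grid$r1) + pair_u(grid$r1) + fene_u(grid$r2) +
            pair_u(grid$r2) + pair_u(r13)))
  re2_exact <- sum(w * r13^2) / sum(w)
  rg2_exact <- sum(w * (grid$r1^2 + grid$r2^2 + r13^2)) / (9 * sum(w))

  cfg <- simulation_config(n_steps = 3e6, n_equil = 2e5, n_runs = 1, seed = 5,
                           frame_stride = 1e9, obs_stride = 30)
  traj <- run_simulation("(H)3", cfg)
  expect_equal(mean(traj$obs$re^2), re2_exact, tolerance = 0.02)
  expect_equal(mean(traj$obs$rg2), rg2_exact, tolerance = 0.02)
})

test_that("block averages of a homopolymer run are statistically stable", {
  cfg <- simulation_config(n_steps = 1.2e6, n_equil = 2e5, seed = 21,
                           frame_stride = 5000, obs_stride = 200)
  traj <- run_simulation("(H)50", cfg)
  o <- traj$obs
  half <- o$step <= stats::median(o$step)
  m1 <- mean(o$rg2[half]); m2 <- mean(o$rg2[!half])
  se <- sqrt(idpcg:::block_se(o$rg2[half])^2 + idpcg:::block_se(o$rg2[!half])^2)
  expect_lt(abs(m1 - m2), 3 * pmax(se, 1e-8))
})

test_that("static dimensions agree with and without hydrodynamics", {
  ff <- forcefield(eps = 0.5)
  base <- simulation_config(n_steps = 6e5, n_equil = 1e5, n_runs = 2, seed = 3,
                            frame_stride = 2000, obs_stride = 200,
                            forcefield = ff)
  t_fd <- run_simulation("(H)20", base)
  base$hydrodynamics <- "rpy"
  base$cholesky_stride <- 10
  base$seed <- 13
  t_hi <- run_simulation("(H)20", base)
  s_fd <- ensemble_summary(t_fd)
  s_hi <- ensemble_summary(t_hi)
  sig <- sqrt(s_fd$se_rg2^2 + s_hi$se_rg2^2)
  expect_lt(abs(s_fd$mean_rg2 - s_hi$mean_rg2), 3 * sig)
})

test_that("XYZ export writes one block per frame with labels", {
  cfg <- simulation_config(n_steps = 2e3, n_equil = 1e3, seed = 6,
                           frame_stride = 500, obs_stride = 500)
  traj <- run_simulation("(HP)5", cfg)
  path <- tempfile(fileext = ".xyz")
  write_xyz(traj, path)
  lines <- readLines(path)
  expect_equal(lines[1], "10")
  expect_equal(length(lines), (10 + 2) * dim(traj$frames[[1]])[3])
  expect_match(lines[3], "^H ")
  expect_match(lines[4], "^P ")
})
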