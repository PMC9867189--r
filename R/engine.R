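#' Simulation configuration
#'
#' Collects run-control parameters for [run_simulation()]. Step counts are
#' totals including the discarded equilibration segment.
#'
#' @param dt Time step, simulation time units (default 0.001).
#' @param n_steps Total steps per run (default 2e6).
#' @param n_equil Leading steps discarded from analysis (default 1e5).
#' @param n_runs Number of replica runs with independent sub-seeds
#'   (default 1).
#' @param seed Master seed; replica sub-seeds are derived from it.
#' @param frame_stride Post-equilibration steps between stored coordinate
#'   frames (default 1000).
#' @param obs_stride Steps between recorded end-to-end / Rg observations
#'   (default 20).
#' @param hydrodynamics `"off"` (free draining) or `"rpy"`.
#' @param cholesky_stride With RPY, recompute the mobility matrix and its
#'   Cholesky factor every this many steps (default 1; values > 1 are a
#'   documented speed approximation using a slightly stale mobility).
#' @param max_reject Maximum consecutive rejections of a proposed step that
#'   would overstretch a bond before erroring (default 100).
#' @param verlet_skin Neighbour-list skin distance (default 0.75).
#' @param forcefield A [forcefield()].
#' @return A `cg_config` list.
#' @export
simulation_config <- function(dt = 0.001, n_steps = 2e6, n_equil = 1e5,
                              n_runs = 1, seed = 1,
                              frame_stride = 1000, obs_stride = 20,
                              hydrodynamics = c("off", "rpy"),
                              cholesky_stride = 1, max_reject = 100,
                              verlet_skin = 1.2, init = c("saw", "pivot"),
                              forcefield = idpcg::forcefield()) {
  hydrodynamics <- match.arg(hydrodynamics)
  init <- match.arg(init)
  stopifnot(dt > 0, n_steps >= 1, n_equil >= 0, n_equil < n_steps,
            n_runs >= 1, frame_stride >= 1, obs_stride >= 1,
            cholesky_stride >= 1, verlet_skin > 0)
  structure(list(
    dt = dt, n_steps = n_steps, n_equil = n_equil, n_runs = n_runs,
    seed = seed, frame_stride = frame_stride, obs_stride = obs_stride,
    hydrodynamics = hydrodynamics, cholesky_stride = cholesky_stride,
    max_reject = max_reject, verlet_skin = verlet_skin, init = init,
    forcefield = forcefield
  ), class = "cg_config")
}

#' Self-avoiding random walk initial condition
#'
#' Places beads at fixed bond length in uniformly random directions,
#' rejecting placements that bring any nonbonded pair closer than
#' `min_sep`; clashes retry the current bead and, failing that, restart
#' the chain (bounded by `max_restarts`). Deterministic for a given seed.
#'
#' @param seq A [cg_sequence()] or its length N.
#' @param seed Optional integer seed.
#' @param bond Bond length (default 1.35).
#' @param min_sep Minimum nonbonded separation (default 1.5).
#' @param max_restarts Chain-restart budget (default 1e5).
#' @return N x 3 coordinate matrix.
#' @export
init_saw <- function(seq, seed = NULL, bond = 1.35, min_sep = 1.5,
                     max_restarts = 1e5) {
  n <- if (is.numeric(seq) && length(seq) == 1) as.integer(seq) else length(as_cg_sequence(seq))
  if (n < 2) stop("need at least 2 beads")
  gen <- function() cpp_init_saw(n, bond, min_sep, as.integer(max_restarts))
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Single Brownian-dynamics step
#'
#' Advances one Ermak-McCammon step \eqn{\Delta X = M F \Delta T + H \Delta W}
#' with \eqn{\Delta W} i.i.d. normal with variance \eqn{\Delta T} per
#' component. A proposed step that would stretch any bond to `L_max` or
#' beyond is rejected and retried with fresh noise. Convenience wrapper
#' around the compiled loop for inspection and testing; long runs should
#' use [run_simulation()].
#'
#' @param positions N x 3 coordinate matrix.
#' @param seq A [cg_sequence()].
#' @param config A [simulation_config()] (its seed field is ignored here;
#'   the caller controls the RNG state).
#' @return N x 3 matrix of new positions.
#' @export
bd_step <- function(positions, seq, config = simulation_config()) {
  res <- bd_run(positions, seq, config, n_steps = 1, n_equil = 0)
  res$final
}

#' Advance a configuration by many Brownian-dynamics steps
#'
#' Low-level interface to the compiled Ermak-McCammon loop: advances
#' `n_steps` steps from the given configuration using the caller's RNG
#' state (no seeding, no initial-condition generation), recording
#' observables and frames after `n_equil` steps. [run_simulation()] is the
#' high-level replica-aware interface.
#'
#' @param positions N x 3 starting coordinates.
#' @param seq A [cg_sequence()] (length N; a single monomer is allowed,
#'   giving a free bead).
#' @param config A [simulation_config()] (strides, dt, force field,
#'   hydrodynamics are honoured; seed/replica fields are not used).
#' @param n_steps Total steps to advance.
#' @param n_equil Leading steps excluded from recording.
#' @return A list: `frames` (N x 3 x F array), `obs` (matrix with columns
#'   step, re_x, re_y, re_z, rg2), `final` positions, `n_reject`.
#' @export
bd_run <- function(positions, seq, config = simulation_config(),
                   n_steps = config$n_steps, n_equil = config$n_equil) {
  seq <- as_cg_sequence(seq)
  ff <- config$forcefield
  bt <- seq_bead_table(seq, ff)
  cpp_bd_run(as.matrix(positions), bt$codes, ff$types$B,
             as.integer(ff$types$charge), ff$types$cohesive, bt$A,
             ff$eps, ff$eps_LJ, ff$Q, ff$L_D, ff$B0, ff$L_max,
             ff$cohesive_cutoff_factor, ff$elec_cutoff_factor,
             config$dt, n_steps, n_equil,
             as.integer(config$frame_stride), as.integer(config$obs_stride),
             config$hydrodynamics == "rpy", as.integer(config$cholesky_stride),
             as.integer(config$max_reject), config$verlet_skin)
}

#' Run a Brownian-dynamics simulation
#'
#' Runs `config$n_runs` replica trajectories of `config$n_steps` steps each,
#' starting from independent self-avoiding-walk initial conditions. Replica
#' sub-seeds are drawn once from the master seed, so the whole ensemble is
#' reproducible from `config$seed` and replicas are mutually independent.
#'
#' @param seq A [cg_sequence()] or repeat-notation string.
#' @param config A [simulation_config()].
#' @return A `cg_trajectory` object: list of per-replica `frames`
#'   (N x 3 x F arrays), `obs` (a tibble with `run`, `step`, `time`,
#'   `re_x`, `re_y`, `re_z`, `re`, `rg2`), and `meta` (sequence name,
#'   seeds, config).
#' @export
run_simulation <- function(seq, config = simulation_config()) {
  seq <- as_cg_sequence(seq)
  stopifnot(inherits(config, "cg_config"))
  sub_seeds <- withr_seed(config$seed,
                          sample.int(.Machine$integer.max, config$n_runs))
  runs <- lapply(seq_len(config$n_runs), function(k) {
    withr_seed(sub_seeds[k], {
      pos0 <- if (identical(config$init, "pivot")) {
        init_pivot(seq, config$forcefield)
      } else {
        cpp_init_saw(length(seq), 1.35, config$forcefield$B0, 100000L)
      }
      bd_run(pos0, seq, config, config$n_steps, config$n_equil)
    })
  })
  obs <- purrr::map_dfr(seq_along(runs), function(k) {
    o <- runs[[k]]$obs
    tibble::tibble(
      run = k,
      step = o[, 1],
      time = o[, 1] * config$dt,
      re_x = o[, 2], re_y = o[, 3], re_z = o[, 4],
      re = sqrt(o[, 2]^2 + o[, 3]^2 + o[, 4]^2),
      rg2 = o[, 5]
    )
  })
  structure(list(
    frames = lapply(runs, function(r) r$frames),
    obs = obs,
    final = lapply(runs, function(r) r$final),
    n_reject = sum(vapply(runs, function(r) r$n_reject, 0)),
    meta = list(
      sequence = seq, name = seq_name(seq), config = config,
      sub_seeds = sub_seeds
    )
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- sum(vapply(x$frames, function(f) dim(f)[3], 0L))
  cat("<cg_trajectory> ", x$meta$name,
      " | N = ", length(x$meta$sequence),
      " | runs = ", length(x$frames),
      " | frames = ", nf,
      " | obs rows = ", nrow(x$obs),
      " | eps = ", x$meta$config$forcefield$eps,
      " | hydro = ", x$meta$config$hydrodynamics, "\n", sep = "")
  invisible(x)
}

#' Write a trajectory as XYZ with a metadata sidecar
#'
#' One XYZ block per stored frame (element column = monomer label), plus a
#' JSON sidecar with the sequence, seeds and run parameters.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output path for the `.xyz` file; the sidecar gets the same
#'   path with `.json` appended.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  labs <- unclass(traj$meta$sequence)
  n <- length(labs)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    for (f in seq_len(dim(fr)[3])) {
      writeLines(as.character(n), con)
      writeLines(sprintf("run %d frame %d", k, f), con)
      writeLines(sprintf("%s %.6f %.6f %.6f", labs,
                         fr[, 1, f], fr[, 2, f], fr[, 3, f]), con)
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- traj$meta$config
    meta <- list(
      name = traj$meta$name,
      sequence = paste(labs, collapse = ""),
      seed = cfg$seed, sub_seeds = traj$meta$sub_seeds,
      dt = cfg$dt, n_steps = cfg$n_steps, n_equil = cfg$n_equil,
      hydrodynamics = cfg$hydrodynamics,
      eps = cfg$forcefield$eps
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Pivot Monte Carlo pre-equilibration
#'
#' Generates a near-equilibrium starting configuration by running a pivot
#' Metropolis Monte Carlo chain (random tail rotations about a random
#' bead, accepted with the Boltzmann criterion on the full potential
#' energy) from a self-avoiding-walk start. Pivot moves decorrelate
#' global shape orders of magnitude faster than local dynamics, so a few
#' thousand pivots at N = 100 produce a configuration whose shape
#' statistics are already equilibrated; bond lengths stay at their
#' initial value and thermalise within the first few time units of the
#' subsequent Brownian dynamics.
#'
#' @param seq A [cg_sequence()] (or any [as_cg_sequence()] input).
#' @param ff A [forcefield()].
#' @param n_pivots Number of attempted pivot moves (default 60 per bead).
#' @param seed Optional integer seed (deterministic given the seed).
#' @return N x 3 coordinate matrix.
#' @export
init_pivot <- function(seq, ff = forcefield(), n_pivots = NULL, seed = NULL) {
  seq <- as_cg_sequence(seq)
  n <- length(seq)
  if (n < 3) return(init_saw(seq, seed = seed))
  if (is.null(n_pivots)) n_pivots <- 60L * n
  bt <- seq_bead_table(seq, ff)
  energy <- function(p) {
    cpp_total_energy(p, bt$codes, ff$types$B, as.integer(ff$types$charge),
                     ff$types$cohesive, ff$eps, ff$eps_LJ, ff$Q, ff$L_D,
                     ff$B0, ff$L_max, ff$cohesive_cutoff_factor,
                     ff$elec_cutoff_factor)
  }
  run_mc <- function() {
    p <- cpp_init_saw(n, 1.35, ff$B0, 100000L)
    u <- energy(p)
    for (it in seq_len(n_pivots)) {
      k <- sample(2:(n - 1), 1)
      ax <- stats::rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      th <- stats::runif(1, -pi, pi)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      tail_idx <- (k + 1):n
      prop <- p
      prop[tail_idx, ] <- sweep(sweep(prop[tail_idx, , drop = FALSE], 2,
                                      p[k, ]) %*% t(R), 2, p[k, ], "+")
      u_new <- energy(prop)
      if (is.finite(u_new) && stats::runif(1) < exp(u - u_new)) {
        p <- prop
        u <- u_new
      }
    }
    p
  }
  if (is.null(seed)) run_mc() else withr_seed(seed, run_mc())
}
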