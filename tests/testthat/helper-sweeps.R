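# Shared simulation campaigns for the acceptance-level tests. Cached in an
# environment so several test blocks can reuse one sweep.

.sweep_cache <- new.env(parent = emptyenv())

# N = 50 homopolymer cohesiveness sweep (fast theta-point variant plus the
# eps = 0 and high-eps anchors used for monotonicity checks)
homopolymer_sweep_n50 <- function() {
  if (!is.null(.sweep_cache$n50)) return(.sweep_cache$n50)
  eps_grid <- c(0, 0.5, 0.7, 0.85, 1.0)
  res <- purrr::map_dfr(eps_grid, function(e) {
    cfg <- simulation_config(
      n_steps = 2e6, n_equil = 3e5, n_runs = 2,
      seed = 7000 + round(100 * e),
      frame_stride = 5000, obs_stride = 500, init = "pivot",
      forcefield = forcefield(eps = e)
    )
    ensemble_summary(run_simulation("(H)50", cfg))
  })
  .sweep_cache$n50 <- res
  res
}
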