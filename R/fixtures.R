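#' Named study sequence set
#'
#' The eleven sequences used throughout the package's reference analyses:
#' the five 60-mers of 30 cohesive and 30 neutral monomers with patch sizes
#' 1-5, the four 100-mer dynamics sequences (the cohesive homopolymer, the
#' alternating (HP)50 chain, and the HPP-repeat chains with cohesive and
#' with neutral ends), and the two 50-mer polyampholytes (strictly
#' alternating, and blocks of five).
#'
#' @return Named list of [cg_sequence()] objects.
#' @export
reference_sequences <- function() {
  specs <- c(
    "(HP)30", "(PHHP)15", "(PHHHPP)10", "PP(HHHHPPPP)7HH", "(PPHHHHHPPP)6",
    "(H)100", "(HP)50", "(HPP)33H", "P(HPP)33"
  )
  out <- lapply(specs, parse_sequence)
  names(out) <- specs
  out[["ampholyte_alternating_50"]] <-
    generate_polyampholyte(25, 25, "alternating")
  out[["ampholyte_blocks5_50"]] <-
    generate_polyampholyte(25, 25, "blocks", block_size = 5)
  out
}

#' Freely jointed (ideal) chain ensemble
#'
#' Random-walk chains with fixed bond length and uniformly random bond
#' directions — the theta-point analytic reference: \eqn{\langle R_e^2
#' \rangle = (N-1) b^2} and \eqn{\langle R_e^2\rangle/\langle R_g^2\rangle
#' = 6N/(N+1)}.
#'
#' @param n Beads per chain (>= 2).
#' @param n_conformations Number of independent chains.
#' @param seed Integer seed (deterministic ensemble).
#' @param bond Bond length (default 1.35, matching the simulator's bond).
#' @return List of N x 3 coordinate matrices.
#' @export
ideal_chain_ensemble <- function(n, n_conformations, seed = 1, bond = 1.35) {
  stopifnot(n >= 2, n_conformations >= 1)
  withr_seed(seed, {
    lapply(seq_len(n_conformations), function(k) {
      steps <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
      steps <- steps * (bond / sqrt(rowSums(steps^2)))
      apply(rbind(0, steps), 2, cumsum)
    })
  })
}

#' Uniform point pairs in a ball
#'
#' Pairs of independent uniform points inside a ball of radius `R` — the
#' dense-globule reference: \eqn{\langle d^2\rangle / R_g^2(\mathrm{ball})
#' = 2} and \eqn{\langle 1/d\rangle = 6/(5R)}. Points are drawn by the
#' radial inverse-CDF (radius \eqn{R u^{1/3}}) with uniform directions.
#'
#' @param R Ball radius (> 0).
#' @param n_pairs Number of point pairs.
#' @param seed Integer seed.
#' @return List with matrices `p1`, `p2` (n_pairs x 3).
#' @export
ball_point_ensemble <- function(R, n_pairs, seed = 1) {
  stopifnot(R > 0, n_pairs >= 1)
  draw <- function(m) {
    u <- matrix(stats::rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- R * stats::runif(m)^(1 / 3)
    u * r
  }
  withr_seed(seed, list(p1 = draw(n_pairs), p2 = draw(n_pairs)))
}

#' Statistics of an ideal-chain or coordinate ensemble
#'
#' Ensemble means of squared end-to-end distance, squared radius of
#' gyration, their ratio and the Kirkwood radius for a list of coordinate
#' matrices (e.g. from [ideal_chain_ensemble()]).
#'
#' @param conformations List of N x 3 matrices.
#' @param kirkwood Also accumulate the Kirkwood radius (default TRUE).
#' @return One-row tibble: `mean_re2`, `mean_rg2`, `ratio_re2_rg2`, `rk`,
#'   `ratio_rg_rk`.
#' @export
ensemble_statistics <- function(conformations, kirkwood = TRUE) {
  n <- nrow(conformations[[1]])
  re2 <- vapply(conformations, function(p) sum((p[1, ] - p[n, ])^2), 0)
  rg2 <- vapply(conformations, function(p) {
    c0 <- sweep(p, 2, colMeans(p))
    sum(c0^2) / n
  }, 0)
  rk <- NA_real_
  if (kirkwood) {
    inv <- vapply(conformations, function(p) 2 * sum(1 / stats::dist(p)), 0)
    rk <- n^2 / mean(inv)
  }
  tibble::tibble(
    mean_re2 = mean(re2), mean_rg2 = mean(rg2),
    ratio_re2_rg2 = mean(re2) / mean(rg2),
    rk = rk,
    ratio_rg_rk = sqrt(mean(rg2)) / rk
  )
}
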