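#' Dimensionless mobility matrix
#'
#' Builds the 3N x 3N mobility matrix used in the Brownian-dynamics step,
#' in units of the reference single-bead mobility \eqn{1/\xi_0} (Stokes
#' drag of a bead of radius `a0`). Self blocks are \eqn{(a_0/A_i) I}. With
#' `mode = "rpy"` the cross blocks are the Rotne-Prager-Yamakawa tensor,
#' including the overlapping-sphere correction for `r < 2a`, which keeps
#' the matrix positive definite for every configuration; unequal-radius
#' pairs use the mean radius \eqn{a = (A_i + A_j)/2}. With
#' `mode = "free_draining"` all cross blocks are zero.
#'
#' @param positions N x 3 matrix of bead coordinates.
#' @param radii Per-bead hydrodynamic radii (default `a0` for all beads).
#' @param mode `"rpy"` or `"free_draining"`.
#' @param a0 Reference bead radius setting the mobility scale (default
#'   3/4, half the default steric diameter).
#' @return 3N x 3N symmetric numeric matrix.
#' @export
mobility_matrix <- function(positions, radii = NULL,
                            mode = c("rpy", "free_draining"), a0 = 0.75) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  n <- nrow(positions)
  if (is.null(radii)) radii <- rep(a0, n)
  stopifnot(length(radii) == n, all(radii > 0))
  m <- cpp_mobility_matrix(positions, as.numeric(radii), a0, mode == "rpy")
  unname(as.matrix(m))
}

#' Cholesky noise square root of a mobility matrix
#'
#' Lower-triangular `H` with `H %*% t(H) = M`, used to colour the random
#' displacements so their covariance matches the mobility
#' (fluctuation-dissipation).
#'
#' @param M Symmetric positive-definite matrix.
#' @return Lower-triangular matrix of the same dimension.
#' @export
noise_root <- function(M) {
  M <- as.matrix(M)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf("matrix is not positive definite (most negative eigenvalue %.3e)",
                 min(ev)))
  }
  t(ch)
}
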