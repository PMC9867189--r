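#' FENE bond force
#'
#' Magnitude of the attractive bonded force at separation `R`, in the
#' dimensionless simulation units in which the spring constant is absorbed
#' into the length and force units, so that the force is exactly
#' \eqn{R/(1-(R/L_{max})^2)}. The corresponding bond energy in kT is
#' \eqn{-L_{max}^2 \log(1-(R/L_{max})^2)}.
#'
#' @param R Bond length(s), simulation units, `0 <= R < L_max`.
#' @param L_max Maximum extension (default 3).
#' @return Force magnitude(s), simulation force units (attractive along the
#'   bond).
#' @examples
#' fene_force(1.35)  # 1.6928...
#' @export
fene_force <- function(R, L_max = 3) {
  if (any(R < 0)) stop("bond length must be non-negative")
  if (any(R >= L_max)) stop("bond overstretched: R >= L_max")
  R / (1 - (R / L_max)^2)
}

#' FENE bond energy in kT
#'
#' @inheritParams fene_force
#' @return Energy in kT (0 at R = 0, divergent as R approaches `L_max`).
#' @export
fene_energy <- function(R, L_max = 3) {
  if (any(R < 0)) stop("bond length must be non-negative")
  if (any(R >= L_max)) stop("bond overstretched: R >= L_max")
  -L_max^2 * log(1 - (R / L_max)^2)
}

pair_contact_b <- function(type_i, type_j, ff, bonded = FALSE) {
  if (bonded) return(ff$B0)
  Bi <- ff$types$B[match(type_i, ff$types$label)]
  Bj <- ff$types$B[match(type_j, ff$types$label)]
  (Bi + Bj) / 2
}

#' Nonbonded pair potential
#'
#' Energy in kT of a pair of monomers at separation `r`:
#' a repulsive 8-6 Lennard-Jones core for `r < b` (shifted by
#' \eqn{(\epsilon_{LJ}-\epsilon_{pair})/3} for continuity), a cohesive 8-6
#' tail for cohesive pairs on `b < r < 4b`, and a screened-Coulomb
#' (Debye-Hueckel) term \eqn{Q z_i z_j e^{-r/L_D}/r} for charged pairs.
#' The contact distance is `b = (B_i + B_j)/2`, except `b = B0` for bonded
#' neighbours.
#'
#' @param r Separation(s), simulation units, > 0.
#' @param type_i,type_j Monomer labels (see [monomer_alphabet()]).
#' @param ff A [forcefield()].
#' @param bonded Are the two beads bonded neighbours along the chain?
#' @param include_elec Include the electrostatic term (default TRUE).
#' @return Energy (kT), vectorised over `r`.
#' @examples
#' ff <- forcefield(eps = 1)
#' pair_potential(1.5, "H", "H", ff)  # -eps/3 at contact
#' @export
pair_potential <- function(r, type_i, type_j, ff = forcefield(),
                           bonded = FALSE, include_elec = TRUE) {
  if (any(r <= 0)) stop("separation must be positive")
  b <- pair_contact_b(type_i, type_j, ff, bonded)
  coh_i <- ff$types$cohesive[match(type_i, ff$types$label)]
  coh_j <- ff$types$cohesive[match(type_j, ff$types$label)]
  eps_pair <- if (coh_i && coh_j) ff$eps else 0
  z_i <- ff$types$charge[match(type_i, ff$types$label)]
  z_j <- ff$types$charge[match(type_j, ff$types$label)]

  core <- (b / r)^8 - (4 / 3) * (b / r)^6
  u <- ifelse(r < b,
              ff$eps_LJ * core + (ff$eps_LJ - eps_pair) / 3,
              0)
  if (eps_pair > 0) {
    in_tail <- r >= b & r < ff$cohesive_cutoff_factor * b
    u <- u + ifelse(in_tail, eps_pair * core, 0)
  }
  zz <- z_i * z_j
  if (include_elec && zz != 0) {
    in_elec <- r < ff$elec_cutoff_factor * ff$L_D
    u <- u + ifelse(in_elec, ff$Q * zz * exp(-r / ff$L_D) / r, 0)
  }
  u
}

#' Total potential energy of a configuration
#'
#' Sum of FENE bond energies, bonded-pair repulsion and all nonbonded pair
#' terms, in kT. Reference implementation in R; the simulation engine uses
#' an equivalent compiled kernel.
#'
#' @param positions N x 3 matrix of bead coordinates, simulation units.
#' @param seq A [cg_sequence()] (length N).
#' @param ff A [forcefield()].
#' @return Scalar energy in kT.
#' @export
total_energy <- function(positions, seq, ff = forcefield()) {
  seq <- as_cg_sequence(seq)
  n <- nrow(positions)
  stopifnot(n == length(seq), ncol(positions) == 3)
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  u <- 0
  labs <- unclass(seq)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((positions[i, ] - positions[j, ])^2))
      bonded <- (j == i + 1)
      u <- u + pair_potential(r, labs[i], labs[j], ff, bonded = bonded)
      if (bonded) u <- u + fene_energy(r, ff$L_max)
    }
  }
  u
}

#' Total deterministic forces on all beads
#'
#' N x 3 matrix of forces in simulation force units: the sum of FENE bonded
#' forces and the steric, cohesive and electrostatic pair forces (the
#' negative configurational gradient of [total_energy()], with energies in
#' kT and the factor 1/2 from the unit system `f_c = 2 kT / x_c`).
#'
#' @inheritParams total_energy
#' @return N x 3 numeric matrix.
#' @export
total_forces <- function(positions, seq, ff = forcefield()) {
  seq <- as_cg_sequence(seq)
  stopifnot(nrow(positions) == length(seq), ncol(positions) == 3)
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  bt <- seq_bead_table(seq, ff)
  cpp_total_forces(as.matrix(positions), bt$codes, ff$types$B,
                   as.integer(ff$types$charge), ff$types$cohesive,
                   ff$eps, ff$eps_LJ, ff$Q, ff$L_D, ff$B0, ff$L_max,
                   ff$cohesive_cutoff_factor, ff$elec_cutoff_factor)
}
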