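#' Force-field parameters in simulation units
#'
#' All interaction parameters of the model, in the dimensionless simulation
#' unit system (length unit \eqn{x_c = \sqrt{2k_BT/k} = (2/3)b_0}, force
#' unit \eqn{f_c = 2k_BT/x_c}, time unit \eqn{t_c = \xi_0/k}). Energies are
#' in units of \eqn{k_BT}.
#'
#' @param eps Cohesive attraction strength between pairs of cohesive
#'   monomers, in kT. The main control parameter of the model.
#' @param eps_LJ Strength of the universal 8-6 steric repulsion, in kT
#'   (default 1).
#' @param Q Dimensionless electrostatic prefactor of the screened Coulomb
#'   interaction (default 2).
#' @param L_D Debye screening length, simulation units (default 4,
#'   roughly 1.1 nm).
#' @param B0 Steric diameter of the default monomer and zero-force distance
#'   of bonded pairs (default 3/2).
#' @param L_max Maximum FENE bond extension (default `2 * B0`).
#' @param B_plus,B_minus Steric diameters of the charged monomers
#'   (defaults 2.44 and 2.29, the relative volumes of lysine and glutamic
#'   acid).
#' @param cohesive_cutoff_factor Cohesive tail truncated at this multiple
#'   of the contact distance b (default 4).
#' @param elec_cutoff_factor Electrostatics truncated at this multiple of
#'   the Debye length (default 5; the screened potential there is below 1%
#'   of its contact scale).
#' @return A `cg_forcefield` list with the resolved per-type tables:
#'   `$types` is a tibble with `label`, `B` (steric diameter), `A`
#'   (hydrodynamic radius, `B/2`), `charge`, `cohesive`.
#' @examples
#' forcefield(eps = 0.7)
#' @export
forcefield <- function(eps = 0, eps_LJ = 1, Q = 2, L_D = 4,
                       B0 = 1.5, L_max = 2 * B0,
                       B_plus = 2.44, B_minus = 2.29,
                       cohesive_cutoff_factor = 4,
                       elec_cutoff_factor = 5) {
  stopifnot(eps >= 0, eps_LJ > 0, L_D > 0, B0 > 0, L_max > 0,
            B_plus > 0, B_minus > 0, cohesive_cutoff_factor > 1,
            elec_cutoff_factor > 0)
  types <- tibble::tibble(
    label = c("P", "H", "+", "-"),
    B = c(B0, B0, B_plus, B_minus),
    charge = c(0L, 0L, 1L, -1L),
    cohesive = c(FALSE, TRUE, FALSE, FALSE)
  )
  types$A <- types$B / 2
  structure(list(
    eps = eps, eps_LJ = eps_LJ, Q = Q, L_D = L_D,
    B0 = B0, L_max = L_max,
    cohesive_cutoff_factor = cohesive_cutoff_factor,
    elec_cutoff_factor = elec_cutoff_factor,
    types = types
  ), class = "cg_forcefield")
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("<cg_forcefield>\n")
  cat(sprintf("  eps = %g kT, eps_LJ = %g kT, Q = %g, L_D = %g\n",
              x$eps, x$eps_LJ, x$Q, x$L_D))
  cat(sprintf("  B0 = %g, L_max = %g, cohesive cutoff = %g b, elec cutoff = %g L_D\n",
              x$B0, x$L_max, x$cohesive_cutoff_factor, x$elec_cutoff_factor))
  print(x$types)
  invisible(x)
}

#' Resolved force-field parameter table
#'
#' One row per scalar parameter plus the per-type table, for provenance
#' logging alongside a run.
#'
#' @param ff A [forcefield()].
#' @return A tibble with `parameter` and `value` columns.
#' @export
forcefield_table <- function(ff) {
  stopifnot(inherits(ff, "cg_forcefield"))
  tibble::tibble(
    parameter = c("eps", "eps_LJ", "Q", "L_D", "B0", "L_max",
                  "cohesive_cutoff_factor", "elec_cutoff_factor",
                  "B_P", "B_H", "B_plus", "B_minus"),
    value = c(ff$eps, ff$eps_LJ, ff$Q, ff$L_D, ff$B0, ff$L_max,
              ff$cohesive_cutoff_factor, ff$elec_cutoff_factor,
              ff$types$B)
  )
}

#' Simulation unit system
#'
#' Conversion factors between the dimensionless simulation units and
#' physical units. The length unit is \eqn{x_c = (2/3)b_0}; with the bond
#' length of 1.35 simulation units corresponding to ~0.38 nm between
#' adjacent C-alpha atoms, one simulation length unit is ~0.2815 nm.
#'
#' @param nm_per_unit Nanometres per simulation length unit.
#' @return A list with `nm_per_unit` and helper conversion functions
#'   `to_nm(x)`, `from_nm(x)`.
#' @export
unit_system <- function(nm_per_unit = 0.38 / 1.35) {
  list(
    nm_per_unit = nm_per_unit,
    to_nm = function(x) x * nm_per_unit,
    from_nm = function(x) x / nm_per_unit
  )
}

# integer codes used by the C++ kernels: P=0, H=1, "+"=2, "-"=3
seq_type_codes <- function(seq) {
  match(unclass(as_cg_sequence(seq)), monomer_alphabet()) - 1L
}

# per-bead attribute vectors in sequence order
seq_bead_table <- function(seq, ff) {
  codes <- seq_type_codes(seq)
  t <- ff$types
  list(
    codes = codes,
    B = t$B[codes + 1L],
    A = t$A[codes + 1L],
    charge = t$charge[codes + 1L],
    cohesive = t$cohesive[codes + 1L]
  )
}
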