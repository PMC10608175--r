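# Closed-form estimates converting per-unit-length energetics of the 1D
# model into absolute energies and peptide surface concentrations for
# circular domains of radius R.

#' Effective domain-domain interaction length
#'
#' Converts per-unit-length energies of the 1D model into absolute energies
#' for circular domains of radius R: the facing arcs interact over an
#' effective length \eqn{2\sqrt{2\lambda R}}, where \eqn{\lambda} is the
#' lateral decay length of membrane deformations (about 1 nm).
#'
#' @param lambda_decay deformation decay length, nm.
#' @param R domain radius, nm.
#' @return effective interaction length, nm.
#' @examples
#' effective_interaction_length(1, 50)  # 20 nm
#' @export
effective_interaction_length <- function(lambda_decay, R) {
  stopifnot(lambda_decay > 0, R > 0)
  2 * sqrt(2 * lambda_decay * R)
}

#' Peptide/lipid ratio that saturates all domain boundaries
#'
#' For domains of radius R covering an area fraction `phi_d` of a membrane,
#' the number of peptides of helix length `Lp` needed to fully occupy all
#' domain boundaries, per lipid (one leaflet, `A0/a_L` lipids):
#' \eqn{P/L = 2 a_L \phi_d / (L_p R)}. The total membrane area cancels.
#'
#' @param R mean domain radius, nm.
#' @param phi_d area fraction of the ordered phase, in (0, 1).
#' @param a_L mean area per lipid, nm^2.
#' @param Lp peptide helix length, nm.
#' @return dimensionless peptide-to-lipid number ratio.
#' @examples
#' peptide_concentration_full_boundary(R = 50, phi_d = 0.3, a_L = 0.6,
#'                                     Lp = 3.5)  # ~1/500
#' @export
peptide_concentration_full_boundary <- function(R, phi_d = 0.3, a_L = 0.6,
                                                Lp = 3.5) {
  stopifnot(R > 0, phi_d > 0, phi_d < 1, a_L > 0, Lp > 0)
  2 * a_L * phi_d / (Lp * R)
}

#' Absolute depth of the boundary well for a peptide of finite length
#'
#' Multiplies the per-unit-length well depth by the effective length
#' `1.3 * Lp` of the membrane deformations induced by a peptide of helix
#' length `Lp`.
#'
#' @param well_per_length well depth per unit length, kB*T/nm.
#' @param Lp peptide helix length, nm.
#' @return absolute well depth, kB*T.
#' @examples
#' absolute_well_depth(0.8, 3.5)  # ~3.6 kBT
#' @export
absolute_well_depth <- function(well_per_length, Lp) {
  stopifnot(well_per_length >= 0, Lp > 0)
  well_per_length * 1.3 * Lp
}

#' Absolute domain-domain fusion barrier
#'
#' Per-unit-length barrier times the effective interaction length
#' \eqn{2\sqrt{2\lambda R}}.
#'
#' @param barrier_per_length fusion barrier per unit length, kB*T/nm.
#' @param lambda_decay deformation decay length, nm.
#' @param R domain radius, nm.
#' @return absolute barrier, kB*T.
#' @examples
#' absolute_fusion_barrier(0.08, 1, 50)  # 1.6 kBT
#' @export
absolute_fusion_barrier <- function(barrier_per_length, lambda_decay, R) {
  stopifnot(barrier_per_length >= 0)
  barrier_per_length * effective_interaction_length(lambda_decay, R)
}
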