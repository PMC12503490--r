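#' Force-field parameters for the bead-spring membrane model
#'
#' Collects every interaction constant of the model. Lipids are chains of
#' beads: a bilayer lipid is head-tail-tail with one straightening angle of
#' strength `k0`; a bolalipid is two bilayer lipids joined tail-to-tail by a
#' FENE bond, with backbone angles of strength `k0` over each three-bead half
#' and two hinge angles of strength `k_bola` across the junction. Heads
#' interact by volume exclusion only; tails of different lipids attract with
#' depth `eps_p` and range `omega`. An optional cargo sphere of radius
#' `r_cargo` adheres to head beads with depth `eps_mc`.
#'
#' All angle potentials have the form k (1 + cos theta), with minimum (zero
#' energy) at theta = pi, so a `k_bola = 0` bolalipid has a fully flexible
#' hinge. Repulsion is WCA with core diameters `b_head` = 0.95 sigma for any
#' pair involving a head and `b_tail` = 1 sigma for tail-tail, the standard
#' Cooke-model constants, as are the FENE parameters (k = 30 eps/sigma^2,
#' rmax = 1.5 sigma).
#'
#' @param eps_p tail-tail attraction depth (energy unit; keep at 1 and vary
#'   the thermostat temperature, which then equals the effective temperature
#'   T_eff = k_B T / eps_p).
#' @param omega attraction range (sigma).
#' @param k0 backbone straightening strength (k_B T).
#' @param k_bola hinge strength of the bolalipid junction (k_B T); 0 gives a
#'   fully flexible bolalipid.
#' @param eps_mc cargo-head adhesion depth (k_B T); 0 disables adhesion.
#' @param r_cargo cargo bead radius (sigma).
#' @param b_head,b_tail repulsive core diameters (sigma).
#' @param eps_rep WCA repulsion strength (energy).
#' @param fene_k,fene_rmax FENE bond stiffness (energy/sigma^2) and
#'   divergence length (sigma).
#' @param excl_bonds non-bonded exclusion depth along a chain: 1 excludes
#'   only directly bonded pairs (the LAMMPS FENE convention; second and
#'   third neighbours interact, which stabilises the U shape through
#'   intramolecular tail contacts), 3 excludes 1-2, 1-3 and 1-4 pairs.
#' @return An object of class `forcefield_params` (a named list).
#' @examples
#' ff <- forcefield_params(k_bola = 1)
#' pair_potential(2^(1/6), "tail", "tail", ff) # depth -eps_p at the minimum
#' @export
forcefield_params <- function(eps_p = 1, omega = 1.5, k0 = 10, k_bola = 0,
                              eps_mc = 0, r_cargo = 5,
                              b_head = 0.95, b_tail = 1, eps_rep = 1,
                              fene_k = 30, fene_rmax = 1.5, excl_bonds = 1) {
  stopifnot(eps_p > 0, omega > 0, k0 >= 0, k_bola >= 0, eps_mc >= 0,
            b_head > 0, b_tail > 0, fene_rmax > max(b_head, b_tail),
            r_cargo > 0, excl_bonds %in% c(1, 3))
  structure(list(eps_p = eps_p, omega = omega, k0 = k0, k_bola = k_bola,
                 eps_mc = eps_mc, r_cargo = r_cargo, b_head = b_head,
                 b_tail = b_tail, eps_rep = eps_rep, fene_k = fene_k,
                 fene_rmax = fene_rmax, excl_bonds = as.integer(excl_bonds)),
            class = "forcefield_params")
}

#' @export
print.forcefield_params <- function(x, ...) {
  cat("Force field (reduced units: sigma, eps_p, tau)\n")
  cat(sprintf("  tail attraction : depth %g, range %g sigma\n", x$eps_p, x$omega))
  cat(sprintf("  angles          : k0 = %g, k_bola = %g k_BT\n", x$k0, x$k_bola))
  cat(sprintf("  cores           : b_head %g, b_tail %g sigma (WCA %g)\n",
              x$b_head, x$b_tail, x$eps_rep))
  cat(sprintf("  FENE            : k %g, rmax %g sigma\n", x$fene_k, x$fene_rmax))
  if (x$eps_mc > 0)
    cat(sprintf("  cargo           : radius %g sigma, adhesion %g k_BT\n",
                x$r_cargo, x$eps_mc))
  invisible(x)
}

#' Model units
#'
#' The reduced unit system: lengths in sigma (about 1 nm), energies in eps_p,
#' masses 1 per bead, time unit tau = sigma sqrt(m / eps_p). The effective
#' temperature is T_eff = k_B T / eps_p.
#'
#' @param sigma,epsilon,tau,mass the four base units.
#' @param T_eff dimensionless effective temperature.
#' @return A named list of class `model_units`.
#' @export
model_units <- function(sigma = 1, epsilon = 1, tau = 1, mass = 1, T_eff = 1) {
  stopifnot(sigma > 0, epsilon > 0, tau > 0, mass > 0, T_eff > 0)
  structure(list(sigma = sigma, epsilon = epsilon, tau = tau, mass = mass,
                 T_eff = T_eff), class = "model_units")
}

.role_code <- function(role) {
  r <- match(role, c("head", "tail", "cargo"))
  if (anyNA(r)) stop("role must be one of 'head', 'tail', 'cargo'")
  r
}

#' Pairwise non-bonded potential
#'
#' Energy and radial force (-dE/dr) for a non-bonded bead pair. Head-head and
#' head-tail pairs are purely repulsive (WCA); tail-tail pairs additionally
#' feel the flat-bottomed attraction of depth `eps_p` tapered to zero with a
#' cos^2 profile over the range `omega`. Pairs involving a cargo bead use the
#' shifted distance so the interaction acts at the cargo surface; cargo-head
#' pairs carry the adhesion depth `eps_mc`, cargo-tail pairs are repulsive.
#'
#' @param r distances (sigma), all > 0.
#' @param role_i,role_j bead roles: "head", "tail" or "cargo".
#' @param ff a [forcefield_params()] object.
#' @return data.frame with columns `energy` and `force` (= -dE/dr).
#' @export
pair_potential <- function(r, role_i, role_j, ff) {
  stopifnot(inherits(ff, "forcefield_params"))
  if (any(r <= 0)) stop("overlapping beads: pair distance must be > 0")
  m <- cpp_pair_ef(as.numeric(r), .role_code(role_i), .role_code(role_j),
                   unclass(ff))
  data.frame(energy = m[, 1], force = m[, 2])
}

#' FENE bond potential (with WCA core)
#'
#' @param r bond lengths (sigma), 0 < r < `fene_rmax`; lengths at or beyond
#'   `fene_rmax` signal a broken bond.
#' @param ff a [forcefield_params()] object.
#' @param b core diameter used for the WCA part (defaults to `b_tail`).
#' @return data.frame with columns `energy`, `force`.
#' @export
bond_potential <- function(r, ff, b = ff$b_tail) {
  stopifnot(inherits(ff, "forcefield_params"))
  m <- cpp_bond_ef(as.numeric(r), unclass(ff), b)
  data.frame(energy = m[, 1], force = m[, 2])
}

#' Cosine angle potential k (1 + cos theta)
#'
#' Zero energy and zero torque at theta = pi (straight), maximal energy 2k at
#' theta = 0. Used with k = `k0` for backbone angles and k = `k_bola` for the
#' bolalipid hinge.
#'
#' @param theta angles in radians, in `[0, pi]`.
#' @param k strength (k_B T).
#' @return data.frame with columns `energy` and `torque` (= -dE/dtheta).
#' @export
angle_potential <- function(theta, k) {
  stopifnot(k >= 0, all(theta >= -1e-9), all(theta <= pi + 1e-9))
  m <- cpp_angle_ef(as.numeric(theta), k)
  data.frame(energy = m[, 1], torque = m[, 2])
}

#' Cargo adhesion potential acting on a head or tail bead
#'
#' Convenience wrapper around [pair_potential()] with one cargo partner.
#'
#' @inheritParams pair_potential
#' @param role role of the non-cargo bead ("head" or "tail").
#' @export
cargo_potential <- function(r, role, ff) {
  pair_potential(r, role, "cargo", ff)
}

#' Lipid topology template
#'
#' Bead roles, bonds and angle definitions for one molecule. A bolalipid is
#' exactly two bilayer lipids joined tail-to-tail by one FENE bond (the same
#' parameters as intra-lipid bonds); its hinge angles span beads (2,3,4) and
#' (3,4,5) of the six-bead chain.
#'
#' @param species "bilayer" or "bola".
#' @return list with `roles` (character), `bonds` (matrix of in-molecule bead
#'   index pairs), `angles` (matrix of triplets) and `angle_type` (1 =
#'   backbone k0, 2 = hinge k_bola).
#' @export
lipid_topology <- function(species = c("bilayer", "bola")) {
  species <- match.arg(species)
  if (species == "bilayer") {
    list(roles = c("head", "tail", "tail"),
         bonds = rbind(c(1, 2), c(2, 3)),
         angles = rbind(c(1, 2, 3)),
         angle_type = 1L)
  } else {
    list(roles = c("head", "tail", "tail", "tail", "tail", "head"),
         bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6)),
         angles = rbind(c(1, 2, 3), c(4, 5, 6), c(2, 3, 4), c(3, 4, 5)),
         angle_type = c(1L, 1L, 2L, 2L))
  }
}

# materialise per-angle strengths from the force field
.angle_strengths <- function(sys, ff) {
  ifelse(sys$angle_type == 1L, ff$k0, ff$k_bola)
}

#' Total energy, forces and virial of a configuration
#'
#' Evaluates all interactions (non-bonded pairs, cargo, FENE bonds, angles)
#' for the current configuration. Forces are the exact negative gradient of
#' the energy; the diagonal virial is returned for pressure calculations.
#'
#' @param sys a [particle_system()].
#' @param ff a [forcefield_params()].
#' @return list with `energy` (total potential), `forces` (N x 3 matrix),
#'   `virial` (c(Wxx, Wyy, Wzz)) and `kinetic` (per-axis kinetic energies).
#' @export
system_energy <- function(sys, ff) {
  stopifnot(inherits(sys, "particle_system"), inherits(ff, "forcefield_params"))
  cpp_compute(sys$positions, sys$velocities, sys$role, sys$mass,
              sys$bonds, sys$angles, .angle_strengths(sys, ff),
              sys$box, unclass(ff))
}
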