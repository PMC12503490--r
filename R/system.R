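#' Particle system: the mutable simulation state
#'
#' Positions, velocities, species and topology of all beads plus the periodic
#' box. Positions are kept unwrapped (continuous across box images) so that
#' diffusion can be measured directly; they are wrapped into the box on
#' output by [wrap_positions()] and internally for force evaluation.
#'
#' @param positions N x 3 matrix (sigma).
#' @param velocities N x 3 matrix (sigma/tau).
#' @param role integer per bead: 1 head, 2 tail, 3 cargo.
#' @param lipid integer per bead: molecule index (0 for cargo).
#' @param lipid_species character per molecule: "bilayer" or "bola".
#' @param bonds M x 2 integer matrix of bonded bead indices (1-based).
#' @param angles K x 3 integer matrix of angle triplets (central bead second).
#' @param angle_type integer per angle: 1 backbone (k0), 2 hinge (k_bola).
#' @param box c(Lx, Ly, Lz), periodic in all three directions.
#' @param mass per-bead masses (default 1; cargo gets its own mass).
#' @param time elapsed simulation time (tau).
#' @param step integration step counter (drives the counter-based RNG).
#' @return object of class `particle_system`.
#' @export
particle_system <- function(positions, velocities, role, lipid, lipid_species,
                            bonds, angles, angle_type, box,
                            mass = rep(1, nrow(positions)),
                            time = 0, step = 0) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  storage.mode(positions) <- "double"
  storage.mode(velocities) <- "double"
  bonds <- matrix(as.integer(bonds), ncol = 2)
  angles <- matrix(as.integer(angles), ncol = 3)
  sys <- structure(list(
    positions = positions, velocities = velocities,
    role = as.integer(role), lipid = as.integer(lipid),
    lipid_species = as.character(lipid_species),
    bonds = bonds, angles = angles, angle_type = as.integer(angle_type),
    box = as.numeric(box), mass = as.numeric(mass),
    time = time, step = step), class = "particle_system")
  validate_system(sys)
  sys
}

#' Validate a particle system
#'
#' Checks bead-count bookkeeping (3 beads per bilayer lipid, 6 per bola, one
#' per cargo), index ranges and box sanity. Called by the constructor and the
#' builders; exported because analysis code on externally read trajectories
#' benefits from the same checks.
#'
#' @param sys a `particle_system`.
#' @return `sys`, invisibly; errors on inconsistency.
#' @export
validate_system <- function(sys) {
  n <- nrow(sys$positions)
  stopifnot(nrow(sys$velocities) == n, length(sys$role) == n,
            length(sys$lipid) == n, length(sys$mass) == n,
            length(sys$box) == 3, all(sys$box > 0))
  if (nrow(sys$angles) != length(sys$angle_type))
    stop("angle_type must have one entry per angle")
  nb <- tabulate(sys$lipid[sys$lipid > 0], nbins = length(sys$lipid_species))
  want <- ifelse(sys$lipid_species == "bola", 6L, 3L)
  if (length(nb) && any(nb != want))
    stop("bead count inconsistent with topology: expected 3 beads per ",
         "bilayer lipid and 6 per bolalipid")
  ncargo <- sum(sys$role == 3L)
  if (n != sum(want) + ncargo)
    stop("total bead count does not match 3*n_bilayer + 6*n_bola + n_cargo")
  if (nrow(sys$bonds) && (min(sys$bonds) < 1 || max(sys$bonds) > n))
    stop("bond index out of range")
  if (nrow(sys$angles) && (min(sys$angles) < 1 || max(sys$angles) > n))
    stop("angle index out of range")
  invisible(sys)
}

#' @export
print.particle_system <- function(x, ...) {
  ns <- table(factor(x$lipid_species, levels = c("bilayer", "bola")))
  cat(sprintf("Particle system: %d beads (%d bilayer lipids, %d bolalipids%s)\n",
              nrow(x$positions), ns[["bilayer"]], ns[["bola"]],
              if (any(x$role == 3L)) ", 1 cargo" else ""))
  cat(sprintf("  box %.2f x %.2f x %.2f sigma, t = %.1f tau (step %d)\n",
              x$box[1], x$box[2], x$box[3], x$time, as.integer(x$step)))
  invisible(x)
}

#' Number of lipids in a system
#' @param sys a `particle_system`.
#' @export
n_lipids <- function(sys) length(sys$lipid_species)

#' Wrap positions into the primary box image
#'
#' @param sys a `particle_system`.
#' @return the system with positions wrapped into `[0, L)` per axis.
#' @export
wrap_positions <- function(sys) {
  for (d in 1:3) {
    L <- sys$box[d]
    sys$positions[, d] <- sys$positions[, d] - L * floor(sys$positions[, d] / L)
  }
  sys
}

# unwrapped coordinates of one molecule, walking its bead chain with
# minimum-image steps from the first bead (beads of a molecule are stored
# consecutively)
.mol_unwrap <- function(pos, box) {
  n <- nrow(pos)
  if (n == 1) return(pos)
  d <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  out <- pos
  out[-1, ] <- matrix(rep(pos[1, ], n - 1), ncol = 3, byrow = TRUE) +
    apply(d, 2, cumsum)
  out
}

# bead index list per lipid (consecutive storage assumed and verified)
.lipid_beads <- function(sys) {
  split(seq_len(nrow(sys$positions))[sys$lipid > 0],
        sys$lipid[sys$lipid > 0])
}

# centres of mass per lipid (unwrapped: positions are continuous)
.lipid_com <- function(positions, lipid) {
  keep <- lipid > 0
  rowsum(positions[keep, , drop = FALSE], lipid[keep]) /
    as.vector(table(lipid[keep]))
}

#' Assemble the bead-level topology for a vector of lipid species
#'
#' Internal workhorse of the builders: given per-molecule species, produces
#' role/lipid vectors and global bond/angle index matrices.
#' @param species character vector, "bilayer" or "bola" per molecule.
#' @return list(role, lipid, bonds, angles, angle_type, n_beads).
#' @export
make_topology <- function(species) {
  tpl <- list(bilayer = lipid_topology("bilayer"), bola = lipid_topology("bola"))
  nb <- ifelse(species == "bola", 6L, 3L)
  off <- cumsum(c(0L, nb[-length(nb)]))
  role <- integer(0); lipid <- integer(0)
  bonds <- list(); angles <- list(); atype <- list()
  for (i in seq_along(species)) {
    t <- tpl[[species[i]]]
    role <- c(role, .role_code(t$roles))
    lipid <- c(lipid, rep(i, length(t$roles)))
    bonds[[i]] <- t$bonds + off[i]
    angles[[i]] <- t$angles + off[i]
    atype[[i]] <- t$angle_type
  }
  list(role = role, lipid = lipid,
       bonds = do.call(rbind, bonds),
       angles = do.call(rbind, angles),
       angle_type = unlist(atype),
       n_beads = sum(nb))
}
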