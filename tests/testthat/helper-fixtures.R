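# Programmatic fixtures: small constructed systems with known geometry.

# a system of bolalipids from a list of 6x3 coordinate matrices
make_bola_system <- function(coords, box = c(40, 40, 40), k0 = 10) {
  species <- rep("bola", length(coords))
  topo <- make_topology(species)
  pos <- do.call(rbind, coords)
  particle_system(pos, matrix(0, nrow(pos), 3), topo$role, topo$lipid,
                  species, topo$bonds, topo$angles, topo$angle_type, box)
}

# straight bola along +z starting at `at`
straight_bola <- function(at = c(0, 0, 0), spacing = 0.9) {
  sweep(cbind(0, 0, spacing * (0:5)), 2, at, "+")
}

# ideal hairpin: both halves parallel, heads at the same end
hairpin_bola <- function(at = c(0, 0, 0), spacing = 0.9, gap = 1) {
  up <- cbind(0, 0, spacing * (2:0))      # beads 1..3: head top -> junction
  dn <- cbind(gap, 0, spacing * (0:2))    # beads 4..6: junction -> head top
  sweep(rbind(up, dn), 2, at, "+")        # order: head,t,t,t,t,head
}

# right-angle bend: first half along -z, second along +x
right_angle_bola <- function(at = c(0, 0, 0), spacing = 0.9) {
  h1 <- cbind(0, 0, spacing * c(2, 1, 0))         # head, tail, tail (junction)
  h2 <- cbind(spacing * c(1, 2, 3), 0, -0.9)      # tail, tail, head
  sweep(rbind(h1, h2), 2, at, "+")
}

# a flat crystalline monolayer sheet of single head beads (pore fixtures):
# returns a particle-like system of "bilayer" lipids standing on a lattice,
# optionally with all lipids within `hole_aperture`/2 + 0.5 of the centre
# removed so a sphere of diameter `hole_aperture` can pass
flat_lattice_membrane <- function(nside = 30, spacing = 1.05,
                                  hole_aperture = NULL, box_z = 20) {
  g <- expand.grid(x = (seq_len(nside) - 0.5) * spacing,
                   y = (seq_len(nside) - 0.5) * spacing)
  L <- nside * spacing
  keep <- rep(TRUE, nrow(g))
  if (!is.null(hole_aperture)) {
    # free aperture of the requested diameter: remove sites whose bead
    # surfaces would intrude into the cylinder of that diameter
    rexcl <- hole_aperture / 2 + 0.5
    keep <- sqrt((g$x - L / 2)^2 + (g$y - L / 2)^2) >= rexcl
  }
  g <- g[keep, ]
  blocks <- lapply(seq_len(nrow(g)), function(i)
    list(species = "bilayer",
         pos = cbind(g$x[i], g$y[i], box_z / 2 + c(1.8, 0.9, 0))))
  species <- rep("bilayer", nrow(g))
  topo <- make_topology(species)
  pos <- do.call(rbind, lapply(blocks, `[[`, "pos"))
  particle_system(pos, matrix(0, nrow(pos), 3), topo$role, topo$lipid,
                  species, topo$bonds, topo$angles, topo$angle_type,
                  c(L, L, box_z))
}

# small equilibrated-ish membrane cached across tests (built once per run)
.cache <- new.env()
small_liquid_membrane <- function() {
  if (is.null(.cache$memb)) {
    ff <- forcefield_params()
    ip <- integrator_params(temperature = 1.1, barostat = TRUE, seed = 5)
    sys <- build_flat(100, f_bi = 1, temperature = 1.1, seed = 5)
    .cache$memb <- md_run(sys, ff, ip, 10000)$system
  }
  .cache$memb
}
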