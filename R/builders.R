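# Seeded builders for every initial configuration used in the experiments:
# dispersed gas (self-assembly), pre-assembled flat membranes, cylinders
# (membrane tubes), free-edged patches and adhesive-cargo setups.
#
# All builders are deterministic under a fixed seed, produce overlap-free
# configurations and Maxwell-distributed velocities, and leave bolalipids
# straight (initial U-fraction 0); mixtures interleave species uniformly at
# random with bilayer lipids assigned to leaflets in balanced pairs.

# species assignment for n lipids at bilayer fraction f_bi: lattice "sites"
# hold either one straight bola or a pair of opposing bilayer lipids
.site_plan <- function(n_lipids, f_bi) {
  stopifnot(n_lipids >= 1, f_bi >= 0, f_bi <= 1)
  n_bi <- round(f_bi * n_lipids)
  n_bola <- n_lipids - n_bi
  n_bi_sites <- ceiling(n_bi / 2)
  sites <- c(rep("bola", n_bola), rep("bi_pair", n_bi_sites))
  if (n_bi %% 2 == 1) sites[length(sites)] <- "bi_single"
  list(sites = sample(sites), n_bola = n_bola, n_bi = n_bi)
}

# beads of one site at centre `ctr`, oriented along unit vector `u`
# (from inner/lower head to outer/upper head); returns list of per-lipid
# coordinate blocks and species
.site_beads <- function(kind, ctr, u, spacing = 0.9) {
  zs <- spacing * c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  at <- function(s) rbind(ctr + s * u)
  pos6 <- do.call(rbind, lapply(zs, at))
  if (kind == "bola") {
    # head, tail x4, head from bottom to top
    list(list(species = "bola", pos = pos6))
  } else if (kind == "bi_pair") {
    up <- pos6[6:4, , drop = FALSE]   # head at top, tails inward
    lo <- pos6[1:3, , drop = FALSE]
    list(list(species = "bilayer", pos = up),
         list(species = "bilayer", pos = lo))
  } else { # bi_single: upper leaflet only
    list(list(species = "bilayer", pos = pos6[6:4, , drop = FALSE]))
  }
}

.assemble <- function(blocks, box, temperature, time = 0) {
  species <- vapply(blocks, `[[`, "", "species")
  pos <- do.call(rbind, lapply(blocks, `[[`, "pos"))
  topo <- make_topology(species)
  vel <- maxwell_velocities(nrow(pos), temperature)
  particle_system(pos, vel, topo$role, topo$lipid, species,
                  topo$bonds, topo$angles, topo$angle_type, box,
                  time = time)
}

#' Build a flat membrane
#'
#' Two-leaflet square lattice in the x-y midplane of the box: straight
#' bolalipids span both leaflets (one site each), bilayer lipids come in
#' opposing upper/lower pairs per site. Mixtures are interleaved uniformly at
#' random. The lattice spacing corresponds to roughly 1.2 sigma^2 per tail
#' site, near the liquid density, so the zero-tension barostat only has a
#' small relaxation to do.
#'
#' @param n_lipids total number of lipid molecules.
#' @param f_bi bilayer-lipid number fraction in `[0, 1]`.
#' @param temperature k_B T for the initial Maxwell velocities.
#' @param seed RNG seed (placement and velocities).
#' @param spacing lattice constant (sigma).
#' @param box_z box height (sigma).
#' @return a [particle_system()].
#' @export
build_flat <- function(n_lipids, f_bi = 0, temperature = 1, seed = 1,
                       spacing = 1.1, box_z = 30) {
  with_seed(seed, {
    plan <- .site_plan(n_lipids, f_bi)
    n_sites <- length(plan$sites)
    ns <- ceiling(sqrt(n_sites))
    L <- ns * spacing
    box <- c(L, L, box_z)
    idx <- sample(ns * ns, n_sites)
    gx <- ((idx - 1) %% ns + 0.5) * spacing
    gy <- ((idx - 1) %/% ns + 0.5) * spacing
    blocks <- list()
    for (s in seq_len(n_sites)) {
      ctr <- c(gx[s], gy[s], box_z / 2)
      blocks <- c(blocks, .site_beads(plan$sites[s], ctr, c(0, 0, 1)))
    }
    .assemble(blocks, box, temperature)
  })
}

#' Build a dispersed lipid gas
#'
#' Straight molecules at random positions and orientations in a periodic 3D
#' box, with no core overlaps (used as the start of self-assembly runs).
#'
#' @inheritParams build_flat
#' @param box c(Lx, Ly, Lz).
#' @param min_dist minimum allowed inter-molecular bead distance (sigma).
#' @param max_tries placement attempts per molecule before giving up.
#' @param slab optional c(zlo, zhi): confine molecule centres to this z
#'   range (orientations stay isotropic). A slab-seeded gas assembles into
#'   a box-spanning membrane instead of a free-floating aggregate, while
#'   lipid conformations still equilibrate during aggregation.
#' @export
build_gas <- function(n_lipids, f_bi = 0, box = c(20, 20, 20),
                      temperature = 1, seed = 1, min_dist = 0.9,
                      max_tries = 200, slab = NULL) {
  with_seed(seed, {
    n_bi <- round(f_bi * n_lipids)
    species <- sample(c(rep("bilayer", n_bi), rep("bola", n_lipids - n_bi)))
    placed <- NULL
    blocks <- list()
    for (i in seq_len(n_lipids)) {
      nb <- if (species[i] == "bola") 6 else 3
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ctr <- runif(3) * box
        if (!is.null(slab))
          ctr[3] <- runif(1, slab[1], slab[2])
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        s <- 0.9 * (seq_len(nb) - (nb + 1) / 2)
        pos <- t(vapply(s, function(z) ctr + z * u, numeric(3)))
        if (!is.null(placed)) {
          d2min <- min(vapply(seq_len(nrow(pos)), function(k) {
            d <- sweep(placed, 2, pos[k, ])
            for (dd in 1:3) d[, dd] <- d[, dd] - box[dd] * round(d[, dd] / box[dd])
            min(rowSums(d^2))
          }, numeric(1)))
          if (d2min < min_dist^2) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("gas builder: could not place molecule ", i,
                    " without overlap; lower the density")
      placed <- rbind(placed, pos)
      # bead order along u serves directly: head-tail-tail (bilayer) or
      # head-tail*4-head (bola); orientation u is isotropic anyway
      blocks[[i]] <- list(species = species[i], pos = pos)
    }
    .assemble(blocks, box, temperature)
  })
}

#' Build a cylindrical membrane (tube)
#'
#' Membrane tube of mean radius `radius`, periodic along its z axis, lipids
#' placed radially on rings: bolalipids span the monolayer, bilayer-lipid
#' pairs form the two leaflets. Mean curvature H = 1 / (2 radius).
#'
#' @param radius target midsurface radius (sigma); must exceed the membrane
#'   half-thickness (3 sigma).
#' @param length tube length = box Lz (sigma).
#' @param area_per_site midsurface area per lipid site (sigma^2).
#' @param margin lateral vacuum margin beyond the outer heads (sigma).
#' @inheritParams build_flat
#' @export
build_cylinder <- function(radius, length = 20, f_bi = 0, temperature = 1,
                           seed = 1, area_per_site = 1.2, margin = 8) {
  if (radius < 3)
    stop("cylinder radius below membrane thickness; rejected")
  with_seed(seed, {
    ring_dz <- sqrt(area_per_site)
    n_rings <- max(1, round(length / ring_dz))
    dz <- length / n_rings
    n_phi <- max(3, round(2 * pi * radius / sqrt(area_per_site)))
    n_sites <- n_rings * n_phi
    plan <- .site_plan(n_sites, f_bi) # one lipid (or pair) per site
    Lxy <- 2 * (radius + 2.5) + margin
    box <- c(Lxy, Lxy, length)
    ctr0 <- c(Lxy / 2, Lxy / 2, 0)
    blocks <- list()
    s <- 0
    for (iz in seq_len(n_rings)) {
      phase <- if (iz %% 2 == 0) pi / n_phi else 0
      for (ip in seq_len(n_phi)) {
        s <- s + 1
        phi <- 2 * pi * (ip - 1) / n_phi + phase
        u <- c(cos(phi), sin(phi), 0)
        ctr <- ctr0 + c(radius * u[1], radius * u[2], (iz - 0.5) * dz)
        blocks <- c(blocks, .site_beads(plan$sites[s], ctr, u))
      }
    }
    .assemble(blocks, box, temperature)
  })
}

#' Build a free-standing membrane patch
#'
#' A disc cut from the flat two-leaflet lattice, centred in a large
#' non-constraining box with one exposed edge; used for patch-closure
#' (Gaussian modulus) ensembles.
#'
#' @inheritParams build_flat
#' @param box_margin vacuum margin around the disc in every direction
#'   (sigma); make it comfortably larger than the disc radius so a closing
#'   patch never interacts with its periodic images.
#' @export
build_patch <- function(n_lipids, f_bi = 1, temperature = 1, seed = 1,
                        spacing = 1.1, box_margin = 18) {
  with_seed(seed, {
    plan <- .site_plan(n_lipids, f_bi)
    n_sites <- length(plan$sites)
    # square lattice, keep the n_sites cells closest to the centre -> disc
    ns <- ceiling(sqrt(n_sites / pi) * 2) + 2
    g <- expand.grid(ix = seq_len(ns), iy = seq_len(ns))
    cx <- (ns + 1) / 2
    ord <- order((g$ix - cx)^2 + (g$iy - cx)^2)
    g <- g[ord[seq_len(n_sites)], ]
    r_disc <- sqrt(n_sites * spacing^2 / pi)
    L <- 2 * (r_disc + box_margin)
    blocks <- list()
    for (s in seq_len(n_sites)) {
      ctr <- c(L / 2 + (g$ix[s] - cx) * spacing,
               L / 2 + (g$iy[s] - cx) * spacing, L / 2)
      blocks <- c(blocks, .site_beads(plan$sites[s], ctr, c(0, 0, 1)))
    }
    sys <- .assemble(blocks, c(L, L, L), temperature)
    attr(sys, "r_disc") <- r_disc
    sys
  })
}

#' Add an adhesive cargo bead above a flat membrane
#'
#' Places one large sphere bead (role "cargo") tangent to the membrane: its
#' surface sits at WCA contact with the topmost lipid heads, so at least one
#' head starts within adhesion range. The cargo mass is `r_cargo^3` (unit
#' bead density). The box is extended in z if needed.
#'
#' @param sys a flat-membrane [particle_system()].
#' @param ff [forcefield_params()] carrying `r_cargo` (and `eps_mc` used
#'   during the run).
#' @param gap extra clearance above contact (sigma).
#' @export
add_cargo <- function(sys, ff, gap = 0.05) {
  stopifnot(!any(sys$role == 3L))
  w <- wrap_positions(sys)
  heads <- w$positions[w$role == 1L, , drop = FALSE]
  ztop <- max(heads[, 3])
  delta <- ff$r_cargo - 0.5 * ff$b_head
  zc <- ztop + delta + 2^(1/6) * ff$b_head + gap
  need <- zc + ff$r_cargo + 4
  if (need > sys$box[3]) sys$box[3] <- need
  sys$positions <- rbind(sys$positions, c(sys$box[1] / 2, sys$box[2] / 2, zc))
  sys$velocities <- rbind(sys$velocities, c(0, 0, 0))
  sys$role <- c(sys$role, 3L)
  sys$lipid <- c(sys$lipid, 0L)
  sys$mass <- c(sys$mass, ff$r_cargo^3)
  validate_system(sys)
  sys
}

# Fibonacci sphere directions
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a fully wrapped reference fixture
#'
#' A closed two-leaflet vesicle shell of bilayer lipids around a central
#' cargo bead, with the inner-leaflet heads at adhesion contact. Serves as
#' the normalisation reference for [wrapping_fraction()] (its adhered-head
#' count defines "fully wrapped") and as a geometric fixture for budding
#' detection. `coverage < 1` keeps only the spherical cap of that area
#' fraction (e.g. 0.5 = hemisphere).
#'
#' @param ff [forcefield_params()] (uses `r_cargo`, `b_head`, `omega`).
#' @param coverage fraction of the sphere covered by the shell, in (0, 1].
#' @param area_per_head head area on each leaflet sphere (sigma^2).
#' @param box box side (sigma); default fits the shell comfortably.
#' @param temperature k_B T for velocities.
#' @param seed RNG seed.
#' @param with_cargo include the central cargo bead (FALSE gives an empty
#'   vesicle shell, e.g. for closure-detection fixtures).
#' @export
build_wrapped_fixture <- function(ff, coverage = 1, area_per_head = 1.2,
                                  box = NULL, temperature = 1, seed = 1,
                                  with_cargo = TRUE) {
  stopifnot(coverage > 0, coverage <= 1)
  with_seed(seed, {
    delta <- ff$r_cargo - 0.5 * ff$b_head
    r_in <- delta + 2^(1/6) * ff$b_head      # inner head radius (contact)
    r_out <- r_in + 4.5                       # outer head radius
    if (is.null(box)) box <- 2 * (r_out + 6)
    ctr <- rep(box / 2, 3)
    blocks <- list()
    for (leaf in c("in", "out")) {
      rh <- if (leaf == "in") r_in else r_out
      n <- max(4, round(4 * pi * rh^2 / area_per_head))
      dirs <- .fib_sphere(n)
      keep <- dirs[, 3] >= 1 - 2 * coverage   # spherical cap of given area
      dirs <- dirs[keep, , drop = FALSE]
      sgn <- if (leaf == "in") 1 else -1      # tails point away from heads
      for (k in seq_len(nrow(dirs))) {
        u <- dirs[k, ]
        rr <- rh + sgn * c(0, 0.9, 1.8)
        pos <- t(vapply(rr, function(r) ctr + r * u, numeric(3)))
        blocks <- c(blocks, list(list(species = "bilayer", pos = pos)))
      }
    }
    sys <- .assemble(blocks, rep(box, 3), temperature)
    if (with_cargo) {
      sys$positions <- rbind(sys$positions, ctr)
      sys$velocities <- rbind(sys$velocities, c(0, 0, 0))
      sys$role <- c(sys$role, 3L)
      sys$lipid <- c(sys$lipid, 0L)
      sys$mass <- c(sys$mass, ff$r_cargo^3)
    }
    validate_system(sys)
    sys
  })
}

#' Merge two particle systems into one box
#'
#' Concatenates beads and topology; the second system's coordinates are used
#' as-is, so place it inside the first system's box beforehand. Used to
#' compose fixtures (e.g. a detached vesicle plus a flat membrane).
#'
#' @param a,b `particle_system`s; the merged system keeps `a`'s box.
#' @export
merge_systems <- function(a, b) {
  off <- nrow(a$positions)
  nlip <- n_lipids(a)
  lip_b <- ifelse(b$lipid > 0L, b$lipid + nlip, 0L)
  particle_system(rbind(a$positions, b$positions),
                  rbind(a$velocities, b$velocities),
                  c(a$role, b$role), c(a$lipid, lip_b),
                  c(a$lipid_species, b$lipid_species),
                  rbind(a$bonds, b$bonds + off),
                  rbind(a$angles, b$angles + off),
                  c(a$angle_type, b$angle_type),
                  a$box,
                  mass = c(a$mass, b$mass),
                  time = a$time, step = a$step)
}
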