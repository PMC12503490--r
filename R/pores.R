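# Probe-sphere pore detection: a pore is a membrane opening through which a
# sphere of a given diameter can cross from one face of the membrane to the
# other. Space is discretised on a 3D occupancy grid (bead cores inflated by
# the probe radius); pores are free-cell components connecting the two
# offset surfaces at +/- (half thickness + 1 sigma) from the midsurface.

# occupancy + free-space component labels for a given probe diameter
.pore_labels <- function(w, box, radii_core, probe_d, cell, periodic) {
  radii <- radii_core + probe_d / 2
  nx <- max(3, ceiling(box[1] / cell))
  ny <- max(3, ceiling(box[2] / cell))
  nz <- max(3, ceiling(box[3] / cell))
  occ <- cpp_occupancy(w, radii, box, nx, ny, nz, periodic)
  lab <- cpp_free_components(occ, nx, ny, nz, periodic)
  list(lab = lab, dim = c(nx, ny, nz))
}

# cell centre coordinates for a labelled grid
.grid_centres <- function(dim, box) {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  idx <- seq_len(nx * ny * nz) - 1
  cbind(((idx %% nx) + 0.5) * box[1] / nx,
        (((idx %/% nx) %% ny) + 0.5) * box[2] / ny,
        ((idx %/% (nx * ny)) + 0.5) * box[3] / nz)
}

# does any free component connect side A to side B? returns crossing count
.crossings <- function(lab, sideA, sideB) {
  a <- unique(lab[sideA & lab > 0])
  b <- unique(lab[sideB & lab > 0])
  length(intersect(a, b))
}

#' Detect transmembrane pores
#'
#' For a flat geometry the two sides are the half-spaces beyond
#' `z0 +/- (half_thickness + 1)`; for a spherical geometry (membrane bud)
#' they are inside/outside the shell `R_mid -/+ (half_thickness + 1)`,
#' restricted to the half-space above `z_min` so the bud neck toward the
#' mother membrane is not mistaken for a pore. A pore exists when a
#' connected free path crosses between the sides; the pore diameter is the
#' largest probe that can still cross, found by bisection.
#'
#' @param sys a [particle_system()].
#' @param ff force field (bead core diameters).
#' @param geometry list: `type = "flat"` with optional `z0`,
#'   `half_thickness`; or `type = "spherical"` with `center`, `R_mid`,
#'   optional `half_thickness`, `z_min`.
#' @param probe minimum probe diameter defining a pore (sigma).
#' @param max_probe upper bound of the diameter search (sigma).
#' @param tol bisection tolerance on the diameter (sigma).
#' @param cell occupancy grid cell size (sigma).
#' @return data.frame of class `pore_record`: `time`, `region`,
#'   `max_diameter` (0 when pore-free), `pore_count`.
#' @export
detect_pores <- function(sys, ff, geometry = list(type = "flat"),
                         probe = 1, max_probe = 10, tol = 0.25, cell = 0.5) {
  w <- wrap_positions(sys)
  pos <- w$positions
  radii_core <- ifelse(w$role == 1L, ff$b_head / 2,
                       ifelse(w$role == 2L, ff$b_tail / 2, ff$r_cargo))
  if (geometry$type == "flat") {
    heads <- pos[w$role == 1L, 3]
    z0 <- geometry$z0 %||% mean(heads)
    ht <- geometry$half_thickness %||% (mean(abs(heads - z0)) + 0.5)
    periodic <- c(TRUE, TRUE, FALSE)
    sides <- function(ctr) list(A = ctr[, 3] > z0 + ht + 1,
                                B = ctr[, 3] < z0 - ht - 1)
    region <- "mother_flat"
  } else if (geometry$type == "spherical") {
    ctr0 <- geometry$center
    R_mid <- geometry$R_mid
    ht <- geometry$half_thickness %||% 3
    zmin <- geometry$z_min %||% -Inf
    periodic <- c(TRUE, TRUE, FALSE)
    sides <- function(ctr) {
      r <- sqrt((ctr[, 1] - ctr0[1])^2 + (ctr[, 2] - ctr0[2])^2 +
                (ctr[, 3] - ctr0[3])^2)
      above <- ctr[, 3] > zmin
      list(A = above & r < pmax(0, R_mid - ht - 1),
           B = above & r > R_mid + ht + 1 & r < R_mid + ht + 4)
    }
    region <- "bud"
  } else stop("unknown geometry type: ", geometry$type)

  test <- function(d) {
    pl <- .pore_labels(pos, sys$box, radii_core, d, cell, periodic)
    ctr <- .grid_centres(pl$dim, sys$box)
    s <- sides(ctr)
    .crossings(pl$lab, s$A, s$B)
  }
  n0 <- test(probe)
  if (n0 == 0) {
    out <- data.frame(time = sys$time, region = region, max_diameter = 0,
                      pore_count = 0L)
  } else {
    lo <- probe; hi <- max_probe
    if (test(hi) > 0) {
      lo <- hi
    } else {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (test(mid) > 0) lo <- mid else hi <- mid
      }
    }
    out <- data.frame(time = sys$time, region = region, max_diameter = lo,
                      pore_count = as.integer(n0))
  }
  class(out) <- c("pore_record", "data.frame")
  out
}

#' Time-averaged pore statistics
#'
#' Mean of the per-frame maximum pore diameter per region; frames without a
#' pore contribute zero. Standard errors over frames.
#'
#' @param records rbind of [detect_pores()] records over frames.
#' @return data.frame region, mean_max_diameter, se, n_frames,
#'   pore_fraction (fraction of frames with any pore).
#' @export
pore_statistics <- function(records) {
  stopifnot(nrow(records) >= 1)
  do.call(rbind, lapply(split(records, records$region), function(g)
    data.frame(region = g$region[1],
               mean_max_diameter = mean(g$max_diameter),
               se = sd(g$max_diameter) / sqrt(nrow(g)),
               n_frames = nrow(g),
               pore_fraction = mean(g$max_diameter > 0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
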