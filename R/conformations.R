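# Per-lipid geometric classification: the bolalipid head-to-head angle
# theta, the U/straight dichotomy, leaflet/layer assignment of head beads,
# and region labels (cargo bud versus flat mother membrane).

#' Head-to-head angle of every bolalipid
#'
#' theta is the angle between the two half-lipid end-to-end vectors (head
#' bead minus the junction tail bead of its half), computed on
#' periodic-image-corrected molecule coordinates. A perfectly straight
#' (collinear) bolalipid has theta = pi, an ideal hairpin (both halves
#' antiparallel) theta = 0.
#'
#' @param sys a [particle_system()].
#' @return named numeric vector, one angle in `[0, pi]` per bolalipid
#'   (names = lipid indices).
#' @export
head_to_head_angle <- function(sys) {
  beads <- .lipid_beads(sys)
  bolas <- which(sys$lipid_species == "bola")
  out <- vapply(bolas, function(l) {
    p <- .mol_unwrap(sys$positions[beads[[l]], , drop = FALSE], sys$box)
    v1 <- p[1, ] - p[3, ]  # head 1 relative to its junction-side tail
    v2 <- p[6, ] - p[4, ]  # head 2 likewise
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-9 || n2 < 1e-9) stop("degenerate zero-length half-lipid vector")
    acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2))))
  }, numeric(1))
  names(out) <- bolas
  out
}

#' Classify bolalipid conformations
#'
#' U-shaped if theta < pi/2, straight otherwise (theta = pi/2 counts as
#' straight).
#'
#' @param theta angles in `[0, pi]`.
#' @return character vector "U" / "straight".
#' @export
classify_conformation <- function(theta) {
  stopifnot(all(theta >= -1e-9 & theta <= pi + 1e-9))
  ifelse(theta < pi / 2, "U", "straight")
}

#' U-shape fraction of a configuration
#'
#' @param sys a [particle_system()] containing bolalipids.
#' @return fraction of bolalipids with theta < pi/2.
#' @export
u_fraction <- function(sys) {
  th <- head_to_head_angle(sys)
  if (!length(th)) stop("no bolalipids in system")
  mean(th < pi / 2)
}

# local midplane height of the membrane on a 2-sigma x-y grid (mean head z
# per cell, empty cells filled from the global mean)
.local_midplane <- function(heads_xy, heads_z, box, grid = 2) {
  nx <- max(1, floor(box[1] / grid)); ny <- max(1, floor(box[2] / grid))
  ix <- pmin(nx, pmax(1, ceiling(heads_xy[, 1] / box[1] * nx)))
  iy <- pmin(ny, pmax(1, ceiling(heads_xy[, 2] / box[2] * ny)))
  cell <- (iy - 1) * nx + ix
  mids <- tapply(heads_z, cell, mean)
  mid <- rep(mean(heads_z), nx * ny)
  mid[as.integer(names(mids))] <- mids
  mid[cell]
}

#' Conformation table with layer and region labels
#'
#' One row per head bead, carrying the owning lipid, its species and (for
#' bolalipids) theta and U/straight class, plus a layer label and a region
#' label depending on the experiment geometry:
#'
#' * `geometry = "flat"`: layer "upper"/"lower" by head height against the
#'   local membrane midplane (2-sigma grid); region "mother_flat".
#' * `geometry = "cargo"`: lipids with their centre within
#'   `r_cargo + bud_margin` of the cargo centre are region "bud", the rest
#'   "mother_flat". Bud heads are layered "outer"/"inner" by radial distance
#'   from the cargo centre against the local mid-shell radius; mother heads
#'   by midplane as in "flat". Straight bolalipids lying flat with both
#'   heads in the bud outer layer are relabelled region "pore_rim" (they
#'   line pore edges) and are excluded from u_f by default.
#' * `geometry = "cylinder"`: layer by radial distance from the given axis.
#'
#' @param sys a [particle_system()].
#' @param geometry "flat", "cargo" or "cylinder".
#' @param bud_margin bud region cutoff beyond the cargo radius (sigma).
#' @param r_cargo cargo radius (taken from the cargo bead geometry; required
#'   only for `geometry = "cargo"`).
#' @param axis for "cylinder": c(x, y) of the tube axis (defaults to the box
#'   centre).
#' @return data.frame of class `conformation_table` with columns `lipid`,
#'   `species`, `head` (1 or 2), `theta`, `class`, `layer`, `region`.
#' @export
conformation_table <- function(sys, geometry = c("flat", "cargo", "cylinder"),
                               bud_margin = 4, r_cargo = NULL, axis = NULL) {
  geometry <- match.arg(geometry)
  w <- wrap_positions(sys)
  beads <- .lipid_beads(sys)
  th_all <- rep(NA_real_, n_lipids(sys))
  bolas <- sys$lipid_species == "bola"
  if (any(bolas)) th_all[bolas] <- head_to_head_angle(sys)

  rows <- list()
  for (l in seq_len(n_lipids(sys))) {
    b <- beads[[l]]
    hidx <- b[sys$role[b] == 1L]
    for (h in seq_along(hidx)) {
      rows[[length(rows) + 1]] <- data.frame(
        lipid = l, species = sys$lipid_species[l], head = h,
        bead = hidx[h], theta = th_all[l],
        class = if (bolas[l]) classify_conformation(th_all[l]) else NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  hp <- w$positions[tab$bead, , drop = FALSE]

  if (geometry == "flat") {
    mid <- .local_midplane(hp[, 1:2, drop = FALSE], hp[, 3], sys$box)
    tab$layer <- ifelse(hp[, 3] >= mid, "upper", "lower")
    tab$region <- "mother_flat"
  } else if (geometry == "cylinder") {
    if (is.null(axis)) axis <- sys$box[1:2] / 2
    r <- sqrt((hp[, 1] - axis[1])^2 + (hp[, 2] - axis[2])^2)
    tab$layer <- ifelse(r >= median(r), "outer", "inner")
    tab$region <- "cylinder"
  } else {
    ci <- which(sys$role == 3L)
    if (length(ci) != 1) stop("cargo geometry needs exactly one cargo bead")
    if (is.null(r_cargo)) stop("r_cargo required for cargo geometry")
    ctr <- w$positions[ci, ]
    dd <- sweep(hp, 2, ctr)
    for (d in 1:3) dd[, d] <- dd[, d] - sys$box[d] * round(dd[, d] / sys$box[d])
    rhead <- sqrt(rowSums(dd^2))
    # region by the lipid centre: a lipid is in the bud if its mean head
    # distance is below the cutoff
    rlip <- tapply(rhead, tab$lipid, mean)[as.character(tab$lipid)]
    bud <- rlip < (r_cargo + bud_margin + 2.5)
    tab$region <- ifelse(bud, "bud", "mother_flat")
    tab$layer <- NA_character_
    if (any(bud)) {
      rmid <- median(rhead[bud])
      tab$layer[bud] <- ifelse(rhead[bud] >= rmid, "outer", "inner")
    }
    if (any(!bud)) {
      hp2 <- hp[!bud, , drop = FALSE]
      mid <- .local_midplane(hp2[, 1:2, drop = FALSE], hp2[, 3], sys$box)
      tab$layer[!bud] <- ifelse(hp2[, 3] >= mid, "upper", "lower")
    }
    # straight bolas lying flat in the bud with both heads outer: pore rim
    if (any(bud)) {
      agg <- tapply(tab$layer[bud] == "outer", tab$lipid[bud], all)
      rim <- as.integer(names(agg))[agg]
      rim <- rim[sys$lipid_species[rim] == "bola" &
                 !is.na(th_all[rim]) & th_all[rim] >= pi / 2]
      tab$region[tab$lipid %in% rim] <- "pore_rim"
    }
  }
  class(tab) <- c("conformation_table", "data.frame")
  tab
}

#' Composition fractions from a conformation table
#'
#' u_f = N_U / N_bola among bolalipids in the selected region(s);
#' f_bi_h = bilayer head beads / all head beads, per layer.
#'
#' @param tab a [conformation_table()].
#' @param region regions to include (default: all except "pore_rim", whose
#'   flat-lying straight bolalipids would otherwise dilute u_f).
#' @param include_rim include "pore_rim" lipids in u_f.
#' @return list with `u_f`, `n_bola`, and data.frame `f_bi_h` per layer.
#' @export
composition_fractions <- function(tab, region = NULL, include_rim = FALSE) {
  stopifnot(inherits(tab, "conformation_table"))
  if (is.null(region)) region <- setdiff(unique(tab$region),
                                         if (include_rim) character(0) else "pore_rim")
  sel <- tab$region %in% region
  if (!any(sel)) stop("empty region selection; fractions undefined")
  one <- tab[sel & !duplicated(tab$lipid), ]   # per-lipid view
  bol <- one$species == "bola"
  u_f <- if (any(bol)) mean(one$class[bol] == "U") else NA_real_
  heads <- tab[sel, ]
  f_bi_h <- do.call(rbind, lapply(split(heads, heads$layer), function(g)
    data.frame(layer = g$layer[1], f_bi_h = mean(g$species == "bilayer"),
               n_heads = nrow(g))))
  rownames(f_bi_h) <- NULL
  list(u_f = u_f, n_bola = sum(bol), f_bi_h = f_bi_h)
}
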