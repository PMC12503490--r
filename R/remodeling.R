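# Cargo-wrapping experiments: wrapping progress, budding/fission detection
# and the onset adhesion energy by bisection.

#' Wrapping fraction of a cargo bead
#'
#' Number of head beads within adhesion range of the cargo surface,
#' normalised by the adhered-head count of a fully wrapped reference
#' fixture ([build_wrapped_fixture()]) with the same cargo radius. Clamped
#' to `[0, 1]`.
#'
#' @param sys a [particle_system()] with one cargo bead.
#' @param ff force field (adhesion range).
#' @param reference adhered-head count defining "fully wrapped"; computed
#'   from the reference fixture when NULL.
#' @export
wrapping_fraction <- function(sys, ff, reference = NULL) {
  if (is.null(reference)) reference <- wrapped_reference_count(ff)
  min(1, n_adhered_heads(sys, ff) / reference)
}

#' Count head beads within adhesion range of the cargo
#' @inheritParams wrapping_fraction
#' @export
n_adhered_heads <- function(sys, ff) {
  ci <- which(sys$role == 3L)
  if (length(ci) != 1) stop("system must contain exactly one cargo bead")
  w <- wrap_positions(sys)
  heads <- which(w$role == 1L)
  d <- sweep(w$positions[heads, , drop = FALSE], 2, w$positions[ci, ])
  for (k in 1:3) d[, k] <- d[, k] - sys$box[k] * round(d[, k] / sys$box[k])
  r <- sqrt(rowSums(d^2))
  rng <- (ff$r_cargo - 0.5 * ff$b_head) + 2^(1/6) * ff$b_head + ff$omega
  sum(r < rng)
}

#' Adhered-head count of the fully wrapped reference fixture
#' @param ff force field.
#' @export
wrapped_reference_count <- function(ff) {
  n_adhered_heads(build_wrapped_fixture(ff), ff)
}

#' Detect budding state of a wrapping configuration
#'
#' The final state is `fully_wrapped_budded` when the lipid cluster
#' enveloping the cargo is (a) disconnected from the mother membrane and
#' (b) closed, i.e. the space just outside the cargo surface is no longer
#' reachable from the box boundary (occupancy-grid flood fill, periodic in
#' x-y). Otherwise the state is `partial` when any heads adhere, else
#' `unwrapped`.
#'
#' @param sys a [particle_system()] with one cargo bead.
#' @param ff force field.
#' @param cell occupancy grid cell (sigma).
#' @param probe probe radius used to close single-bead gaps (sigma).
#' @return list with `state`, `wrapping_fraction`, `detached`, `enclosed`.
#' @export
detect_budding <- function(sys, ff, cell = 0.5, probe = 0.5) {
  wf <- wrapping_fraction(sys, ff)
  ci <- which(sys$role == 3L)
  w <- wrap_positions(sys)
  # cluster containing the most adhered lipids vs the largest other cluster
  cl <- lipid_clusters(sys)
  heads <- which(w$role == 1L)
  d <- sweep(w$positions[heads, , drop = FALSE], 2, w$positions[ci, ])
  for (k in 1:3) d[, k] <- d[, k] - sys$box[k] * round(d[, k] / sys$box[k])
  rng <- (ff$r_cargo - 0.5 * ff$b_head) + 2^(1/6) * ff$b_head + ff$omega
  adh_lip <- unique(sys$lipid[heads[sqrt(rowSums(d^2)) < rng]])
  detached <- FALSE
  if (length(adh_lip)) {
    bud_cl <- as.integer(names(which.max(table(cl$membership[adh_lip]))))
    other <- cl$membership != bud_cl
    detached <- any(other) &&
      max(tabulate(cl$membership[other])) >= 0.2 * n_lipids(sys)
  }
  # enclosure: flood from the boundary; periodic laterally, open in z
  radii <- ifelse(w$role == 1L, ff$b_head / 2,
                  ifelse(w$role == 2L, ff$b_tail / 2, ff$r_cargo)) + probe
  nx <- max(3, ceiling(sys$box[1] / cell))
  ny <- max(3, ceiling(sys$box[2] / cell))
  nz <- max(3, ceiling(sys$box[3] / cell))
  occ <- cpp_occupancy(w$positions, radii, sys$box, nx, ny, nz,
                       c(TRUE, TRUE, FALSE))
  lab <- cpp_free_components(occ, nx, ny, nz, c(TRUE, TRUE, FALSE))
  # the cargo is enclosed when the outside free-space component (the one
  # touching the top box face) comes nowhere near the cargo surface
  lab_out <- lab[(nz - 1) * ny * nx + 1]
  idx <- which(lab == lab_out) - 1
  cx <- ((idx %% nx) + 0.5) * sys$box[1] / nx
  cy <- (((idx %/% nx) %% ny) + 0.5) * sys$box[2] / ny
  cz <- ((idx %/% (nx * ny)) + 0.5) * sys$box[3] / nz
  dx <- cx - w$positions[ci, 1]; dx <- dx - sys$box[1] * round(dx / sys$box[1])
  dy <- cy - w$positions[ci, 2]; dy <- dy - sys$box[2] * round(dy / sys$box[2])
  dz <- cz - w$positions[ci, 3]
  enclosed <- lab_out != 0 &&
    min(sqrt(dx^2 + dy^2 + dz^2)) > ff$r_cargo + 2 * probe + 1.5
  state <- if (wf >= 0.05 && detached && enclosed) "fully_wrapped_budded"
           else if (wf >= 0.05) "partial" else "unwrapped"
  list(state = state, wrapping_fraction = wf, detached = detached,
       enclosed = enclosed)
}

#' Onset adhesion energy by bisection
#'
#' The minimum adhesion energy eps_mc at which the cargo is fully wrapped
#' and buds off. `runner(eps_mc, seed)` must perform one wrapping run and
#' return the final state string; success at a given eps_mc means a
#' majority of `replicates` runs end `fully_wrapped_budded`. The interval
#' `range` is bisected down to `resolution`. Runs that never bracket the
#' transition are flagged `unresolved`.
#'
#' @param runner function(eps_mc, seed) -> state string.
#' @param range c(lo, hi) adhesion energies (k_B T).
#' @param resolution bracket width at which bisection stops (k_B T).
#' @param replicates runs per tested eps_mc.
#' @param seed base seed.
#' @return object of class `onset_estimate`: `eps_star`, `bracket`,
#'   `unresolved`, `log` (all outcomes).
#' @export
onset_energy <- function(runner, range = c(0.5, 12), resolution = 0.1,
                         replicates = 3, seed = 1) {
  log <- list()
  test <- function(eps) {
    states <- vapply(seq_len(replicates), function(r)
      runner(eps, seed + 97 * r + round(1000 * eps)), character(1))
    log[[length(log) + 1]] <<- data.frame(eps_mc = eps, state = states)
    mean(states == "fully_wrapped_budded") > 0.5
  }
  lo <- range[1]; hi <- range[2]
  ok_lo <- test(lo); ok_hi <- test(hi)
  unresolved <- FALSE
  if (ok_lo) {
    # success everywhere: onset at or below the lower sweep bound
    eps_star <- lo; bracket <- c(NA_real_, lo); unresolved <- TRUE
  } else if (!ok_hi) {
    eps_star <- NA_real_; bracket <- c(hi, NA_real_); unresolved <- TRUE
  } else {
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (test(mid)) hi <- mid else lo <- mid
    }
    eps_star <- hi; bracket <- c(lo, hi)
  }
  structure(list(eps_star = eps_star, bracket = bracket,
                 unresolved = unresolved, resolution = resolution,
                 log = do.call(rbind, log)),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (x$unresolved) {
    cat("Onset energy: unresolved in the sweep range",
        if (!is.na(x$eps_star)) sprintf("(success already at %.2f k_BT)", x$eps_star)
        else "(no success up to the upper bound)", "\n")
  } else {
    cat(sprintf("Onset adhesion energy eps*_mc = %.2f k_BT (bracket %.2f-%.2f)\n",
                x$eps_star, x$bracket[1], x$bracket[2]))
  }
  invisible(x)
}

#' Standard wrapping-run runner
#'
#' Builds a flat membrane with a cargo bead on top, runs `n_steps` at the
#' requested adhesion energy and returns the budding state. Used by
#' [onset_energy()]; exposed so scripts can run single wrapping experiments.
#'
#' @param eps_mc adhesion depth (k_B T).
#' @param seed RNG seed.
#' @param n_lipids,f_bi membrane composition.
#' @param k_bola hinge stiffness.
#' @param r_cargo cargo radius (sigma).
#' @param temperature k_B T.
#' @param n_steps run length.
#' @param omega tail attraction range.
#' @return final state string.
#' @export
run_wrapping <- function(eps_mc, seed = 1, n_lipids = 300, f_bi = 0,
                         k_bola = 0, r_cargo = 4, temperature = 1.1,
                         n_steps = 200000, omega = 1.5) {
  ff <- forcefield_params(omega = omega, k_bola = k_bola, eps_mc = eps_mc,
                          r_cargo = r_cargo)
  sys <- build_flat(n_lipids, f_bi = f_bi, temperature = temperature,
                    seed = seed)
  sys <- add_cargo(sys, ff)
  ip <- integrator_params(temperature = temperature, barostat = TRUE,
                          seed = seed)
  r <- md_run(sys, ff, ip, n_steps)
  detect_budding(r$system, ff)$state
}
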