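# Diffusion measurement and gel/liquid/gas phase classification, plus the
# phase-diagram scan driver.

#' Positions observer for md_run
#'
#' Returns a closure recording, at each sample, the lipid centres of mass
#' (in-plane diffusion), the box and the time.
#' @return function suitable for the `observers` argument of [md_run()].
#' @export
observe_lipid_com <- function() {
  function(sys) list(time = sys$time,
                     com = .lipid_com(sys$positions, sys$lipid),
                     box = sys$box)
}

#' Observer recording head-bead positions (for spectra)
#' @export
observe_heads <- function() {
  function(sys) {
    w <- wrap_positions(sys)
    list(time = sys$time, heads = w$positions[w$role == 1L, , drop = FALSE],
         box = sys$box)
  }
}

#' Observer recording the full wrapped configuration
#' @export
observe_positions <- function() {
  function(sys) {
    w <- wrap_positions(sys)
    list(time = sys$time, positions = w$positions, box = sys$box)
  }
}

#' In-plane mean-squared displacement and diffusion coefficient
#'
#' Computes the in-plane (x, y) MSD of lipid centres of mass from a series
#' of `observe_lipid_com()` samples and fits MSD(t) = 4 D t + c over the lag
#' window. Box-rescaling motion from the barostat is removed by working in
#' scaled coordinates multiplied by the time-averaged box. The first
#' `discard` fraction of frames is dropped as equilibration.
#'
#' @param frames list of samples from [observe_lipid_com()].
#' @param species optional species filter ("bola"/"bilayer"); needs
#'   `lipid_species`.
#' @param lipid_species per-lipid species vector (from the system) when
#'   filtering.
#' @param lag_window c(min, max) lag times (tau) for the linear fit.
#' @param discard fraction of initial frames dropped.
#' @return list with `D` (sigma^2/tau), `msd` (data.frame lag, msd),
#'   `quality` ("ok" or "sublinear" when the MSD is strongly caged).
#' @export
msd_diffusion <- function(frames, species = NULL, lipid_species = NULL,
                          lag_window = c(10, 100), discard = 0.25) {
  stopifnot(length(frames) >= 3)
  frames <- frames[seq.int(floor(length(frames) * discard) + 1, length(frames))]
  times <- vapply(frames, `[[`, 0, "time")
  Lref <- rowMeans(vapply(frames, function(f) f$box[1:2], numeric(2)))
  keep <- seq_len(nrow(frames[[1]]$com))
  if (!is.null(species)) {
    stopifnot(!is.null(lipid_species))
    keep <- which(lipid_species == species)
    if (!length(keep)) stop("no lipids of species ", species)
  }
  # scaled in-plane coordinates remove the affine barostat motion
  sxy <- lapply(frames, function(f)
    sweep(f$com[keep, 1:2, drop = FALSE], 2, f$box[1:2], "/"))
  nf <- length(frames)
  lags <- seq_len(nf - 1)
  msd <- vapply(lags, function(k) {
    d <- 0; n <- 0
    for (i in seq_len(nf - k)) {
      ds <- sweep(sxy[[i + k]] - sxy[[i]], 2, Lref, "*")
      d <- d + sum(ds^2); n <- n + nrow(ds)
    }
    d / n
  }, numeric(1))
  lag_t <- times[1 + lags] - times[1]
  df <- data.frame(lag = lag_t, msd = msd)
  sel <- which(df$lag >= lag_window[1] & df$lag <= lag_window[2])
  if (length(sel) < 2) sel <- seq_len(min(nrow(df), max(2, nrow(df) %/% 2)))
  fit <- lm(msd ~ lag, data = df[sel, ])
  D <- max(0, unname(coef(fit)[2]) / 4)
  # caging check: late-window slope much below early slope => sublinear
  half <- sel[seq_len(ceiling(length(sel) / 2))]
  fit1 <- lm(msd ~ lag, data = df[half, ])
  quality <- if (coef(fit1)[2] > 4 * max(coef(fit)[2], 1e-12) &&
                 coef(fit)[2] < 1e-5) "sublinear" else "ok"
  list(D = D, msd = df, quality = quality)
}

#' Lipid connectivity clusters
#'
#' Two lipids are connected when any of their tail beads are within
#' `cutoff`. Used for gas detection (membrane disintegration), cylinder
#' stability and budding analysis.
#'
#' @param sys a [particle_system()].
#' @param cutoff tail-tail connection distance (sigma).
#' @return list with `membership` (cluster id per lipid), `sizes`, and
#'   `largest_fraction` (largest cluster size / number of lipids).
#' @export
lipid_clusters <- function(sys, cutoff = 1.5) {
  w <- wrap_positions(sys)
  tails <- which(w$role == 2L)
  pr <- cpp_close_pairs(w$positions[tails, , drop = FALSE], w$box, cutoff)
  lp <- cbind(w$lipid[tails[pr[, 1]]], w$lipid[tails[pr[, 2]]])
  lp <- lp[lp[, 1] != lp[, 2], , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(as.character(lp), ncol = 2), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(n_lipids(sys))),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  memb <- comp$membership[as.character(seq_len(n_lipids(sys)))]
  list(membership = unname(memb), sizes = comp$csize,
       largest_fraction = max(comp$csize) / n_lipids(sys))
}

#' Classify the phase of a membrane state point
#'
#' Gas if the largest connected lipid cluster holds less than
#' `gas_threshold` of all lipids (membrane disintegrated); otherwise liquid
#' if the diffusion coefficient exceeds `D_star` (the discontinuity in D
#' marks the gel-liquid transition), else gel.
#'
#' @param D diffusion coefficient (sigma^2/tau).
#' @param largest_fraction largest-cluster fraction from [lipid_clusters()].
#' @param D_star liquid threshold (sigma^2/tau).
#' @param gas_threshold cluster fraction below which the point is gas.
#' @return "gel", "liquid" or "gas".
#' @export
classify_phase <- function(D, largest_fraction, D_star = 1e-3,
                           gas_threshold = 0.5) {
  if (largest_fraction < gas_threshold) return("gas")
  if (D > D_star) "liquid" else "gel"
}

#' Scan a phase diagram
#'
#' One simulation per grid point: build a flat membrane, equilibrate, sample
#' lipid centres of mass, then classify. Per-point failures (e.g. unstable
#' integration deep in the gas phase) are recorded and the scan continues.
#'
#' @param grid data.frame with columns among `T_eff`, `omega`, `k_bola`,
#'   `f_bi` (missing ones take defaults).
#' @param n_lipids lipids per point.
#' @param steps_equil,steps_sample step counts per phase.
#' @param sample_every sampling stride (steps).
#' @param seed base seed; point i uses seed + i.
#' @param ... further arguments to [integrator_params()].
#' @return data.frame: the grid plus `D` (per species where mixed),
#'   `largest_fraction`, `phase`, `seed`, `error`.
#' @export
scan_phase_diagram <- function(grid, n_lipids = 200, steps_equil = 40000,
                               steps_sample = 60000, sample_every = 2000,
                               seed = 1, ...) {
  defaults <- list(T_eff = 1.1, omega = 1.5, k_bola = 0, f_bi = 0)
  for (nm in names(defaults))
    if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  out <- grid
  out$D_bola <- NA_real_; out$D_bilayer <- NA_real_
  out$largest_fraction <- NA_real_; out$phase <- NA_character_
  out$seed <- seed + seq_len(nrow(grid)); out$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      ff <- forcefield_params(omega = grid$omega[i], k_bola = grid$k_bola[i])
      ip <- integrator_params(temperature = grid$T_eff[i], barostat = TRUE,
                              seed = out$seed[i], ...)
      sys <- build_flat(n_lipids, f_bi = grid$f_bi[i],
                        temperature = grid$T_eff[i], seed = out$seed[i])
      r1 <- md_run(sys, ff, ip, steps_equil)
      r2 <- md_run(r1$system, ff, ip, steps_sample, sample_every,
                   observers = list(com = observe_lipid_com()))
      cl <- lipid_clusters(r2$system)
      sp <- r2$system$lipid_species
      Db <- if (any(sp == "bola"))
        msd_diffusion(r2$samples$com, "bola", sp)$D else NA_real_
      Di <- if (any(sp == "bilayer"))
        msd_diffusion(r2$samples$com, "bilayer", sp)$D else NA_real_
      D <- max(Db, Di, na.rm = TRUE)
      list(Db = Db, Di = Di, lf = cl$largest_fraction,
           phase = classify_phase(D, cl$largest_fraction))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$D_bola[i] <- res$Db; out$D_bilayer[i] <- res$Di
      out$largest_fraction[i] <- res$lf; out$phase[i] <- res$phase
    }
  }
  out
}
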