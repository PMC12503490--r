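#' Integrator parameters
#'
#' Langevin dynamics (Gronbech-Jensen/Farago discretisation; exact
#' free-particle diffusion D = k_B T / (gamma m), reduces to velocity Verlet
#' when `gamma = 0`) with an optional Berendsen-style barostat that rescales
#' the box and coordinates in x-y toward zero lateral pressure, the
#' zero-tension ensemble used for all flat-membrane work. Randomness is a
#' counter-based stream keyed on (seed, absolute step, bead), so runs are
#' bitwise reproducible and restartable from any step.
#'
#' @param dt timestep (tau).
#' @param gamma Langevin friction (1/tau); 0 means NVE.
#' @param temperature thermostat k_B T (equals T_eff when eps_p = 1).
#' @param barostat logical; couple Lx, Ly to zero lateral pressure.
#' @param tau_p barostat coupling time (tau).
#' @param baro_every apply the barostat every this many steps.
#' @param baro_max_scale cap on the relative box rescale per application.
#' @param skin Verlet-list skin (sigma).
#' @param seed integer seed for the noise stream.
#' @return object of class `integrator_params`.
#' @export
integrator_params <- function(dt = 0.01, gamma = 1, temperature = 1,
                              barostat = FALSE, tau_p = 10, baro_every = 10L,
                              baro_max_scale = 5e-4, skin = 0.7, seed = 1L) {
  stopifnot(dt > 0, gamma >= 0, temperature > 0, tau_p > 0, baro_every >= 1,
            skin > 0)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 barostat = isTRUE(barostat), tau_p = tau_p,
                 baro_every = as.integer(baro_every),
                 baro_max_scale = baro_max_scale, skin = skin,
                 seed = as.numeric(seed)),
            class = "integrator_params")
}

#' Effective temperature of a run
#'
#' T_eff = k_B T / eps_p, the control parameter for membrane fluidity.
#' @param ip [integrator_params()].
#' @param ff [forcefield_params()].
#' @export
t_eff <- function(ip, ff) ip$temperature / ff$eps_p

#' Run molecular dynamics
#'
#' Integrates `n_steps` steps, optionally in chunks of `sample_every` steps
#' between which observers are evaluated on the current state. Per-chunk
#' time averages (potential energy, diagonal virial, per-axis kinetic
#' energy, box area) are collected in `$stats`. An observer failure is
#' caught and recorded without stopping the integration.
#'
#' When the barostat is on, `sample_every` should be a multiple of
#' `baro_every` so that chunked and uninterrupted runs follow identical
#' trajectories.
#'
#' @param sys a [particle_system()].
#' @param ff a [forcefield_params()].
#' @param ip an [integrator_params()].
#' @param n_steps number of steps (0 returns the state unchanged).
#' @param sample_every chunk length in steps; 0 = single chunk, no sampling.
#' @param observers named list of functions `f(sys)`; their return values
#'   are collected per sample in `$samples[[name]]`.
#' @return list with `system` (final state), `stats` (data.frame of
#'   per-chunk means), `samples` (list per observer).
#' @export
md_run <- function(sys, ff, ip, n_steps, sample_every = 0, observers = NULL) {
  stopifnot(inherits(sys, "particle_system"),
            inherits(ff, "forcefield_params"),
            inherits(ip, "integrator_params"), n_steps >= 0)
  if (n_steps == 0)
    return(list(system = sys, stats = NULL, samples = NULL))
  if (sample_every > 0 && ip$barostat && sample_every %% ip$baro_every != 0)
    warning("sample_every is not a multiple of baro_every; ",
            "chunked and uninterrupted runs will differ")
  chunk <- if (sample_every > 0) sample_every else n_steps
  ak <- .angle_strengths(sys, ff)
  ffl <- unclass(ff); ipl <- unclass(ip)
  samples <- if (is.null(observers)) NULL else
    setNames(vector("list", length(observers)), names(observers))
  stats <- list()
  done <- 0
  while (done < n_steps) {
    todo <- min(chunk, n_steps - done)
    out <- cpp_run(sys$positions, sys$velocities, sys$role, sys$mass,
                   sys$bonds, sys$angles, ak, sys$box, ffl, ipl,
                   as.integer(todo), sys$step)
    sys$positions <- out$positions
    sys$velocities <- out$velocities
    sys$box <- out$box
    sys$step <- out$step
    sys$time <- sys$time + todo * ip$dt
    done <- done + todo
    stats[[length(stats) + 1]] <- data.frame(
      time = sys$time, pe = out$mean_pe,
      wxx = out$mean_virial[1], wyy = out$mean_virial[2],
      wzz = out$mean_virial[3],
      kex = out$mean_kinetic[1], key = out$mean_kinetic[2],
      kez = out$mean_kinetic[3],
      area = out$mean_area)
    if (!is.null(observers) && sample_every > 0) {
      for (nm in names(observers)) {
        val <- tryCatch(observers[[nm]](sys), error = function(e) {
          warning("observer '", nm, "' failed: ", conditionMessage(e))
          NULL
        })
        samples[[nm]][[length(samples[[nm]]) + 1]] <- val
      }
    }
  }
  list(system = sys, stats = do.call(rbind, stats), samples = samples)
}

#' Advance a system by one step
#' @inheritParams md_run
#' @return the updated `particle_system`.
#' @export
md_step <- function(sys, ff, ip) md_run(sys, ff, ip, 1L)$system

#' Instantaneous lateral pressure
#'
#' Virial expression (Pxx + Pyy) / 2 with P_aa = (2 K_a + W_aa) / V. The
#' barostat drives the time average of this quantity to zero.
#'
#' @param sys a [particle_system()].
#' @param ff a [forcefield_params()].
#' @return lateral pressure (eps/sigma^3).
#' @export
lateral_pressure <- function(sys, ff) {
  e <- system_energy(sys, ff)
  V <- prod(sys$box)
  (2 * e$kinetic[1] + e$virial[1] + 2 * e$kinetic[2] + e$virial[2]) / (2 * V)
}

#' Axial (z) force transmitted through the box
#'
#' For a membrane tube periodic along z this is the contractile force
#' f = -P_zz Lx Ly, related to the bending rigidity by f = 2 pi kappa / R.
#' Accepts either a system (instantaneous) or an `md_run` stats table
#' (time-averaged).
#'
#' @param x a `particle_system` or the `stats` data.frame of [md_run()].
#' @param ff force field (needed for a system).
#' @param box box dimensions (needed for a stats table).
#' @return axial force (eps/sigma).
#' @export
axial_force <- function(x, ff = NULL, box = NULL) {
  if (inherits(x, "particle_system")) {
    e <- system_energy(x, ff)
    return(-(2 * e$kinetic[3] + e$virial[3]) / x$box[3])
  }
  stopifnot(is.data.frame(x), !is.null(box))
  -(2 * mean(x$kez) + mean(x$wzz)) / box[3]
}

#' Maxwell-Boltzmann velocities
#'
#' @param n number of beads.
#' @param temperature k_B T.
#' @param mass per-bead masses.
#' @return n x 3 matrix of velocities.
#' @keywords internal
maxwell_velocities <- function(n, temperature, mass = rep(1, n)) {
  matrix(rnorm(3 * n, 0, rep(sqrt(temperature / mass), 3)), n, 3)
}

#' Write / read a checkpoint
#'
#' The full state (positions, velocities, box, step counter) plus the
#' integrator parameters, sufficient to restart bit-exactly: the noise
#' stream is keyed on the absolute step counter, so a restarted run follows
#' the identical trajectory.
#'
#' @param sys a `particle_system`; `ip` its integrator parameters.
#' @param path file path.
#' @export
checkpoint_write <- function(sys, ip, path) {
  saveRDS(list(system = sys, ip = ip), path)
  invisible(path)
}

#' @rdname checkpoint_write
#' @return `checkpoint_read` returns `list(system, ip)`.
#' @export
checkpoint_read <- function(path) readRDS(path)

# run a function with a temporary RNG seed, restoring .Random.seed after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Monte-Carlo conformation flips for bolalipids
#'
#' Proposes reflections of one half of a randomly chosen bolalipid through
#' the plane that contains its junction bead and is perpendicular to the
#' membrane normal (`mode = "z"` for flat membranes, `"radial"` for tubes
#' with axis at `axis`). The reflection is an isometry that preserves every
#' bond length and the moved half's internal angles, and is its own
#' inverse; Metropolis acceptance on the energy change therefore samples
#' the canonical U/straight conformation equilibrium directly. This is the
#' package's equilibration route for conformation statistics: spontaneous
#' flips require a head bead to cross the hydrophobic core and are orders
#' of magnitude slower than every other relaxation in the system.
#'
#' @param sys a [particle_system()] containing bolalipids.
#' @param ff a [forcefield_params()].
#' @param kT temperature of the Metropolis acceptance.
#' @param n_attempts number of single-lipid proposals.
#' @param mode "z" (flat) or "radial" (cylinder).
#' @param axis for `"radial"`: c(x, y) of the tube axis (defaults to the
#'   box centre).
#' @param seed RNG seed for the proposal stream; the per-system counter in
#'   `sys$mc_counter` advances so repeated calls continue the stream.
#' @return the updated system, with attribute `accepted` (count).
#' @export
mc_flip <- function(sys, ff, kT, n_attempts, mode = c("z", "radial"),
                    axis = NULL, seed = 1) {
  mode <- match.arg(mode)
  bolas <- which(sys$lipid_species == "bola")
  if (!length(bolas)) return(structure(sys, accepted = 0L))
  beads <- .lipid_beads(sys)
  bb <- do.call(rbind, lapply(bolas, function(l) beads[[l]]))
  if (is.null(axis)) axis <- sys$box[1:2] / 2
  ctr <- sys$mc_counter %||% 0
  out <- cpp_mc_flip(sys$positions, sys$role, sys$mass, sys$bonds,
                     sys$angles, .angle_strengths(sys, ff), sys$box,
                     unclass(ff), matrix(as.integer(bb), ncol = 6), kT,
                     as.integer(n_attempts), as.numeric(seed), ctr,
                     if (mode == "z") 0L else 1L, axis)
  sys$positions <- out$positions
  sys$mc_counter <- out$counter
  structure(sys, accepted = out$accepted)
}

#' Langevin dynamics interleaved with conformation flips
#'
#' Runs cycles of [md_run()] chunks followed by [mc_flip()] sweeps; the
#' standard driver for any measurement that depends on the U/straight
#' conformation equilibrium (flat u_f, two-state scans, curved membranes).
#' Observers are evaluated once per cycle, after the flip sweep.
#'
#' @inheritParams md_run
#' @param cycle_steps MD steps per cycle.
#' @param n_cycles number of cycles.
#' @param flip_attempts flip proposals per cycle (default: 2 per bola).
#' @param mode,axis passed to [mc_flip()].
#' @return list(system, stats, samples, acceptance) as in [md_run()], with
#'   the mean flip acceptance rate.
#' @export
run_with_flips <- function(sys, ff, ip, n_cycles, cycle_steps = 500,
                           flip_attempts = NULL, observers = NULL,
                           mode = "z", axis = NULL) {
  if (is.null(flip_attempts))
    flip_attempts <- 2 * sum(sys$lipid_species == "bola")
  samples <- if (is.null(observers)) NULL else
    setNames(vector("list", length(observers)), names(observers))
  stats <- list(); acc <- 0
  for (cy in seq_len(n_cycles)) {
    r <- md_run(sys, ff, ip, cycle_steps)
    sys <- r$system
    sys <- mc_flip(sys, ff, ip$temperature, flip_attempts, mode = mode,
                   axis = axis, seed = ip$seed + 7919)
    acc <- acc + attr(sys, "accepted")
    stats[[cy]] <- r$stats
    if (!is.null(observers)) {
      for (nm in names(observers)) {
        val <- tryCatch(observers[[nm]](sys), error = function(e) NULL)
        samples[[nm]][[length(samples[[nm]]) + 1]] <- val
      }
    }
  }
  list(system = sys, stats = do.call(rbind, stats), samples = samples,
       acceptance = acc / max(1, n_cycles * flip_attempts))
}
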