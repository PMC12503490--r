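# Membrane mechanics: height-field extraction, fluctuation spectra and the
# tilt-corrected Helfrich fit, tube (cylinder) rigidity, edge line tension,
# Gaussian-modulus estimation from patch-closure ensembles, the two-state
# conformation fit, and the closed-form fission barrier.

#' Height field of a flat membrane frame
#'
#' Grid-averaged head-bead height relative to the mean plane. Empty cells
#' are filled by iterative neighbour averaging (periodic); frames with more
#' than 10 percent empty cells are flagged (possible pore or rupture) via
#' the `flagged` attribute. The returned field has zero mean.
#'
#' @param frame a sample from [observe_heads()] (list with `heads`, `box`)
#'   or a [particle_system()].
#' @param n_grid grid cells per side (default: nearest power of two to
#'   L / 1.5).
#' @return n_grid x n_grid matrix of heights, with attributes `L`,
#'   `empty_fraction`, `flagged`.
#' @export
height_field <- function(frame, n_grid = NULL) {
  if (inherits(frame, "particle_system")) {
    w <- wrap_positions(frame)
    frame <- list(heads = w$positions[w$role == 1L, , drop = FALSE],
                  box = w$box)
  }
  L <- frame$box[1]
  if (is.null(n_grid)) n_grid <- 2^max(2, round(log2(L / 1.5)))
  hx <- frame$heads[, 1] %% L
  hy <- frame$heads[, 2] %% frame$box[2]
  ix <- pmin(n_grid, pmax(1, ceiling(hx / L * n_grid)))
  iy <- pmin(n_grid, pmax(1, ceiling(hy / frame$box[2] * n_grid)))
  h <- matrix(NA_real_, n_grid, n_grid)
  cnt <- matrix(0L, n_grid, n_grid)
  zsum <- matrix(0, n_grid, n_grid)
  for (k in seq_along(ix)) {
    zsum[ix[k], iy[k]] <- zsum[ix[k], iy[k]] + frame$heads[k, 3]
    cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1L
  }
  h[cnt > 0] <- zsum[cnt > 0] / cnt[cnt > 0]
  empty <- mean(cnt == 0)
  # periodic neighbour fill for empty cells
  it <- 0
  while (anyNA(h) && it < 100) {
    it <- it + 1
    up <- h[c(n_grid, seq_len(n_grid - 1)), ]
    dn <- h[c(seq_len(n_grid - 1) + 1, 1), ]
    lf <- h[, c(n_grid, seq_len(n_grid - 1))]
    rt <- h[, c(seq_len(n_grid - 1) + 1, 1)]
    nb <- array(c(up, dn, lf, rt), c(n_grid, n_grid, 4))
    fill <- apply(nb, c(1, 2), mean, na.rm = TRUE)
    h[is.na(h)] <- fill[is.na(h)]
    h[is.nan(h)] <- NA_real_
  }
  if (anyNA(h)) h[is.na(h)] <- mean(h, na.rm = TRUE)
  h <- h - mean(h)
  attr(h, "L") <- L
  attr(h, "empty_fraction") <- empty
  attr(h, "flagged") <- empty > 0.10
  h
}

#' Height-fluctuation spectrum of a flat membrane
#'
#' Averages |h_q|^2 over frames, where h_q is the discrete Fourier transform
#' of the height field normalised such that <|h_q|^2> matches the continuum
#' convention S(q) = kT/L^2 (1/(kappa q^4) + 1/(kappa_theta q^2)) at
#' vanishing tension. Modes are binned radially in q = 2 pi sqrt(m^2+n^2)/L.
#' Frames flagged by [height_field()] (pores/rupture) are excluded.
#'
#' @param frames list of samples from [observe_heads()].
#' @param n_grid grid resolution per side (see [height_field()]).
#' @return data.frame with columns `q`, `S`, `n_modes`; attributes `L`
#'   (mean box side), `n_frames` (used), `n_flagged`.
#' @export
membrane_spectrum <- function(frames, n_grid = NULL) {
  stopifnot(length(frames) >= 1)
  Ls <- vapply(frames, function(f) f$box[1], 0)
  L <- mean(Ls)
  acc <- NULL; used <- 0; flagged <- 0
  for (f in frames) {
    h <- height_field(f, n_grid)
    if (attr(h, "flagged")) { flagged <- flagged + 1; next }
    n <- nrow(h)
    hq <- fft(h) / n^2
    p <- Mod(hq)^2
    acc <- if (is.null(acc)) p else acc + p
    used <- used + 1
  }
  if (used == 0) stop("all frames flagged (pores/rupture); no spectrum")
  p <- acc / used
  n <- nrow(p)
  m <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  qx <- outer(2 * pi * m / L, rep(1, n))
  qy <- t(qx)
  q <- sqrt(qx^2 + qy^2)
  sel <- q > 1e-9
  qb <- round(q[sel], 6)
  df <- data.frame(q = as.numeric(names(tapply(p[sel], qb, mean))) * 0 +
                     sort(unique(qb)),
                   S = as.numeric(tapply(p[sel], qb, mean)[as.character(sort(unique(qb)))]),
                   n_modes = as.integer(table(qb)[as.character(sort(unique(qb)))]))
  attr(df, "L") <- L
  attr(df, "n_frames") <- used
  attr(df, "n_flagged") <- flagged
  df
}

#' Continuum model for the height spectrum
#'
#' S(q) = kT / L^2 * (1 / (kappa q^4) + 1 / (kappa_theta q^2)) with
#' kappa_theta = kappa / l_theta^2; the second term is the lipid-tilt
#' contribution, negligible when l_theta is below the analysed wavelengths.
#'
#' @param q wave numbers (1/sigma).
#' @param kappa bending rigidity (k_B T).
#' @param l_theta tilt persistence length (sigma); 0 gives the pure
#'   Helfrich spectrum.
#' @param L box side (sigma).
#' @param kT thermal energy.
#' @export
spectrum_model <- function(q, kappa, l_theta, L, kT = 1) {
  kT / L^2 * (1 + q^2 * l_theta^2) / (kappa * q^4)
}

#' Fit the tilt-corrected Helfrich spectrum
#'
#' Least squares in log S over modes with q < `q_max` (default 2 pi / 12,
#' i.e. wavelengths at least twice the membrane thickness). Returns the
#' bending rigidity kappa, the tilt modulus kappa_theta, the tilt
#' persistence length l_theta = sqrt(kappa/kappa_theta), and, for
#' comparison, the kappa of a pure Helfrich (1/q^4) fit, which is biased
#' downward when l_theta is large (the neglected tilt power is absorbed
#' into the amplitude). If the tilt fit fails to converge the
#' Helfrich-only result is returned with `converged = FALSE`.
#'
#' @param spec data.frame from [membrane_spectrum()] (columns q, S), or any
#'   data.frame with those columns.
#' @param L box side (sigma); defaults to the spectrum attribute.
#' @param kT thermal energy (k_B T of the run).
#' @param q_max fit cutoff (1/sigma).
#' @param floor also fit an additive q-independent power `C`: the
#'   incoherent protrusion noise of the discretised head field, which
#'   dominates measured spectra beyond q of about 0.5/sigma. Needed when
#'   small boxes force the fit range above the standard cutoff; at the
#'   standard cutoff it is negligible and off by default.
#' @return object of class `spectrum_fit`.
#' @export
fit_spectrum <- function(spec, L = attr(spec, "L"), kT = 1,
                         q_max = 2 * pi / 12, floor = FALSE) {
  stopifnot(!is.null(L), all(spec$S > 0))
  d <- spec[spec$q < q_max, ]
  need <- if (floor) 5 else 4
  if (nrow(d) < need)
    stop("need at least ", need, " q-bins below q_max = ", signif(q_max, 3),
         " (have ", nrow(d), "); use a larger box or raise q_max")
  # pure Helfrich closed form: log S = log(kT/(L^2 kappa)) - 4 log q
  log_kh <- mean(log(kT / L^2) - 4 * log(d$q) - log(d$S))
  kappa_h <- exp(log_kh)
  model <- function(p) {
    spectrum_model(d$q, exp(p[1]), exp(p[2]), L, kT) +
      if (floor) exp(p[3]) else 0
  }
  obj <- function(p) sum((log(d$S) - log(model(p)))^2)
  start <- c(log(kappa_h), log(1))
  if (floor) start <- c(start, log(min(d$S) / 2))
  fit <- tryCatch(
    optim(start, obj, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    out <- list(kappa = kappa_h, kappa_theta = Inf, l_theta = 0,
                noise_floor = 0, kappa_helfrich = kappa_h, converged = FALSE)
  } else {
    kappa <- exp(fit$par[1]); l_theta <- exp(fit$par[2])
    out <- list(kappa = kappa, kappa_theta = kappa / l_theta^2,
                l_theta = l_theta,
                noise_floor = if (floor) exp(fit$par[3]) else 0,
                kappa_helfrich = kappa_h, converged = TRUE)
  }
  pred <- spectrum_model(d$q, out$kappa, out$l_theta, L, kT) + out$noise_floor
  ss_res <- sum((log(d$S) - log(pred))^2)
  ss_tot <- sum((log(d$S) - mean(log(d$S)))^2)
  out$r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out$q_max <- q_max; out$n_modes <- nrow(d); out$L <- L; out$kT <- kT
  out$data <- d
  class(out) <- "spectrum_fit"
  out
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat("Tilt-corrected Helfrich spectrum fit\n")
  cat(sprintf("  kappa       = %.3g k_BT\n", x$kappa))
  cat(sprintf("  kappa_theta = %.3g k_BT/sigma^2\n", x$kappa_theta))
  cat(sprintf("  l_theta     = %.3g sigma\n", x$l_theta))
  cat(sprintf("  Helfrich-only kappa = %.3g k_BT\n", x$kappa_helfrich))
  cat(sprintf("  %d modes with q < %.3g; R^2(log) = %.3f%s\n", x$n_modes,
              x$q_max, x$r_squared,
              if (x$converged) "" else "  [tilt fit did not converge]"))
  invisible(x)
}

#' @export
coef.spectrum_fit <- function(object, ...) {
  c(kappa = object$kappa, kappa_theta = object$kappa_theta,
    l_theta = object$l_theta, kappa_helfrich = object$kappa_helfrich)
}

#' Tilt persistence length
#'
#' l_theta = sqrt(kappa / kappa_theta): the length below which tilt, rather
#' than bending, carries membrane shape fluctuations.
#'
#' @param kappa bending rigidity (k_B T), > 0.
#' @param kappa_theta tilt modulus (k_B T / length^2), > 0; lengths come out
#'   in whatever unit kappa_theta uses.
#' @export
tilt_persistence_length <- function(kappa, kappa_theta) {
  if (any(kappa <= 0) || any(kappa_theta <= 0))
    stop("kappa and kappa_theta must be positive")
  sqrt(kappa / kappa_theta)
}

#' Bending rigidity of a membrane tube
#'
#' A cylinder periodic along z exerts a contractile axial force
#' f = 2 pi kappa / R, so kappa = f R / (2 pi). The force is measured from
#' the time-averaged axial virial (see [axial_force()]), the radius from the
#' mean in-plane distance of tail beads to the tube axis. The estimate is
#' flagged unstable when the membrane has broken up (largest lipid cluster
#' below `stable_fraction`).
#'
#' @param run result of [md_run()] on a cylinder (fixed box, no barostat).
#' @param stable_fraction cluster-fraction threshold for stability.
#' @return list of class `cylinder_rigidity`: `kappa` (k_BT, NA when
#'   unstable), `R`, `H` = 1/(2R), `f_axial`, `stable`.
#' @export
cylinder_rigidity <- function(run, stable_fraction = 0.9) {
  sys <- run$system
  f <- axial_force(run$stats, box = sys$box)
  w <- wrap_positions(sys)
  tails <- w$positions[w$role == 2L, 1:2, drop = FALSE]
  ctr <- colMeans(tails)
  R <- mean(sqrt((tails[, 1] - ctr[1])^2 + (tails[, 2] - ctr[2])^2))
  cl <- lipid_clusters(sys)
  stable <- cl$largest_fraction >= stable_fraction
  structure(list(kappa = if (stable) f * R / (2 * pi) else NA_real_,
                 R = R, H = 1 / (2 * R), f_axial = f,
                 stable = stable,
                 largest_fraction = cl$largest_fraction),
            class = "cylinder_rigidity")
}

#' @export
print.cylinder_rigidity <- function(x, ...) {
  cat(sprintf("Membrane tube: R = %.2f sigma (H = %.3f/sigma), f = %.3f eps/sigma\n",
              x$R, x$H, x$f_axial))
  if (x$stable) cat(sprintf("  kappa = %.2f k_BT\n", x$kappa))
  else cat(sprintf("  ruptured (largest cluster %.0f%%); kappa undefined\n",
                   100 * x$largest_fraction))
  invisible(x)
}

#' Edge line tension of a membrane ribbon
#'
#' A flat ribbon periodic along one axis with two free edges parallel to it
#' pulls the box together along that axis with force 2 lambda (the membrane
#' itself is tension-free because the free edges let its width relax), so
#' lambda = -P_aa V / (2 L_a).
#'
#' @param stats `stats` table from [md_run()].
#' @param box box dimensions.
#' @param axis periodic axis along the edges (1 = x).
#' @return line tension lambda (eps/sigma).
#' @export
line_tension <- function(stats, box, axis = 1) {
  ke <- c(mean(stats$kex), mean(stats$key), mean(stats$kez))[axis]
  wv <- c(mean(stats$wxx), mean(stats$wyy), mean(stats$wzz))[axis]
  -(2 * ke + wv) / (2 * box[axis])
}

#' Detect closure of a membrane patch
#'
#' A patch has closed into a vesicle when its surface encloses volume that a
#' probe cannot reach from outside: the occupancy grid (bead cores inflated
#' by the probe radius) is flood-filled from the box corner and any
#' unreachable free volume above `min_volume` counts as enclosed.
#'
#' @param sys a [particle_system()] (patch in a large box).
#' @param ff force field (core diameters).
#' @param cell occupancy grid cell (sigma).
#' @param probe probe radius (sigma).
#' @param min_volume enclosed-volume threshold (sigma^3).
#' @return list with `closed`, `enclosed_volume`.
#' @export
detect_closure <- function(sys, ff, cell = 0.5, probe = 0.5, min_volume = 5) {
  w <- wrap_positions(sys)
  radii <- ifelse(w$role == 1L, ff$b_head / 2,
                  ifelse(w$role == 2L, ff$b_tail / 2, ff$r_cargo)) + probe
  nx <- max(3, ceiling(sys$box[1] / cell))
  ny <- max(3, ceiling(sys$box[2] / cell))
  nz <- max(3, ceiling(sys$box[3] / cell))
  occ <- cpp_occupancy(w$positions, radii, sys$box, nx, ny, nz,
                       rep(FALSE, 3))
  lab <- cpp_free_components(occ, nx, ny, nz, rep(FALSE, 3))
  outside <- lab[1]
  if (outside == 0) stop("corner cell blocked; enlarge the box")
  enc <- sum(lab != 0 & lab != outside) * prod(sys$box / c(nx, ny, nz))
  list(closed = enc >= min_volume, enclosed_volume = enc)
}

#' Run a patch-closure ensemble
#'
#' For each patch size, `replicates` independent simulations from a flat
#' disc; closure is scored with [detect_closure()] on the final state.
#'
#' @param sizes lipid counts of the patches.
#' @param replicates runs per size.
#' @param f_bi bilayer fraction of the patches (1 = pure bilayer).
#' @param ff force field.
#' @param temperature k_B T.
#' @param n_steps steps per run.
#' @param seed base seed.
#' @param ... passed to [integrator_params()].
#' @return data.frame size, r_disc, replicate, closed, enclosed_volume.
#' @export
patch_closure_scan <- function(sizes, replicates = 3, f_bi = 1,
                               ff = forcefield_params(), temperature = 1.2,
                               n_steps = 150000, seed = 1, ...) {
  out <- list()
  k <- 0
  for (sz in sizes) for (rep in seq_len(replicates)) {
    k <- k + 1
    sd <- seed + 1000 * k
    sys <- build_patch(sz, f_bi = f_bi, temperature = temperature, seed = sd)
    ip <- integrator_params(temperature = temperature, barostat = FALSE,
                            seed = sd, ...)
    res <- tryCatch({
      r <- md_run(sys, ff, ip, n_steps)
      cl <- detect_closure(r$system, ff)
      data.frame(size = sz, r_disc = attr(sys, "r_disc"), replicate = rep,
                 closed = cl$closed, enclosed_volume = cl$enclosed_volume,
                 seed = sd)
    }, error = function(e)
      data.frame(size = sz, r_disc = attr(sys, "r_disc"), replicate = rep,
                 closed = NA, enclosed_volume = NA_real_, seed = sd))
    out[[k]] <- res
  }
  do.call(rbind, out)
}

#' Gaussian bending modulus from patch closure
#'
#' Energy balance at the critical disc radius r* where closing becomes
#' favourable: a flat disc of radius r costs edge energy 2 pi r lambda,
#' the closed sphere of equal area costs 8 pi kappa + 4 pi kappa_bar, so
#' kappa_bar = lambda r*/2 - 2 kappa. r* is taken from a logistic fit of
#' the closure probability against disc radius; the uncertainty is a
#' bootstrap over the ensemble.
#'
#' @param closure data.frame from [patch_closure_scan()].
#' @param kappa bending rigidity (k_B T), e.g. from [fit_spectrum()].
#' @param lambda edge line tension (eps/sigma), from [line_tension()].
#' @param n_boot bootstrap resamples.
#' @return object of class `gaussian_modulus_estimate` with `kappa_bar`,
#'   `ratio` = -kappa_bar/kappa, standard errors, `r_star`, and an
#'   `inconclusive` flag when closure never/always happened.
#' @export
gaussian_modulus <- function(closure, kappa, lambda, n_boot = 200) {
  d <- closure[!is.na(closure$closed), ]
  est1 <- function(dd) {
    if (all(dd$closed) || all(!dd$closed)) return(NA_real_)
    fit <- suppressWarnings(
      stats::glm(closed ~ r_disc, family = stats::binomial(), data = dd))
    unname(-coef(fit)[1] / coef(fit)[2])
  }
  r_star <- est1(d)
  inconclusive <- is.na(r_star) || r_star < 0
  kbar <- if (inconclusive) NA_real_ else lambda * r_star / 2 - 2 * kappa
  boots <- rep(NA_real_, 0)
  if (!inconclusive && n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      rs <- est1(d[sample(nrow(d), replace = TRUE), ])
      if (is.na(rs) || rs < 0) NA_real_ else lambda * rs / 2 - 2 * kappa
    }, numeric(1))
  }
  structure(list(kappa_bar = kbar,
                 se = sd(boots, na.rm = TRUE),
                 ratio = if (is.na(kbar)) NA_real_ else -kbar / kappa,
                 ratio_se = sd(-boots / kappa, na.rm = TRUE),
                 r_star = unname(r_star), kappa = kappa, lambda = lambda,
                 inconclusive = inconclusive, closure = d),
            class = "gaussian_modulus_estimate")
}

#' @export
print.gaussian_modulus_estimate <- function(x, ...) {
  if (x$inconclusive) {
    cat("Gaussian modulus: inconclusive (no closure crossing in ensemble)\n")
  } else {
    cat(sprintf("Gaussian modulus: kappa_bar = %.2f +/- %.2f k_BT\n",
                x$kappa_bar, x$se))
    cat(sprintf("  -kappa_bar/kappa = %.2f +/- %.2f (kappa = %.2f, lambda = %.2f)\n",
                x$ratio, x$ratio_se, x$kappa, x$lambda))
    cat(sprintf("  critical disc radius r* = %.2f sigma\n", x$r_star))
  }
  invisible(x)
}

#' Two-state fit of the U-shape fraction
#'
#' Models bolalipid conformations as a two-state system: the straight state
#' has zero energy and the U state E_u = c0 + c1 k_bola, giving
#' u_f(k_bola) = 1 / (1 + exp(beta (c0 + c1 k_bola))) with beta = 1/(k_B T).
#' Fitted by nonlinear least squares; c0 < 0 means the U shape is favoured
#' for fully flexible molecules.
#'
#' @param k_bola hinge strengths (k_B T), at least 3 values.
#' @param u_f measured U-shape fractions in (0, 1).
#' @param kT thermal energy (sets beta).
#' @return object of class `two_state_fit` with `c0`, `c1`, `beta`,
#'   `r_squared`, `degenerate`.
#' @export
two_state_fit <- function(k_bola, u_f, kT = 1) {
  stopifnot(length(k_bola) == length(u_f), length(k_bola) >= 3)
  beta <- 1 / kT
  degenerate <- all(u_f <= 0) || all(u_f >= 1) || sd(u_f) < 1e-12
  if (degenerate) {
    warning("degenerate conformation data (all 0 or all 1); fit flagged")
    out <- list(c0 = NA_real_, c1 = NA_real_, beta = beta,
                r_squared = NA_real_, degenerate = TRUE,
                data = data.frame(k_bola = k_bola, u_f = u_f))
    class(out) <- "two_state_fit"
    return(out)
  }
  uc <- pmin(1 - 1e-9, pmax(1e-9, u_f))
  start <- coef(lm(I(log(1 / uc - 1) / beta) ~ k_bola))
  # the logit-linear start is already exact for noise-free data, where nls
  # then reports a singular gradient; suppress that cosmetic warning (fit
  # quality is carried by r_squared)
  fit <- suppressWarnings(
    nls(u_f ~ 1 / (1 + exp(beta * (c0 + c1 * k_bola))),
        start = list(c0 = unname(start[1]), c1 = unname(start[2])),
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE)))
  cf <- coef(fit)
  res <- u_f - predict(fit)
  r2 <- 1 - sum(res^2) / max(sum((u_f - mean(u_f))^2), 1e-300)
  out <- list(c0 = unname(cf["c0"]), c1 = unname(cf["c1"]), beta = beta,
              r_squared = r2, degenerate = FALSE, fit = fit,
              data = data.frame(k_bola = k_bola, u_f = u_f))
  class(out) <- "two_state_fit"
  out
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (x$degenerate) { cat("Two-state fit: degenerate data\n"); return(invisible(x)) }
  cat(sprintf("Two-state fit: E_u = %.3g %+.3g k_bola (beta = %.3g); R^2 = %.4f\n",
              x$c0, x$c1, x$beta, x$r_squared))
  cat(sprintf("  u_f(0) = %.3f%s\n", predict(x, 0),
              if (x$c0 < 0) "  (U shape favoured at k_bola = 0)" else ""))
  invisible(x)
}

#' @export
coef.two_state_fit <- function(object, ...) c(c0 = object$c0, c1 = object$c1)

#' @export
predict.two_state_fit <- function(object, newdata = NULL, ...) {
  k <- if (is.null(newdata)) object$data$k_bola
       else if (is.data.frame(newdata)) newdata$k_bola else newdata
  1 / (1 + exp(object$beta * (object$c0 + object$c1 * k)))
}

#' Fission energy barrier
#'
#' Splitting one vesicle into two raises the bending energy by 8 pi kappa
#' and lowers the Gaussian-curvature energy by 4 pi |kappa_bar|, giving
#' Delta E = 4 pi kappa (2 - |kappa_bar| / kappa).
#'
#' @param kappa bending rigidity (k_B T), > 0.
#' @param kappa_bar Gaussian modulus (k_B T; sign ignored).
#' @return barrier height (k_B T).
#' @export
fission_barrier <- function(kappa, kappa_bar) {
  stopifnot(all(kappa > 0))
  4 * pi * kappa * (2 - abs(kappa_bar) / kappa)
}
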