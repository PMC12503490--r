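# Interaction potentials: closed-form values, smoothness, force/energy
# consistency, and exact force evaluation at the system level.

ff <- forcefield_params()
rc_tt <- 2^(1/6) * ff$b_tail

test_that("tail-tail attraction has the constructed depth and range", {
  expect_equal(pair_potential(rc_tt, "tail", "tail", ff)$energy, -ff$eps_p)
  # halfway through the cos^2 taper the well is at half depth
  expect_equal(pair_potential(rc_tt + ff$omega / 2, "tail", "tail", ff)$energy,
               -ff$eps_p * cos(pi / 4)^2)
  expect_equal(pair_potential(rc_tt + ff$omega / 2, "tail", "tail", ff)$energy,
               -ff$eps_p / 2)
  beyond <- pair_potential(c(rc_tt + ff$omega, 4), "tail", "tail", ff)
  expect_equal(beyond$energy, c(0, 0))
  expect_equal(beyond$force, c(0, 0))
})

test_that("head pairs are purely repulsive and symmetric", {
  r <- seq(0.7, 3, by = 0.01)
  for (pair in list(c("head", "head"), c("head", "tail"))) {
    e <- pair_potential(r, pair[1], pair[2], ff)
    expect_true(all(e$energy >= 0))
    e2 <- pair_potential(r, pair[2], pair[1], ff)
    expect_identical(e, e2)
  }
  expect_identical(pair_potential(r, "tail", "tail", ff),
                   pair_potential(r, "tail", "tail", ff))
  expect_error(pair_potential(0, "tail", "tail", ff), "overlap")
})

test_that("all pair classes are C1: force matches -dE/dr on a fine grid", {
  h <- 1e-6
  cases <- list(list("tail", "tail", seq(0.85, rc_tt + ff$omega + 0.2, by = 0.004)),
                list("head", "head", seq(0.7, 1.3, by = 0.004)),
                list("head", "cargo", seq(ff$r_cargo + 0.2, ff$r_cargo + 3,
                                          by = 0.004)))
  ffa <- forcefield_params(eps_mc = 2)
  for (cs in cases) {
    ep <- pair_potential(cs[[3]] + h, cs[[1]], cs[[2]], ffa)$energy
    em <- pair_potential(cs[[3]] - h, cs[[1]], cs[[2]], ffa)$energy
    f <- pair_potential(cs[[3]], cs[[1]], cs[[2]], ffa)$force
    expect_lt(max(abs(f + (ep - em) / (2 * h))), 1e-5)
  }
})

test_that("FENE bond diverges at rmax and repels at short range", {
  expect_gt(bond_potential(0.05, ff)$energy, 1e10)    # WCA core dominates
  near <- bond_potential(ff$fene_rmax * (1 - 1e-6), ff)$energy
  nearer <- bond_potential(ff$fene_rmax * (1 - 1e-9), ff)$energy
  expect_gt(near, 400)          # ~ -0.5 k rmax^2 log(2e-6)
  expect_gt(nearer, near)       # monotone divergence
  expect_error(bond_potential(ff$fene_rmax, ff), "broken")
  # force/energy consistency at r = 1 sigma
  h <- 1e-6
  fd <- -(bond_potential(1 + h, ff)$energy - bond_potential(1 - h, ff)$energy) / (2 * h)
  expect_equal(bond_potential(1, ff)$force, fd, tolerance = 1e-6)
})

test_that("angle potential: minimum at pi, k scaling, flexible limit", {
  expect_equal(angle_potential(pi, 5)$energy, 0)
  expect_equal(angle_potential(pi / 2, 3)$energy, 3)     # k(1 + cos(pi/2)) = k
  th <- seq(0, pi, length.out = 50)
  expect_true(all(angle_potential(th, 0)$energy == 0))   # fully flexible
  # even about the minimum: E(pi - d) == E(pi + ...) via cos symmetry
  expect_equal(angle_potential(pi - 0.3, 2)$energy,
               2 * (1 + cos(pi - 0.3)))
})

test_that("cargo adhesion acts on heads only, with depth eps_mc at contact", {
  ffc <- forcefield_params(eps_mc = 3, r_cargo = 5)
  contact <- (ffc$r_cargo - ffc$b_head / 2) + 2^(1/6) * ffc$b_head
  expect_equal(cargo_potential(contact, "head", ffc)$energy, -3)
  r <- seq(ffc$r_cargo + 0.3, ffc$r_cargo + 4, by = 0.05)
  expect_true(all(cargo_potential(r, "tail", ffc)$energy >= 0))
  ff0 <- forcefield_params(eps_mc = 0, r_cargo = 5)
  expect_true(all(cargo_potential(r, "head", ff0)$energy >= 0))
})

test_that("system forces are the exact negative energy gradient", {
  sys <- build_gas(12, f_bi = 0.5, box = c(12, 12, 12), seed = 3,
                   temperature = 1)
  ffk <- forcefield_params(k_bola = 1.5)
  e0 <- system_energy(sys, ffk)
  h <- 2e-6
  idx <- cbind(sample(nrow(sys$positions), 20, replace = TRUE),
               sample(3, 20, replace = TRUE))
  for (k in seq_len(nrow(idx))) {
    sp <- sys; sp$positions[idx[k, 1], idx[k, 2]] <- sp$positions[idx[k, 1], idx[k, 2]] + h
    sm <- sys; sm$positions[idx[k, 1], idx[k, 2]] <- sm$positions[idx[k, 1], idx[k, 2]] - h
    fd <- -(system_energy(sp, ffk)$energy - system_energy(sm, ffk)$energy) / (2 * h)
    expect_equal(e0$forces[idx[k, 1], idx[k, 2]], fd, tolerance = 2e-4)
  }
})

test_that("forces obey Newton's third law (zero net force)", {
  sys <- build_gas(15, f_bi = 0.3, box = c(10, 10, 10), seed = 8,
                   temperature = 1)
  f <- system_energy(sys, forcefield_params(k_bola = 2))$forces
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("isolated beads beyond cutoff: zero energy, zero forces", {
  sys <- make_bola_system(list(straight_bola(c(5, 5, 5)),
                               straight_bola(c(25, 25, 25))),
                          box = c(40, 40, 40))
  e <- system_energy(sys, ff)
  # only intramolecular terms remain; the two molecules do not interact:
  # doubling one molecule's energy equals the pair's total
  one <- make_bola_system(list(straight_bola(c(5, 5, 5))), box = c(40, 40, 40))
  expect_equal(e$energy, 2 * system_energy(one, ff)$energy)
})

test_that("a flexible hinge contributes exactly zero energy", {
  bent <- make_bola_system(list(right_angle_bola(c(10, 10, 10))))
  straight <- make_bola_system(list(straight_bola(c(10, 10, 10))))
  ff0 <- forcefield_params(k_bola = 0)
  ff5 <- forcefield_params(k_bola = 5)
  # same configuration: raising k_bola adds exactly the two hinge terms
  th <- head_to_head_angle(bent) # sanity: it is bent
  expect_lt(th, pi)
  e0 <- system_energy(bent, ff0)$energy
  e5 <- system_energy(bent, ff5)$energy
  ang <- function(p, i, j, k) {
    v1 <- p[i, ] - p[j, ]; v2 <- p[k, ] - p[j, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  }
  p <- bent$positions
  expected <- 5 * (1 + cos(ang(p, 2, 3, 4))) + 5 * (1 + cos(ang(p, 3, 4, 5)))
  expect_equal(e5 - e0, expected, tolerance = 1e-8)
  # straight molecule: hinge energy zero at any k
  expect_equal(system_energy(straight, ff5)$energy,
               system_energy(straight, ff0)$energy)
})

test_that("neighbour-list forces agree with a brute-force reference", {
  sys <- build_gas(10, f_bi = 0, box = c(9, 9, 9), seed = 4, temperature = 1)
  ffk <- forcefield_params(k_bola = 1)
  got <- system_energy(sys, ffk)
  # independent all-pairs reference in R (analytic formulas, no cell list)
  w <- wrap_positions(sys)
  n <- nrow(w$positions)
  eref <- 0
  # exclusions: pairs within excl_bonds bonds along a chain; beads of a
  # molecule are consecutive, so chain distance = index gap
  excluded <- function(i, j)
    sys$lipid[i] == sys$lipid[j] && abs(i - j) <= ffk$excl_bonds
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (excluded(i, j)) next
    d <- w$positions[i, ] - w$positions[j, ]
    d <- d - sys$box * round(d / sys$box)
    r <- sqrt(sum(d^2))
    tt <- sys$role[i] == 2 && sys$role[j] == 2
    b <- if (tt) 1 else 0.95
    if (r < 2^(1/6) * b) eref <- eref + 4 * ((b / r)^12 - (b / r)^6) + 1
    if (tt) {
      rc <- 2^(1/6)
      if (r < rc) eref <- eref - 1
      else if (r < rc + 1.5) eref <- eref - cos(pi * (r - rc) / 3)^2
    }
  }
  for (k in seq_len(nrow(sys$bonds))) {
    d <- w$positions[sys$bonds[k, 1], ] - w$positions[sys$bonds[k, 2], ]
    d <- d - sys$box * round(d / sys$box)
    r <- sqrt(sum(d^2))
    tt <- all(sys$role[sys$bonds[k, ]] == 2)
    b <- if (tt) 1 else 0.95
    eref <- eref - 0.5 * 30 * 1.5^2 * log(1 - (r / 1.5)^2)
    if (r < 2^(1/6) * b) eref <- eref + 4 * ((b / r)^12 - (b / r)^6) + 1
  }
  for (k in seq_len(nrow(sys$angles))) {
    a <- sys$angles[k, ]
    v1 <- w$positions[a[1], ] - w$positions[a[2], ]
    v2 <- w$positions[a[3], ] - w$positions[a[2], ]
    v1 <- v1 - sys$box * round(v1 / sys$box)
    v2 <- v2 - sys$box * round(v2 / sys$box)
    ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    kk <- if (sys$angle_type[k] == 1) ffk$k0 else ffk$k_bola
    eref <- eref + kk * (1 + ct)
  }
  expect_equal(got$energy, eref, tolerance = 1e-6)
})
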