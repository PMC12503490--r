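# Initial-configuration builders: determinism, overlap freedom, geometry
# contracts.

test_that("builders are deterministic under a fixed seed", {
  a <- build_flat(50, f_bi = 0.3, temperature = 1.1, seed = 12)
  b <- build_flat(50, f_bi = 0.3, temperature = 1.1, seed = 12)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  expect_identical(a$lipid_species, b$lipid_species)
  c <- build_flat(50, f_bi = 0.3, temperature = 1.1, seed = 13)
  expect_false(identical(a$positions, c$positions))
  g1 <- build_gas(10, box = c(15, 15, 15), seed = 4, temperature = 1)
  g2 <- build_gas(10, box = c(15, 15, 15), seed = 4, temperature = 1)
  expect_identical(g1$positions, g2$positions)
})

test_that("builders do not perturb the caller's RNG stream", {
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(build_flat(10, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("gas builder: single lipid and overlap-free packing", {
  one <- build_gas(1, box = c(10, 10, 10), seed = 1, temperature = 1)
  expect_equal(n_lipids(one), 1)
  sys <- build_gas(25, f_bi = 0.4, box = c(18, 18, 18), seed = 2,
                   temperature = 1)
  w <- wrap_positions(sys)
  pr <- bolasim:::cpp_close_pairs(w$positions, sys$box, 0.9)
  # any close pair must be intra-lipid (bonded chain), never inter-lipid
  if (nrow(pr))
    expect_true(all(sys$lipid[pr[, 1]] == sys$lipid[pr[, 2]]))
  expect_error(build_gas(500, box = c(8, 8, 8), seed = 1, max_tries = 20),
               "overlap")
})

test_that("flat builder honours composition and orientation", {
  pure_bi <- build_flat(60, f_bi = 1, temperature = 1, seed = 3)
  expect_true(all(pure_bi$lipid_species == "bilayer"))
  # heads outward in both leaflets: every lipid's head is farther from the
  # midplane than its tails
  mid <- mean(pure_bi$positions[, 3])
  for (b in split(seq_len(180), pure_bi$lipid)) {
    head_z <- pure_bi$positions[b[1], 3]
    tail_z <- pure_bi$positions[b[-1], 3]
    expect_true(all(abs(head_z - mid) > abs(tail_z - mid)))
  }
  pure_bola <- build_flat(60, f_bi = 0, temperature = 1, seed = 3)
  expect_true(all(pure_bola$lipid_species == "bola"))
  expect_equal(u_fraction(pure_bola), 0)   # all straight at build time
  mixed <- build_flat(60, f_bi = 0.5, temperature = 1, seed = 3)
  expect_equal(sum(mixed$lipid_species == "bilayer"), 30)
})

test_that("lipids stay in one membrane through a relaxation run", {
  sys <- build_flat(80, f_bi = 0, temperature = 1.1, seed = 6)
  ff <- forcefield_params()
  ip <- integrator_params(temperature = 1.1, barostat = TRUE, seed = 6)
  r <- md_run(sys, ff, ip, 15000)
  expect_equal(n_lipids(r$system), 80)
  expect_gte(lipid_clusters(r$system)$largest_fraction, 0.99)
})

test_that("cylinder builder: curvature target and rejection", {
  expect_error(build_cylinder(2), "thickness")
  sys <- build_cylinder(8, length = 12, temperature = 1, seed = 1)
  w <- wrap_positions(sys)
  tails <- w$positions[w$role == 2L, 1:2]
  ctr <- sys$box[1:2] / 2
  R <- mean(sqrt((tails[, 1] - ctr[1])^2 + (tails[, 2] - ctr[2])^2))
  expect_equal(R, 8, tolerance = 0.08)
  # large radius: local site spacing approaches the flat lattice constant
  big <- build_cylinder(50, length = 6, temperature = 1, seed = 1)
  heads <- wrap_positions(big)$positions[big$role == 1L, ]
  outer <- heads[sqrt((heads[, 1] - big$box[1]/2)^2 +
                      (heads[, 2] - big$box[2]/2)^2) > 50, ]
  d <- as.matrix(dist(outer[1:200, ]))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_equal(median(nn), sqrt(1.2), tolerance = 0.06)
})

test_that("patch builder produces one connected free-standing disc", {
  sys <- build_patch(120, f_bi = 1, temperature = 1, seed = 5)
  expect_equal(lipid_clusters(sys)$largest_fraction, 1)
  # free edge: the disc does not touch the periodic images (large box)
  expect_gt(sys$box[1], 2 * attr(sys, "r_disc") + 20)
})

test_that("cargo placement starts in adhesion contact", {
  ff <- forcefield_params(r_cargo = 5, eps_mc = 2)
  sys <- add_cargo(build_flat(80, temperature = 1, seed = 7, box_z = 40), ff)
  expect_gte(n_adhered_heads(sys, ff), 1)
  expect_equal(sum(sys$role == 3L), 1)
  # cargo core does not overlap any bead
  w <- wrap_positions(sys)
  ci <- which(w$role == 3L)
  d <- sweep(w$positions[-ci, ], 2, w$positions[ci, ])
  for (k in 1:3) d[, k] <- d[, k] - sys$box[k] * round(d[, k] / sys$box[k])
  expect_gt(min(sqrt(rowSums(d^2))), ff$r_cargo - 0.5)
})

test_that("all builds pass the universal validity check", {
  ff <- forcefield_params()
  for (sys in list(build_flat(40, 0.25, seed = 1),
                   build_gas(10, box = c(15, 15, 15), seed = 1),
                   build_cylinder(6, length = 10, seed = 1),
                   build_patch(50, seed = 1))) {
    expect_silent(validate_system(sys))
    # bonds under the FENE divergence length
    w <- wrap_positions(sys)
    d <- w$positions[sys$bonds[, 1], ] - w$positions[sys$bonds[, 2], ]
    for (k in 1:3) d[, k] <- d[, k] - sys$box[k] * round(d[, k] / sys$box[k])
    expect_lt(max(sqrt(rowSums(d^2))), 1.5)
  }
})
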