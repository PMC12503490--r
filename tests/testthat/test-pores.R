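# Probe-sphere pore detection on constructed fixtures, agreement with an
# exhaustive path-search oracle, and the time-average statistics.

ff <- forcefield_params()

test_that("an intact defect-free sheet has no pores", {
  sys <- flat_lattice_membrane(nside = 20)
  rec <- detect_pores(sys, ff, geometry = list(type = "flat", z0 = 10.9,
                                               half_thickness = 1.5))
  expect_equal(rec$max_diameter, 0)
  expect_equal(rec$pore_count, 0L)
})

test_that("a punched hole is recovered at its aperture diameter", {
  for (ap in c(3, 4)) {
    sys <- flat_lattice_membrane(nside = 24, hole_aperture = ap)
    rec <- detect_pores(sys, ff, geometry = list(type = "flat", z0 = 10.9,
                                                 half_thickness = 1.5))
    expect_gte(rec$pore_count, 1L)
    # grid (0.5 sigma) + bisection tolerance (0.25 sigma)
    expect_lt(abs(rec$max_diameter - ap), 0.85)
  }
})

test_that("pore diameter >= probe whenever a pore is reported", {
  sys <- flat_lattice_membrane(nside = 20, hole_aperture = 2)
  rec <- detect_pores(sys, ff, geometry = list(type = "flat", z0 = 10.9,
                                               half_thickness = 1.5))
  if (rec$pore_count > 0) expect_gte(rec$max_diameter, 1)
})

test_that("grid crossing detection matches an exhaustive graph search", {
  # random small occupancy grids: component-label crossing test vs
  # brute-force path existence via igraph
  set.seed(42)
  for (rep in 1:12) {
    dim <- c(10, 10, 10)
    occ <- as.integer(runif(prod(dim)) < 0.42)
    lab <- bolasim:::cpp_free_components(occ, dim[1], dim[2], dim[3],
                                         rep(FALSE, 3))
    idx <- seq_len(prod(dim)) - 1
    z <- idx %/% (dim[1] * dim[2])
    topc <- unique(lab[z == dim[3] - 1 & lab > 0])
    botc <- unique(lab[z == 0 & lab > 0])
    crossing_labels <- length(intersect(topc, botc)) > 0
    # oracle: 6-connected free-cell graph, any top-bottom path
    free <- which(occ == 0)
    co <- cbind(idx %% dim[1], (idx %/% dim[1]) %% dim[2], z)[free, , drop = FALSE]
    key <- co[, 1] + co[, 2] * 100 + co[, 3] * 10000
    edges <- NULL
    for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      nb <- sweep(co, 2, off, "+")
      nbkey <- nb[, 1] + nb[, 2] * 100 + nb[, 3] * 10000
      hit <- match(nbkey, key)
      ok <- !is.na(hit) & nb[, 1] < dim[1] & nb[, 2] < dim[2] & nb[, 3] < dim[3]
      edges <- rbind(edges, cbind(which(ok), hit[ok]))
    }
    g <- igraph::make_empty_graph(n = length(free), directed = FALSE)
    if (!is.null(edges) && nrow(edges))
      g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    crossing_oracle <- length(intersect(comp[co[, 3] == dim[3] - 1],
                                        comp[co[, 3] == 0])) > 0
    expect_equal(crossing_labels, crossing_oracle)
  }
})

test_that("pore statistics average per-frame maxima", {
  recs <- rbind(
    data.frame(time = 1:4, region = "bud", max_diameter = c(0, 2, 0, 2),
               pore_count = c(0L, 1L, 0L, 1L)),
    data.frame(time = 1:4, region = "mother_flat", max_diameter = 0,
               pore_count = 0L))
  st <- pore_statistics(recs)
  expect_equal(st$mean_max_diameter[st$region == "bud"], 1)     # d/2
  expect_equal(st$mean_max_diameter[st$region == "mother_flat"], 0)
  one <- pore_statistics(data.frame(time = 1:3, region = "bud",
                                    max_diameter = 3, pore_count = 1L))
  expect_equal(one$mean_max_diameter, 3)
})
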