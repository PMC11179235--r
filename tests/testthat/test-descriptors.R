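# Geometric and atomistic descriptor panel against independent oracles.

test_that("axis diameters equal the max pairwise extent per component", {
  two <- particle(data.frame(element = "Ar", x = c(0, 3), y = c(0, 4),
                             z = c(0, 0)), check_overlap = FALSE)
  expect_equal(axis_diameters(two), c(dx = 3, dy = 4, dz = 0))
  lone <- particle(data.frame(element = "Ar", x = 1, y = 2, z = 3))
  expect_equal(unname(axis_diameters(lone)), c(0, 0, 0))
  withr::with_seed(3, p <- random_cluster(50, box = 10, min_sep = 0.8))
  xyz <- as.matrix(p[, c("x", "y", "z")])
  oracle <- apply(xyz, 2, function(v) max(outer(v, v, `-`)))
  expect_equal(unname(axis_diameters(p)), unname(oracle))
})

test_that("the Thomsen area is exact for spheres and within its error bound", {
  expect_equal(thomsen_surface_area(3, 3, 3), 4 * pi * 9, tolerance = 1e-12)
  # the paper-scale ellipsoid and a broad aspect-ratio sweep vs quadrature
  expect_lt(abs(thomsen_surface_area(2.5, 1.95, 1.64) /
                  quadrature_area(2.5, 1.95, 1.64) - 1), 0.01061)
  ratios <- exp(seq(log(1), log(100), length.out = 9))
  for (r in ratios) {
    rel_p <- abs(thomsen_surface_area(1, 1, r) / quadrature_area(1, 1, r) - 1)
    rel_o <- abs(thomsen_surface_area(1, r, r) / quadrature_area(1, r, r) - 1)
    expect_lt(rel_p, 0.01061)
    expect_lt(rel_o, 0.01061)
  }
  expect_error(thomsen_surface_area(0, 1, 1), class = "nanocarve_domain_error")
})

test_that("ellipsoid volume follows 4/3 pi abc", {
  expect_equal(round(ellipsoid_volume(2, 2, 2), 2), 33.51)
  expect_equal(ellipsoid_volume(1, 1, 1), 4 * pi / 3)
  expect_equal(ellipsoid_volume(2.5, 1.95, 1.64), 33.49, tolerance = 1e-3)
})

test_that("core/surface classification shrinks the ellipsoid by the shell thickness", {
  p <- particle(data.frame(element = "Ar",
                           x = c(0, 7, -7), y = 0, z = 0),
                check_overlap = FALSE)
  # symmetric triple: centroid at origin
  lab <- classify_core_surface(p, c(10, 10, 10))
  expect_equal(lab, c("core", "surface", "surface"))  # 7 > 10 - 4
  expect_equal(classify_core_surface(p, c(3, 10, 10)),
               rep("surface", 3))  # degenerate: shell swallows the core
  withr::with_seed(8, q <- random_cluster(40, box = 12, min_sep = 1))
  lab2 <- classify_core_surface(q, c(6, 6, 6))
  expect_equal(sum(lab2 == "core") + sum(lab2 == "surface"), 40L)
})

test_that("coordination cutoffs follow the one/two/many species rule", {
  s <- descriptor_settings()
  one <- coordination_cutoff("O", charges = -2, settings = s)
  expect_equal(unname(one[1, 1]), 2.4 * 1.40)
  nacl <- coordination_cutoff(c("Na", "Cl"), charges = c(1, -1), settings = s)
  expect_equal(unname(nacl["Na", "Cl"]), 1.2 * (1.02 + 1.81))
  expect_equal(unname(nacl["Na", "Na"]), 1.2 * 2 * 1.02)
  three <- coordination_cutoff(c("Na", "Cl", "O"),
                               charges = c(1, -1, -2), settings = s)
  expect_true(all(three == 5))
})

test_that("coordination counts match lattice geometry and a brute-force oracle", {
  lone <- particle(data.frame(element = "Ar", x = 0, y = 0, z = 0))
  expect_equal(avg_coordination(lone, cutoff = 3)$average, 0)

  # rock-salt interior: 6 unlike neighbours under the two-species rule
  rs <- build_supercell(generate_fixture("rocksalt")$cell, 3, 3, 3)
  co <- avg_coordination(rs)
  interior <- which.min(rowSums(sweep(as.matrix(rs[, c("x", "y", "z")]), 2,
                                      colMeans(as.matrix(rs[, c("x", "y", "z")])))^2))
  expect_equal(co$per_atom[[interior]], 6L)

  # FCC interior: 12 with any cutoff between the first and second shell
  blk <- fcc_block(4, a = 4.05)
  mid <- which.min(rowSums(sweep(as.matrix(blk[, c("x", "y", "z")]), 2,
                                 colMeans(as.matrix(blk[, c("x", "y", "z")])))^2))
  cut <- (4.05 / sqrt(2) + 4.05) / 2
  co2 <- avg_coordination(blk, cutoff = cut)
  expect_equal(co2$per_atom[[mid]], 12L)
  expect_equal(as.integer(co2$per_atom), coordination_oracle(blk, cut))
  # the single-species rule lands in the same window via the covalent radius
  expect_equal(suppressWarnings(avg_coordination(blk)$per_atom[[mid]]), 12L)
})

test_that("CNP is zero on perfect FCC, positive and uniform on HCP", {
  blk <- fcc_block(4, a = 4.05)
  cut <- 3.4  # between first (2.86) and second (4.05) shells
  q <- cnp(blk, cutoff = cut)
  co <- avg_coordination(blk, cutoff = cut)$per_atom
  interior <- co == 12L
  expect_true(any(interior))
  expect_lt(max(abs(q$per_atom[interior])), 1e-8)
  expect_equal(q$per_atom, cnp_oracle(blk, cut), tolerance = 1e-8)

  hcp <- hcp_block(4, 4, 3, a = 2.9)
  cuth <- 2.9 * 1.2
  qh <- cnp(hcp, cutoff = cuth)
  coh <- avg_coordination(hcp, cutoff = cuth)$per_atom
  inner <- coh == 12L
  expect_true(any(inner))
  expect_gt(min(qh$per_atom[inner]), 1e-4)
  expect_lt(diff(range(qh$per_atom[inner])), 1e-8)
  expect_equal(qh$per_atom, cnp_oracle(hcp, cuth), tolerance = 1e-8)

  dimer <- particle(data.frame(element = "Ar", x = c(0, 1), y = 0, z = 0),
                    check_overlap = FALSE)
  expect_equal(cnp(dimer, cutoff = 2)$per_atom, c(0, 0))
})

test_that("hexatic order is 1 on a perfect hexagonal monolayer", {
  # single bond along +x
  pair <- particle(data.frame(element = "Ar", x = c(0, 1), y = 0, z = 0),
                   check_overlap = FALSE)
  hx <- hexatic(pair, cutoff = 1.5)
  expect_equal(hx$per_atom[1], 1 + 0i, tolerance = 1e-12)

  # single bond at 30 degrees in-plane: 6 theta = pi
  tilted <- particle(data.frame(element = "Ar",
                                x = c(0, cos(pi / 6)), y = c(0, sin(pi / 6)),
                                z = 0), check_overlap = FALSE)
  expect_equal(hexatic(tilted, cutoff = 1.5)$per_atom[1], -1 + 0i,
               tolerance = 1e-9)

  # hexagonal monolayer: one z = 0 layer of the HCP generator
  mono <- hcp_block(6, 6, 1, a = 2.9)
  mono <- keep_atoms(mono, abs(mono$z) < 1e-9)
  cut <- 2.9 * 1.2
  hx2 <- hexatic(mono, cutoff = cut)
  six <- avg_coordination(mono, cutoff = cut)$per_atom == 6L
  expect_true(any(six))
  expect_lt(max(Mod(hx2$per_atom[six] - (1 + 0i))), 1e-8)
  expect_equal(hx2$per_atom, hexatic_oracle(mono, cut), tolerance = 1e-8)
})

test_that("descriptors are translation invariant; frame-bound ones rotate", {
  blk <- carve_sphere(fcc_block(4, a = 4.05), 12)
  cut <- 3.4
  shift <- blk; shift$x <- shift$x + 100; shift$y <- shift$y - 31
  expect_equal(cnp(shift, cutoff = cut)$per_atom,
               cnp(blk, cutoff = cut)$per_atom, tolerance = 1e-8)
  expect_equal(hexatic(shift, cutoff = cut)$per_atom,
               hexatic(blk, cutoff = cut)$per_atom, tolerance = 1e-8)
  expect_equal(avg_coordination(shift, cutoff = cut)$per_atom,
               avg_coordination(blk, cutoff = cut)$per_atom)

  # a tetragonal (z-squashed) block: 90-degree z-rotation preserves the
  # extents, a 90-degree x-rotation swaps them
  tet <- particle(data.frame(element = "Ar",
                             x = c(0, 4, 0, 4, 0, 4, 0, 4),
                             y = c(0, 0, 4, 4, 0, 0, 4, 4),
                             z = c(0, 0, 0, 0, 2, 2, 2, 2)),
                  check_overlap = FALSE)
  rz <- rotate_structure(tet, c(0, 0, 1), 90)
  expect_equal(unname(axis_diameters(rz)), c(4, 4, 2), tolerance = 1e-9)
  rx <- rotate_structure(tet, c(1, 0, 0), 90)
  expect_equal(unname(axis_diameters(rx)), c(4, 2, 4), tolerance = 1e-9)
})

test_that("the descriptor report partitions regions and averages consistently", {
  cell <- substitute_element(generate_fixture("rutile_MO2")$cell, "Ti", "Zr")
  np <- build_ellipsoidal_np(cell, ellipsoid_spec(2.4, 2, 2))
  pot <- read_potential_file(system.file("extdata", "buckingham_zro2.pot",
                                         package = "nanocarve"))
  fit <- minimize_structure(np, pot, minimization_settings(max_iterations = 20))
  ds <- np_descriptors(fit$structure)
  r <- ds$regions
  whole <- r[r$region == "whole", ]
  core <- r[r$region == "core", ]
  surf <- r[r$region == "surface", ]
  expect_equal(core$n_atoms + surf$n_atoms, whole$n_atoms)
  for (col in c("avg_energy", "avg_coordination", "avg_cnp",
                "hex_real", "hex_imag")) {
    weighted <- (core[[col]] * core$n_atoms + surf[[col]] * surf$n_atoms) /
      whole$n_atoms
    expect_equal(whole[[col]], weighted, tolerance = 1e-10, info = col)
  }
  # derived block consistency
  d <- ds$derived
  expect_equal(d$difference, d$core - d$surface, tolerance = 1e-12)
  ok <- !is.na(d$ratio)
  expect_equal(d$ratio[ok], (d$core / d$surface)[ok], tolerance = 1e-12)

  # refusing unminimized structures unless overridden
  expect_error(np_descriptors(np), class = "nanocarve_stage_error")
  expect_error(np_descriptors(np, allow_unminimized = TRUE), NA)
})

test_that("an all-surface particle reports missing core values", {
  thin <- particle(data.frame(element = "Ar",
                              x = c(0, 2, 4), y = 0, z = 0),
                   check_overlap = FALSE)
  ds <- np_descriptors(thin, potential = unit_lj(), allow_unminimized = TRUE,
                       cutoff = 3)
  r <- ds$regions
  expect_equal(r$n_atoms[r$region == "core"], 0L)
  expect_true(is.na(r$avg_energy[r$region == "core"]))
  expect_equal(r$avg_energy[r$region == "whole"],
               r$avg_energy[r$region == "surface"])
})

test_that("ratio and difference derive from the region energy averages", {
  # one core atom at -7.0 eV, two surface atoms at -6.5 eV
  p <- particle(data.frame(element = "Ar", x = c(-9, 0, 9), y = 0, z = 0,
                           energy = c(-6.5, -7.0, -6.5)),
                check_overlap = FALSE)
  ds <- np_descriptors(p, allow_unminimized = TRUE, cutoff = 3,
                       semilengths = c(10, 10, 10))
  d <- ds$derived[ds$derived$descriptor == "avg_energy", ]
  expect_equal(d$difference, -0.5, tolerance = 1e-12)
  expect_equal(d$ratio, 1.076923, tolerance = 1e-6)
})
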