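# Supercell replication, carving, rotation, stoichiometry neutralization.

cubic_cell <- function(a = 4, element = "Ti") {
  unit_cell(a, a, a, sites = data.frame(element = element, fx = 0, fy = 0, fz = 0))
}

test_that("supercell dimensions cover the sphere with one cell of margin", {
  expect_equal(supercell_dimensions(cubic_cell(5), 10), c(3L, 3L, 3L))
  expect_equal(supercell_dimensions(cubic_cell(4), 1), c(2L, 2L, 2L))
  rutile <- generate_fixture("rutile_MO2")$cell
  expect_error(supercell_dimensions(rutile, 50, max_atoms = 1000),
               class = "nanocarve_memory_error")
})

test_that("build_supercell replicates sites across all lattice offsets", {
  cell <- cubic_cell(4)
  expect_equal(n_atoms(build_supercell(cell, 1, 1, 1)), 1L)
  two <- build_supercell(cell, 2, 1, 1)
  expect_equal(n_atoms(two), 2L)
  expect_equal(sort(two$x), c(0, 4))
  rutile <- generate_fixture("rutile_MO2")$cell
  expect_equal(n_atoms(build_supercell(rutile, 3, 3, 3)), 162L)
})

test_that("carve_sphere keeps exactly the atoms within the radius", {
  blk <- cubic_block(5, a = 1)
  attr(blk, "center") <- c(0, 0, 0)
  # diameter 2: center + 6 face neighbours (brute force: r <= 1)
  seven <- carve_sphere(blk, 2)
  expect_equal(n_atoms(seven), 7L)
  xyz <- as.matrix(blk[, c("x", "y", "z")])
  expect_equal(n_atoms(seven), sum(sqrt(rowSums(xyz^2)) <= 1 + 1e-9))
  # superset sphere keeps everything
  expect_equal(n_atoms(carve_sphere(blk, 100)), n_atoms(blk))
})

test_that("rotation follows the right-hand rule and is an isometry", {
  tri <- particle(data.frame(element = "Ar",
                             x = c(0, 1, 0), y = c(0, 0, 2), z = c(0, 0, 0)),
                  check_overlap = FALSE)
  centroid <- colMeans(as.matrix(tri[, c("x", "y", "z")]))
  r90 <- rotate_structure(tri, c(0, 0, 1), 90)
  # offset (1,0,0) from centroid must land at centroid + (0,1,0)
  off <- as.matrix(tri[, c("x", "y", "z")]) - rep(centroid, each = 3)
  new_off <- as.matrix(r90[, c("x", "y", "z")]) - rep(centroid, each = 3)
  expect_equal(new_off[2, ], c(-off[2, 2], off[2, 1], off[2, 3]),
               tolerance = 1e-12, ignore_attr = TRUE)

  r0 <- rotate_structure(tri, c(0, 0, 1), 0)
  expect_equal(as.matrix(r0[, c("x", "y", "z")]),
               as.matrix(tri[, c("x", "y", "z")]), tolerance = 1e-12)
  r360 <- rotate_structure(tri, c(1, 2, 3), 360)
  expect_lt(max(abs(as.matrix(r360[, c("x", "y", "z")]) -
                      as.matrix(tri[, c("x", "y", "z")]))), 1e-9)

  withr::with_seed(11, {
    for (rep in 1:5) {
      p <- random_cluster(12)
      axis <- stats::rnorm(3)
      ang <- stats::runif(1, 0, 360)
      q <- rotate_structure(p, axis, ang)
      expect_equal(distance_multiset(q), distance_multiset(p),
                   tolerance = 1e-9)
      back <- rotate_structure(q, axis, -ang)
      expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                          as.matrix(p[, c("x", "y", "z")]))), 1e-9)
    }
  })
  expect_error(rotate_structure(tri, c(0, 0, 0), 10),
               class = "nanocarve_axis_error")
})

test_that("carve_ellipsoid matches a brute-force membership check", {
  blk <- cubic_block(9, a = 1)
  spec <- ellipsoid_spec(0.6, 0.4, 0.2)  # Rx=3, Ry=2, Rz=1 Angstrom
  carved <- carve_ellipsoid(blk, spec)
  xyz <- as.matrix(blk[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  s <- sqrt(((xyz[, 1] - ctr[1]) / 3)^2 + ((xyz[, 2] - ctr[2]) / 2)^2 +
              ((xyz[, 3] - ctr[3]) / 1)^2)
  expect_equal(n_atoms(carved), sum(s <= 1 + 1e-9))

  two <- particle(data.frame(element = "Ar", x = c(0, 2), y = 0, z = 0),
                  check_overlap = FALSE)
  # centroid at (1,0,0); unit sphere keeps neither atom? both at s = 1: kept
  kept <- carve_ellipsoid(two, ellipsoid_spec(0.2, 0.2, 0.2))
  expect_equal(n_atoms(kept), 2L)  # both on the closed surface
  # even-sized block: no atom sits at the centroid, so a tiny ellipsoid
  # keeps nothing
  expect_error(carve_ellipsoid(cubic_block(2, a = 10),
                               ellipsoid_spec(0.01, 0.01, 0.01)),
               class = "nanocarve_empty_error")
})

test_that("smaller ellipsoids carve subsets of larger ones", {
  blk <- cubic_block(9, a = 1)
  big <- carve_ellipsoid(blk, ellipsoid_spec(0.7, 0.5, 0.4))
  small <- carve_ellipsoid(blk, ellipsoid_spec(0.5, 0.3, 0.2))
  key <- function(p) paste(p$x, p$y, p$z)
  expect_true(all(key(small) %in% key(big)))
})

test_that("neutralization removes minimal atoms nearest the surface", {
  # 50 Zr + 101 O with known geometry: exactly one O must go, the one with
  # the largest normalized ellipsoidal coordinate
  withr::with_seed(7, {
    zr <- random_cluster(50, box = 12, min_sep = 1.4, elements = "Zr")
    o <- random_cluster(101, box = 12, min_sep = 1.4, elements = "O")
    o$x <- o$x + 14  # keep the two clouds apart (overlap guard irrelevant)
    both <- particle(rbind(as.data.frame(zr), as.data.frame(o)),
                     check_overlap = FALSE)
  })
  spec <- ellipsoid_spec(4, 4, 4)
  out <- neutralize_stoichiometry(both, c(Zr = 1L, O = 2L), spec)
  expect_equal(as.integer(table(out$element)[c("Zr", "O")]), c(50L, 100L))

  # already stoichiometric input is untouched
  balanced <- keep_atoms(both, c(rep(TRUE, 50), rep(TRUE, 100), FALSE))
  same <- neutralize_stoichiometry(balanced, c(Zr = 1L, O = 2L), spec)
  expect_equal(as.data.frame(same)[, 1:4], as.data.frame(balanced)[, 1:4])

  # n_fu = 0 is an empty-particle error
  tiny <- particle(data.frame(element = c("Zr", "Zr", "Zr", "O"),
                              x = c(0, 3, 6, 9), y = 0, z = 0),
                   check_overlap = FALSE)
  expect_error(neutralize_stoichiometry(tiny, c(Zr = 1L, O = 2L), spec),
               class = "nanocarve_empty_error")
  expect_error(neutralize_stoichiometry(zr, c(Zr = 1L, O = 2L), spec),
               class = "nanocarve_composition_error")
})

test_that("end-to-end build is stoichiometric, neutral and deterministic", {
  cell <- substitute_element(generate_fixture("rutile_MO2")$cell, "Ti", "Zr")
  spec <- ellipsoid_spec(2, 2, 2)
  np <- build_ellipsoidal_np(cell, spec)
  cnt <- table(np$element)
  expect_equal(as.integer(cnt[["O"]]), 2L * as.integer(cnt[["Zr"]]))
  expect_equal(sum(np$charge), 0)

  again <- build_ellipsoidal_np(cell, spec)
  expect_identical(as.data.frame(np), as.data.frame(again))

  full_turn <- build_ellipsoidal_np(cell, ellipsoid_spec(2, 2, 2,
                                                         c(0, 0, 1), 360))
  expect_equal(as.matrix(np[, c("x", "y", "z")]),
               as.matrix(full_turn[, c("x", "y", "z")]), tolerance = 1e-6)
})

test_that("90-degree rotation about z of a tetragonal cell carves a congruent particle", {
  cell <- generate_fixture("rutile_MO2")$cell  # tetragonal: 4-fold about z
  a0 <- build_ellipsoidal_np(cell, ellipsoid_spec(1.5, 1.5, 1.5, c(0, 0, 1), 0))
  a90 <- build_ellipsoidal_np(cell, ellipsoid_spec(1.5, 1.5, 1.5, c(0, 0, 1), 90))
  expect_equal(n_atoms(a0), n_atoms(a90))
  expect_equal(distance_multiset(a0), distance_multiset(a90), tolerance = 1e-6)
})
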