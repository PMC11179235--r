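# Geometric construction: replicate the unit cell into a supercell, carve a
# sphere of the largest axis, rotate the lattice, carve the ellipsoid, and
# remove excess atoms nearest the surface to restore stoichiometry.

#' Supercell replication counts for a target diameter
#'
#' How many times to replicate the cell along each lattice direction so that
#' a sphere of the given diameter fits, with one extra cell of margin:
#' `n_i = ceil(diameter / w_i) + 1` where `w_i` is the perpendicular width
#' of the cell along direction i. A hard cap on the estimated atom count
#' guards against memory blow-ups.
#'
#' @param cell A [unit_cell()].
#' @param diameter Sphere diameter (Angstrom).
#' @param max_atoms Guard on `nx*ny*nz*n_sites` (default 2e6).
#' @return Integer vector `c(nx, ny, nz)`.
#' @export
supercell_dimensions <- function(cell, diameter, max_atoms = 2e6) {
  stopifnot(inherits(cell, "unit_cell"), diameter > 0)
  L <- cell$lattice
  vol <- abs(det(L))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  w <- c(vol / sqrt(sum(cross(L[2, ], L[3, ])^2)),
         vol / sqrt(sum(cross(L[1, ], L[3, ])^2)),
         vol / sqrt(sum(cross(L[1, ], L[2, ])^2)))
  n <- as.integer(ceiling(diameter / w - 1e-9) + 1L)
  est <- prod(as.numeric(n)) * nrow(cell$sites)
  if (est > max_atoms) {
    nc_abort(sprintf(
      "Supercell would hold ~%.3g atoms, above the max_atoms guard of %.3g",
      est, max_atoms), class = "nanocarve_memory_error")
  }
  n
}

#' Replicate a unit cell into a supercell
#'
#' @param cell A [unit_cell()].
#' @param nx,ny,nz Replication counts (>= 1).
#' @return An `nc_particle` containing `nx*ny*nz*n_sites` atoms in Cartesian
#'   coordinates, with the geometric box center recorded for later carving.
#' @export
build_supercell <- function(cell, nx, ny, nz) {
  stopifnot(inherits(cell, "unit_cell"), nx >= 1, ny >= 1, nz >= 1)
  offsets <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  s <- cell$sites
  frac <- as.matrix(s[, c("fx", "fy", "fz")])
  blocks <- purrr::pmap_dfr(offsets, function(i, j, k) {
    f <- frac + matrix(c(i, j, k), nrow(frac), 3, byrow = TRUE)
    xyz <- frac_to_cart(f, cell$lattice)
    tibble(element = s$element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
           charge = s$charge)
  })
  center <- as.numeric(c(nx, ny, nz) %*% cell$lattice) / 2
  particle(blocks, stage = "supercell", center = center, check_overlap = FALSE)
}

#' Carve a sphere out of a structure
#'
#' Keeps atoms within `diameter/2` of the reference center (the geometric
#' center of the supercell box, not snapped to any atom).
#'
#' @param structure An `nc_particle`.
#' @param diameter Sphere diameter (Angstrom).
#' @return The carved `nc_particle`.
#' @export
carve_sphere <- function(structure, diameter) {
  stopifnot(is_particle(structure), diameter > 0)
  ctr <- attr(structure, "center")
  if (is.null(ctr)) {
    xyz <- positions(structure)
    ctr <- (apply(xyz, 2, min) + apply(xyz, 2, max)) / 2
  }
  xyz <- positions(structure)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  keep <- d2 <= (diameter / 2 + 1e-9)^2
  if (!any(keep)) {
    nc_abort("Sphere carve removed every atom", class = "nanocarve_empty_error")
  }
  keep_atoms(structure, keep, stage = "sphere", center = ctr)
}

rodrigues_matrix <- function(axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (k %o% k)
}

#' Rotate a structure about an axis through its centroid
#'
#' Right-hand-rule rotation (Rodrigues formula). An isometry: pairwise
#' distances are preserved to floating-point accuracy.
#'
#' @param structure An `nc_particle`.
#' @param axis Rotation axis (length-3, nonzero).
#' @param angle Angle in degrees.
#' @return The rotated `nc_particle`.
#' @export
rotate_structure <- function(structure, axis, angle) {
  stopifnot(is_particle(structure))
  if (sum(axis^2) == 0) {
    nc_abort("Rotation axis must be nonzero", class = "nanocarve_axis_error")
  }
  ctr <- particle_centroid(structure)
  R <- rodrigues_matrix(axis, angle)
  xyz <- positions(structure)
  rotated <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, `+`)
  out <- set_positions(structure, rotated)
  attr(out, "stage") <- "rotated"
  out
}

# Normalized ellipsoidal coordinate of each atom, centroid-relative:
# s(r) = sqrt((x/Rx)^2 + (y/Ry)^2 + (z/Rz)^2); s = 1 on the surface.
ellipsoid_s <- function(structure, semilengths, center = NULL) {
  xyz <- positions(structure)
  ctr <- center %||% colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  sqrt((rel[, 1] / semilengths[1])^2 +
         (rel[, 2] / semilengths[2])^2 +
         (rel[, 3] / semilengths[3])^2)
}

#' Carve an axis-aligned ellipsoid
#'
#' Keeps atoms whose normalized ellipsoidal coordinate (relative to the
#' structure's centroid) is at most 1. The ellipsoid is aligned with the
#' laboratory frame — the lattice, not the ellipsoid, was rotated.
#'
#' @param structure An `nc_particle`.
#' @param spec An [ellipsoid_spec()] (axis lengths in nm).
#' @return The carved `nc_particle`.
#' @export
carve_ellipsoid <- function(structure, spec) {
  stopifnot(is_particle(structure), inherits(spec, "ellipsoid_spec"))
  semi <- spec_semilengths_A(spec)
  ctr <- particle_centroid(structure)
  s <- ellipsoid_s(structure, semi, ctr)
  keep <- s <= 1 + 1e-9
  if (!any(keep)) {
    nc_abort("Ellipsoid carve removed every atom", class = "nanocarve_empty_error")
  }
  keep_atoms(structure, keep, stage = "ellipsoid", spec = spec, center = ctr)
}

#' Remove excess atoms to restore stoichiometry
#'
#' Finds the largest whole number of formula units the carved particle can
#' hold (`n_fu = min_e floor(count_e / nu_e)`) and removes, per element, the
#' surplus atoms closest to the ellipsoid surface from inside — largest
#' normalized ellipsoidal coordinate first, ties broken by lexicographic
#' (x, y, z). For a neutral formula the result is charge neutral.
#'
#' @param structure An `nc_particle`.
#' @param formula_unit Named integer vector, element -> count per formula
#'   unit (e.g. `c(O = 2, Zr = 1)`).
#' @param spec The [ellipsoid_spec()] defining the surface metric.
#' @return The stoichiometric `nc_particle`.
#' @export
neutralize_stoichiometry <- function(structure, formula_unit, spec) {
  stopifnot(is_particle(structure), inherits(spec, "ellipsoid_spec"))
  counts <- table(structure$element)
  missing <- setdiff(names(formula_unit), names(counts))
  if (length(missing) > 0L) {
    nc_abort(paste0("Formula element(s) absent from particle: ",
                    paste(missing, collapse = ", ")),
             class = "nanocarve_composition_error")
  }
  n_fu <- min(floor(as.numeric(counts[names(formula_unit)]) / formula_unit))
  if (n_fu < 1) {
    nc_abort("Particle cannot hold a single formula unit",
             class = "nanocarve_empty_error")
  }
  semi <- spec_semilengths_A(spec)
  s <- ellipsoid_s(structure, semi)
  drop <- logical(n_atoms(structure))
  for (el in names(formula_unit)) {
    excess <- as.integer(counts[[el]]) - formula_unit[[el]] * n_fu
    if (excess > 0L) {
      idx <- which(structure$element == el)
      ord <- idx[order(-s[idx], structure$x[idx], structure$y[idx],
                       structure$z[idx])]
      drop[ord[seq_len(excess)]] <- TRUE
    }
  }
  keep_atoms(structure, !drop, stage = "neutralized")
}

#' Build a stoichiometric ellipsoidal nanoparticle end-to-end
#'
#' The full geometric pipeline: supercell sized to the largest axis, sphere
#' carve at that diameter, lattice rotation, ellipsoid carve, stoichiometry
#' neutralization. Fully deterministic: the same cell and spec always yield
#' the same atom set.
#'
#' @param cell A [unit_cell()].
#' @param spec An [ellipsoid_spec()].
#' @param max_atoms Supercell memory guard (see [supercell_dimensions()]).
#' @return An `nc_particle` with provenance attributes set.
#' @export
#' @examples
#' cell <- generate_fixture("rutile_MO2")$cell
#' np <- build_ellipsoidal_np(cell, ellipsoid_spec(2, 2, 2))
#' table(np$element)  # exactly 2 O per Ti
build_ellipsoidal_np <- function(cell, spec, max_atoms = 2e6) {
  stopifnot(inherits(cell, "unit_cell"), inherits(spec, "ellipsoid_spec"))
  d_max <- max(spec$dx, spec$dy, spec$dz) * 10
  n <- supercell_dimensions(cell, d_max, max_atoms)
  sc <- build_supercell(cell, n[1], n[2], n[3])
  np <- carve_sphere(sc, d_max)
  np <- rotate_structure(np, spec$rotation_vector, spec$rotation_angle)
  np <- carve_ellipsoid(np, spec)
  np <- neutralize_stoichiometry(np, cell$formula_unit, spec)
  attr(np, "spec") <- spec
  np
}
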