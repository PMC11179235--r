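# Finite clusters in vacuum. A particle is a tibble of atoms (element, x, y,
# z in Angstrom, optional formal charge and per-atom energy) carrying
# provenance attributes: construction stage, the ellipsoid spec it came
# from, and whether it has been energy-minimized.

#' Create a particle (finite atom cluster)
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (Angstrom)
#'   and optionally `charge` (e) and `energy` (eV per atom).
#' @param stage Construction stage tag (e.g. `"supercell"`, `"ellipsoid"`).
#' @param spec The [ellipsoid_spec()] the particle was carved with, if any.
#' @param minimized Has the particle been energy-minimized?
#' @param center Reference center (Cartesian, length 3) used by carving;
#'   defaults to the centroid.
#' @param check_overlap Guard against atoms closer than 0.5 Angstrom.
#' @return A `nc_particle` tibble.
#' @export
particle <- function(atoms, stage = "constructed", spec = NULL,
                     minimized = FALSE, center = NULL, check_overlap = TRUE) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"energy" %in% names(atoms)) atoms$energy <- NA_real_
  atoms <- atoms[, c("element", "x", "y", "z", "charge", "energy")]
  if (check_overlap && nrow(atoms) > 1L) {
    if (has_close_pair_cpp(positions(atoms), 0.5)) {
      nc_abort("Atoms closer than 0.5 A: overlapping structure",
               class = "nanocarve_overlap_error")
    }
  }
  structure(
    atoms,
    stage = stage, spec = spec, minimized = isTRUE(minimized),
    center = center,
    class = c("nc_particle", class(tibble()))
  )
}

is_particle <- function(x) inherits(x, "nc_particle")

positions <- function(p) unname(as.matrix(p[, c("x", "y", "z")]))

n_atoms <- function(p) nrow(p)

particle_centroid <- function(p) colMeans(positions(p))

# Subset atoms while preserving particle attributes.
keep_atoms <- function(p, idx, stage = attr(p, "stage"),
                       spec = attr(p, "spec"), center = attr(p, "center")) {
  particle(as_tibble(as.data.frame(p))[idx, , drop = FALSE],
           stage = stage, spec = spec,
           minimized = attr(p, "minimized"), center = center,
           check_overlap = FALSE)
}

set_positions <- function(p, xyz) {
  p$x <- xyz[, 1]; p$y <- xyz[, 2]; p$z <- xyz[, 3]
  p
}

#' @export
print.nc_particle <- function(x, ...) {
  cnt <- table(x$element)
  cat(sprintf("<particle> %d atoms (%s), stage '%s'%s\n",
              nrow(x),
              paste0(names(cnt), ":", cnt, collapse = " "),
              attr(x, "stage") %||% "?",
              if (isTRUE(attr(x, "minimized"))) ", minimized" else ""))
  NextMethod()
}

#' Ellipsoid specification
#'
#' Axis full lengths in nanometres plus the rotation applied to the crystal
#' lattice before carving. The ellipsoid itself is always axis-aligned with
#' the laboratory frame; the rotation reorients the lattice inside it.
#'
#' @param dx,dy,dz Axis full lengths (nm).
#' @param rotation_vector Rotation axis components (any nonzero vector).
#' @param rotation_angle Rotation angle (degrees, right-hand rule).
#' @return An `ellipsoid_spec`.
#' @export
#' @examples
#' ellipsoid_spec(2, 2, 2)                      # 2 nm sphere
#' ellipsoid_spec(5, 3.9, 3.28, c(0, 0, 1), 0)  # most stable shape of a scan
ellipsoid_spec <- function(dx, dy, dz, rotation_vector = c(0, 0, 1),
                           rotation_angle = 0) {
  stopifnot(length(rotation_vector) == 3L)
  if (!all(is.finite(c(dx, dy, dz))) || any(c(dx, dy, dz) <= 0)) {
    nc_abort("Ellipsoid axis lengths must be positive", class = "nanocarve_domain_error")
  }
  if (sum(rotation_vector^2) == 0) {
    nc_abort("Rotation vector must have nonzero norm", class = "nanocarve_axis_error")
  }
  structure(
    list(dx = dx, dy = dy, dz = dz,
         rotation_vector = as.numeric(rotation_vector),
         rotation_angle = as.numeric(rotation_angle)),
    class = "ellipsoid_spec"
  )
}

# semilengths in Angstrom (user units are nm; exact factor 10)
spec_semilengths_A <- function(spec) c(spec$dx, spec$dy, spec$dz) * 10 / 2

#' @export
print.ellipsoid_spec <- function(x, ...) {
  cat(sprintf("<ellipsoid_spec> D = [%g %g %g] nm, rotation (%g,%g,%g) @ %g deg\n",
              x$dx, x$dy, x$dz,
              x$rotation_vector[1], x$rotation_vector[2], x$rotation_vector[3],
              x$rotation_angle))
  invisible(x)
}
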