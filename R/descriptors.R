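# Geometric and atomistic descriptors of a particle, split into whole /
# core / surface regions. Core atoms lie inside the ellipsoid shrunk by a
# uniform 4 Angstrom surface thickness; everything else is surface.

#' Descriptor settings
#'
#' @param surface_thickness Uniform shell thickness separating surface from
#'   core atoms (Angstrom; default 4).
#' @param thomsen_p Exponent of the Thomsen surface-area approximation
#'   (default 1.6075, worst-case relative error about 1.061%).
#' @param single_species_factor Coordination cutoff = this factor times the
#'   ionic radius when only one species is present (default 2.4).
#' @param two_species_factor Cutoff = factor times the sum of the two ionic
#'   radii when exactly two species are present (default 1.2; like pairs use
#'   twice their own radius).
#' @param multi_species_cutoff Flat cutoff when more than two species are
#'   present (Angstrom; default 5).
#' @return A `descriptor_settings` object.
#' @export
descriptor_settings <- function(surface_thickness = 4, thomsen_p = 1.6075,
                                single_species_factor = 2.4,
                                two_species_factor = 1.2,
                                multi_species_cutoff = 5) {
  stopifnot(surface_thickness > 0, thomsen_p > 1)
  structure(list(surface_thickness = surface_thickness,
                 thomsen_p = thomsen_p,
                 single_species_factor = single_species_factor,
                 two_species_factor = two_species_factor,
                 multi_species_cutoff = multi_species_cutoff),
            class = "descriptor_settings")
}

#' Axis diameters of a particle
#'
#' Maximum extent of the atom positions along each laboratory axis
#' (`max - min` per Cartesian component, which equals the maximum pairwise
#' separation per component). Frame-dependent by definition.
#'
#' @param structure An `nc_particle`.
#' @return Named numeric vector `c(dx, dy, dz)` in Angstrom.
#' @export
axis_diameters <- function(structure) {
  stopifnot(is_particle(structure))
  if (n_atoms(structure) == 0L) {
    nc_abort("Empty particle has no axis diameters", class = "nanocarve_empty_error")
  }
  xyz <- positions(structure)
  d <- apply(xyz, 2, max) - apply(xyz, 2, min)
  setNames(d, c("dx", "dy", "dz"))
}

#' Thomsen approximate surface area of an ellipsoid
#'
#' `S = 4 pi (((ab)^p + (ac)^p + (bc)^p) / 3)^(1/p)` with `p = 1.6075`;
#' exact for spheres and within about 1.061% of the true area otherwise.
#'
#' @param rx,ry,rz Semilengths (any consistent length unit).
#' @param p Exponent (default 1.6075).
#' @return Surface area in the squared input unit.
#' @export
#' @examples
#' thomsen_surface_area(1, 1, 1)  # 4*pi, exact in the sphere limit
thomsen_surface_area <- function(rx, ry, rz, p = 1.6075) {
  if (any(c(rx, ry, rz) <= 0)) {
    nc_abort("Semilengths must be positive", class = "nanocarve_domain_error")
  }
  4 * pi * (((rx * ry)^p + (rx * rz)^p + (ry * rz)^p) / 3)^(1 / p)
}

#' Ellipsoid volume
#'
#' `V = (4/3) pi rx ry rz`.
#'
#' @inheritParams thomsen_surface_area
#' @return Volume in the cubed input unit.
#' @export
#' @examples
#' ellipsoid_volume(2, 2, 2)  # 33.51 nm^3 when semilengths are in nm
ellipsoid_volume <- function(rx, ry, rz) {
  if (any(c(rx, ry, rz) <= 0)) {
    nc_abort("Semilengths must be positive", class = "nanocarve_domain_error")
  }
  4 / 3 * pi * rx * ry * rz
}

#' Label atoms as core or surface
#'
#' An atom is core when it lies inside the ellipsoid whose semilengths are
#' reduced by the surface thickness: `(x/(Rx-t))^2 + (y/(Ry-t))^2 +
#' (z/(Rz-t))^2 <= 1` with centroid-relative coordinates. If any shrunk
#' semilength is nonpositive every atom is surface.
#'
#' @param structure An `nc_particle`.
#' @param semilengths Ellipsoid semilengths (Angstrom, length 3).
#' @param settings A [descriptor_settings()].
#' @return Character vector of `"core"` / `"surface"` labels.
#' @export
classify_core_surface <- function(structure, semilengths,
                                  settings = descriptor_settings()) {
  stopifnot(is_particle(structure), length(semilengths) == 3L)
  t <- settings$surface_thickness
  inner <- semilengths - t
  if (any(inner <= 0)) return(rep("surface", n_atoms(structure)))
  s <- ellipsoid_s(structure, inner)
  ifelse(s <= 1 + 1e-9, "core", "surface")
}

#' Coordination cutoff matrix from the species-count rule
#'
#' One species: 2.4 times its ionic radius. Two species: 1.2 times the sum
#' of the two ionic radii per pair (like pairs use twice their own radius).
#' More than two species: a flat 5 Angstrom for every pair. Radii are
#' Shannon ionic radii at the species' formal charge, falling back to
#' covalent radii (with a warning) when no ionic entry exists.
#'
#' @param species Character vector of element symbols.
#' @param charges Formal charges aligned with `species` (optional).
#' @param settings A [descriptor_settings()].
#' @return A symmetric matrix of cutoffs (Angstrom) with species dimnames.
#' @export
#' @examples
#' coordination_cutoff(c("Na", "Cl"), charges = c(1, -1))
coordination_cutoff <- function(species, charges = NULL,
                                settings = descriptor_settings()) {
  if (is.null(charges)) charges <- rep(NA_real_, length(species))
  stopifnot(length(charges) == length(species))
  o <- order(species)
  species <- species[o]; charges <- charges[o]
  keep <- !duplicated(species)
  species <- species[keep]; charges <- charges[keep]
  ns <- length(species)
  if (ns > 2L) {
    m <- matrix(settings$multi_species_cutoff, ns, ns)
  } else {
    r <- vapply(seq_len(ns),
                function(i) species_radius(species[i], charges[i]),
                numeric(1))
    m <- if (ns == 1L) {
      matrix(settings$single_species_factor * r, 1, 1)
    } else {
      settings$two_species_factor * outer(r, r, `+`)
    }
  }
  dimnames(m) <- list(species, species)
  m
}

# Resolve a cutoff argument (NULL / scalar / named matrix) plus the
# structure into the matrix + neighbor lists used by the atomistic
# descriptors.
neighbor_lists <- function(structure, cutoff = NULL,
                           settings = descriptor_settings()) {
  species <- sort(unique(structure$element))
  if (is.null(cutoff)) {
    charges <- vapply(species, function(el) {
      q <- structure$charge[structure$element == el]
      q <- q[!is.na(q)]
      if (length(q) > 0L) q[1] else NA_real_
    }, numeric(1))
    cutoff <- coordination_cutoff(species, charges, settings)
  } else if (is.matrix(cutoff)) {
    if (is.null(dimnames(cutoff))) stopifnot(nrow(cutoff) == length(species))
    else cutoff <- cutoff[species, species, drop = FALSE]
  } else {
    cutoff <- matrix(cutoff, length(species), length(species))
  }
  type <- match(structure$element, species) - 1L
  list(cutoff = cutoff,
       nbrs = neighbor_list_cpp(positions(structure), type, cutoff))
}

#' Average coordination number
#'
#' Neighbours are atoms strictly closer than the pair cutoff (see
#' [coordination_cutoff()]).
#'
#' @param structure An `nc_particle`.
#' @param cutoff Optional cutoff override: a scalar, or a species-named
#'   matrix. Default: derived from the species-count rule.
#' @param settings A [descriptor_settings()].
#' @return List with `per_atom` (integer counts) and `average`.
#' @export
avg_coordination <- function(structure, cutoff = NULL,
                             settings = descriptor_settings()) {
  nl <- neighbor_lists(structure, cutoff, settings)
  counts <- lengths(nl$nbrs)
  list(per_atom = counts, average = mean(counts))
}

#' Common neighbourhood parameter (CNP)
#'
#' For each atom i with neighbours j, the squared norm of the sum of
#' `r_ik + r_jk` over the neighbours k common to i and j, averaged over j.
#' Zero in a perfect FCC environment; atoms without neighbours score 0.
#'
#' @inheritParams avg_coordination
#' @return List with `per_atom` (Angstrom^2) and `average`.
#' @export
cnp <- function(structure, cutoff = NULL, settings = descriptor_settings()) {
  nl <- neighbor_lists(structure, cutoff, settings)
  q <- cnp_cpp(positions(structure), nl$nbrs)
  list(per_atom = q, average = mean(q))
}

#' Hexatic (six-fold bond-orientational) order parameter
#'
#' `q_k = (1/N) sum_j exp(i 6 theta_kj)` where `theta_kj` is the angle of
#' the bond vector's xy-plane projection against the x axis. Bonds with a
#' projection shorter than 1e-9 Angstrom are skipped; atoms without
#' neighbours contribute 0. The averages of the real and imaginary parts
#' are the "first" and "second" hexatic descriptors.
#'
#' @inheritParams avg_coordination
#' @return List with `per_atom` (complex), `first` (mean real part) and
#'   `second` (mean imaginary part).
#' @export
hexatic <- function(structure, cutoff = NULL,
                    settings = descriptor_settings()) {
  nl <- neighbor_lists(structure, cutoff, settings)
  q <- hexatic_from_nbrs(positions(structure), nl$nbrs)
  list(per_atom = q, first = mean(Re(q)), second = mean(Im(q)))
}

hexatic_from_nbrs <- function(xyz, nbrs) {
  vapply(seq_len(nrow(xyz)), function(k) {
    nb <- nbrs[[k]]
    if (length(nb) == 0L) return(complex(real = 0, imaginary = 0))
    dx <- xyz[nb, 1] - xyz[k, 1]
    dy <- xyz[nb, 2] - xyz[k, 2]
    keep <- sqrt(dx^2 + dy^2) >= 1e-9
    if (!any(keep)) return(complex(real = 0, imaginary = 0))
    th <- atan2(dy[keep], dx[keep])
    # average over all N neighbours; near-vertical bonds contribute nothing
    sum(exp(1i * 6 * th)) / length(nb)
  }, complex(1))
}

region_geometry <- function(structure, idx, p) {
  if (sum(idx) == 0L) {
    return(list(n = 0L, d = c(NA_real_, NA_real_, NA_real_),
                s = NA_real_, v = NA_real_))
  }
  sub <- keep_atoms(structure, idx)
  d <- axis_diameters(sub)
  semi <- pmax(d / 2, 1e-12)
  list(n = sum(idx), d = unname(d),
       s = thomsen_surface_area(semi[1], semi[2], semi[3], p),
       v = ellipsoid_volume(semi[1], semi[2], semi[3]))
}

#' Full descriptor report for a particle
#'
#' Computes the geometric descriptors (axis diameters, Thomsen surface
#' area, volume) and the atomistic descriptors (average potential energy
#' per atom, coordination, CNP, hexatic order) for the whole particle and
#' for its core and surface regions, plus core/surface ratios and
#' differences of the atomistic descriptors. Atomistic descriptors are
#' meaningful on relaxed structures, so an unminimized particle is refused
#' unless `allow_unminimized = TRUE`.
#'
#' @param structure An `nc_particle` (normally the output of
#'   [minimize_structure()]; per-atom energies are reused when present).
#' @param potential Optional `potential_model` used to fill per-atom
#'   energies when the particle has none.
#' @param settings A [descriptor_settings()].
#' @param cutoff Optional neighbour-cutoff override (see
#'   [avg_coordination()]).
#' @param semilengths Semilengths (Angstrom) defining the core/surface
#'   split: `"effective"` (default) uses half the axis diameters of the
#'   structure as given (atoms relax during minimization, so the user
#'   ellipsoid may no longer bound them), `"spec"` uses the carving
#'   ellipsoid, or pass a numeric length-3 vector.
#' @param allow_unminimized Permit descriptor calculation on a structure
#'   whose minimized flag is unset.
#' @return An `nc_descriptor_set` with a per-region tibble and a derived
#'   (ratio/difference) tibble; supports [tidy()] and [glance()].
#' @export
np_descriptors <- function(structure, potential = NULL,
                           settings = descriptor_settings(),
                           cutoff = NULL,
                           semilengths = c("effective", "spec"),
                           allow_unminimized = FALSE) {
  stopifnot(is_particle(structure))
  if (!isTRUE(attr(structure, "minimized")) && !allow_unminimized) {
    nc_abort(paste0("Structure has not been energy-minimized; atomistic ",
                    "descriptors assume a relaxed structure. Run ",
                    "minimize_structure() first or set allow_unminimized = TRUE"),
             class = "nanocarve_stage_error")
  }
  if (is.character(semilengths)) {
    semilengths <- match.arg(semilengths)
    semi <- if (semilengths == "spec") {
      spec <- attr(structure, "spec")
      if (is.null(spec)) {
        nc_abort("semilengths = 'spec' but the particle carries no ellipsoid spec",
                 class = "nanocarve_domain_error")
      }
      spec_semilengths_A(spec)
    } else {
      unname(axis_diameters(structure) / 2)
    }
  } else {
    stopifnot(length(semilengths) == 3L)
    semi <- as.numeric(semilengths)
  }

  region <- classify_core_surface(structure, semi, settings)

  energies <- structure$energy
  if (all(is.na(energies)) && !is.null(potential)) {
    energies <- total_energy(structure, potential)$per_atom
  }
  # one neighbour-list pass shared by all three atomistic descriptors
  nl <- neighbor_lists(structure, cutoff, settings)
  coord <- list(per_atom = lengths(nl$nbrs))
  qcnp <- list(per_atom = cnp_cpp(positions(structure), nl$nbrs))
  hex <- list(per_atom = hexatic_from_nbrs(positions(structure), nl$nbrs))

  region_row <- function(name, idx) {
    g <- region_geometry(structure, idx, settings$thomsen_p)
    avg <- function(v) if (g$n == 0L || all(is.na(v[idx]))) NA_real_ else mean(v[idx])
    tibble(region = name, n_atoms = g$n,
           dx = g$d[1], dy = g$d[2], dz = g$d[3],
           surface_area = g$s, volume = g$v,
           avg_energy = avg(energies),
           avg_coordination = avg(as.numeric(coord$per_atom)),
           avg_cnp = avg(qcnp$per_atom),
           hex_real = avg(Re(hex$per_atom)),
           hex_imag = avg(Im(hex$per_atom)))
  }
  regions <- bind_rows(
    region_row("whole", rep(TRUE, n_atoms(structure))),
    region_row("core", region == "core"),
    region_row("surface", region == "surface")
  )

  atomistic <- c("avg_energy", "avg_coordination", "avg_cnp",
                 "hex_real", "hex_imag")
  core <- regions[regions$region == "core", ]
  surf <- regions[regions$region == "surface", ]
  derived <- purrr::map_dfr(atomistic, function(dn) {
    cv <- core[[dn]]; sv <- surf[[dn]]
    tibble(descriptor = dn, core = cv, surface = sv,
           ratio = if (!is.na(sv) && sv != 0 && !is.na(cv)) cv / sv else NA_real_,
           difference = cv - sv)
  })

  structure(list(regions = regions, derived = derived,
                 region_labels = region, semilengths = semi,
                 settings = settings),
            class = "nc_descriptor_set")
}

#' @export
print.nc_descriptor_set <- function(x, ...) {
  cat("<descriptor_set>\n")
  print(x$regions)
  cat("core-vs-surface derived descriptors:\n")
  print(x$derived)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nc_descriptor_set <- function(x, ...) {
  tidyr::pivot_longer(x$regions, -"region",
                      names_to = "descriptor", values_to = "value")
}

#' @exportS3Method generics::glance
glance.nc_descriptor_set <- function(x, ...) {
  whole <- x$regions[x$regions$region == "whole", ]
  d <- x$derived
  wide <- setNames(as.list(c(d$ratio, d$difference)),
                   c(paste0(d$descriptor, "_ratio"),
                     paste0(d$descriptor, "_diff")))
  dplyr::bind_cols(whole[, -1], as_tibble(wide))
}
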