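# File writers/readers: XYZ (with provenance in the comment line), LAMMPS
# data files (atom_style charge), and descriptor/scan reports. All writers
# are deterministic byte-for-byte for fixed inputs.

#' Write a particle as an XYZ file
#'
#' Standard XYZ: atom count, a comment line of `key=value` provenance pairs
#' (stage, minimized flag, spec, energy), then one `El x y z` line per atom
#' with 6-decimal coordinates (a charge column is appended when the
#' particle carries formal charges, so ionic structures round-trip).
#'
#' @param structure An `nc_particle` (nonempty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  stopifnot(is_particle(structure))
  if (n_atoms(structure) == 0L) {
    nc_abort("Refusing to write an empty particle", class = "nanocarve_empty_error")
  }
  spec <- attr(structure, "spec")
  kv <- c(
    stage = attr(structure, "stage") %||% "constructed",
    minimized = tolower(as.character(isTRUE(attr(structure, "minimized"))))
  )
  if (!is.null(spec)) {
    kv["spec"] <- paste(c(spec$dx, spec$dy, spec$dz, spec$rotation_vector,
                          spec$rotation_angle), collapse = ",")
  }
  if (!all(is.na(structure$energy))) {
    kv["energy"] <- sprintf("%.8f", sum(structure$energy))
  }
  has_q <- !all(is.na(structure$charge))
  if (has_q) kv["charges"] <- "true"
  comment <- paste(paste0(names(kv), "=", kv), collapse = " ")
  body <- if (has_q) {
    sprintf("%s %.6f %.6f %.6f %.4f", structure$element,
            structure$x, structure$y, structure$z,
            ifelse(is.na(structure$charge), 0, structure$charge))
  } else {
    sprintf("%s %.6f %.6f %.6f", structure$element,
            structure$x, structure$y, structure$z)
  }
  writeLines(c(as.character(n_atoms(structure)), comment, body), path)
  invisible(path)
}

#' Read an XYZ file back into a particle
#'
#' Restores the provenance attributes written by [write_xyz()] when the
#' comment line carries them.
#'
#' @param path XYZ file path.
#' @return An `nc_particle`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) {
    nc_abort("Malformed XYZ file: fewer than 3 lines", class = "nanocarve_parse_error")
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L || length(lines) < 2L + n) {
    nc_abort("Malformed XYZ file: bad atom count", class = "nanocarve_parse_error")
  }
  kv <- list()
  for (tok in strsplit(trimws(lines[2]), "[[:space:]]+")[[1]]) {
    if (grepl("=", tok, fixed = TRUE)) {
      p <- strsplit(tok, "=", fixed = TRUE)[[1]]
      kv[[p[1]]] <- p[2]
    }
  }
  toks <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  ncol <- unique(lengths(toks))
  if (length(ncol) != 1L || !ncol %in% c(4L, 5L)) {
    nc_abort("Malformed XYZ atom lines", class = "nanocarve_parse_error")
  }
  m <- do.call(rbind, toks)
  atoms <- tibble(
    element = m[, 1],
    x = as.numeric(m[, 2]), y = as.numeric(m[, 3]), z = as.numeric(m[, 4]),
    charge = if (ncol == 5L) as.numeric(m[, 5]) else NA_real_
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    nc_abort("Malformed XYZ coordinates", class = "nanocarve_parse_error")
  }
  spec <- NULL
  if (!is.null(kv$spec)) {
    v <- as.numeric(strsplit(kv$spec, ",", fixed = TRUE)[[1]])
    if (length(v) == 7L) spec <- ellipsoid_spec(v[1], v[2], v[3], v[4:6], v[7])
  }
  particle(atoms,
           stage = kv$stage %||% "constructed",
           spec = spec,
           minimized = identical(kv$minimized, "true"),
           check_overlap = FALSE)
}

#' Write a LAMMPS data file (atom_style charge)
#'
#' Emits `id type q x y z` atoms with type ids assigned by sorted element
#' symbol, masses from the bundled periodic table, and an axis-aligned
#' bounding box padded by 10 Angstrom (a cluster in vacuum). This file is
#' the bridge to external force-field engines: feed it to a LAMMPS run
#' (e.g. with a charge-optimised many-body potential) to score the exact
#' atom set this package constructed.
#'
#' @param structure An `nc_particle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(structure, path) {
  stopifnot(is_particle(structure))
  if (n_atoms(structure) == 0L) {
    nc_abort("Refusing to write an empty particle", class = "nanocarve_empty_error")
  }
  species <- sort(unique(structure$element))
  type <- match(structure$element, species)
  xyz <- positions(structure)
  lo <- apply(xyz, 2, min) - 10
  hi <- apply(xyz, 2, max) + 10
  q <- ifelse(is.na(structure$charge), 0, structure$charge)
  lines <- c(
    "LAMMPS data file: nanocarve cluster in vacuum (atom_style charge)",
    "",
    sprintf("%d atoms", n_atoms(structure)),
    sprintf("%d atom types", length(species)),
    "",
    sprintf("%.6f %.6f xlo xhi", lo[1], hi[1]),
    sprintf("%.6f %.6f ylo yhi", lo[2], hi[2]),
    sprintf("%.6f %.6f zlo zhi", lo[3], hi[3]),
    "",
    "Masses",
    "",
    sprintf("%d %.4f  # %s", seq_along(species),
            vapply(species, element_mass, numeric(1)), species),
    "",
    "Atoms  # charge",
    "",
    sprintf("%d %d %.6f %.6f %.6f %.6f",
            seq_len(n_atoms(structure)), type, q,
            xyz[, 1], xyz[, 2], xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a descriptor report as CSV and/or JSON
#'
#' CSV: one row per region followed by the derived ratio/difference block
#' (long format, stable column set). JSON: an object with `regions` and
#' `derived` arrays.
#'
#' @param descriptors An `nc_descriptor_set` from [np_descriptors()].
#' @param csv Optional CSV output path.
#' @param json Optional JSON output path.
#' @return Invisibly, the descriptor set.
#' @export
write_descriptor_report <- function(descriptors, csv = NULL, json = NULL) {
  stopifnot(inherits(descriptors, "nc_descriptor_set"))
  if (!is.null(csv)) {
    utils::write.csv(descriptors$regions, csv, row.names = FALSE)
    derived_csv <- sub("(\\.[^.]*)?$", "_derived\\1", csv)
    utils::write.csv(descriptors$derived, derived_csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(regions = descriptors$regions, derived = descriptors$derived,
           semilengths = descriptors$semilengths,
           surface_thickness = descriptors$settings$surface_thickness),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(descriptors)
}

#' Write a scan result as CSV
#'
#' Mirrors the shape-scan / rotation-scan table structure: run id or angle,
#' axes, volume, atom count, average potential energy per atom and the
#' minimizer termination reason.
#'
#' @param scan An `nc_shape_scan` or `nc_rotation_scan` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}

#' Write a growth pathway as JSON
#'
#' Nodes of the chosen path plus every scored candidate per step.
#'
#' @param pathway An `nc_growth_path`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_json <- function(pathway, path) {
  stopifnot(inherits(pathway, "nc_growth_path"))
  jsonlite::write_json(
    list(status = pathway$status, target = pathway$target,
         moves = pathway$moves, path = pathway$path,
         candidates = pathway$candidates),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
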