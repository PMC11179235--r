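# Pluggable pair potentials over finite clusters: Lennard-Jones and
# Buckingham, optionally with a direct (cutoff-free) Coulomb sum on formal
# charges. Every pair term is split half-and-half onto its two atoms, so the
# per-atom energies sum exactly to the total.

K_COULOMB <- 14.399645  # eV * Angstrom / e^2

#' Lennard-Jones pair potential
#'
#' `E(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)` for `r < cutoff`. Parameters
#' are per species pair; a pair with `el1 = "*"` applies to every pair not
#' otherwise matched.
#'
#' @param pairs Data frame with columns `el1`, `el2`, `epsilon` (eV),
#'   `sigma` (Angstrom), `cutoff` (Angstrom). Alternatively leave `NULL` and
#'   give scalar `epsilon`, `sigma`, `cutoff` for a universal single set.
#' @param epsilon,sigma,cutoff Scalars used when `pairs` is `NULL`.
#' @param coulomb Add a direct Coulomb sum over formal charges?
#' @return A `potential_model`.
#' @export
#' @examples
#' lj <- lj_potential(epsilon = 1, sigma = 1, cutoff = 10)
lj_potential <- function(pairs = NULL, epsilon = NULL, sigma = NULL,
                         cutoff = NULL, coulomb = FALSE) {
  if (is.null(pairs)) {
    stopifnot(!is.null(epsilon), !is.null(sigma), !is.null(cutoff))
    pairs <- tibble(el1 = "*", el2 = "*", epsilon = epsilon,
                    sigma = sigma, cutoff = cutoff)
  }
  pairs <- as_tibble(pairs)
  stopifnot(all(c("el1", "el2", "epsilon", "sigma", "cutoff") %in% names(pairs)))
  if (any(pairs$epsilon < 0 | pairs$sigma <= 0 | pairs$cutoff <= 0)) {
    nc_abort("LJ parameters must satisfy epsilon >= 0, sigma > 0, cutoff > 0",
             class = "nanocarve_parameter_error")
  }
  structure(list(style = "lj", pairs = pairs, coulomb = coulomb),
            class = "potential_model")
}

#' Buckingham (+ optional Coulomb) pair potential
#'
#' `E(r) = A exp(-r/rho) - C/r^6` for `r < cutoff`, plus, when `coulomb` is
#' on, `k q_i q_j / r` over all pairs with `k = 14.399645` eV A/e^2.
#'
#' @param pairs Data frame with columns `el1`, `el2`, `A` (eV), `rho`
#'   (Angstrom), `C` (eV A^6), `cutoff` (Angstrom). `A = 0` rows disable the
#'   short-range term for that pair.
#' @param coulomb Add the Coulomb sum (default `TRUE`; this family is meant
#'   for ionic systems).
#' @return A `potential_model`.
#' @export
buckingham_potential <- function(pairs, coulomb = TRUE) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("el1", "el2", "A", "rho", "C", "cutoff") %in% names(pairs)))
  if (any(pairs$rho <= 0 | pairs$cutoff <= 0)) {
    nc_abort("Buckingham parameters must satisfy rho > 0 and cutoff > 0",
             class = "nanocarve_parameter_error")
  }
  structure(list(style = "buckingham", pairs = pairs, coulomb = coulomb),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model> style %s, %d pair row(s)%s\n",
              x$style, nrow(x$pairs), if (x$coulomb) ", Coulomb on" else ""))
  invisible(x)
}

#' Read a potential parameter file
#'
#' Plain key-value schema: a `style lj|buckingham` line, an optional
#' `coulomb on|off` line, then one `pair` line per species pair:
#' `pair EL1 EL2 <params> <cutoff>` with params `epsilon sigma` (lj) or
#' `A rho C` (buckingham). `*` is the wildcard species. Lines starting with
#' `#` are comments.
#'
#' @param path File path.
#' @return A `potential_model`.
#' @export
read_potential_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  style <- NULL; coulomb <- FALSE; rows <- list()
  for (tk in toks) {
    key <- tolower(tk[1])
    if (key == "style") style <- tolower(tk[2])
    else if (key == "coulomb") coulomb <- tolower(tk[2]) %in% c("on", "true", "yes")
    else if (key == "pair") rows[[length(rows) + 1L]] <- tk[-1]
    else nc_abort(paste0("Unknown potential-file keyword: ", tk[1]),
                  class = "nanocarve_parameter_error")
  }
  if (is.null(style) || !style %in% c("lj", "buckingham")) {
    nc_abort("Potential file must declare 'style lj' or 'style buckingham'",
             class = "nanocarve_parameter_error")
  }
  np <- if (style == "lj") 3L else 4L
  bad <- vapply(rows, function(r) length(r) != 2L + np, logical(1))
  if (length(rows) == 0L || any(bad)) {
    nc_abort("Malformed pair lines in potential file",
             class = "nanocarve_parameter_error")
  }
  m <- do.call(rbind, rows)
  if (style == "lj") {
    lj_potential(tibble(el1 = m[, 1], el2 = m[, 2],
                        epsilon = as.numeric(m[, 3]),
                        sigma = as.numeric(m[, 4]),
                        cutoff = as.numeric(m[, 5])), coulomb = coulomb)
  } else {
    buckingham_potential(tibble(el1 = m[, 1], el2 = m[, 2],
                                A = as.numeric(m[, 3]),
                                rho = as.numeric(m[, 4]),
                                C = as.numeric(m[, 5]),
                                cutoff = as.numeric(m[, 6])), coulomb = coulomb)
  }
}

# Resolve the pair table into dense per-species matrices for the C++ kernel.
prepare_potential <- function(structure, potential) {
  species <- sort(unique(structure$element))
  ns <- length(species)
  pnames <- if (potential$style == "lj") c("epsilon", "sigma") else c("A", "rho", "C")
  mats <- lapply(seq_len(3), function(i) matrix(0, ns, ns))
  cut <- matrix(0, ns, ns)
  pr <- potential$pairs
  for (a in seq_len(ns)) {
    for (b in a:ns) {
      hit <- which((pr$el1 == species[a] & pr$el2 == species[b]) |
                     (pr$el1 == species[b] & pr$el2 == species[a]))
      if (length(hit) == 0L) hit <- which(pr$el1 == "*" | pr$el2 == "*")
      if (length(hit) == 0L) {
        nc_abort(paste0("No potential parameters for pair ",
                        species[a], "-", species[b]),
                 class = "nanocarve_parameter_error")
      }
      h <- hit[1L]
      for (k in seq_along(pnames)) {
        mats[[k]][a, b] <- mats[[k]][b, a] <- pr[[pnames[k]]][h]
      }
      cut[a, b] <- cut[b, a] <- pr$cutoff[h]
    }
  }
  q <- structure$charge
  if (potential$coulomb) {
    if (all(is.na(q))) {
      nc_abort("Coulomb term enabled but the structure has no formal charges",
               class = "nanocarve_parameter_error")
    }
    q[is.na(q)] <- 0
  } else {
    q <- rep(0, n_atoms(structure))
  }
  list(species = species,
       type = match(structure$element, species) - 1L,
       style = if (potential$style == "lj") 1L else 2L,
       p1 = mats[[1]], p2 = mats[[2]], p3 = mats[[3]], cutoff = cut,
       q = q)
}

eval_energy <- function(xyz, prep, potential, want_forces = TRUE) {
  pair_energy_cpp(xyz, prep$type, prep$style, prep$p1, prep$p2, prep$p3,
                  prep$cutoff, prep$q, potential$coulomb, K_COULOMB,
                  want_forces)
}

#' Total potential energy with per-atom partition
#'
#' Sums all pair terms within their cutoffs (plus the full Coulomb sum when
#' the potential enables it). Half of each pair term is assigned to each
#' partner, so `sum(per_atom)` equals `total` as a summation identity.
#'
#' @param structure An `nc_particle`.
#' @param potential A `potential_model`.
#' @return List with `total` (eV) and `per_atom` (eV, one per atom).
#' @export
#' @examples
#' dimer <- particle(data.frame(element = "Ar",
#'   x = c(0, 2^(1/6)), y = 0, z = 0))
#' total_energy(dimer, lj_potential(epsilon = 1, sigma = 1, cutoff = 10))
total_energy <- function(structure, potential) {
  stopifnot(is_particle(structure), inherits(potential, "potential_model"))
  prep <- prepare_potential(structure, potential)
  res <- eval_energy(positions(structure), prep, potential, want_forces = FALSE)
  list(total = res$total, per_atom = res$per_atom)
}

#' Analytic forces
#'
#' Negative gradient of [total_energy()]; the net force over the cluster is
#' zero (translation invariance of the pair sums).
#'
#' @inheritParams total_energy
#' @return An `n x 3` matrix of forces (eV/Angstrom).
#' @export
forces <- function(structure, potential) {
  stopifnot(is_particle(structure), inherits(potential, "potential_model"))
  prep <- prepare_potential(structure, potential)
  eval_energy(positions(structure), prep, potential, want_forces = TRUE)$forces
}
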