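# Unit cells: lattice parameters + symmetry-expanded fractional sites.
# The cell is the seed of every construction; all carving happens on the
# Cartesian supercell derived from it.

FRAC_TOL <- 1e-3  # dedup tolerance for symmetry-equivalent sites (fractional)

#' Construct a unit cell
#'
#' Builds a `unit_cell` from lattice parameters and asymmetric-unit sites,
#' expanding the sites under the given symmetry operators, wrapping all
#' fractional coordinates into `[0, 1)` and removing duplicates at a
#' fractional tolerance of 1e-3.
#'
#' @param a,b,c Cell edge lengths (Angstrom).
#' @param alpha,beta,gamma Cell angles (degrees).
#' @param sites Data frame with columns `element`, `fx`, `fy`, `fz` and
#'   optionally `charge` (formal charge, e) and `occupancy` (must be 1).
#' @param symmetry_ops Character vector of operators in `"x,y,z"` notation
#'   (rational translations such as `"1/2+x"` allowed). Default: identity.
#' @param expand Expand sites under `symmetry_ops`? Set `FALSE` when `sites`
#'   is already a full P1 list (operators are then recorded but not applied).
#' @return A `unit_cell`: lattice parameters, a 3x3 `lattice` matrix whose
#'   rows are the cell vectors (a along x, b in the xy-plane), the expanded
#'   `sites` tibble, `symmetry_ops`, and `formula_unit` (named integer
#'   vector, coprime counts).
#' @export
#' @examples
#' cell <- unit_cell(4, 4, 4, sites = data.frame(
#'   element = "Ti", fx = 0, fy = 0, fz = 0))
#' cell$formula_unit
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      sites, symmetry_ops = "x,y,z", expand = TRUE) {
  if (!all(is.finite(c(a, b, c, alpha, beta, gamma))) || any(c(a, b, c) <= 0)) {
    nc_abort("Cell parameters must be finite and lengths positive",
             class = "nanocarve_parse_error")
  }
  sites <- as_tibble(sites)
  required <- c("element", "fx", "fy", "fz")
  if (!all(required %in% names(sites)) || nrow(sites) == 0L) {
    nc_abort("`sites` needs columns element, fx, fy, fz and at least one row",
             class = "nanocarve_parse_error")
  }
  if (!all(is_known_element(sites$element))) {
    nc_abort(paste0("Unknown element symbol(s): ",
                    paste(setdiff(sites$element, periodic_table()$symbol),
                          collapse = ", ")),
             class = "nanocarve_parse_error")
  }
  if (!"charge" %in% names(sites)) sites$charge <- NA_real_
  if (!"occupancy" %in% names(sites)) sites$occupancy <- 1
  if (any(abs(sites$occupancy - 1) > 1e-3)) {
    nc_abort("Partial site occupancy is not supported (carving a disordered cell is undefined)",
             class = "nanocarve_occupancy_error")
  }

  ops <- lapply(symmetry_ops, parse_symop)
  expanded <- if (expand) expand_sites(sites, ops) else wrap_dedup_sites(sites)

  charges <- expanded$charge
  if (any(!is.na(charges) & charges != 0)) {
    qtot <- sum(ifelse(is.na(charges), 0, charges) * expanded$occupancy)
    if (abs(qtot) > 1e-6 * nrow(expanded)) {
      nc_abort(sprintf("Unit cell is not charge neutral (total %.4g e)", qtot),
               class = "nanocarve_neutrality_error")
    }
  }

  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         lattice = lattice_matrix(a, b, c, alpha, beta, gamma),
         sites = expanded,
         symmetry_ops = symmetry_ops,
         formula_unit = formula_unit_counts(expanded$element)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g A  alpha=%g beta=%g gamma=%g deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  fu <- paste0(names(x$formula_unit), x$formula_unit, collapse = " ")
  cat(sprintf("  %d sites, formula unit %s, %d symmetry operator(s)\n",
              nrow(x$sites), fu, length(x$symmetry_ops)))
  invisible(x)
}

# Rows are the lattice vectors: a along x, b in the xy-plane.
lattice_matrix <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) nc_abort("Degenerate cell angles", class = "nanocarve_parse_error")
  rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(v) / sg)
  )
}

# "x,y,z"-notation operator -> 3x4 affine matrix [R | t] acting on fractional
# coordinates. Accepts rational ("1/2") and decimal translations.
parse_symop <- function(op) {
  comps <- strsplit(tolower(gsub("[[:space:]'\"]", "", op)), ",", fixed = TRUE)[[1]]
  if (length(comps) != 3L) {
    nc_abort(paste0("Malformed symmetry operator: ", op),
             class = "nanocarve_parse_error")
  }
  M <- matrix(0, 3, 4)
  for (i in 1:3) {
    terms <- regmatches(comps[i], gregexpr("[+-]?[^+-]+", comps[i]))[[1]]
    for (term in terms) {
      sgn <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        M[i, match(body, c("x", "y", "z"))] <- M[i, match(body, c("x", "y", "z"))] + sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        pq <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        M[i, 4] <- M[i, 4] + sgn * pq[1] / pq[2]
      } else if (grepl("^[0-9]*\\.?[0-9]+$", body)) {
        M[i, 4] <- M[i, 4] + sgn * as.numeric(body)
      } else {
        nc_abort(paste0("Cannot parse symmetry term '", term, "' in: ", op),
                 class = "nanocarve_parse_error")
      }
    }
  }
  M
}

wrap_frac <- function(x) {
  x <- x - floor(x)
  x[x > 1 - 1e-9] <- 0
  x
}

# Periodic fractional distance per component.
frac_delta <- function(d) {
  d <- abs(d - round(d))
  d
}

wrap_dedup_sites <- function(sites, tol = FRAC_TOL) {
  sites$fx <- wrap_frac(sites$fx)
  sites$fy <- wrap_frac(sites$fy)
  sites$fz <- wrap_frac(sites$fz)
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!keep[i]) next
    if (i < nrow(sites)) {
      j <- (i + 1):nrow(sites)
      dup <- keep[j] &
        sites$element[j] == sites$element[i] &
        frac_delta(sites$fx[j] - sites$fx[i]) < tol &
        frac_delta(sites$fy[j] - sites$fy[i]) < tol &
        frac_delta(sites$fz[j] - sites$fz[i]) < tol
      keep[j][dup] <- FALSE
    }
  }
  sites[keep, ]
}

expand_sites <- function(sites, ops, tol = FRAC_TOL) {
  out <- purrr::map_dfr(ops, function(M) {
    f <- as.matrix(sites[, c("fx", "fy", "fz")]) %*% t(M[, 1:3]) +
      matrix(M[, 4], nrow(sites), 3, byrow = TRUE)
    tibble(element = sites$element,
           fx = f[, 1], fy = f[, 2], fz = f[, 3],
           charge = sites$charge, occupancy = sites$occupancy)
  })
  wrap_dedup_sites(out, tol)
}

formula_unit_counts <- function(elements) {
  counts <- table(elements)
  g <- Reduce(gcd2, as.integer(counts))
  setNames(as.integer(counts) %/% g, names(counts))
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

frac_to_cart <- function(frac, lattice) as.matrix(frac) %*% lattice

#' Substitute one element for another throughout a cell
#'
#' Relabels every site of element `old` as `new`, leaving geometry, charges
#' and occupancies untouched. The replacement must be chemically plausible:
#' `new` must share `old`'s IUPAC group and sit at most one period away
#' (see [substitution_candidates()]).
#'
#' @param cell A `unit_cell`.
#' @param old,new Element symbols.
#' @return The relabelled `unit_cell`.
#' @export
#' @examples
#' rutile <- generate_fixture("rutile_MO2")$cell
#' zirconia <- substitute_element(rutile, "Ti", "Zr")
#' zirconia$formula_unit
substitute_element <- function(cell, old, new) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!old %in% cell$sites$element) {
    nc_abort(paste0(old, " does not occur in the cell"),
             class = "nanocarve_notfound_error")
  }
  if (!new %in% substitution_candidates(old)) {
    nc_abort(paste0(old, " -> ", new, " is not an allowed substitution ",
                    "(same group, at most one period away, not self)"),
             class = "nanocarve_substitution_error")
  }
  cell$sites$element[cell$sites$element == old] <- new
  names(cell$formula_unit)[names(cell$formula_unit) == old] <- new
  cell$formula_unit <- cell$formula_unit[order(names(cell$formula_unit))]
  cell
}
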