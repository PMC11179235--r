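# Built-in crystal fixtures: small, well-known structure types emitted as
# P1 CIF text so the whole pipeline is runnable and testable without any
# database download. These are first-class generators, not test stubs.

#' Generate a reference crystal structure
#'
#' Three structure types cover the shapes the builder and descriptors are
#' designed around:
#' \describe{
#'   \item{`rutile_MO2`}{Tetragonal rutile-type MO2 (P4_2/mnm arrangement):
#'     2 metal atoms at (0,0,0) and (1/2,1/2,1/2), 4 oxygens at
#'     (u,u,0), (1-u,1-u,0), (1/2+u,1/2-u,1/2), (1/2-u,1/2+u,1/2).
#'     Defaults are the rutile titania cell (a = 4.593, c = 2.959 A,
#'     u = 0.305) with formal charges +4/-2.}
#'   \item{`rocksalt`}{Cubic AB rock salt, 4 + 4 sites, defaults Na/Cl with
#'     a = 5.64 A and charges +1/-1.}
#'   \item{`fcc`}{Single-species face-centred cubic, 4 sites, default
#'     Al with a = 4.05 A, no charges.}
#' }
#'
#' @param name One of `"rutile_MO2"`, `"rocksalt"`, `"fcc"`.
#' @param element Metal / first species symbol (fixture-dependent default).
#' @param element_b Second species for `rocksalt` (default `"Cl"`).
#' @param a,c Cell edges (Angstrom); `c` applies to `rutile_MO2` only.
#' @param u Rutile internal oxygen coordinate, in (0, 0.5).
#' @param charges Emit formal charges? (ignored for `fcc`).
#' @return List with `cif` (character vector, P1 CIF) and `cell`
#'   (the parsed [unit_cell()]).
#' @export
#' @examples
#' fx <- generate_fixture("rutile_MO2")
#' fx$cell$formula_unit
generate_fixture <- function(name = c("rutile_MO2", "rocksalt", "fcc"),
                             element = NULL, element_b = "Cl",
                             a = NULL, c = NULL, u = 0.305,
                             charges = TRUE) {
  name <- match.arg(name)
  if (name == "rutile_MO2") {
    element <- element %||% "Ti"
    a <- a %||% 4.593
    c <- c %||% 2.959
    if (a <= 0 || c <= 0 || u <= 0 || u >= 0.5) {
      nc_abort("rutile_MO2 needs a > 0, c > 0 and u in (0, 0.5)",
               class = "nanocarve_domain_error")
    }
    sites <- tibble(
      element = c(element, element, "O", "O", "O", "O"),
      fx = c(0, 0.5, u, 1 - u, 0.5 + u, 0.5 - u),
      fy = c(0, 0.5, u, 1 - u, 0.5 - u, 0.5 + u),
      fz = c(0, 0.5, 0, 0, 0.5, 0.5),
      charge = if (charges) c(4, 4, -2, -2, -2, -2) else NA_real_
    )
    cell <- unit_cell(a, a, c, sites = sites, expand = FALSE)
  } else if (name == "rocksalt") {
    element <- element %||% "Na"
    a <- a %||% 5.64
    if (a <= 0) nc_abort("rocksalt needs a > 0", class = "nanocarve_domain_error")
    fcc0 <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
    fcc1 <- rbind(c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5), c(0.5, 0.5, 0.5))
    sites <- tibble(
      element = c(rep(element, 4), rep(element_b, 4)),
      fx = c(fcc0[, 1], fcc1[, 1]),
      fy = c(fcc0[, 2], fcc1[, 2]),
      fz = c(fcc0[, 3], fcc1[, 3]),
      charge = if (charges) c(rep(1, 4), rep(-1, 4)) else NA_real_
    )
    cell <- unit_cell(a, a, a, sites = sites, expand = FALSE)
  } else {
    element <- element %||% "Al"
    a <- a %||% 4.05
    if (a <= 0) nc_abort("fcc needs a > 0", class = "nanocarve_domain_error")
    f <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
    sites <- tibble(element = element, fx = f[, 1], fy = f[, 2], fz = f[, 3])
    cell <- unit_cell(a, a, a, sites = sites, expand = FALSE)
  }
  list(cif = write_cif_p1(cell), cell = cell)
}
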