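# Bundled periodic-table data: IUPAC group/period, atomic mass, Cordero
# covalent radii, and Shannon ionic radii (VI coordination) keyed by formal
# oxidation state. Loaded once per session.

the <- new.env(parent = emptyenv())

pt_path <- function(file) {
  system.file("extdata", file, package = "nanocarve", mustWork = TRUE)
}

#' Periodic-table reference data
#'
#' Returns the bundled element table used for substitution rules, LAMMPS
#' masses and coordination cutoffs: atomic number, symbol, period, IUPAC
#' group (NA for the f-block), standard atomic mass (u) and covalent radius
#' (Angstrom).
#'
#' @return A tibble with one row per element (Z = 1..86).
#' @export
#' @examples
#' periodic_table()
periodic_table <- function() {
  if (is.null(the$ptable)) {
    tab <- read.delim(pt_path("periodic_table.tsv"), stringsAsFactors = FALSE)
    the$ptable <- as_tibble(tab)
  }
  the$ptable
}

#' Shannon ionic radii
#'
#' The bundled Shannon ionic radius table (VI coordination, Angstrom) keyed
#' by element symbol and formal charge.
#'
#' @return A tibble with columns `symbol`, `charge`, `radius`.
#' @export
shannon_radii <- function() {
  if (is.null(the$shannon)) {
    the$shannon <- as_tibble(
      read.delim(pt_path("shannon_radii.tsv"), stringsAsFactors = FALSE)
    )
  }
  the$shannon
}

element_info <- function(symbol) {
  tab <- periodic_table()
  i <- match(symbol, tab$symbol)
  if (anyNA(i)) {
    nc_abort(
      paste0("Unknown element symbol(s): ",
             paste(unique(symbol[is.na(i)]), collapse = ", ")),
      class = "nanocarve_parse_error"
    )
  }
  tab[i, ]
}

is_known_element <- function(symbol) symbol %in% periodic_table()$symbol

#' Ionic (or fallback covalent) radius of a species
#'
#' Looks up the Shannon ionic radius for `symbol` at formal charge `charge`;
#' when the charge is zero, missing, or has no tabulated entry, falls back to
#' the covalent radius with a warning.
#'
#' @param symbol Element symbol.
#' @param charge Formal charge in units of e (may be `NA` or 0).
#' @param quiet Suppress the fallback warning.
#' @return Radius in Angstrom (scalar).
#' @export
species_radius <- function(symbol, charge = NA_real_, quiet = FALSE) {
  stopifnot(length(symbol) == 1L)
  if (!is.na(charge) && charge != 0) {
    sh <- shannon_radii()
    hit <- which(sh$symbol == symbol & sh$charge == round(charge))
    if (length(hit) >= 1L) return(sh$radius[hit[1L]])
  }
  info <- element_info(symbol)
  if (!quiet) {
    warn(paste0("No Shannon radius for ", symbol,
                if (!is.na(charge)) paste0(" (charge ", charge, ")") else "",
                "; using covalent radius ", info$covalent_radius, " A"))
  }
  info$covalent_radius
}

#' Allowed substitution partners for an element
#'
#' Elements eligible to replace `element` in a crystal: same IUPAC group and
#' at most one period away (the element itself excluded). f-block elements
#' carry no IUPAC group and cannot be substituted.
#'
#' @param element Element symbol.
#' @return Character vector of candidate symbols (possibly empty).
#' @export
#' @examples
#' substitution_candidates("Ti")  # "Zr": group 4, one period down
#' substitution_candidates("Zr")  # "Ti" and "Hf"
substitution_candidates <- function(element) {
  info <- element_info(element)
  if (is.na(info$group)) {
    nc_abort(
      paste0(element, " has no IUPAC group (f-block); substitution is not supported"),
      class = "nanocarve_substitution_error"
    )
  }
  tab <- periodic_table()
  cand <- tab$symbol[!is.na(tab$group) &
                       tab$group == info$group &
                       abs(tab$period - info$period) <= 1L &
                       tab$symbol != element]
  sort(cand)
}

element_mass <- function(symbol) element_info(symbol)$mass
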