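# Minimal CIF dialect reader/writer for COD-style files: cell parameters,
# one symmetry-operator loop, fractional atom sites with optional charge
# suffixes ("Zr4+") and occupancies. Everything else is ignored.

#' Parse a CIF document into a unit cell
#'
#' Reads the minimal crystallographic dialect this package supports:
#' `_cell_length_*` / `_cell_angle_*`, a symmetry loop
#' (`_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz`;
#' identity assumed when absent), and an atom-site loop with
#' `_atom_site_fract_{x,y,z}`, `_atom_site_type_symbol` (or `_atom_site_label`)
#' and optional `_atom_site_occupancy`. Charge suffixes on type symbols
#' (`"Ti4+"`, `"O2-"`) become formal charges. Sites are symmetry-expanded,
#' wrapped and deduplicated (see [unit_cell()]).
#'
#' @param x Path to a CIF file, or the document itself as a character vector
#'   (one string or one element per line).
#' @return A [unit_cell()].
#' @export
parse_cif <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- sub("^#.*$", "", lines)
  lines <- trimws(lines)

  kv <- list()      # non-loop tag -> raw token
  loops <- list()   # each: list(tags = chr, rows = list of chr vectors)

  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "data_")) { i <- i + 1L; next }
    if (tolower(ln) == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, tolower(strsplit(lines[i], "[[:space:]]+")[[1]][1]))
        i <- i + 1L
      }
      vals <- character()
      while (i <= n && !startsWith(lines[i], "_") &&
             !startsWith(lines[i], "data_") &&
             tolower(lines[i]) != "loop_") {
        if (lines[i] != "") vals <- c(vals, cif_tokens(lines[i]))
        i <- i + 1L
      }
      if (length(tags) > 0L && length(vals) %% length(tags) == 0L &&
          length(vals) > 0L) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        loops[[length(loops) + 1L]] <- list(tags = tags, values = m)
      }
      next
    }
    if (startsWith(ln, "_")) {
      toks <- cif_tokens(ln)
      if (length(toks) >= 2L) kv[[tolower(toks[1])]] <- toks[2]
      i <- i + 1L
      next
    }
    i <- i + 1L
  }

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  if (!all(need %in% names(kv))) {
    nc_abort("CIF is missing cell length parameters", class = "nanocarve_parse_error")
  }
  num <- function(tag, default = NULL) {
    if (is.null(kv[[tag]])) {
      if (is.null(default)) {
        nc_abort(paste0("CIF is missing ", tag), class = "nanocarve_parse_error")
      }
      return(default)
    }
    cif_number(kv[[tag]])
  }

  ops <- "x,y,z"
  for (lp in loops) {
    hit <- lp$tags %in% c("_symmetry_equiv_pos_as_xyz",
                          "_space_group_symop_operation_xyz")
    if (any(hit)) ops <- unname(gsub("['\"]", "", lp$values[, which(hit)[1]]))
  }

  site_loop <- NULL
  for (lp in loops) {
    if (all(c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
            %in% lp$tags)) site_loop <- lp
  }
  if (is.null(site_loop)) {
    nc_abort("CIF has no atom-site loop with fractional coordinates",
             class = "nanocarve_parse_error")
  }
  col <- function(tag) {
    j <- match(tag, site_loop$tags)
    if (is.na(j)) NULL else site_loop$values[, j]
  }
  type_raw <- col("_atom_site_type_symbol") %||% col("_atom_site_label")
  if (is.null(type_raw)) {
    nc_abort("Atom-site loop lacks both type symbol and label",
             class = "nanocarve_parse_error")
  }
  parsed <- parse_type_symbols(type_raw)
  occ <- col("_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, nrow(site_loop$values)) else
    vapply(occ, cif_number, numeric(1))

  sites <- tibble(
    element = parsed$element,
    fx = vapply(col("_atom_site_fract_x"), cif_number, numeric(1)),
    fy = vapply(col("_atom_site_fract_y"), cif_number, numeric(1)),
    fz = vapply(col("_atom_site_fract_z"), cif_number, numeric(1)),
    charge = parsed$charge,
    occupancy = occ
  )

  unit_cell(
    a = num("_cell_length_a"), b = num("_cell_length_b"), c = num("_cell_length_c"),
    alpha = num("_cell_angle_alpha", 90), beta = num("_cell_angle_beta", 90),
    gamma = num("_cell_angle_gamma", 90),
    sites = sites, symmetry_ops = ops
  )
}

cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)[[1]]
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

# "4.5930(2)" -> 4.593
cif_number <- function(tok) {
  v <- suppressWarnings(as.numeric(sub("\\(.*\\)$", "", tok)))
  if (is.na(v)) {
    nc_abort(paste0("Expected a number in CIF, got '", tok, "'"),
             class = "nanocarve_parse_error")
  }
  v
}

# "Zr4+", "O2-", "O-2", "Ti" (or labels like "Ti1") -> element + formal charge
parse_type_symbols <- function(x) {
  sym <- sub("^([A-Z][a-z]?).*$", "\\1", x)
  rest <- substr(x, nchar(sym) + 1L, nchar(x))
  charge <- rep(NA_real_, length(x))
  m1 <- regexpr("^([0-9]+)([+-])$", rest)
  m2 <- regexpr("^([+-])([0-9]+)$", rest)
  for (i in seq_along(x)) {
    r <- rest[i]
    if (grepl("^[0-9]+[+-]$", r)) {
      charge[i] <- as.numeric(sub("[+-]$", "", r)) *
        (if (endsWith(r, "-")) -1 else 1)
    } else if (grepl("^[+-][0-9]+$", r)) {
      charge[i] <- as.numeric(r)
    } else if (r %in% c("+", "-")) {
      charge[i] <- if (r == "-") -1 else 1
    }
  }
  bad <- !sym %in% periodic_table()$symbol
  if (any(bad)) {
    nc_abort(paste0("Unknown element symbol(s) in CIF: ",
                    paste(unique(x[bad]), collapse = ", ")),
             class = "nanocarve_parse_error")
  }
  list(element = sym, charge = charge)
}

#' Write a unit cell as a P1 CIF
#'
#' Emits the symmetry-expanded cell with the identity as its only operator,
#' suitable for round-tripping through [parse_cif()].
#'
#' @param cell A `unit_cell`.
#' @param path Optional output file; when `NULL` the document is returned as
#'   a character vector of lines.
#' @return `path` (invisibly) or the CIF text.
#' @export
write_cif_p1 <- function(cell, path = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  s <- cell$sites
  type_symbol <- ifelse(
    is.na(s$charge) | s$charge == 0, s$element,
    paste0(s$element, abs(s$charge), ifelse(s$charge < 0, "-", "+"))
  )
  lines <- c(
    "data_nanocarve",
    sprintf("_cell_length_a %.6f", cell$a),
    sprintf("_cell_length_b %.6f", cell$b),
    sprintf("_cell_length_c %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x,y,z'",
    "loop_",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    sprintf("%s %.6f %.6f %.6f %.4f",
            type_symbol, s$fx, s$fy, s$fz, s$occupancy)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
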