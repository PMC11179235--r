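# Stability-driven exploration: fixed-volume shape ranking, rotation-angle
# scans, and a greedy lowest-energy crystal-growth pathway. The stability
# metric throughout is the average potential energy per atom after
# minimization (lower = more stable). Everything is deterministic: no RNG,
# fixed tie-breaks.

#' Enumerate ellipsoid axes at fixed volume
#'
#' Given a target volume and (Dx, Dy) pairs, solves `Dz = 6V / (pi Dx Dy)`
#' so every candidate encloses the same ellipsoid volume. The reported `dz`
#' is rounded to 2 decimals; `dz_exact` is kept for carving.
#'
#' @param volume Target ellipsoid volume (nm^3).
#' @param axis_pairs Data frame (columns `dx`, `dy`) or list of length-2
#'   vectors, in nm.
#' @return Tibble with `run_id`, `dx`, `dy`, `dz` (2 d.p.), `dz_exact`,
#'   `volume`.
#' @export
#' @examples
#' enumerate_fixed_volume(33.51, list(c(4, 4), c(3, 4), c(2, 2.5)))
enumerate_fixed_volume <- function(volume, axis_pairs) {
  if (!is.finite(volume) || volume <= 0) {
    nc_abort("Volume must be positive", class = "nanocarve_domain_error")
  }
  if (is.data.frame(axis_pairs)) {
    dx <- axis_pairs$dx; dy <- axis_pairs$dy
  } else {
    m <- do.call(rbind, axis_pairs)
    dx <- m[, 1]; dy <- m[, 2]
  }
  if (any(!is.finite(c(dx, dy))) || any(c(dx, dy) <= 0)) {
    nc_abort("Axis pairs must be positive", class = "nanocarve_domain_error")
  }
  dz_solved <- 6 * volume / (pi * dx * dy)
  tibble(run_id = seq_along(dx), dx = dx, dy = dy,
         dz = round(dz_solved, 2), dz_exact = dz_solved, volume = volume)
}

# Build + minimize + score one candidate; failures are captured, not fatal.
score_candidate <- function(cell, spec, potential, settings, max_atoms) {
  tryCatch({
    np <- build_ellipsoidal_np(cell, spec, max_atoms = max_atoms)
    fit <- minimize_structure(np, potential, settings)
    list(n_atoms = n_atoms(fit$structure),
         energy_per_atom = fit$energy_per_atom,
         iterations = fit$iterations,
         termination = fit$termination,
         error = NA_character_,
         fit = fit)
  }, nanocarve_error = function(e) {
    list(n_atoms = NA_integer_, energy_per_atom = NA_real_,
         iterations = NA_integer_, termination = NA_character_,
         error = conditionMessage(e), fit = NULL)
  })
}

#' Rank candidate ellipsoid shapes by stability
#'
#' Builds, minimizes and scores each candidate, then orders them by average
#' potential energy per atom (most stable first; ties broken by run id;
#' failed candidates sink to the bottom with their error recorded).
#'
#' @param cell A [unit_cell()].
#' @param candidates Tibble from [enumerate_fixed_volume()] or any data
#'   frame with `dx`, `dy`, `dz` in nm (`dz_exact`, when present, is used
#'   for carving).
#' @param potential A `potential_model`.
#' @param settings A [minimization_settings()].
#' @param rotation_vector,rotation_angle Rotation applied to every
#'   candidate (defaults: (0,0,1) at 0 degrees).
#' @param max_atoms Supercell guard per candidate.
#' @return An `nc_shape_scan` tibble (one row per candidate, sorted).
#'   Supports [autoplot()].
#' @export
rank_shapes <- function(cell, candidates, potential,
                        settings = minimization_settings(),
                        rotation_vector = c(0, 0, 1), rotation_angle = 0,
                        max_atoms = 2e6) {
  candidates <- as_tibble(candidates)
  stopifnot(all(c("dx", "dy", "dz") %in% names(candidates)))
  if (!"run_id" %in% names(candidates)) {
    candidates$run_id <- seq_len(nrow(candidates))
  }
  dz_carve <- if ("dz_exact" %in% names(candidates)) candidates$dz_exact else
    candidates$dz
  rows <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    spec <- ellipsoid_spec(candidates$dx[i], candidates$dy[i], dz_carve[i],
                           rotation_vector, rotation_angle)
    sc <- score_candidate(cell, spec, potential, settings, max_atoms)
    tibble(run_id = candidates$run_id[i],
           dx = candidates$dx[i], dy = candidates$dy[i],
           dz = candidates$dz[i],
           volume = pi / 6 * candidates$dx[i] * candidates$dy[i] * dz_carve[i],
           n_atoms = sc$n_atoms, energy_per_atom = sc$energy_per_atom,
           iterations = sc$iterations, termination = sc$termination,
           error = sc$error)
  })
  out <- rows[order(!is.na(rows$energy_per_atom), decreasing = TRUE), ]
  out <- out[order(is.na(out$energy_per_atom), out$energy_per_atom, out$run_id), ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("nc_shape_scan", class(tibble()))
  out
}

#' Scan rotation angles at fixed ellipsoid axes
#'
#' One build + minimize per angle, axes held fixed; the result table keeps
#' the input angle order.
#'
#' @param cell A [unit_cell()].
#' @param axes Length-3 numeric, ellipsoid axis lengths (nm).
#' @param rotation_vector Rotation axis (shared by all angles).
#' @param angles Angles to scan (degrees).
#' @inheritParams rank_shapes
#' @return An `nc_rotation_scan` tibble (angle, atom count, energy per
#'   atom, termination, error). Supports [autoplot()].
#' @export
rotation_scan <- function(cell, axes, rotation_vector, angles, potential,
                          settings = minimization_settings(),
                          max_atoms = 2e6) {
  stopifnot(length(axes) == 3L, all(is.finite(angles)))
  rows <- purrr::map_dfr(angles, function(ang) {
    spec <- ellipsoid_spec(axes[1], axes[2], axes[3], rotation_vector, ang)
    sc <- score_candidate(cell, spec, potential, settings, max_atoms)
    tibble(angle = ang, dx = axes[1], dy = axes[2], dz = axes[3],
           n_atoms = sc$n_atoms, energy_per_atom = sc$energy_per_atom,
           termination = sc$termination, error = sc$error)
  })
  class(rows) <- c("nc_rotation_scan", class(tibble()))
  rows
}

#' Greedy lowest-energy crystal-growth pathway
#'
#' Starting from a small (near-spherical) particle, repeatedly grows the
#' ellipsoid by applying every allowed move (each increment added to each
#' axis in turn), scoring every candidate by average potential energy per
#' atom after minimization, and advancing to the most stable one (ties:
#' lexicographically smallest axes). Stops once the largest axis reaches
#' `target` or no candidate can be built. All per-step candidate energies
#' are retained for pathway-map plotting.
#'
#' @param cell A [unit_cell()].
#' @param start Length-3 numeric, starting axis lengths (nm), e.g.
#'   `c(2, 2, 2)` for a 2 nm sphere.
#' @param moves Numeric vector of axis increments (nm); each move is one
#'   increment applied to one axis.
#' @param target Stop once `max(axes) >= target` (nm).
#' @inheritParams rank_shapes
#' @return An `nc_growth_path`: `path` (chosen node per step), `candidates`
#'   (every scored candidate with a `chosen` flag) and a `status`
#'   (`"completed"` or `"truncated"`). Supports [autoplot()].
#' @export
growth_pathway <- function(cell, start, moves, target, potential,
                           settings = minimization_settings(),
                           rotation_vector = c(0, 0, 1), rotation_angle = 0,
                           max_atoms = 2e6) {
  stopifnot(length(start) == 3L, length(moves) >= 1L)
  if (any(start <= 0) || any(moves <= 0)) {
    nc_abort("Start axes and moves must be positive", class = "nanocarve_domain_error")
  }
  if (target <= max(start)) {
    nc_abort("Target must exceed the largest starting axis",
             class = "nanocarve_domain_error")
  }
  score_axes <- function(ax) {
    spec <- ellipsoid_spec(ax[1], ax[2], ax[3], rotation_vector, rotation_angle)
    score_candidate(cell, spec, potential, settings, max_atoms)
  }
  current <- as.numeric(start)
  sc0 <- score_axes(current)
  path <- tibble(step = 0L, dx = current[1], dy = current[2], dz = current[3],
                 n_atoms = sc0$n_atoms, energy_per_atom = sc0$energy_per_atom,
                 termination = sc0$termination)
  cand_log <- list()
  status <- "completed"
  step <- 0L
  while (max(current) < target - 1e-9) {
    step <- step + 1L
    cands <- unique(do.call(rbind, lapply(moves, function(m) {
      t(vapply(1:3, function(i) { ax <- current; ax[i] <- ax[i] + m; ax },
               numeric(3)))
    })))
    scored <- purrr::map_dfr(seq_len(nrow(cands)), function(i) {
      sc <- score_axes(cands[i, ])
      tibble(step = step, dx = cands[i, 1], dy = cands[i, 2], dz = cands[i, 3],
             n_atoms = sc$n_atoms, energy_per_atom = sc$energy_per_atom,
             termination = sc$termination, error = sc$error)
    })
    ok <- !is.na(scored$energy_per_atom)
    if (!any(ok)) {
      status <- "truncated"
      scored$chosen <- FALSE
      cand_log[[step]] <- scored
      break
    }
    pick <- scored[ok, ]
    pick <- pick[order(pick$energy_per_atom, pick$dx, pick$dy, pick$dz), ][1, ]
    scored$chosen <- scored$dx == pick$dx & scored$dy == pick$dy &
      scored$dz == pick$dz
    cand_log[[step]] <- scored
    current <- c(pick$dx, pick$dy, pick$dz)
    path <- bind_rows(path, tibble(step = step, dx = pick$dx, dy = pick$dy,
                                   dz = pick$dz, n_atoms = pick$n_atoms,
                                   energy_per_atom = pick$energy_per_atom,
                                   termination = pick$termination))
  }
  structure(list(path = path,
                 candidates = if (length(cand_log)) bind_rows(cand_log) else
                   tibble(),
                 moves = moves, target = target, status = status),
            class = "nc_growth_path")
}

#' @export
print.nc_growth_path <- function(x, ...) {
  cat(sprintf("<growth_path> %d step(s), status %s, target max axis %g nm\n",
              nrow(x$path) - 1L, x$status, x$target))
  print(x$path)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nc_growth_path <- function(x, ...) x$path

#' @exportS3Method generics::glance
glance.nc_growth_path <- function(x, ...) {
  last <- x$path[nrow(x$path), ]
  tibble(steps = nrow(x$path) - 1L, status = x$status,
         final_dx = last$dx, final_dy = last$dy, final_dz = last$dz,
         final_energy_per_atom = last$energy_per_atom,
         candidates_scored = nrow(x$candidates))
}
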