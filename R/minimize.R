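# Conjugate-gradient (Polak-Ribiere) energy minimization with a
# backtracking Armijo line search and four stopping criteria checked in a
# fixed order after each iteration: relative energy change, global force
# norm, iteration budget, evaluation budget.

#' Minimization stopping criteria
#'
#' @param etol Relative energy-change tolerance,
#'   `|E_k - E_{k-1}| / max(|E_k|, 1e-12)` (dimensionless; default 1e-4).
#' @param ftol Force tolerance: 2-norm of the global force vector
#'   (eV/Angstrom; default 1e-6).
#' @param max_iterations Iteration budget (default 1000).
#' @param max_evaluations Energy/force evaluation budget (default 1e5).
#' @return A `minimization_settings` object.
#' @export
minimization_settings <- function(etol = 1e-4, ftol = 1e-6,
                                  max_iterations = 1000,
                                  max_evaluations = 1e5) {
  vals <- c(etol, ftol, max_iterations, max_evaluations)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    nc_abort("Minimization settings must be nonnegative and finite",
             class = "nanocarve_parameter_error")
  }
  structure(list(etol = etol, ftol = ftol,
                 max_iterations = as.integer(max_iterations),
                 max_evaluations = as.integer(max_evaluations)),
            class = "minimization_settings")
}

#' Minimize the energy of a particle
#'
#' Polak-Ribiere conjugate gradient with a backtracking Armijo line search
#' (c = 1e-4, shrink 0.5, first trial step capped at 0.1 Angstrom of atomic
#' displacement; CG restart every 3N iterations or on a non-descent
#' direction). The energy sequence is monotone non-increasing. Stops on the
#' first criterion met, tested in the order etol, ftol, maxiter, maxeval.
#'
#' @param structure An `nc_particle` with finite starting energy.
#' @param potential A `potential_model`.
#' @param settings A [minimization_settings()].
#' @return An `nc_minimization`: the relaxed particle (with per-atom
#'   energies filled in and the minimized flag set), initial/final total
#'   energy (eV), average potential energy per atom (eV), iteration and
#'   evaluation counts, termination reason and the per-iteration energy
#'   trace. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' dimer <- particle(data.frame(element = "Ar", x = c(0, 1.5), y = 0, z = 0))
#' fit <- minimize_structure(dimer, lj_potential(epsilon = 1, sigma = 1, cutoff = 10))
#' glance(fit)
minimize_structure <- function(structure, potential,
                               settings = minimization_settings()) {
  stopifnot(is_particle(structure), inherits(potential, "potential_model"),
            inherits(settings, "minimization_settings"))
  prep <- prepare_potential(structure, potential)
  x <- positions(structure)
  n <- nrow(x)

  evals <- 0L
  full_eval <- function(xyz) {
    evals <<- evals + 1L
    eval_energy(xyz, prep, potential, want_forces = TRUE)
  }
  energy_only <- function(xyz) {
    evals <<- evals + 1L
    eval_energy(xyz, prep, potential, want_forces = FALSE)$total
  }

  cur <- full_eval(x)
  if (!isTRUE(cur$finite) || !is.finite(cur$total)) {
    nc_abort(paste0("Non-finite energy at the starting configuration ",
                    "(overlapping atoms?); consider a different force field ",
                    "if convergence cannot be achieved"),
             class = "nanocarve_unstable_error")
  }
  E <- cur$total
  FF <- cur$forces
  trace <- E
  iter <- 0L
  fnorm <- sqrt(sum(FF^2))
  termination <- NULL
  if (fnorm <= settings$ftol) termination <- "ftol"
  if (is.null(termination) && iter >= settings$max_iterations) termination <- "maxiter"
  if (is.null(termination) && evals >= settings$max_evaluations) termination <- "maxeval"

  d <- FF  # first search direction: steepest descent (gradient = -F)
  restart_every <- 3L * n

  while (is.null(termination)) {
    slope <- -sum(FF * d)  # dE/dalpha along d
    if (slope >= 0) { d <- FF; slope <- -sum(FF * d) }
    dmax <- sqrt(max(rowSums(d^2)))
    alpha <- if (dmax > 0) 0.1 / dmax else 0
    accepted <- FALSE
    E_new <- E
    for (bt in seq_len(40L)) {
      E_try <- energy_only(x + alpha * d)
      if (is.finite(E_try) && E_try <= E + 1e-4 * alpha * slope) {
        x <- x + alpha * d
        E_new <- E_try
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
      if (evals >= settings$max_evaluations) break
    }
    if (!accepted) {
      if (!identical(d, FF)) { d <- FF; next }  # retry as steepest descent
      # cannot decrease the energy along the gradient: converged in energy
      termination <- if (evals >= settings$max_evaluations) "maxeval" else "etol"
      break
    }
    nxt <- full_eval(x)
    iter <- iter + 1L
    F_new <- nxt$forces
    E_prev <- E
    E <- nxt$total
    trace <- c(trace, E)
    fnorm <- sqrt(sum(F_new^2))

    rel_de <- abs(E - E_prev) / max(abs(E), 1e-12)
    if (rel_de <= settings$etol) termination <- "etol"
    else if (fnorm <= settings$ftol) termination <- "ftol"
    else if (iter >= settings$max_iterations) termination <- "maxiter"
    else if (evals >= settings$max_evaluations) termination <- "maxeval"

    if (is.null(termination)) {
      beta <- sum(F_new * (F_new - FF)) / max(sum(FF * FF), 1e-300)
      beta <- max(0, beta)  # PR+
      d <- if (iter %% restart_every == 0L) F_new else F_new + beta * d
    }
    FF <- F_new
  }

  final <- eval_energy(x, prep, potential, want_forces = FALSE)
  out <- set_positions(structure, x)
  out$energy <- final$per_atom
  attr(out, "minimized") <- TRUE
  attr(out, "stage") <- "minimized"

  structure(
    list(structure = out,
         energy_initial = trace[1],
         energy = final$total,
         energy_per_atom = final$total / n,
         iterations = iter,
         evaluations = evals,
         termination = termination,
         trace = trace),
    class = "nc_minimization"
  )
}

#' @export
print.nc_minimization <- function(x, ...) {
  cat(sprintf(paste0("<minimization> E %.6f -> %.6f eV (%.6f eV/atom), ",
                     "%d iterations, %d evaluations, stopped on %s\n"),
              x$energy_initial, x$energy, x$energy_per_atom,
              x$iterations, x$evaluations, x$termination))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nc_minimization <- function(x, ...) {
  s <- x$structure
  tibble(atom = seq_len(n_atoms(s)), element = s$element,
         x = s$x, y = s$y, z = s$z, energy = s$energy)
}

#' @exportS3Method generics::glance
glance.nc_minimization <- function(x, ...) {
  tibble(energy_initial = x$energy_initial,
         energy = x$energy,
         energy_per_atom = x$energy_per_atom,
         n_atoms = n_atoms(x$structure),
         iterations = x$iterations,
         evaluations = x$evaluations,
         termination = x$termination)
}
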