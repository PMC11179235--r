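# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain double/triple loops so they share no code with the package
# internals they check.

# --- small structure generators (built in code, no files) -------------------

# cubic lattice of single atoms, n^3 sites, spacing a, centered at origin
cubic_block <- function(n, a = 1, element = "Ar") {
  g <- seq_len(n) - (n + 1) / 2
  pts <- expand.grid(x = g * a, y = g * a, z = g * a)
  particle(data.frame(element = element, pts), check_overlap = FALSE)
}

# FCC block: m^3 conventional cells, 4 atoms each
fcc_block <- function(m, a = 4.05, element = "Al") {
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  cells <- expand.grid(i = 0:(m - 1), j = 0:(m - 1), k = 0:(m - 1))
  pts <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    sweep(basis, 2, as.numeric(cells[r, ]), `+`) * a
  }))
  particle(data.frame(element = element, x = pts[, 1], y = pts[, 2],
                      z = pts[, 3]), check_overlap = FALSE)
}

# HCP block: a, c = sqrt(8/3) a, two-layer ABAB stacking
hcp_block <- function(nx, ny, nz, a = 2.9, element = "Mg") {
  c_ax <- sqrt(8 / 3) * a
  rows <- list()
  for (k in 0:(nz - 1)) {
    for (j in 0:(ny - 1)) {
      for (i in 0:(nx - 1)) {
        ox <- i * a + (j %% 2) * a / 2
        oy <- j * a * sqrt(3) / 2
        oz <- k * c_ax
        rows[[length(rows) + 1]] <- c(ox, oy, oz)
        rows[[length(rows) + 1]] <- c(ox + a / 2, oy + a * sqrt(3) / 6,
                                      oz + c_ax / 2)
      }
    }
  }
  pts <- do.call(rbind, rows)
  particle(data.frame(element = element, x = pts[, 1], y = pts[, 2],
                      z = pts[, 3]), check_overlap = FALSE)
}

# random cluster with a minimum-separation guard (rejection sampling)
random_cluster <- function(n, box = 8, min_sep = 1.5, elements = "Ar",
                           charges = NULL) {
  pts <- matrix(NA_real_, n, 3)
  placed <- 0
  while (placed < n) {
    cand <- runif(3, 0, box)
    ok <- placed == 0 ||
      min(sqrt(rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2,
                             cand)^2))) >= min_sep
    if (ok) {
      placed <- placed + 1
      pts[placed, ] <- cand
    }
  }
  el <- rep_len(elements, n)
  df <- data.frame(element = el, x = pts[, 1], y = pts[, 2], z = pts[, 3])
  if (!is.null(charges)) df$charge <- rep_len(charges, n)
  particle(df, check_overlap = FALSE)
}

# --- independent oracles ----------------------------------------------------

# O(N^2) neighbour counts under a single scalar cutoff, strict "<"
coordination_oracle <- function(p, cutoff) {
  xyz <- as.matrix(p[, c("x", "y", "z")])
  n <- nrow(xyz)
  counts <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

# triple-loop CNP
cnp_oracle <- function(p, cutoff) {
  xyz <- as.matrix(p[, c("x", "y", "z")])
  n <- nrow(xyz)
  nbr <- lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j) {
      j != i && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff
    }, logical(1)))
  })
  vapply(seq_len(n), function(i) {
    ni <- length(nbr[[i]])
    if (ni == 0) return(0)
    acc <- 0
    for (j in nbr[[i]]) {
      s <- c(0, 0, 0)
      for (k in intersect(nbr[[i]], nbr[[j]])) {
        s <- s + (xyz[k, ] - xyz[i, ]) + (xyz[k, ] - xyz[j, ])
      }
      acc <- acc + sum(s^2)
    }
    acc / ni
  }, numeric(1))
}

# double-loop hexatic order parameter
hexatic_oracle <- function(p, cutoff) {
  xyz <- as.matrix(p[, c("x", "y", "z")])
  n <- nrow(xyz)
  vapply(seq_len(n), function(k) {
    nb <- which(vapply(seq_len(n), function(j) {
      j != k && sqrt(sum((xyz[k, ] - xyz[j, ])^2)) < cutoff
    }, logical(1)))
    if (length(nb) == 0) return(0 + 0i)
    acc <- 0 + 0i
    for (j in nb) {
      dx <- xyz[j, 1] - xyz[k, 1]
      dy <- xyz[j, 2] - xyz[k, 2]
      if (sqrt(dx^2 + dy^2) >= 1e-9) {
        acc <- acc + exp(1i * 6 * atan2(dy, dx))
      }
    }
    acc / length(nb)
  }, complex(1))
}

# central finite-difference forces (h in Angstrom)
fd_forces <- function(p, pot, h = 1e-5) {
  n <- nrow(p)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (d in c("x", "y", "z")) {
      pp <- p; pp[[d]][i] <- pp[[d]][i] + h
      pm <- p; pm[[d]][i] <- pm[[d]][i] - h
      ep <- total_energy(particle(pp, check_overlap = FALSE), pot)$total
      em <- total_energy(particle(pm, check_overlap = FALSE), pot)$total
      out[i, match(d, c("x", "y", "z"))] <- -(ep - em) / (2 * h)
    }
  }
  out
}

# sorted multiset of pairwise distances (congruence tests)
distance_multiset <- function(p) {
  sort(as.numeric(dist(as.matrix(p[, c("x", "y", "z")]))))
}

# quadrature ellipsoid surface area (needs pracma)
quadrature_area <- function(a, b, c) {
  f <- function(th, ph) {
    st <- sin(th); ct <- cos(th)
    sp <- sin(ph); cp <- cos(ph)
    st * sqrt((b * c * st * cp)^2 + (a * c * st * sp)^2 + (a * b * ct)^2)
  }
  8 * pracma::integral2(f, 0, pi / 2, 0, pi / 2, reltol = 1e-10)$Q
}

# small LJ model shared by several tests
unit_lj <- function(cutoff = 10) lj_potential(epsilon = 1, sigma = 1, cutoff = cutoff)
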