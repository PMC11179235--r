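---
title: "Building and scoring ellipsoidal nanoparticles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and scoring ellipsoidal nanoparticles: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocarve)
```

## The problem

Finite nanoparticles (NPs) carved from a bulk crystal are the natural
starting model for predicting which particle shapes a material prefers to
grow into, and which surface chemistry it will expose. nanocarve constructs
neutral, stoichiometric, ellipsoidal NPs *in vacuo* directly from a
crystal's CIF description, relaxes them with a conjugate-gradient energy
minimizer over classical pair potentials, and summarises each particle with
a panel of geometric and atomistic descriptors. On top of that sits a small
exploration layer that ranks candidate shapes, scans lattice orientations,
and follows greedy lowest-energy growth pathways, using the average
potential energy per atom as the stability metric (lower = more stable).

## The construction pipeline

Construction happens in three stages, each usable on its own.

**Stage 1 — unit cell.** `parse_cif()` reads a deliberately minimal CIF
dialect: cell lengths/angles, one symmetry-operator loop in `"x,y,z"`
notation, and a fractional atom-site loop. Sites are expanded under all
listed operators, wrapped into `[0, 1)`, and deduplicated at a fractional
tolerance of 1e-3. Charge suffixes on type symbols (`"Zr4+"`) become formal
charges, and a charged cell must be neutral; partially occupied sites are a
hard error because carving a disordered cell is not well defined. Space-group
*names* are never interpreted: if no operator loop is present the cell is
treated as P1. Element substitution (`substitute_element()`) is restricted
to chemically sensible swaps: same IUPAC group, at most one period away
(so Ti can become Zr, and Zr can become Ti or Hf). f-block elements carry no
IUPAC group in this scheme, so substitution there is refused rather than
guessed.

**Stage 2 — geometry.** The cell is replicated
`n_i = ceil(d_max / w_i) + 1` times per lattice direction, where `w_i` is
the perpendicular width of the cell and `d_max` the largest ellipsoid axis;
the extra cell is safety margin, and a configurable `max_atoms` guard
(default 2e6) refuses supercells that would exhaust memory. A sphere of
diameter `d_max` is carved about the geometric center of the supercell box
(not snapped to an atom — reproducible and unbiased, since no convention is
forced by the geometry), the lattice is rotated about that cluster's
centroid by the user's rotation vector and angle (Rodrigues formula,
right-hand rule), and the axis-aligned ellipsoid is carved with the closed
predicate `s(r) <= 1`, where

\[ s(\mathbf r) = \sqrt{(x/R_x)^2 + (y/R_y)^2 + (z/R_z)^2} \]

with centroid-relative coordinates. The ellipsoid is *always* laboratory
axis-aligned; the rotation reorients the crystal inside it. Finally
`neutralize_stoichiometry()` trims the particle to an integer number of
formula units: `n_fu = min_e floor(count_e / nu_e)`, removing per element
exactly the surplus, chosen by descending `s(r)` (closest to the surface
from inside) with lexicographic (x, y, z) tie-breaks. `s(r)` is used as the
surface-proximity metric rather than the true Euclidean distance to the
ellipsoid because it is a monotone, cheap and unambiguous proxy. There is no
randomness anywhere in the pipeline, so rebuilding with the same inputs is
bit-identical.

User-facing axis lengths are nanometres (matching how practitioners specify
particle sizes); everything internal and every file is Angstrom, converted
by an exact factor of 10.

**Stage 3 — energy.** Two pair-potential families are built in:
Lennard-Jones and Buckingham, optionally with a Coulomb term on the formal
charges using `k = 14.399645` eV Å/e². Because the particles are finite
clusters in vacuum, the Coulomb sum is a direct O(N²) double sum — no Ewald
or Wolf summation, which exist to handle periodicity this package does not
have. Charge-equilibrating many-body force fields (e.g. third-generation
charge-optimised many-body potentials) are intentionally *not*
reimplemented: the LAMMPS data-file writer (`write_lammps_data()`,
atom_style `charge`) exports the exact constructed atom set so such
potentials can score it externally. The built-in potentials make every
downstream feature exercisable at desk scale.

Every pair term is split half-and-half onto its two atoms (a three-body
term would contribute 1/3 per atom, a four-body term 1/4 — with pair
potentials only the 1/2 rule is active), and the total energy is defined as
the sum of the per-atom vector in index order, so
`total == sum(per_atom)` holds exactly, not just to rounding.

## Minimization

`minimize_structure()` is Polak-Ribiere (PR+) conjugate gradient with a
backtracking Armijo line search: `c = 1e-4`, shrink factor 0.5, first trial
step scaled so no atom moves more than 0.1 Å, restart to steepest descent
every 3N iterations or whenever the CG direction stops being a descent
direction. Four stopping criteria are tested after each iteration, in a
fixed order:

1. `etol` — *relative* energy change `|E_k - E_{k-1}| / max(|E_k|, 1e-12)`,
   default 1e-4;
2. `ftol` — 2-norm of the global force vector, default 1e-6 eV/Å;
3. `max_iterations`, default 1000;
4. `max_evaluations` (energy/force calls, line-search trials included),
   default 1e5.

The default numbers are the conventional settings for this kind of cluster
relaxation; their *semantics* (relative energy change, global force 2-norm
— the LAMMPS conventions) are this package's documented choice, since bare
numbers do not pin down units. Because the line search only ever accepts a
decrease, the energy trace is monotone non-increasing by construction. A
non-finite starting energy (overlapping atoms) raises an error advising a
different force field rather than silently diverging. When no decrease can
be found along the steepest-descent direction the structure is at numerical
convergence and the run reports `etol`.

## The descriptor panel

Geometric descriptors: axis diameters `D_c = max(c) - min(c)` per Cartesian
component (frame-dependent by definition — a 90° z-rotation of a tetragonal
block permutes them, and the tests pin this down); the Thomsen closed-form
ellipsoid surface area

\[ S = 4\pi \left( \frac{(R_xR_y)^p + (R_xR_z)^p + (R_yR_z)^p}{3}
   \right)^{1/p}, \quad p = 1.6075, \]

exact for spheres and within about 1.061% of the true area in the worst
case (the package's acceptance script measures 1.059% over aspect ratios up
to 1:1:100 and 1:100:100 against adaptive quadrature); and the ellipsoid
volume `V = (4/3) pi Rx Ry Rz`.

Atomistic descriptors are computed from neighbour lists with the strict
predicate `distance < cutoff`. The cutoff follows a species-count rule: one
species — 2.4 x its ionic radius; two species — 1.2 x the sum of the two
ionic radii per pair (like pairs use twice their own radius); three or more
— a flat 5 Å. The rule's boundary case is genuinely ambiguous as usually
stated ("more than one" would contradict the explicit two-species clause),
so this package reads it as *more than two*. Radii are Shannon ionic radii
(VI coordination) keyed by the formal charge, falling back to Cordero
covalent radii with a warning when no ionic entry applies (e.g. neutral
metals).

* **Average coordination** — mean neighbour count.
* **Common neighbourhood parameter (CNP)** —
  `Q_i = (1/n_i) sum_j || sum_{k in common(i,j)} (r_ik + r_jk) ||^2`, the
  Tsuzuki-style formulation: zero in perfect FCC environments by symmetry,
  positive at defects, surfaces and HCP stacking. Atoms without neighbours
  score 0, and empty common-neighbour sums contribute 0.
* **Hexatic order** — `q_k = (1/N) sum_j exp(i 6 theta_kj)` with
  `theta_kj` the angle of the bond's xy-plane projection against the x
  axis; bonds whose projection is shorter than 1e-9 Å (near-vertical) are
  skipped, and the full neighbour count N stays in the denominator. The
  averages of the real and imaginary parts are reported as the first and
  second hexatic parameters. This is the standard psi-6 convention
  restricted to the laboratory frame, which is also why it is deliberately
  *not* rotation invariant.

**Core/surface split.** Atoms inside the ellipsoid shrunk by a uniform
4 Å surface thickness are core; everything else is surface. A fixed
thickness keeps descriptor comparisons unbiased across chemistries. Because
atoms move during relaxation, the user's carving ellipsoid may no longer
bound the particle, so `np_descriptors()` defaults to *effective*
semilengths — half the axis diameters of the structure as given — and can be
overridden to the carving spec or an explicit triple. If any shrunk
semilength is nonpositive the particle is all surface, and the empty core's
values are reported missing rather than erroring. For every atomistic
descriptor the core/surface ratio (missing when the surface value is 0) and
difference are derived; whole-particle averages are identically the
atom-count-weighted mean of the region averages, which the tests assert to
1e-10.

The panel is meaningful on *relaxed* structures — the geometric and
minimized structures can differ substantially — so `np_descriptors()`
refuses a particle whose minimized flag is unset unless explicitly
overridden, and the CLI maps that refusal to its stage-order exit code.

## Exploration

`enumerate_fixed_volume()` closes (Dx, Dy) pairs to `Dz = 6V/(pi Dx Dy)`
so all candidates share one volume; the reported Dz is rounded to 2
decimals while the unrounded value is used for carving, and at
`V = 33.51` nm³ the pairs (4.00, 4.00), (3.00, 4.00) and (2.00, 2.50) close
to 4.00, 5.33 and 12.80 nm. `rank_shapes()` builds, minimizes and scores
every candidate, sorts ascending by energy per atom with run-id tie-breaks,
and records failures per candidate instead of aborting the scan.
`rotation_scan()` does one build+minimize per angle at fixed axes.
`growth_pathway()` is a *greedy* search: from a small near-spherical seed,
each step applies every allowed move (each increment to each axis), scores
all candidates, and advances to the argmin with lexicographically-smallest
tie-breaks, stopping at a target size. Greedy search matches the practice of
investigating selected routes through an otherwise combinatorial space; an
exhaustive path enumeration exists only as a test oracle at toy scale. The
move set is a user parameter because no canonical set exists. All candidate
energies are retained so `autoplot()` can draw the pathway map.

## What the fixtures emulate — and what they do not

`generate_fixture()` provides three first-class cells: rutile-type MO₂
(tetragonal, 2 metal + 4 oxygen sites, default titania geometry a = 4.593 Å,
c = 2.959 Å, u = 0.305, formal charges +4/−2), rock salt (Na/Cl, a = 5.64 Å,
±1) and FCC (Al, a = 4.05 Å). They stand in for database CIFs so nothing is
downloaded at build or test time, and they cover the symmetry cases the
geometry code must honour (4-fold tetragonal congruence, two-species cutoff
rule, single-species close packing). They are ideal crystals: no thermal
disorder, no defects, no surface reconstruction, no real covalent-ionic
mixing. Passing tests therefore certify the *construction, bookkeeping and
numerics*, not the physical accuracy of any particular force field on a
real material — for that, export the LAMMPS data file and score the
identical atom set with a production potential.

## Numerical choices and degenerate inputs

* Boundary predicates are closed (`<=`) with a 1e-9 guard so atoms exactly
  on a surface are kept deterministically.
* Symmetry dedup tolerance: 1e-3 fractional; XYZ round-trips hold to 1e-6 Å
  (6-decimal output).
* Neighbour predicate is strict `<`, per the cutoff rule's wording.
* Rotation is an isometry to better than 1e-9 relative on pairwise
  distances; 360° composes to the identity within the same bound.
* Overlap guard: structures with atoms closer than 0.5 Å are refused at
  construction, and a non-finite starting energy aborts minimization with
  advice instead of NaNs.
* Empty regions, empty carves, and `n_fu = 0` all raise typed errors
  (`nanocarve_empty_error`, `nanocarve_composition_error`, ...) so callers
  and the CLI can map them to exit codes without parsing messages.
* Printed tables round axis values to 2 decimals; all carving uses
  unrounded values.

## Problem sizes

The examples and the test suite run at desk scale by choice: particles of a
few hundred to a few thousand atoms (a 2 nm rutile-type sphere is ~400
atoms; a 4 nm one ~3,000), shape scans over a handful of candidates, and
growth pathways of a few steps on 1-2 nm seeds. These sizes exercise every
code path — supercell guard, carving, neutralization, minimization,
descriptors, ranking — while each individual build+minimize stays in the
seconds range with the O(N²) compiled kernels. Nothing in the algorithms
caps particle size below the `max_atoms` guard; larger studies simply cost
proportionally more evaluations.

## Known limitations

* Pair potentials only; no many-body, bond-order or variable-charge models
  (export to LAMMPS for those), and no molecular-dynamics annealing — the
  minimizer finds *a* local minimum, not provably the global one.
* No periodic boundary conditions: everything is a cluster in vacuum.
* Space-group names are not expanded into operators; disordered and
  partially occupied structures are rejected.
* Only ellipsoidal (and spherical) shapes; no polyhedra, rods or
  core-shell particles.
* The coordination/CNP/hexatic cutoff is the rule-derived value or a single
  user override; systematic cutoff sweeps are out of scope.
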