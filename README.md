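# nanocarve

Digital construction and stability analysis of ellipsoidal nanoparticles
from crystal structures.

## What it does, and for whom

Materials and nanoinformatics researchers often need finite, physically
sensible nanoparticle (NP) models: given a bulk crystal, what atoms make up
a 4 nm ellipsoidal particle of it? Is the compact shape or the elongated
one more stable? Along which axis would the crystal prefer to grow?
nanocarve answers these questions in three stages:

1. **Unit cell** — parse a CIF (cell parameters, symmetry operators,
   fractional sites, formal charges), symmetry-expand it, and optionally
   substitute elements under a periodic-table constraint (same IUPAC
   group, at most one period away — e.g. Ti → Zr).
2. **Geometry** — replicate the cell into a supercell, carve a sphere of
   the largest ellipsoid axis, rotate the lattice about a user vector,
   carve the laboratory-frame ellipsoid with semilengths
   `R = D/2` (axes `D` in nm), and remove the excess atoms closest to the
   surface so the particle is exactly stoichiometric and charge neutral.
3. **Energy** — relax the cluster in vacuum with Polak-Ribiere conjugate
   gradient over Lennard-Jones or Buckingham(+Coulomb) pair potentials,
   with four stopping criteria (relative energy tolerance 1e-4, force
   2-norm 1e-6 eV/Å, 1000 iterations, 1e5 evaluations by default), then
   summarise the particle with a descriptor panel.

The descriptor panel covers, for the whole particle and its core and
surface regions (split by a uniform 4 Å surface thickness), plus
core/surface ratios and differences:

- axis diameters `D_x, D_y, D_z` (max extent per lab axis),
- Thomsen surface area
  `S = 4π(((R_xR_y)^p + (R_xR_z)^p + (R_yR_z)^p)/3)^{1/p}`, `p = 1.6075`
  (≤ ~1.061% from the exact area),
- volume `V = (4/3)π R_x R_y R_z`,
- average potential energy per atom (the stability metric; each pair term
  split 1/2 per atom so per-atom energies sum exactly to the total),
- average coordination number (cutoff rule: 2.4·r for one species,
  1.2·(r_a + r_b) for two, 5 Å for more; Shannon ionic radii with covalent
  fallback),
- common neighbourhood parameter (CNP; 0 on perfect FCC),
- hexatic order parameter (real and imaginary parts of the six-fold
  bond-orientational average).

On top sit exploration tools: `enumerate_fixed_volume()` +
`rank_shapes()` (fixed-volume shape ranking), `rotation_scan()`, and
`growth_pathway()` (greedy lowest-energy-per-atom growth routes). Particles
export as XYZ and LAMMPS data files (atom_style `charge`) so external
engines with many-body/charge-equilibrating force fields can score the
exact same atom set; such force fields are deliberately not reimplemented
here.

## Worked example

Build a 2 nm rutile-type zirconia particle, relax it with the bundled
rigid-ion Buckingham+Coulomb parameter set, and report descriptors:

```r
library(nanocarve)

cell <- generate_fixture("rutile_MO2")$cell |> substitute_element("Ti", "Zr")
cell
#> <unit_cell> a=4.593 b=4.593 c=2.959 A  alpha=90 beta=90 gamma=90 deg
#>   6 sites, formula unit O2 Zr1, 1 symmetry operator(s)

np <- build_ellipsoidal_np(cell, ellipsoid_spec(2, 2, 2))
np
#> <particle> 393 atoms (O:262 Zr:131), stage 'neutralized'

pot <- read_potential_file(system.file("extdata", "buckingham_zro2.pot",
                                       package = "nanocarve"))
fit <- minimize_structure(np, pot)
fit
#> <minimization> E -13515.478678 -> -14100.616937 eV (-35.879432 eV/atom),
#>   22 iterations, 47 evaluations, stopped on etol

np_descriptors(fit$structure)$regions
#> # A tibble: 3 x 12
#>   region  n_atoms    dx    dy    dz surface_area volume avg_energy
#>   <chr>     <int> <dbl> <dbl> <dbl>        <dbl>  <dbl>      <dbl>
#> 1 whole       393 17.8  17.8  19.1         1046.  3176.      -35.9
#> 2 core         51  9.51  9.51  9.53         284.   451.      -34.8
#> 3 surface     342 17.8  17.8  19.1         1046.  3176.      -36.0
```

The particle holds exactly two O per Zr (131 formula units, net charge 0);
after relaxation the surface atoms sit ~1.2 eV/atom lower than the core
under this rigid-ion model, and the core retains the higher coordination
(the derived ratio/difference block in `np_descriptors(...)$derived` makes
that comparison directly). Enumerating shapes at the fixed volume of a
4 nm sphere closes the third axis over each (Dx, Dy) pair:

```r
enumerate_fixed_volume(33.51, list(c(4, 4), c(3, 4), c(2, 2.5)))
#> # A tibble: 3 x 6
#>   run_id    dx    dy    dz dz_exact volume
#>    <int> <dbl> <dbl> <dbl>    <dbl>  <dbl>
#> 1      1     4   4    4        4.00   33.5
#> 2      2     3   4    5.33     5.33   33.5
#> 3      3     2   2.5 12.8     12.8    33.5
```

`rank_shapes(cell, cands, pot)` then builds and relaxes each candidate and
orders them by average potential energy per atom; `autoplot()` draws the
result, and `tidy()`/`glance()` give broom-style summaries of fits and
pathways.

A command-line wrapper with the same stages
(`fixture | build | minimize | descriptors | scan-shapes | scan-rotation |
grow`) lives at `system.file("cli", "nanocarve.R", package = "nanocarve")`;
stages refuse to run out of order (exit code 3) and echo a reproducible
`config.json` per run.

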