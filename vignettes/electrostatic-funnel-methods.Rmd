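---
title: "Methods: grid electrostatics and the binding-energy funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid electrostatics and the binding-energy funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efunnel)
```

## The problem

Processive cytoskeletal motors such as cytoplasmic dynein must repeatedly
re-bind a small, weakly charged domain (the microtubule-binding domain, the
"probe" in this package) to precise lattice sites on a strongly negatively
charged filament, tens of nanometres away from the site of ATP hydrolysis.
`efunnel` implements the continuum-electrostatics toolchain needed to ask
whether long-range electrostatics can supply the missing guidance: a
finite-difference Poisson solver with computational focusing, rigid-body
pose sampling reduced to a two-dimensional binding-energy "funnel" map,
electric-field forces and work-of-detachment estimates on a charge-silenced
probe, a segment-angle hinge detector for coiled-coil trajectories, alanine
charge-neutralisation scans, and a linear calibration linking the
electrostatic binding energy to single-molecule velocity and run length.

Everything is testable offline: the `make_*` generators build toy systems
with planted ground truth (a net-neutral probe with a positive binding
face, a neutral slab with an asymmetric acidic pocket, helical chains with
planted hinges, linear energy-phenotype data), and the package's test suite
checks every stage against closed-form oracles on those systems.

## The electrostatic model

The solver treats the solute as a rigid body of point charges inside a
low-dielectric cavity embedded in high-dielectric solvent, and solves the
zero-salt linear Poisson equation

$$\nabla\cdot\big(\varepsilon(\mathbf{x})\nabla\phi(\mathbf{x})\big)
  = -4\pi C\,\rho(\mathbf{x}),$$

on a regular cubic grid, with potentials in kT/e at 298 K and the Coulomb
constant $C = 561.0\ \mathrm{kT\,\mathring{A}/e^2}$ used consistently
(1 kT = 4.114 pN nm = 0.5925 kcal/mol). Salt is zero throughout — the
systems of interest are so highly charged that a mean-field ion cloud is
of questionable validity, and the zero-salt equation is linear, which the
energy decomposition and the per-source force partition both exploit.

Defaults (all in `solver_config()`): 2 grid points per Angstrom; *perfil*
70 (the solute extent fills 70% of the cubic box edge); dielectric 2
inside the solute and 80 in water; dipole boundary condition; SOR
relaxation with $\omega = 1.9$, checkerboard ordering, and a convergence
tolerance of $10^{-4}$ kT/e maximum change per sweep.

Numerical choices worth knowing about:

* **Dielectric boundary.** The cavity is the union of atom spheres (van
  der Waals surface), not a probe-rolled molecular surface. This is
  simpler than the production choice of DelPhi-class solvers and is
  calibrated by the Born and Coulomb oracles in the test suite: at 2
  grids/A the reaction field of a 3 A Born ion is reproduced to ~2% and
  point-charge potentials to well under 5%.
* **Link dielectrics.** Fluxes between adjacent nodes use the harmonic
  mean of the node dielectrics, the standard flux-continuous
  discretisation for sharp interfaces.
* **Charge spreading.** Each atom's charge is distributed to its 8
  surrounding nodes with trilinear weights, which conserves total charge
  exactly; the resulting grid self-energy is large but cancels exactly in
  the reaction-field and binding differences because those are taken
  between solves on the identical grid with identical spreading.
* **Boundary conditions.** The "dipole" mode evaluates the analytic
  potential of the system's net charge and dipole moment (placed at the
  |q|-weighted charge centroid, screened by the solvent dielectric) on
  the box faces; "coulombic" sums all node charges and "zero" grounds the
  box. The exact boundary formula used by DelPhi is not published; the
  monopole+dipole construction is this package's documented stand-in, and
  the test suite shows it agrees with the full Coulomb sum to <2% at
  perfil 70 for compact systems.
* **Computational focusing.** `focus_solve()` interpolates a coarse
  whole-system solution onto the boundary of a fine subregion grid and
  re-solves there, so a probe-sized box feels the entire filament at a
  fraction of the cost. Focused solutions agree with direct fine solves
  to ~3% and are insensitive to fine-box placement to ~5%.

## Energies

`electrostatic_energy()` reports the Coulombic term as the analytic
pairwise sum screened by the solute dielectric (the DelPhi convention)
and the reaction field as a two-solve difference: heterogeneous map minus
uniform-$\varepsilon_{in}$ map on the same grid.
`binding_energy(A, B)` computes
$\Delta G = G_{complex} - G_A - G_B$
with all three terms on one shared grid. Each part's solve uses that
part's own cavity (the partner's cavity is absent), matching the
thermodynamic cycle of rigid-body binding from separated, solvated
partners; whether the published workflow used part-shaped or
complex-shaped dielectric maps for the isolated terms is not stated, so
the choice is explicit here and configurable through the `cavity`
argument of `electrostatic_energy()`. For uniform-dielectric systems
(`eps_in == eps_out`) the reaction field vanishes and
`reaction_field = FALSE` skips the grid solves entirely — the tests use
this to make Coulomb's law an exact oracle.

## Pose sampling and the funnel map

`pose_grid()` enumerates rigid probe poses over a longitudinal window, an
angular (cylindrical frames) or lateral (planar frames) window, a normal
approach range, and 9 orientation rotamers. Counting is half-open — the
closing endpoint of each axis is excluded — which is what makes the
production window (±20 A and ±12 degrees at 0.5 steps, 20 A of normal
approach, 9 rotamers) come out to exactly 80 × 48 × 40 × 9 = 1,382,400
poses. The 9 rotamers are the identity plus all ±tilt combinations about
the two axes orthogonal to the binding-face normal (default ±5 degrees);
the published 9-rotamer Euler recipe is not public, so this explicit tilt
grid is the package's stand-in, with the magnitude configurable. The
binding face stays oriented toward the filament by construction.

Scoring is rigid-body electrostatics plus van der Waals: a 6-12
Lennard-Jones with $r_{min}$ the sum of the atom radii, one uniform well
depth (0.1 kcal/mol), and hard clash rejection below
$0.5\,r_{min}$ — rigid-body funnels need short-range repulsion and mild
attraction, nothing more. The default electrostatic score is the
interaction energy $\sum_i q_i \phi_{filament}(\mathbf{x}_i)$, with the
filament potential focused from one coarse whole-system solve into a fine
box shared by all poses of a (longitudinal, angular) cell. This is the
term that shapes the funnel; the per-pose desolvation corrections of the
full three-state decomposition would cost six grid solves per pose
(prohibitive at $10^6$ poses) and cancel to first order between
neighbouring poses of a rigid pair. The full decomposition remains
available for any single pose via `score_pose(..., method = "full")`.

`build_energy_map()` reduces the four-dimensional pose energies to the
2D funnel map by recording, per surface cell, the minimum over the
normal × rotamer axes (ties break toward smaller normal distance, then
lower rotamer index). On the synthetic pocket system the map's argmin
falls on the constructed pocket centre and the approach path above the
pocket is monotonically downhill, which is the property-level content of
the funnel claim. The production-resolution map is expensive by design;
the tests and the acceptance script run a coarsened window (2 A / 2
degree steps, 12 A normal range, 9 rotamers — 5,400 poses, a few minutes
at 1 grid/A) and assert location, not absolute depths.

## Forces and the work of detachment

`field_at_atoms()` mirrors the charge-silencing protocol: the grid is
solved with the source's charges only while the probe atoms still carve
their cavity (configurable off), the field is $-\nabla\phi$ by central
differences, and forces are $q_i E(\mathbf{x}_i)$, converted at
1 kT/A = 41.14 pN. Per-source decompositions (e.g. the two tubulin
monomers of a dimer) charge each subset alone; by linearity the
per-source forces sum exactly to the total. `separation_scan()` repeats
the calculation along a detachment direction (default 2 A increments to
20 A) and `integrate_work()` applies the trapezoidal rule — either to
|F| (the small-angle "magnitude" method, which can only overestimate and
is the default for parity with the published analysis) or to the
component opposing displacement ("projected"). On the synthetic system
the projected work matches the independent binding-energy drop to ~2%,
comfortably inside the 15% consistency band the tests assert.

## Hinge detection and salt bridges

The segment angle at residue $i$ is the angle at its Calpha between the
vectors to the Calphas of $i - w$ and $i + w$ ($w = 10$ by default; that
window is the one that best picks up global, segment-scale bending).
`hinge_profile()` takes the per-residue standard deviation of this angle
across trajectory snapshots — a population (not sample) standard
deviation, fixed for determinism since the choice is otherwise
unspecified — and calls the global argmax plus any local maxima above
80% of it, so that two independent hinges are both reported. The first
and last $w$ residues are undefined by construction. On planted-hinge
trajectories (15 degree hinge s.d. against a 2 degree baseline, 200
snapshots) the detector localises the hinge to ±1 residue; the ±1 slack
is geometric, since the immediate neighbours of a bending pivot see the
same lever arms.

Salt bridges use the standard 4 A threshold (inclusive) between acidic
side-chain oxygens (Asp/Glu) and basic side-chain nitrogens (Lys/Arg,
His configurable — the convention adopted here counts His as basic), and
`bridge_occupancy()` reports the satisfying fraction of snapshots.

## Alanine scans and the phenotype calibration

`mutate_to_alanine()` truncates a residue's side chain beyond Cbeta with
no geometry relaxation — deliberately, so that the mutant differs from
the wild type purely electrostatically. `select_remote_acidics()` picks
the Glu/Asp residues all of whose atoms are >10 A from the partner (10 A
being the interface criterion in this literature), and
`ensemble_binding_energy()` averages per-snapshot binding energies with a
standard error of the mean.

`fit_phenotype()` regresses energy on phenotype (the orientation in which
these calibrations are tabulated) by ordinary least squares;
`predict_phenotype()` inverts the line algebraically rather than
re-fitting phenotype on energy, which is what reproduces the published
prediction arithmetic from the published coefficients. Predictions
outside the calibrated energy ranges (−35..−15 kT high-affinity,
−5..−25 kT low-affinity) warn but are not refused. Reported values round
to integer nm/s for velocity and one decimal (two significant figures
below 1) um for run length; where published per-conformation cells are
not rounding-consistent with their own coefficients, the package asserts
only the consistent cells.

## What the synthetic systems do and do not show

The generators are pure functions of their specs (seed included): the
probe is a compact jittered ball whose face charge (+4 e over the lowest
quarter of atoms, compensated on the top quarter for a net-neutral body)
emulates a positively charged binding face on a neutral domain; the
surface is a neutral slab with `round(|pocket_charge|)` single-atom
acidic pseudo-residues on a ring (default −8 e total, skewed along the
longitudinal axis to make the pocket asymmetric); hinge trajectories are
ideal helices bent per-residue by seeded Gaussian angles; phenotype data
are an exact line plus Gaussian noise with defaults matching the
low-affinity velocity calibration (5 constructs, 0.35 kT s/nm, −43 kT).

Passing tests on these systems demonstrate that the machinery — solver,
focusing, funnel reduction, force integration, detector, regression —
is numerically faithful. They do not reproduce figure-level results that
depend on deposited cryo-EM structures and molecular-dynamics ensembles
(absolute funnel depths, specific hinge residue identities, per-mutant
energies); those enter only through the printed coefficients and
parameters that the package takes as inputs.

## Known limitations

Linear zero-salt Poisson only (no Boltzmann term, no ionic strength); a
van der Waals dielectric surface rather than a molecular surface; no
conformational relaxation anywhere (rigid-body throughout, by design);
the dipole boundary and 9-rotamer constructions are documented stand-ins
for unpublished details; and the ideal-lattice filament builder does not
reproduce the exact helical parameters of deposited microtubule models —
supply explicit transform matrices to `build_filament()` when those are
available.
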