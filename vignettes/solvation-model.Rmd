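---
title: "A noniterative COSMO solvation model driven by semiempirical atomic charges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A noniterative COSMO solvation model driven by semiempirical atomic charges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosolv)
```

## The model

`cosolv` estimates the standard-state solvation free energy of a rigid
solute from nothing but its gas-phase geometry, per-atom partial charges
$Q_A$ (in practice PM7 charges from a MOPAC or Gaussian single point), and
a solvent specification. The total is a sum of two terms,

$$\Delta G^\circ_{solv} = E_{elst} + \Delta G^\circ_{corr},$$

an electrostatic polarization energy from a conductor-like screening model
(COSMO) and a linear nonelectrostatic correction.

**Electrostatics.** The solute sits in a cavity formed by the union of
atom-centered van der Waals spheres. The cavity surface is discretized
into $M$ tesserae (points $r_i$ with areas $S_i$); the solvent's response
is a set of induced surface charges $q_i$ obtained in the conductor limit
from one linear solve

$$A q = -B Q, \qquad
A_{ij} = \frac{1}{|r_i - r_j|},\quad
A_{ii} = 1.07\sqrt{\frac{4\pi}{S_i}},\quad
B_{iA} = \frac{1}{|r_i - R_A|},$$

the diagonal being the Klamt–Schürmann self-energy of a uniformly
charged tessera. Finite dielectric constants enter only through the Born
scaling factor $f(\varepsilon) = 1 - 1/\varepsilon$:

$$E_{elst} = f(\varepsilon)\,\tfrac12\,k_e\,q^{\mathsf T} B Q,
\qquad k_e = 332.0637\ \mathrm{kcal\,\mathring{A}/(mol\,e^2)}.$$

Because the atomic charges are fixed gas-phase inputs, there is no
self-consistency loop: one cavity, one factorization, one energy. The
working equation makes $q^{\mathsf T}BQ = -q^{\mathsf T}Aq$, an identity
the test suite asserts on every fixture, and the energy is non-positive
for any nonzero charge distribution. Solving in the conductor limit and
scaling afterwards makes the vacuum limit $\varepsilon \to 1$ exact.

**Correction.** The nonelectrostatic part is linear in quantities the
cavity and the solve already provide:

$$\Delta G^\circ_{corr} = \zeta V + \sum_A \kappa_A S_A + \sum_A g_A q_A
\;\left(+\; \xi_{solv} \sum_A S_A\right),$$

where $V$ is the cavity volume, $S_A$ the exposed area of atom $A$, and
$q_A$ the *dielectric-scaled* induced charge aggregated over atom $A$'s
surface patch (so every charge-dependent term vanishes as
$\varepsilon \to 1$). The area term models cavitation plus dispersion, the
volume term implicitly absorbs solute polarization, and the charge term
captures specific first-shell interactions. Solvents fall into four
classes with separate $\kappa_A$, $g_A$, $\zeta$ blocks:

| class | solvents | $\zeta$ (kcal/mol/Å$^3$) |
|---|---|---|
| A | water | 0 |
| B | polar protic (alcohols, phenols) | −0.076 |
| C | polar aprotic | −0.178 |
| D | nonpolar ($\varepsilon < 9$) | −0.129 |

The per-solvent shift $\xi_{solv}$ (classes C and D only) is optional and
defaults to 0 throughout the shipped registry; its fitted values are not
part of the published parameter table, and omitting it costs little
accuracy. A plain-text config file (`name : eps class [xi]`) can supply
values or add solvents. The registry's dielectric constants are standard
25 °C literature values; they are inputs, not fitted quantities. Class
membership of an unknown solvent is never auto-assigned from
$\varepsilon$; the user states the class, and the $\varepsilon < 9$ rule
is only validated for class D.

All nine parameterized elements (H, C, N, O, F, S, Cl, Br, I) share one
radius set for every solvent; class C carries no iodine parameters, and
requesting an unparameterized class/element pair is an error rather than
a silent extrapolation.

## Cavity construction choices

The published description of the surface (32 tesserae per atom on
overlapping modified-Bondi spheres) leaves the tessellation algorithm
open. `cosolv` uses a deterministic Fibonacci (golden-angle) lattice with
exactly equal weights $4\pi R^2/n$, which reproduces every quantity the
model consumes ($S_i$, $S_A$, $q_A$, $S$, $V$) and converges like $O(1/n)$
to the continuum surface. Three choices deserve explanation:

* **Frame anchoring.** A lab-frame tessellation is not rotation
  equivariant: rotating the solute changes which points survive burial
  and moves the energy by amounts far above round-off. Each connected
  cluster of overlapping spheres therefore gets a canonical frame from an
  atomic-number-weighted principal-axes decomposition; the tessellation
  pole is the leading axis and axis signs are fixed by the first
  non-vanishing of (i) the weighted third geometric moment, (ii) the
  charge first moment, (iii) an atom-index moment. The construction is
  equivariant under rotations, translations and reflections, so rigid
  motions leave $\Delta G_{solv}$ unchanged to machine precision, and a
  fragment 50 Å away from everything else is tessellated exactly as it
  would be alone. Axially symmetric clusters (diatomics, linear chains)
  have a degenerate perpendicular axis pair, but with the pole on the
  symmetry axis every azimuthal choice is an isometry of the point set,
  so results are still exactly invariant. The one genuinely open corner
  is an *accidentally* degenerate principal pair in a non-symmetric
  cluster, where equivariance can fail; this is measure-zero for real
  geometries.

* **Burial and seam handling.** A point more than $10^{-9}$ Å below a
  foreign sphere surface is discarded whole (no triangle clipping; the
  discarded-area error is part of the $O(1/n)$ discretization budget).
  Surviving points from different spheres can crowd arbitrarily close
  along seams, and a Coulomb off-diagonal $1/d$ exceeding the
  self-energy diagonal destroys the positive definiteness the solver
  relies on. Points closer than half the local tessera linear size
  $\sqrt{4\pi}R/\sqrt{n}$ (never less than 0.1 Å) are therefore merged —
  areas summed, position area-averaged and re-projected onto the
  larger-area owner's sphere. The threshold scales with refinement, so it
  does not bias convergence; Cholesky factorization succeeded on all 480
  random 2–9-atom cavities in the development sweep at $n$ = 32, 128
  and 512.

* **Volume.** $V$ is the discrete divergence-theorem sum
  $\frac13\sum_i S_i (r_i - c)\cdot n_i$ accumulated per overlap cluster
  about the cluster's atom centroid. This is exact for a single sphere
  (the equal-weight lattice tiles it exactly), exactly invariant under
  rigid motions, and exactly additive over separated fragments — the
  properties the volume term needs so that the correction stays size
  consistent.

The tessellation density (default `n_points = 32`, the published
operating point) is configurable for convergence studies; the Born-limit
error of a single ion falls from ~0.4 % at 32 points to ~0.13 % at 512.

## Parameter fitting

Both correction forms are linear in $(\kappa_A, g_A, \zeta)$, so
parameterization against reference energies is weighted linear least
squares on the response $y = \Delta G^\circ_{ref} - E_{elst}$ with one
area column per element, one induced-charge column per element, and the
volume column. `solv_fit()` solves the problem by QR on the
$\sqrt{w}$-scaled design — a closed-form, deterministic solution — and
reports coefficient standard errors from the weighted residual variance.
Rank deficiency is reported with the names of the collinear columns
rather than silently dropping them. The published weighting scheme
(per-solvent subsets, different weights for ions and neutrals) is not
specified numerically, so all weights default to 1 with a per-row
override column. Radii are treated as fixed model constants and are not
refit; the fit is the linear stage only.

The per-solvent shift is a separate one-parameter fit with the closed
form $\xi = \sum_i r_i S_i / \sum_i S_i^2$ on a solvent's residuals.

Model-quality statistics follow the field's reporting conventions: MSE is
the mean *signed* error, MAE the mean absolute error, and SD the
root-mean-square error (`solv_stats()` documents and tests exactly these
semantics).

## What the synthetic data emulate — and what they do not

All test inputs are generated in code. `make_random_solute()` grows
compact bonded-like clusters (each atom 1.0–1.8 Å from an earlier one, no
pair below 1.0 Å) over H/C/N/O with uniform partial charges in
±0.5 e shifted to an exact integer total — the geometry and charge scales
of small organic solutes and their ions. `make_synthetic_training()`
closes the loop for the fit: it runs the *real* cavity and COSMO stages
for the features and manufactures references
$\Delta G^\circ_{ref} = E_{elst} + \Delta G^\circ_{corr}(\theta^*) +
\mathcal N(0, \sigma^2)$ from planted parameters $\theta^*$, cycling over
dielectric constants typical of class-B alcohols (32.61, 24.85, 19.26)
as fitting subsets. With $\sigma = 0$ the fit must recover $\theta^*$ to
$10^{-8}$; with $\sigma = 0.3$ kcal/mol (the scale of a good experimental
reference) recovery is assessed against the reported standard errors,
which are honestly calibrated (mean squared $z$-score ≈ 0.8 over the
development replicates).

What passing these tests shows: the geometry engine, the linear algebra,
the bookkeeping between modules and the statistical machinery are
correct, and the estimator recovers the generating model. What they do
not show: chemical accuracy against experiment. The generator produces
neither real molecular shapes and conformers, nor real charge
distributions, nor experimental reference energies — benchmarking against
a solvation database with quantum-chemical charges is a separate exercise
outside the package's tests.

Problem sizes in the shipped suite were chosen to exercise every code
path at interactive speeds: solutes of 1–9 atoms (surfaces up to a few
hundred points), tessellations of 32–512 points per atom, training sets
of 30–240 rows, and ten noisy replicates of the recovery study in the
acceptance script.

## Numerical conventions and degenerate inputs

* Coulomb constant $k_e = 332.0637$ kcal·Å/(mol·e²); charges in e,
  lengths in Å, energies in kcal/mol.
* The self-energy constant 1.07 is exposed as `diag_const` in
  `build_system()` because it is a discretization calibration, not
  physics; changing it trades Born-limit accuracy against conditioning.
* $\varepsilon \le 1$ is a domain error. A singular or indefinite
  $A$-matrix reports a remediation hint (raise `n_points`, check the
  geometry) rather than a bare LAPACK error.
* Atomic charges must sum to the declared integer total within 0.01 e
  (semiempirical outputs print rounded charges); atoms closer than 0.1 Å
  are rejected as corrupt input; a missing total-charge record in a
  parsed output is a warning plus an assumed 0, not an error.
* Zero-charge solutes short-circuit nothing: the solve runs and returns
  exact zeros, and only the $\zeta V + \sum\kappa_A S_A (+\xi S)$ terms
  survive.
* Batch processing never aborts on a bad file; the row carries the error
  message and the exit status of the command-line tool signals partial
  failure.

## Known limitations

* Induced charges couple monomers electrostatically even at 50 Å
  (Coulomb and dipole tails through the solve), so the $g_A q_A$ term of
  a charged dimer deviates from monomer additivity by ~10⁻³–10⁻⁴
  kcal/mol. This is physics, not a defect; strict machine-precision
  additivity holds for the geometric terms and for chargeless solutes,
  which is exactly the atom-sum property the correction was designed
  around.
* Separate high-oxidation-state parameters for S and N, refitting of the
  van der Waals radii, temperature dependence and mixed solvents are out
  of scope.
* The model consumes charges; it never computes them. Quality in, quality
  out: with poor input charges the electrostatics are poor.

## A worked call

```{r example}
ion <- make_born_ion("Cl", -1)
solvation_free_energy(ion, "water")
```

The electrostatic term tracks the closed-form Born energy
$-f(\varepsilon) k_e/(2 \cdot 1.75)$ to well under a percent, and the
correction adds the chloride area and induced-charge contributions from
the class-A parameter block.
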