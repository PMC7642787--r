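---
title: "Generalized atom refinement: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized atom refinement: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gar)
```

## The problem and the model

Conventional crystallographic refinement models every atom with a spherical,
isolated-atom form factor (the independent-atom model).  For hydrogen — one
electron, strongly polarized into its bond — that model is badly wrong: X–H
bond lengths refine 0.1 Å too short, and hydrogen anisotropic displacement
parameters (ADPs) are barely refinable at all.  Hirshfeld atom refinement
repairs this by computing a molecular electron density, partitioning it into
*aspherical* atomic densities, Fourier-transforming those into per-atom form
factors, and iterating partitioning and least squares until the geometry is
stationary.  Generalized atom refinement (GAR), implemented here, is the same
loop with the partition treated as an interchangeable component.

Five exhaustive partitions are provided.  All stockholder-type schemes share
the form

$$\rho_a(\mathbf r) \;=\; \rho(\mathbf r)\,
   \frac{w_a(|\mathbf r-\mathbf R_a|)}{\sum_k w_k(|\mathbf r-\mathbf R_k|)},$$

and differ in the spherical weight functions $w_a$:

* **H** (Hirshfeld): isolated neutral-atom densities; one pass, no iteration.
* **IH** (iterative Hirshfeld): a population-interpolated blend of the
  neutral atom and its ions, iterated until the implied populations
  reproduce themselves.
* **IS** (iterative stockholder): $w_a$ is the spherical average of the
  current $\rho_a$ about its own nucleus, iterated to a fixed point, with no
  reference to free-atom densities.
* **MBIS** (minimal-basis iterative stockholder): $w_a$ is a minimal sum of
  normalized Slater shells $N_i\,\zeta_i^3/(8\pi)\,e^{-\zeta_i r}$ whose
  populations and exponents are updated from the partitioned density.
* **B** (Becke): not a stockholder scheme — smoothed Voronoi cells with
  atomic-size adjustment, the same cell functions used for the integration
  grid.  Its charges are not chemically meaningful, which is part of why it
  is interesting as a control.

Every scheme is *exhaustive*: the per-point weights sum to one, so the
atomic densities always reassemble the molecular density exactly.  The total
structure factor therefore differs between schemes only through the
Debye–Waller convolution, which smears each atom's share with its own ADP
tensor.  That is precisely the lever by which the partition choice reaches
the refined hydrogen parameters.

## The synthetic density stand-in

A quantum-chemistry engine is deliberately out of scope.  In its place the
package ships an analytic, polarizable molecular density:

* **Spherical atoms.** Minimal Slater expansions (1 shell for H, 2 for
  C/N/O, 3 for P/S) with exponents derived from screened single-zeta orbital
  exponents (density exponent = twice the orbital exponent, converted to
  1/Å).  Each shell integrates exactly to its population, so electron counts
  are analytic.  Ions at charge states −1…+1 (H, C, N, O) modify the valence
  shell population and contract/dilate its exponent (±15 %); these are
  fixture constants, not physics claims, and `iterative_hirshfeld()` reports
  an error rather than extrapolating outside the shipped bracket — the
  failure mode known for highly ionic oxides is surfaced, not papered over.
* **Dipolar deformations.** Per-atom terms
  $-(\zeta_d/4)\,(\mathbf d_a\!\cdot\!\hat u)\,g(s)$ with
  $g(s) = s\,\zeta_d^4/(8\pi)\,e^{-\zeta_d s}$ carry exactly zero charge and
  a prescribed physical dipole $\mathbf d_a$.  The deformation exponent is
  tied to the outermost shell but contracted by a factor 1.75 so the
  deformation always decays faster than the spherical tail; moderate dipoles
  (≲0.1 e Å on hydrogen) keep the total density positive, and
  `polarized_density()` errors out when a requested point goes negative
  rather than silently clipping.
* **Polarizability.** Linear response $\mathbf d_a = \mathbf d_a^{\rm static}
  + \alpha_a \mathbf E(\mathbf R_a)$ with per-element scalar $\alpha$
  defaults {H 0.4, C 1.8, N 1.1, O 0.8, P 3.6, S 2.9} (Å³ scale,
  order-of-magnitude realism only; configurable).

What this stand-in reproduces: asphericity, polarity, crystal-field
response, exact electron counts, and the partition-dependent ADP convolution
split.  What it does not reproduce: correlation/exchange structure, core
polarization, charge transfer between atoms, or the absolute charges a
quantum density would give.  Tests passing on this model therefore validate
the *machinery* — quadrature, partitions, transforms, least squares,
convergence logic — not the chemistry of any particular compound.

## Quadrature

Molecular integrals use Becke multicenter quadrature: per-atom radial grids
crossed with angular rules, fused with smoothed-cell weights (three
smoothing passes, size-adjustment clipped at $|a_{ij}| \le 1/2$,
Bragg–Slater radii with H at 0.35 Å).

* **Radial.** Power transform $r = a\,x^3$ with $x$ midpoint-uniform on
  (0, 1]; the weight carries the Jacobian and the $r^2$ measure.  The extent
  $a$ defaults to $12\,(R_{\rm BS}/0.35)^{1/3}$ Å per element; node counts
  default to {H 100, C/N/O 148, P/S 175}.  Because the transformed integrand
  has vanishing derivatives at both ends, the midpoint rule converges
  superalgebraically: 148 nodes reproduce a $\zeta = 2$/Å Slater integral to
  1e-10.
* **Angular.** A ladder of rules sized {6, 26, 98, 288, 578, 1152, 1682, …}:
  exact octahedral rules for the two smallest rungs and Gauss–Legendre ×
  uniform-azimuth product rules above, each exact for spherical harmonics up
  to its stated degree.  Pruning uses a small rung inside $0.3\,R_{\rm BS}$,
  the maximum rung through the valence region, and one rung down beyond
  $6\,R_{\rm BS}$.
* **Problem sizes.** Production refinement runs use 48–64 radial nodes and a
  578-point angular cap — enough that shipped-atom form factors are
  converged far below the synthetic noise floor.  Checks asserting
  1e-6-level identities (electron counts, self-partition charges) use the
  full default grid; the closed-form Fourier oracles use a dedicated dense
  rule (300 × 7938) because a ζ = 2/Å tail oscillating against
  $e^{2\pi i\,\mathbf h\cdot\mathbf r}$ at $|\mathbf h| = 1.5$/Å needs
  angular degrees near 110.  These sizes are the package's own accuracy
  choices and are asserted in the acceptance suite.

Numerical guards: stockholder weights fall back to nearest-atom assignment
where the pro-density underflows 1e-30 (such points carry negligible
quadrature mass); iterative-stockholder spherical averages are floored at
1e-30 and interpolated log-linearly between a grid's own radial shells,
clamped at the outermost shell.

## Convergence machinery

Three nested loops, each with an explicit criterion:

1. **Partition iterations** (IH/IS/MBIS): largest population change below
   1e-6 e (and relative exponent change below 1e-6 for MBIS), capped at 500
   iterations.  IH damps its weight updates (factor 0.5) only if charge
   deltas alternate in sign for four iterations.  The plain IS iteration
   contracts linearly with ratio ≈ 0.993 on the 8-atom fixture — more than
   700 iterations to tolerance — so the implementation applies a periodic
   geometric (Aitken-type) extrapolation of the radial profiles every 8
   iterations; convergence is only ever declared from a genuine,
   un-extrapolated iteration, so the accelerator can change *when* the fixed
   point is reached but never *what* is accepted as one.
2. **Multipole embedding**: Hirshfeld charges and dipoles of the current
   density (always Hirshfeld, whatever partition the form factors use, so
   the crystal-field treatment is identical across schemes) are placed on
   all whole-molecule images within 8 Å; dipoles become ±|μ|/s charge pairs
   split by s = 0.02 Å; the Coulomb field of exactly those point charges
   repolarizes the density.  The loop stops when no charge or dipole
   component moves by more than 0.003 atomic units.  Using the split-charge
   field (not an analytic dipole field) means the density feels precisely
   the field the refinement models.
3. **The outer GAR loop**: rebuild density → partition → form factors →
   least squares; stop when both the largest atomic displacement and the
   largest covalent-bond-length change fall below 0.001 Å.  If successive
   geometry steps reverse direction three cycles running, the loop switches
   to averaging the structural parameters and the form factors of the last
   two cycles.  A linear-stability sketch says why: if the undamped cycle
   map has gain λ < −1 (each refinement overcorrects the density's response
   to geometry), two-cycle averaging maps λ to (1+λ)/2, stable down to
   λ = −3.  The shipped `oscillation_fixture()` builds exactly such a
   supercritical coupling (a diatomic whose hydrogen deformation dipole
   follows its displacement, κ = −0.8 e Å/Å — an exaggerated caricature of
   geometry-following bond polarization) and is the acceptance check for the
   damping logic: it diverges with alternating steps undamped and converges
   averaged.

## Least squares

Refinement is against $F^2$ with weights $1/\sigma^2(F_o^2)$ and no
auxiliary weighting parameters.  Gauss–Newton with analytic derivatives of
$|F_c|^2$ with respect to fractional coordinates and CIF-convention
$U_{ij}$; the scale is reset to its closed-form optimum before each step and
refined jointly; step halving guarantees the weighted residual never
increases within accepted steps.  Negative observed intensities are retained
in the target (they only enter $R_1$ through truncation at zero).
Parameter uncertainties come from the inverse normal matrix, rescaled by the
goodness of fit by default (switchable).  Refined ADPs are allowed to go
non-positive-definite but are flagged loudly.  In P1 the origin is
indeterminate (three null directions of the normal matrix); the synthetic
templates therefore default to P-1, and the error message names the
null-space parameters when a user hits the singular case.

CIF $U_{ij}$ follow the reciprocal-basis-scaled convention
$U^{\rm cart} = A\,S\,U^{\rm cif}\,S\,A^{\rm T}$ with
$S = \mathrm{diag}(a^*, b^*, c^*)$ — the de-facto standard of
crystallographic toolkits.  Aspherical form factors under symmetry are
evaluated at the rotated scattering vector $R^{\rm T}\mathbf h$ per
operator (the inverse rotation reuses the complex conjugate since densities
are real), rather than storing per-image densities.

## The synthetic data generator

`make_crystal()` provides an 8-atom planar urea-like molecule (C=O 1.26 Å,
C–N 1.34 Å, N–H ≈ 1.0 Å) in a 6.0 × 5.4 × 4.6 Å cell, and an O–H diatomic,
both defaulting to P-1 with the molecule at a general position.  True ADPs
are fixed template constants on the realistic scale (heavy atoms
0.010–0.018 Å², hydrogens 0.024–0.034 Å², mild anisotropy).
`simulate_reflections()` enumerates a unique hemisphere to `d_min`
(default 0.8 Å; the acceptance runs use 0.9 Å to stay desk-scale), computes
$F$ through the full pipeline, and adds Gaussian noise with
$\sigma(h) = \max(0.5,\; 0.02\,|F|^2)$ by default — chosen once to put wR2
in the low single-percent range typical of careful small-molecule work, with
no claim of modelling counting statistics.

One non-obvious choice: the generator must commit to an atom-wise split for
the ADP convolution, and it uses the Hirshfeld partition by default (the
same reference role it has in the embedding).  Data generated that way carry
a Hirshfeld imprint: stockholder-family refinements agree with each other to
≈ 2 × 10⁻⁶ Å on such data, while the Becke cell partition deviates by a few
10⁻³ Å — the partition artefact itself, made visible.  The generator
therefore accepts a `scheme` argument so every scheme can also be tested as
an exact round trip against its own split.

## Comparison statistics

For an X-ray-refined structure against a neutron benchmark: per-bond
ΔR = R_X − R_N (reported in mÅ) with
wRMSD = [⟨ΔR²/σ²(ΔR)⟩]^{1/2} and σ²(ΔR) = σ_X² + σ_N² (the variance of a
difference of independent measurements — the only defensible reading);
⟨ΔR⟩, ⟨|ΔR|⟩ and the unweighted ⟨R_X/R_N⟩; per-atom ADP component
differences (six unique Cartesian components, flat mean); the similarity
index S12 = 100(1 − R12) with the Gaussian overlap in closed form,

$$R_{12} = 2^{3/2}\,[\det U_1 \det U_2]^{-1/4}\,
   [\det(U_1^{-1}+U_2^{-1})]^{-1/2},$$

cross-checked against direct 3-D numerical integration; ellipsoid volume
ratios $\sqrt{\det U_X/\det U_N}$; and the population standard deviation
(divide by n, not n−1) attached to every mean.  Neutron ADPs can be rescaled
isotropically by the least-squares factor
$k = \sum U_X U_N / \sum U_N^2$ over a (conventionally non-hydrogen)
selection, for benchmark pairs measured at slightly different effective
temperatures.

## Known limitations

* The density stand-in is analytic; absolute charges and fine density
  topology are not comparable to quantum-mechanical results.
* Symmetry support is verbatim operator lists (tested with P1 and P-1);
  no space-group symbol lookup, no special-position constraints.
* No restraints, twinning, extinction, anomalous dispersion, or anharmonic
  (Gram–Charlier) displacements; multipoles stop at dipoles.
* Reflection I/O is HKLF-4 only; structure I/O is a deliberate CIF 1.1
  subset.
* Angular rules above the 26-point rung are product rules of matched degree
  rather than true Lebedev–Laikov sets (≈ 40 % more points for the same
  degree); the integration-exactness contract is identical.
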