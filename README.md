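# gar — generalized atom refinement with alternative electron-density partitions

Crystallographic least-squares refinement against X-ray intensities in which
every atom scatters with an *aspherical* form factor derived from a
partitioned molecular electron density, rather than the spherical
isolated-atom factor of conventional refinement.  This is the
Hirshfeld-atom-refinement idea with the partition treated as an
interchangeable component — hence *generalized* atom refinement (GAR).  The
package is aimed at people studying how the choice of density partition
propagates into refined structural parameters, above all hydrogen positions
and hydrogen anisotropic displacement parameters (ADPs), where aspherical
models matter most.

## What is inside

* **Five exhaustive partitions** of a density sampled on a multicenter
  grid: Becke cells (B), Hirshfeld (H), iterative Hirshfeld (IH), iterative
  stockholder (IS), and minimal-basis iterative stockholder (MBIS).  All
  stockholder schemes share
  `rho_a(r) = rho(r) * w_a(|r−R_a|) / sum_k w_k(|r−R_k|)`
  and differ only in the spherical weight functions `w_a`.
* **Becke multicenter quadrature**: power-transform radial grids
  (`r = a x^3`), an angular ladder exact for spherical harmonics up to the
  rule's degree, smoothed-cell fusion, pruning.
* **Aspherical form factors** `f_a(h) = ∫ rho_a(r) exp(2πi h·(r−R_a)) dV`
  by grid quadrature, Debye–Waller smearing `exp(−2π² hᵀUh)`, and symmetry-
  aware structure-factor assembly.
* **Self-consistent crystal-field embedding**: Hirshfeld charges and
  dipoles on all whole-molecule images within 8 Å (dipoles as ±q pairs
  split by 0.02 Å), iterated to 0.003 a.u.
* **Weighted least squares against F²** (`w = 1/σ²`, no auxiliary weighting
  parameters), Gauss–Newton with analytic derivatives, wrapped in the GAR
  outer loop with a 0.001 Å geometry criterion and two-cycle averaging when
  the loop oscillates.
* **Neutron-benchmark statistics**: ΔR and ΔU_ij aggregates, weighted RMS
  differences, the S12 similarity index
  `S12 = 100(1 − R12)`, `R12 = 2^{3/2} [det U1 det U2]^{−1/4}
  [det(U1^{−1}+U2^{−1})]^{−1/2}`, ellipsoid-volume ratios
  `sqrt(det U_X / det U_N)`, population standard deviations, and isotropic
  neutron-ADP rescaling.
* **A synthetic molecular crystal** (urea-like 8-atom planar molecule or an
  O–H diatomic, P1/P-1) with an analytic, polarizable electron density and
  a noisy diffraction simulator — so the whole pipeline runs and is tested
  with no quantum-chemistry software and no downloads.

File formats: CIF 1.1 subset (cell, symmetry operator list, atom sites,
aniso ADPs), SHELX HKLF-4 `.hkl`, XYZ, YAML/JSON run configs.

## A worked example

Simulate a noise-free urea-like crystal, displace its hydrogens by 0.05 Å,
and let the MBIS-based refinement find them again:

```r
library(gar)

cr    <- make_crystal(synthetic_spec("urea_like"))
model <- molecular_density_model(cr$structure)
refl  <- simulate_reflections(cr$structure, model, d_min = 0.9,
                              noise = "none", scheme = "mbis")

start <- cr$structure
for (a in which(site_table(start)$elements == "H"))
  start$sites[[a]]$frac_pos <- start$sites[[a]]$frac_pos +
    cart_to_frac(start$cell, c(0.05, 0, 0))[1, ] * (-1)^a

res <- gar_loop(start, refl, gar_settings("mbis", max_outer = 10),
                verbose = TRUE)
#> cycle  1  max|dx| 0.050019 A  max|db| 0.042241 A  R1 0.0000  wR2 0.0000
#> cycle  2  max|dx| 0.000039 A  max|db| 0.000036 A  R1 0.0000  wR2 0.0000

max(sqrt(rowSums((site_table(res$structure)$cart -
                  frac_to_cart(cr$structure$cell, cr$truth$frac))^2)))
#> [1] 1.917493e-08
```

The first cycle's refinement pulls the hydrogens the full 0.05 Å back to
the generating geometry (`max|dx|` is the step taken in that cycle); the
second cycle confirms stationarity below the 0.001 Å threshold, and the
recovered positions match the ground truth to ~1e-8 Å, with wR2 at the
numerical floor since the data are noise-free.  The partition's charges are
in `res$partition$charges`, and per-cycle convergence in `res$trace`.

Command-line use (`inst/cli/gar.R`):

```sh
Rscript inst/cli/gar.R simulate --template urea_like --dmin 0.9 --seed 7 --out fix/
Rscript inst/cli/gar.R refine   --cif fix/crystal.cif --hkl fix/crystal.hkl --scheme mbis --out run/
Rscript inst/cli/gar.R compare  --xray run/refined.cif --neutron fix/crystal.cif --out stats/
```

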