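# apatitepdf

Real-space (pair distribution function) analysis of nanocrystalline and
carbonate-substituted hydroxyapatite.

Bone mineral and many synthetic calcium phosphates are nanocrystalline
hydroxyapatite, Ca₁₀(PO₄)₆(OH)₂, in which carbonate substitutes for
phosphate (B-type) or hydroxyl (A-type). Bragg diffraction from such
platy, ~20–40 Å-thick crystallites is severely broadened, and Rietveld
refinement often returns unphysical structures. Total scattering sidesteps
this: the pair distribution function

G(r) = s·γ(r)·e^{−(Q_damp r)²/2} · [ R(r)/r − 4πr ρ₀ ],
  R(r) = Σ_{i≠j} (occ_i Z_i)(occ_j Z_j)/(N⟨Z⟩²) · N(r; d_ij, σ_ij(r))

is fitted directly in real space over 1–50 Å with a single-unit-cell
("small-box") model. This package implements that pipeline for apatite:

- an **ordered P1 cell** (42 non-H sites) built from asymmetric-unit
  parameters and a five-atom rigid-body PO₄ parameterisation (3 bond
  lengths, 2 angles, 2 torsions, one z rotation), avoiding the false PDF
  peaks that partially occupied mirror-split sites produce;
- a **forward G(r)** with a nanosheet shape envelope
  γ(r) = 1 − r/(2t) (r ≤ t), t/(2r) (r > t) for platy crystallites,
  Gaussian instrumental damping, and an r-dependent correlated-motion
  temperature factor interpolating between `beqlo` (r = 0) and `beqhi`
  (r ≥ 2R) with the two-sphere overlap volume;
- **bounded least-squares refinement** (Levenberg–Marquardt, numerical
  Jacobian, esds from the scaled covariance) with optional staging;
- a **charge-balanced composition layer**
  Ca₁₀₋ₓ(PO₄)₆₋ₓ(CO₃)ₓ(OH)₂₋ₓ linking carbonate wt% to expected site
  occupancies (P occupancy (6−x)/6) and crystal density;
- **Scherrer coherence lengths** from split pseudo-Voigt single-peak fits
  of 002/030 maxima; **FT-IR carbonate quantification** from a fixed-centre
  (878/873/866 cm⁻¹) Voigt triplet and a ν₂CO₃ : ν₁ν₃PO₄ area-ratio
  calibration; **correlation reports** (p, adjusted R², signed Pearson r)
  relating refined parameters to carbonate content;
- **synthetic-data generators** that produce every input with known ground
  truth (PDFs, IR spectra, diffraction peaks, multi-sample cohorts with a
  planted occupancy–composition relationship).

## Worked example

Simulate a carbonated nanocrystalline sample (5.6 wt% CO₃, sheet thickness
28 Å, 1% noise), refine occupancies and thickness, and read the carbonate
content back from the refined P occupancy:

```r
library(apatitepdf)

comp  <- expected_occupancies(5.6)
grid  <- pdf_grid_range(1, 50, 0.05)
truth <- ha_parameter_set(t = 28)
for (nm in names(comp$occupancies))
  truth <- set_param(truth, nm, value = comp$occupancies[[nm]])

model <- ha_pdf_model(grid)
obs   <- make_pdf_sample(truth, grid, noise = 0.01, seed = 17, model = model)$pdf

start <- ha_parameter_set(t = 35)
for (nm in names(comp$occupancies)) start <- set_param(start, nm, value = 0.9)
start <- refine_only(start, c("occ_P", "occ_O1", "occ_O2", "occ_O3",
                              "occ_Ca1", "occ_Ca2", "occ_OH", "t"))
res <- refine(obs, start, model)
res
#> refinement: rw 0.04576 (from 0.10218), 5 iterations, converged
#>     name      value     esd
#>    occ_P  0.8692052 0.00353
#>   occ_O1  0.8629265 0.00719
#>   occ_O2  0.8516393 0.00691
#>   occ_O3  0.8593474 0.00539
#>  occ_Ca1  0.9181725 0.00336
#>  occ_Ca2  0.9135606 0.00244
#>   occ_OH  0.5685707 0.01280
#>        t 27.8538070 0.17200

x <- 6 * (1 - param_values(res$params)[["occ_P"]])
co3_wtpc_from_x(x)
#> 5.05
```

The refined P occupancy 0.869(4) sits close to the charge-balance
expectation (6−x)/6 = 0.856 for 5.6 wt% CO₃; the sheet thickness 27.9(2) Å
recovers the generating 28 Å. The implied composition, 5.05 wt%, is what
the occupancy route to carbonate quantification returns at this noise
level.

A command-line front end covers the same stages
(`simulate | refine | scherrer | ftir | report`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "apatitepdf.R", package = "apatitepdf"))') \
    simulate --out cohort/ --n 13 --seed 7
```

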