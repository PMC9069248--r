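---
title: "Real-space refinement of nanocrystalline apatite: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-space refinement of nanocrystalline apatite: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatitepdf)
```

This vignette is the package's account of the science it implements: the
structural model, the forward G(r) calculation, the refinement and
composition layers, the synthetic-data generators, and the choices made
where the design was genuinely open.

## The ordered P1 apatite cell

Hydroxyapatite is conventionally described in P6₃/m, but that description
contains partially occupied, mirror-split sites (most prominently the
channel hydroxyl at (0, 0, z) and (0, 0, ½−z)). A small-box PDF model that
populates both mirror images at half occupancy imprints spurious short
O(H)⋯O(H) vectors (~0.8 Å for physical z) on the calculated curve. We
therefore expand an *ordered* P1 cell: full P6₃/m orbits for the calcium
sublattice (4 Ca1 + 6 Ca2), but only the six *proper* P6₃ operators for
the phosphate rigid bodies and the hydroxyl column. That yields exactly 42
non-hydrogen sites (4 + 6 + 6 P + 6 O1 + 6 O2 + 12 O3 + 2 O(H)), one
hydroxyl per channel position displaced in a single global +z sense, and —
because the out-of-plane O3a/O3b atoms are explicit — no accidental
mirror-image phosphates when the two torsions are refined asymmetrically.
The relative orientation of the two channel segments is not resolvable
from an isotropic PDF, so a single ordered choice is sufficient.

Each PO₄ is a rigid body: P, O1, O2 on the crystallographic mirror plane
(z = ¼ or ¾, not refinable), O3a/O3b out of plane. Its seven internal
parameters are the three P–O bond lengths, the O1–P–O2 and O1–P–O3 angles,
and the torsions of O3a/O3b about the P–O1 axis measured from the O2
half-plane; an ideal tetrahedron is 1.52 Å / 109.5° / 120° and 240°. The
local frame places O2 clockwise from O1 (viewed from +z), which reproduces
the handedness of the literature phosphate; torsions are counted
counter-clockwise about P→O1. Default geometry is measured from the
classic single-crystal coordinates and frozen
(1.537/1.542/1.531 Å, 111.16°/111.28°, 119.91°/240.09°, z-rotation
141.95°).

## Forward model

```
G(r) = s · γ(r) · exp(−(Q_damp r)²/2) · [ R(r)/r − 4π r ρ₀ ]
```

with `R(r)` the weighted sum over all periodic pairs, each broadened by a
Gaussian of variance σ² = (Bᵢ(d) + Bⱼ(d))/(8π²). Weights use the
atomic-number approximation wᵢ = occᵢ Zᵢ normalised by N⟨Z⟩²
(N = Σ occ, ⟨Z⟩ = Σ occ·Z / N), and ρ₀ = N/V. Hydrogen is excluded
throughout (negligible X-ray weight; only the hydroxyl oxygen is
modelled). Conventions worth stating:

- **Correlated motion.** The effective temperature factor rises from
  `beqlo` at r = 0 to `beqhi` at r ≥ 2R along the overlap-volume fraction
  of two spheres of radius R: B(r) = beqhi − (beqhi−beqlo)(1 − 3r/4R +
  r³/16R³). One B-pair per species (Ca, P, O) with a single shared radius;
  defaults beqlo ≈ 0.4–0.6 Å², beqhi ≈ 0.9–1.4 Å², R = 4 Å are ordinary
  apatite magnitudes.
- **Nanosheet envelope.** Platy crystallites attenuate G(r) by the
  orientation-averaged autocorrelation of an infinite slab of thickness t:
  γ(r) = 1 − r/(2t) for r ≤ t and t/(2r) beyond. It multiplies the whole
  curve (the model and envelope are both isotropic; anisotropic,
  plate-axis-resolved shape functions are out of scope). Both γ and B(r)
  are verified against Monte-Carlo geometry oracles in the test suite.
- **Instrumental damping** is the standard Gaussian exp(−(Q_damp r)²/2);
  Q_damp is calibrated by refining the silicon standard and then fixed
  (default 0.03 Å⁻¹).
- **Termination ripples** from the finite Q_max of the reduction are *not*
  convolved into the model; Q_min/Q_max (defaults 0.5/25.6 Å⁻¹) ride along
  as metadata. Small-box practice absorbs ripple structure into the
  residual; revisit if fitting data with strong ripples.
- **Numerics.** The pair sum is compiled; Gaussians are truncated at 8σ
  (relative error < 1e-14) and evaluated with an incremental recurrence;
  lattice images are enumerated out to r_max + 8σ_max. Agreement with a
  brute-force tiled double loop is ~1e-13 on toy cells. The r grid must be
  uniform; observed and calculated curves share one grid.

## Refinement

Bounded Levenberg–Marquardt least squares (numerical Jacobian) minimises
Σ(G_obs − G_calc)² over the flagged parameters with unit weights across
the 1–50 Å range; convergence at relative SSR change 1e-10 or 200
iterations; esds are √diag of the reduced-χ²-scaled covariance, flagged
approximate when a parameter ends on a bound. `staged_refine()` runs the
conventional stabilising order (scale+damping → lattice → coordinates →
rigid body → occupancies/ADPs → thickness); on well-posed noise-free
problems staged and joint refinement agree to the optimizer tolerance.

One structural degeneracy matters and is easy to miss: scaling *all*
occupancies by f is mathematically identical to scaling s by f in this
G(r) convention. Occupancy refinement is therefore only meaningful
relative to a known normalisation — properly reduced total-scattering data
are on an absolute scale — and the occupancy-recovery protocols in this
package hold s fixed while refining occupancies and thickness jointly.
Lattice-parameter refinements are insensitive to this (peak *positions*
carry the signal): a deliberately mis-set scale biases the recovered
silicon a by well under 0.005 Å.

## Composition and density

Carbonate is not placed explicitly; it is expressed through occupancies,
as in the refinement it mirrors. The charge-balanced B-type model with a
phosphorus-site vacancy,

Ca₁₀₋ₓ(PO₄)₆₋ₓ(CO₃)ₓ(OH)₂₋ₓ  (cations 2(10−x) = anions 3(6−x)+2x+(2−x)),

maps carbonate wt% to x by a monotone root-find (tolerance 1e-12) and
implies expected occupancies P (6−x)/6, Ca (10−x)/10, OH (2−x)/2. No
A-type term is included: the ideal-model comparison this layer feeds
assumes the P-site vacancy mechanism, and sodium-balanced variants are
deliberately out of scope. The model is valid up to x = 2 (≈14.6 wt%).
Density is formula mass per cell over N_A·V (stoichiometric apatite at the
certified reference cell: 3.149 g cm⁻³).

## Peak metrics and FT-IR

Coherence lengths come from single-peak split pseudo-Voigt fits (linear
background; independent width and mixing on each side) and Scherrer's
CL = Kλ/(β cosθ) with K = 0.9, β the mean FWHM in radians, Cu Kα by
default; instrumental broadening can be subtracted in quadrature but is
off by default. These desk conventions are stated because K and the
breadth convention materially rescale CL.

Carbonate quantification windows the ν₂CO₃ region to 910–840 cm⁻¹,
subtracts a linear baseline anchored on the mean of the five outermost
points at each end (single-point anchors transmit point noise straight
into the band area; averaging keeps the correction exact for a linear
background), fits three pseudo-Voigts with centres fixed at 878/873/866
cm⁻¹, and ratios the triplet area to the ν₁ν₃PO₄ net area over 1200–900
cm⁻¹ (integration limits are a package default; the phosphate envelope
window is not standardised). Calibration regresses known wt% on the area
ratio — the direction that predicts directly — and predictions are floored
at zero. The overlapped triplet makes the least-squares surface
multimodal, so the fit runs from a narrow and a broad width start and
keeps the better optimum. "Voigt" means pseudo-Voigt with analytic area;
at 4 cm⁻¹ resolution the distinction from a true Voigt is immaterial.

## Statistics

`regress()` is ordinary least squares with intercept, reporting the
two-sided slope p, adjusted R² = 1 − (1−R²)(n−1)/(n−2), and the signed
Pearson correlation; rows with p ≥ 0.05 display as a dash in the report
tables. No multiple-testing correction enters the significance flags
(matching per-row reporting practice); a Benjamini–Hochberg column is
emitted alongside for transparency. Group contrasts use Welch's t-test
(the unequal-variance choice is ours; pooled-variance results would be
nearly identical at these group sizes). Parameters held constant across a
cohort are dropped from the report — there is no relationship to estimate.

## Synthetic data: what it emulates and what it does not

Generators are pure functions of (spec, seed) and carry their ground truth
alongside. A cohort draws carbonate contents uniformly in the group range
(low-temperature group: 13 samples, 1.96–7.98 wt%, t ∈ 20–40 Å;
high-temperature: 5 samples, 1.24–8.12 wt%, thicker crystals), sets true
occupancies from the charge-balance model, and emits per sample a PDF
(forward model + Gaussian noise scaled to max|G|), an IR spectrum whose
ν₂:ν₁ν₃ area ratio is proportional to wt% (triplet area split 0.3/0.5/0.2
across the three fixed centres — a declared convention), and an 002/030
pattern whose breadths follow Scherrer at CL002 = 10t, CL030 = 25t,
reflecting the near-tenfold excess of Bragg coherence lengths over
real-space sheet thickness in platy apatite. IR components are generated
in the Gaussian limit so that no Lorentzian tail crosses the fixed
integration windows and the planted ratio–wt% relation is exactly linear.

Because 100 repetitions of a 13-sample × full-refinement campaign are not
a sensible desk-scale computation, each cohort also carries a "measured"
parameter table: truth plus Gaussian scatter at typical refined-esd
magnitudes (e.g. 0.002 Å on lattice parameters, 0.015 on P occupancy).
Cohort-level statistical properties (the planted negative occ_P–CO₃
correlation is detected in ≥95 of 100 seeded cohorts) are established on
these tables, while the refinement engine's own recovery (occ_P within
0.03, t within 10% at 2% noise; lattice parameters within 0.002 Å from
±0.5% perturbed starts) is demonstrated by actually refining generated
PDFs.

What passing these tests does **not** show about real data: the generator
draws noise i.i.d. (real PDF noise is correlated and r-dependent), embeds
no termination ripples, no amorphous-phase signal, no anisotropic
broadening, and its peak patterns contain exactly the two reflections the
size pipeline fits. Synthetic recovery bounds are therefore lower bounds
on real-data difficulty.

## Problem sizes and degenerate inputs

The test suite refines on 1–50 Å grids (0.05 Å step) where the full
pipeline is exercised and on 1–25 Å (0.1 Å step) in the six-draw random
truth recovery sweep; those sizes are the package's chosen balance of
coverage against runtime on a single CPU. Degenerate inputs fail loudly:
non-monotone grids, empty structures, zero-variance regressors, windows
outside a spectrum, non-finite residuals during refinement; overlapping
sites (< 0.1 Å) warn rather than fail, and fractional coordinates are
always reduced into [0, 1). Known limitations: no anisotropic shape
functions, no Q-space fitting, no explicit carbonate geometry, no Rietveld
layer — the single-peak + Scherrer route is the deliberate desk-scale
stand-in for full-profile analysis.
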