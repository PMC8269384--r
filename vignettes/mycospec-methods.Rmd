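---
title: "Methods: chemometrics of fungal biomass vibrational spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometrics of fungal biomass vibrational spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycospec)
```

## The problem and the data model

Mucoromycota filamentous fungi are screened for biotechnological
production of lipids, cell-wall polysaccharides, polyphosphates and
carotenoids. Two vibrational blocks describe the same biomass samples:
FT-Raman spectra (1064 nm excitation, 3785–50 cm⁻¹) and FTIR
transmission spectra (4000–400 cm⁻¹), both on a 1.928 cm⁻¹ digital
grid. The cultivation design is factorial: 6 strains (Ar, Mc1, Mc2, Mr,
Rs, Uv) × 3 phosphate levels (Pi0.5, Pi1, Pi4) × calcium
presence/absence (Ca1/Ca0) × 2 independent biological replicates = 72
biological samples, each measured in 3 technical replicates (216 spectra
per block).

A `spectra_set` holds the aligned intensity matrix (rows = spectra,
columns = wavenumbers on a strictly descending grid), the per-spectrum
design metadata, and optionally the reference chemistry (total lipids
and phosphorus in % of dry weight, carotenoids in µg/g DW). Region
bounds are always treated as closed intervals in cm⁻¹. On disk the
canonical format is a wide CSV plus metadata/chemistry sidecars; CSV
keeps fixtures diff-able and round-trips losslessly at full double
precision. A minimal JCAMP-DX reader (AFFN `(X++(Y..Y))` and XYPOINTS)
covers instrument exports; interpolation onto a common grid is
piecewise linear with no extrapolation, ever.

## Preprocessing

Two recipes per block, applied strictly in order:

| recipe           | steps |
|------------------|-------|
| `raman_nonderiv` | SG(2, 15, 0) → rubber band → truncate [3200–2400] ∪ [1900–500] → EMSC(3) |
| `raman_deriv`    | SG(2, 15, 2) → EMSC(3) → truncate [1800–900] |
| `ftir_nonderiv`  | EMSC(3) |
| `ftir_deriv`     | SG(2, 15, 2) → EMSC(2) → truncate [1800–900] |

**Savitzky–Golay.** Local quadratic least squares in a 15-point window;
derivatives are scaled by the grid spacing so order-m output is per
(cm⁻¹)ᵐ. The descending grid is differentiated on its ascending copy and
restored. Edges use the filter's one-sided polynomial fits — no
reflection padding — so polynomials up to the filter order are
reproduced exactly everywhere.

**Rubber band.** The baseline is the lower convex hull of the
(wavenumber, intensity) points (Andrew's monotone chain), interpolated
piecewise-linearly and subtracted; corrected spectra are exactly zero at
hull vertices, including both endpoints, and the operation is
idempotent. Peaks must point up.

**EMSC.** Each spectrum is least-squares fitted to
`s = a·m + Σ_{k=0..d} c_k uᵏ`, where `m` is the reference spectrum and
`u` is the wavenumber axis rescaled to [−1, 1]; the corrected spectrum
is `(s − Σ c_k uᵏ)/a`. Plain monomials are used: at degree ≤ 3 on
[−1, 1] the design is well conditioned, and "linear, quadratic and cubic
extension" is read as the degree-3 model including the constant. The
default reference is the mean of the set being corrected; in any
calibration/validation split the reference is recomputed on the
**training partition only** (at the EMSC step's position in the chain)
and reused for the test partition — otherwise the validation spectra
leak into the model. A reference collinear with the polynomial baseline
makes the fit singular and is rejected with advice to pick another.

Technical replicates are averaged (arithmetic mean per biological
sample) *after* preprocessing, restoring one-to-one row correspondence
between blocks.

## Replicate QC

For each biological sample all pairwise Pearson correlations between its
technical replicates are computed across the (preprocessed,
non-derivative) wavenumber axis; the variability score is 1 − mean PCC
(0 = perfect reproducibility, 2 = perfect anticorrelation). The
arithmetic mean over the three pairs is used — a min or max aggregation
would be defensible too, but the mean is the least noisy of the three
for a 3-replicate design. Zero-variance replicates have undefined PCC;
their pairs are excluded from the mean with a warning rather than
silently dropped.

## PCA and consensus PCA

PCA is computed by SVD of the mean-centered matrix with a deterministic
sign convention (each loading's largest-magnitude element is positive),
so scores and figures are reproducible run to run. Consensus PCA of the
two derivative blocks: each centered block is scaled to unit total sum
of squares — the blocks have different numbers of channels and raw
scales, and equal-SS weighting is the neutral choice when no block
should dominate a priori — the scaled blocks are concatenated and the
global model is the PCA of the super-matrix. Block loadings are the
global loading segments renormalized to unit length, block scores are
the scaled block times the block loading, and the squared norm of the
(unnormalized) segment is the block's contribution to that component.
For the extracted components this concatenated-PCA formulation agrees
with the NIPALS consensus algorithm under these weights, and it is
deterministic and directly checkable against an eigensolver.

## PLSR calibration

Single-response PLS by the classical NIPALS weight/score/deflation
scheme on mean-centered data; coefficient vectors are stored for every
number of components A. Cross-validation is leave-one-biological-sample-
out within the training partition — all technical replicates of a sample
leave together, since replicates of one sample are not independent.
The parsimony rule selects the smallest A whose RMSECV is at most
(1 + τ) times the minimum, τ = 0.05 by default; the one-standard-error
rule is available (`rule = "one_se"`). Model validation is strictly by
biological replicate: bioreplicate 1 trains (including the EMSC
reference), bioreplicate 2 validates; overlapping sample ids raise a
leakage error. Models are fitted on replicate-level spectra and
predictions are reported per biological sample as replicate means.
Responses stay in their natural units (% DW, µg/g DW); no response
scaling. Both calibration- and validation-partition R²/RMSE are
reported, since either may be wanted downstream.

Band-intensity ratios read the nearest grid point (lookup error ≤ half
the 1.928 cm⁻¹ spacing) on non-derivative Raman data; presets:
1747/1445 (lipid carbonyl over total-biomass CH deformation), 1163/1155
(polyphosphate P=O over chitin), 1523/1445 (carotenoid C=C over total
biomass).

## ANOVA variance decomposition

Per strain, on replicate-averaged derivative spectra truncated to
1800–900 cm⁻¹: the grand mean is removed and the matrix is decomposed
into level-mean effect matrices for calcium (2 levels), phosphate (3),
their interaction (6 cells, defined as cell mean minus both main
effects — the classical two-way decomposition; using raw cell means for
the "six-level factor" would double-count the main effects), and
biological replicate (2), plus residual. On the balanced 3×2×2 design
the effect matrices are mutually orthogonal and the sums of squares are
additive, which is why unbalanced input is rejected outright rather
than decomposed approximately. Contributions are normalized to 100 %
over the four design factors; the residual is reported separately as a
share of total SS (both conventions circulate, so both numbers are
emitted). The derivative recipe is the default but the non-derivative
recipe can be decomposed identically; the choice is recorded in the
output.

## The synthetic-data generator

The generator produces the statistical structure that the analysis
assumes, with known ground truth:

- **Band structure.** Each of six components (lipid, chitin,
  chitosan/glucan, protein, polyphosphate, carotenoid) is a sum of
  unit-peak Lorentzians at its catalogued band positions, FWHM
  16 cm⁻¹ (10 cm⁻¹ for the resonance-enhanced carotenoid bands) —
  typical condensed-phase Raman linewidths; no linewidths are published
  for these samples. Carotenoid bands exist only in the Raman catalog:
  at biomass concentrations carotenoids are FTIR-silent, and only the
  resonance Raman effect makes them visible.
- **Concentrations.** Per-strain log-normal around the geometric
  mid-point of the published per-strain ranges (lipids e.g. Uv 49–83 %,
  Rs 22–28 % DW; phosphorus e.g. Ar 2.65–6.24, Uv 0.64–1.37 % DW), with
  multiplicative phosphate/calcium modifiers: low phosphate raises
  lipids toward the range top; phosphate supply raises phosphorus
  storage while calcium absence suppresses it (acidocalcisome formation
  is calcium-dependent), more strongly at high Pi; chitin is
  overproduced under low-phosphate acid stress and suppressed without
  calcium (chitin synthase is Ca-dependent). Carotenoid production in
  the carotenogenic strains (Ar, Mc1, Mc2) is induced by the
  low-phosphate/no-calcium stress cell — a ~10.4× multiplier for Mc2,
  concentrated in the Pi0.5/Ca0 cell with near-baseline production
  elsewhere, reproducing the reported hot spot (~1457 vs ~140 µg/g).
- **Bioreplicate jitter.** Log-normal per biological sample; small for
  structural components (sdlog 0.05–0.10) and larger for pigments, with
  the carotenoid log-sd growing with induction strength
  (σ = 0.30 + 0.215·log mult, i.e. ≈0.8 at the Mc2 hot cell): strongly
  stress-induced secondary-metabolite production is proportionally the
  most variable between independent cultivations. This term is what
  makes FTIR-based carotenoid calibration fail honestly — the FTIR
  block sees only design-correlated constituents, and the large
  sample-specific pigment variance does not transfer between
  bioreplicates — while Raman calibration still succeeds because the
  resonance-enhanced bands track the realized concentration directly.
- **Instrument model.** Per spectrum: log-normal multiplicative gain
  (sdlog 0.12), random cubic baseline drift (coefficient sd 0.02 a.u.),
  white noise (sd 0.004 a.u.), and — for the ten heating-flagged
  samples (Rs at Pi1/Pi4 under both Ca conditions, Ar at Pi4/Ca1),
  which are recorded at reduced 200 mW laser power — a broad Gaussian
  thermal-emission baseline rising toward low wavenumbers (center
  −300 cm⁻¹, σ 700 cm⁻¹, amplitude 2.0 a.u. scaled ×0.4 at 200 mW,
  with ×0.3 log-normal between-replicate amplitude jitter) plus a 3×
  noise floor. The emission magnitude is a free parameter: it is shown
  only qualitatively in published spectra, so the default is a choice,
  not a claim.
- **Determinism.** One seed governs everything through five independent
  substreams (concentrations, gains, drifts, heating, noise), so any
  one source can be zeroed in tests without displacing the others, and
  the same seed is bit-reproducible. The Raman block is identical
  whether or not the FTIR block is also generated.

Both blocks share the same concentration draws, so they describe the
same biological material; the chemistry table carries the true values.

What the generator does **not** emulate: physically accurate Raman
cross-sections, fluorescence photobleaching kinetics, instrument line
shapes, water-vapor/CO₂ interference, or cosmic-ray spikes. Passing
parameter-recovery tests therefore shows the *workflow* is correct and
well-calibrated under the stated noise model — not that any particular
accuracy will be achieved on real instrument data.

## Numerical choices and degenerate inputs

- Wavenumber axis stored descending; ascending input is flipped on
  construction. Non-finite intensities, ragged rows and duplicate
  wavenumbers are rejected at read time with the offending row/column
  named.
- Interpolation is linear and never extrapolates; alignment fails if
  spectra do not overlap.
- PCA/PLSR tie-breaks are fixed by the sign convention; PLS component
  extraction stops early if the weight vector vanishes.
- `select_aopt` with τ = 0 reduces to the RMSECV argmin; a
  single-component model returns 1.
- Zero-variance responses, empty truncation results, unbalanced ANOVA
  designs, misaligned CPCA blocks and partition leakage are errors, not
  warnings.

## Problem sizes used in the packaged checks

The test suite and the acceptance script run the full default design
(216 spectra per block, two blocks) end to end — the complete pipeline
takes a few seconds — with smaller ad-hoc matrices (8–72 rows) for the
algebraic oracles: eigendecomposition for PCA, OLS-limit for PLSR,
exhaustive supporting-chord hulls (200-point spectra) for the rubber
band, and 200-replicate null simulations for the ANOVA
degrees-of-freedom calibration.

## Known limitations

- The FTIR-carotenoid negative control is intentionally marginal: with
  only 12 training samples the failure of FTIR-based carotenoid
  calibration is itself noisy (the models are *unstable* rather than
  uniformly poor), and its validation R² varies considerably between
  generator seeds. The packaged check pins the seed.
- CPCA equivalence with NIPALS-based consensus algorithms holds for the
  equal-SS block weighting implemented here; other weightings (e.g.
  per-variable scaling) would need the iterative algorithm.
- The ANOVA decomposition requires the complete balanced design; cells
  lost to failed cultivations would need a missing-data strategy that is
  out of scope.
- JCAMP-DX support is reader-only and AFFN-only (no SQZ/DIF/DUP
  compression).
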