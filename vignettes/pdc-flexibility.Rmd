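---
title: "Detergent-dependent conformational flexibility from SEC-SAXS and fluorescence quenching"
author: "pdcflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detergent-dependent conformational flexibility from SEC-SAXS and fluorescence quenching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcflex)
```

## The scientific problem

Membrane proteins in solution exist as protein:detergent complexes (PDCs):
the protein plus a torus-like belt of detergent wrapped around its
transmembrane (TM) hydrophobic surface. Small-angle X-ray scattering of a
PDC therefore mixes two signals — the protein conformation of interest and
the detergent corona — and any statement about conformational flexibility
(for instance, whether a two-domain enzyme such as a lipid A
phosphoethanolamine transferase opens up around its bridging helix when
moved from a mild maltoside detergent to a harsher phosphocholine one) has
to model both. `pdcflex` implements the complete desk-side workflow:

1. **frames** — SEC-SAXS frame handling: inverse-variance frame averaging,
   buffer subtraction, explicit error-scale correction, per-frame Guinier
   traces across the elution peak.
2. **primary** — Guinier analysis, regularized P(r) inversion,
   dimensionless Kratky plots, molecular weight from forward scattering,
   and conjugate (copolymer) SEC-MALS mass decomposition.
3. **corona / debye** — a five-parameter dummy-atom detergent torus fitted
   against the scattering curve via the Debye sum with per-region
   electron-density contrasts.
4. **refine** — rigid-body refinement of the soluble domain against the TM
   body + corona, joined by self-avoiding dummy-residue linkers, driven by
   a genetic algorithm on the chi-squared fit.
5. **ensemble** — ensemble-optimization flexibility analysis: a randomized
   conformer pool, clash filtering, genetic sub-ensemble selection on the
   low-angle data, and the entropy-based Rflex statistic.
6. **quench** — intrinsic tryptophan fluorescence: Savitzky–Golay
   smoothing, emission maxima, Stern–Volmer ratios against matched
   ionic-strength controls, and KSV estimation restricted to the initial
   linear window.
7. **synthetic** — generators for every input the pipeline consumes, with
   ground-truth sidecars, so all stages are testable without beamline
   data.

## Conventions and core models

**Momentum transfer.** `s = 4π sin(θ)/λ` in Å⁻¹ throughout (the 0.005–0.5
Å⁻¹ regime of protein SAXS); no 2π-free variant is accepted anywhere.

**Debye scattering.** Model intensities are
`I(s) = Σᵢ Σⱼ fᵢ fⱼ sinc(s·rᵢⱼ)` over point scatterers with
*s*-independent effective contrasts: protein atoms carry
`Z − ρ_solv·V_displaced` (per-element displaced volumes, overridable),
corona dummy atoms `(ρ_region − ρ_solv)·V_voxel`. Five-Gaussian atomic
form factors and explicit hydration shells are deliberately out of scope:
at `s ≤ 0.35 Å⁻¹` the contrast-dominated dummy-atom description is what
the corona model can resolve, and the multiplicative scale is refit per
curve anyway. Models under 2 000 scatterers use the exact double loop;
larger ones a weighted pair-distance histogram with 0.5 Å bins (≪ π/s_max;
agreement with the exact sum is ~0.1% over `s·Rg ≤ 3`, beyond which the
intensity has decayed so far that relative error measures only
floating-point cancellation).

**Chi-squared.** `χ² = 1/(N−p) Σ ((c·I_model + b − I_exp)/σ)²` with the
scale `c` (and optional flat offset `b`) solved analytically; `p` counts
the fitted nuisance parameters. When a profile's metadata records that
its sigmas were rescaled (beamline pipelines sometimes report
2-standard-error columns; `rescale_errors(p, 2)` fixes that, explicitly
and never automatically), the chi-squared under the original sigmas is
reported alongside.

**Guinier window.** Automatic window selection is deterministic: iterate
Rg to self-consistency, then take the longest low-angle run with upper
`s·Rg ≤ 1.3`, at most 5% of leading points skipped, linearized
correlation ≥ 0.99 and no systematic residual trend by a one-sided runs
test; if no window meets the trend or correlation criteria they are
relaxed in that order and the criteria actually met are reported. Note a
numerical fact the tests encode: for an ideal solid sphere the Guinier
estimate at the customary `s·Rg ≤ 1.3` window is biased high by ≈1.8%
(the quartic term of the sphere's log-intensity is positive), so
oracle-grade sphere checks fit within `s·Rg ≤ 0.9`, where the bias falls
below 1%. Similarly, the dimensionless Kratky peak of the exact sphere is
at (1.61, 1.03), not at the pure-Guinier landmark (√3, 3/e ≈ 1.104) often
quoted for globular particles; both values appear in the tests, each for
the curve it actually describes.

**P(r) inversion.** `I(s) = 4π ∫ p(r)·sinc(sr) dr` is discretized on
~1 Å r-grids with `p(0) = p(Dmax) = 0` pinned and an `α‖p″‖²` smoothness
penalty, solved in the smoothness-transformed basis by SVD so any `α` is
numerically safe; `α` defaults to the GCV minimum. `estimate_dmax` scans
`[2Rg, 5Rg]` and returns the smallest candidate whose p(r) stays
non-negative (within 2% of max p) once the residual norm has plateaued
(within 10% of the best over the scan); curves with no finite support
edge (e.g. a Gaussian-chain curve) correctly fail to plateau and return
the largest candidate with a warning.

**Corona model.** The detergent belt is an elliptic torus of height `a`,
cross-section axes `b·e` and `b/e` rotated by `ω` about the membrane
normal, with an outer hydrophilic shell of thickness `t`; it is filled
with a cell-centred cubic lattice (default 3 Å — coarser than atoms,
finer than any fitted feature; cell-centring makes point count × voxel
volume an unbiased volume estimate). Protein-occupied space is excluded
(1.8 Å + half lattice diagonal). Whether the head shell covers the
axial faces as well as the lateral rim is not decidable from the
modelled physics; both topologies are supported (`axial_head`, default
`TRUE` — headgroups face solvent wherever the torus is exposed). `ω` is
reported as 0 whenever `e = 1`. Fitting is an exhaustive grid search;
with noiseless self-simulated data the truth geometry scores exactly
χ² = 0 and grid-step recovery is essentially certain, which is what the
acceptance suite measures.

**Rigid-body refinement.** Residues outside the flexible ranges form
rigid bodies (contiguous residue runs); the corona is welded to the TM
body and never refit per conformer. Flexible segments are Cα-level dummy
residues with exact 3.8 Å virtual bonds, grown as self-avoiding chains
between their anchors (the last bead is placed analytically on the
two-bond closure circle; reachability bounds are enforced at every step).
The genetic algorithm (defaults: population 60, 120 generations,
tournament 3, elitism 2, mutation 0.3 — sized for desk-scale runtime)
recombines body transforms and mutates via bounded random rotations
about the bridging anchor. Elitism makes the best fitness non-increasing;
everything is bit-reproducible under a fixed seed. Clash counting uses a
cell-list grid over per-element van der Waals radii (bead models use a
carbon-like 1.7 Å radius so that non-bonded bead contacts under 3.0 Å
count as clashes, matching the 3.0 Å chain-growth avoidance); pairs
within one rigid body, and sequence-adjacent beads of one flexible
chain, are exempt.

**Ensemble analysis.** The pool resamples the mobile domain uniformly
(random rotation; random displacement within the linker's reach) and
discards conformers whose van der Waals overlap with the detergent shell
or the other body exceeds 0.4 Å — the overlap reading of the published
"cut-off < 0.4 Å", since an absolute-distance reading would be vacuous.
On the toy systems roughly half of 2 000 drawn conformers survive,
mirroring the ~5 000/10 000 retention the corresponding experimental
analysis reports. Selection runs on `s ≤ 0.1 Å⁻¹` (the overall-shape
regime) with fixed-size ensembles of 20 with repetition (repetition
encodes weight). **Rflex** is not given by a printed formula in the
source study; following the ensemble-optimization literature it is
implemented as `100·H/H_max`, the Shannon entropy of the (weighted) Rg
histogram over the pool's support relative to the uniform histogram
(natural log, 50 bins by default; the bin count is a reported knob). A
delta distribution gives exactly 0%, a uniform histogram exactly 100%.

**Stern–Volmer.** `F₀/F = 1 + K_SV·[I⁻]`, with `F₀` read from the
KCl-matched control at the same ionic strength, per replicate, before
averaging (this preserves each well's normalization). The intercept is
fixed at 1 — that is the model — with a free-intercept diagnostic fit
reported alongside. If the full range shows `r² < 0.95` or a one-sided
runs test flags systematic curvature, the window shrinks from the
high-concentration end only: downward curvature means heterogeneous
fluorophore shielding and only the initial slope estimates K_SV. The 95%
CI is t-based on n−1 degrees of freedom; across 1 000 simulated
titrations the realized coverage is ≈94% — slightly under nominal
because the data-driven window shrink occasionally truncates at random,
which the calibration test makes visible rather than hiding.

## The synthetic-data generator

`make_toy_protein()` builds a Cα-bead two-domain architecture: an
antiparallel ideal-helix TM bundle (1.5 Å rise, 100°/residue, helix axes
~9.5 Å apart, arranged so the chain exits at the periplasmic face), a
sphere-packed soluble domain (one bead per ~133 Å³, the mean residue
volume), and a bridging linker grown between them. Defaults — 4 TM
helices × 22 residues, 14-residue linker, 14 Å soluble domain, open-state
centroid separation 55 Å — give a ~190-residue protein whose closed/open
states differ only in soluble-domain placement, the minimal geometry that
exercises every downstream stage. One scatterer per residue (58 e⁻,
133 Å³ displaced) is deliberate: at `s ≤ 0.35 Å⁻¹` side-chain detail is
invisible and full atoms would only slow the pool stages.

`simulate_sec_saxs()` lays out buffer-only frames and peak frames under a
Gaussian elution envelope with Poisson-like noise
`σ(s) = sqrt((I+bg)/(exposure·flux))`; the noiseless mode closes exactly
(peak − buffer = envelope × model curve), and the noisy mode's
σ-normalized residuals pass a KS test against the standard normal.
`simulate_quench()` produces Gaussian emission spectra on the 315–405 nm
grid with per-well multiplicative noise; its two-population mode mixes
two K_SV values to reproduce the downward-curved Stern–Volmer plots of a
mobile, partially micelle-buried fluorophore. Every simulator is
deterministic under its seed and ships a ground-truth sidecar.

What the toy data do **not** emulate: real detector error correlations,
inter-particle interference, the chemistry of specific detergents
(micelle thermodynamics, partial unfolding), or native-like linker
dihedral statistics (the chain grower is a geometric self-avoiding walk,
not a Ramachandran sampler). Passing tests therefore demonstrate the
correctness and calibration of the *algorithms*, not the biological
accuracy of any particular PDC model.

## Problem sizes and determinism

The shipped tests and the acceptance script run, per stage: 10⁴-point
sphere oracles; 3 000-scatterer Debye comparisons; a 72-point corona grid
over 12–20 recovery cases at 4 Å lattice; GA refinement at population 36
× 36 generations (three seeded runs); conformer pools of 2 000 with
selection at population 100 × 150 generations; and 1 000-replicate CI
calibrations — sizes chosen so the whole suite completes on one desktop
core in well under half an hour while leaving every recovery margin
comfortable. All stochastic stages take explicit seeds and are
bit-reproducible; nothing depends on the global RNG state of the caller
(seeded paths save and restore `.Random.seed`).

## Known limitations

- The corona grid search is exhaustive; for fine production grids a
  coarse-to-fine schedule (run twice with a refined grid around the first
  optimum) is the intended usage pattern.
- Effective contrasts ignore the weak s-dependence of atomic form
  factors; absolute-scale work should treat `mw_from_i0()`'s inputs (the
  measured I(0), concentration, composition-weighted v̄ and electron
  densities) as the place where calibration enters.
- The conjugate MALS decomposition trusts the supplied per-slice weight
  fractions (or UV/RI signals); it does not model inter-detector band
  broadening.
- The bound-monomer count is reported unrounded alongside the integer:
  on published mass tables the DPC arithmetic gives ≈131 where the
  source reports 123, an unexplained discrepancy the package surfaces
  rather than absorbs.
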