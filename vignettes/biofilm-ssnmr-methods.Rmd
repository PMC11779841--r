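---
title: "Models and methods for time-resolved biofilm ssNMR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for time-resolved biofilm ssNMR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmNMR)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical choices that were genuinely open.

## The measurement model

Time-resolved biofilm samples harvested on successive days come from
different wells, so absolute spectral intensities are not comparable across
days. The analysis therefore works exclusively with the **carbon biomass
density**: the spectral integral divided by sample mass (mg) and number of
scans. This calibrated quantity is linear in the carbon weight fraction and
is the only scale on which day-to-day trends are meaningful. Densities are
reported relative to a reference day (day 2, the biomass maximum, by
default), where the relative value is exactly 1.

Three polarization schemes carve up the sample by molecular mobility:

* **qDP** — direct polarization with a recycle delay long enough (15 s in
  the emulated design, against T1 values up to ~2.6 s) for complete
  longitudinal relaxation of every component: quantitative for the whole
  sample.
* **DP2s** — direct polarization with a 2 s recycle delay. Components with
  fast ¹³C T1 (mobile, liquid-like) relax fully between scans; slowly
  relaxing rigid components are saturated away. The generator models this
  with the mono-exponential saturation factor `1 − exp(−RD/T1)` per phase —
  the simplest model consistent with a recycle-delay-selective experiment.
* **CP** — cross polarization, detecting only the rigid phase. CP transfer
  efficiency depends on local dynamics, so CP spectra are flagged
  non-quantitative and carry a single global efficiency scalar; the
  analysis never derives densities from them.

The **mobile fraction** of a region is the DP2s/qDP density ratio. It is a
biased estimator: with T1(mobile) = 0.5 s the mobile phase itself recovers
only `1 − e^(−4) ≈ 98.2 %` in 2 s, and a long-T1 rigid phase leaks a few
percent in. With the default scenario's relaxation times the net bias is
below 0.015, which is why the recovery tolerance for phase fractions is
0.02. Ratios pushed outside [0, 1] by noise are clamped with a warning —
clamping preserves the invariant, the warning keeps the data issue visible.

Integration is trapezoidal on the native grid with interpolated boundary
points, so integrals over adjacent intervals add exactly and the result is
independent of whether the ppm axis is stored ascending or descending (the
generator stores it descending, the display convention). No baseline
correction is applied by default: synthetic spectra are baseline-free, and
for real data baseline handling belongs upstream. Component regions are
half-open `[low, high)` so adjacent class regions cannot double-count a
grid point; carbohydrates use 74–105 ppm and proteins the combined
10–29, 34–48, 106–124 and 132–160 ppm ranges, which exclude lipid signals
by construction rather than by peak-level deconvolution.

## Degradation kinetics and the proportion solver

For first-order degradation, `[S](t) = C₀e^(−kt)`, the average
concentration over `[0, t]` is `⟨[S]⟩ = C₀(1 − e^(−kt))/(kt)`, and the
degraded quantity `D = C₀(1 − e^(−kt))V = ⟨[S]⟩·kt·V` is linear in the
average concentration. That linearity is the reason degraded quantities can
be read as proxies for local substrate concentrations.

Two numerical points. First, `1 − e^(−kt)` is evaluated as `-expm1(-kt)`,
which is accurate for all `kt`; the series `C₀(1 − kt/2 + (kt)²/6)` is
additionally substituted below `kt = 1e-8` so the average-concentration
quotient never divides two vanishing quantities. Second, the equality of
the two forms of `D` is an algebraic identity and is tested as one (to
1e-12 relative over a random parameter grid), not an approximation.

Given degraded quantities for proteins and carbohydrates over two
consecutive intervals, and assuming equal volume and total biomass in both
intervals, the compositional percentages satisfy

```
p1 + c1 = 100,  p2 + c2 = 100,  p1/p2 = Dp1/Dp2,  c1/c2 = Dc1/Dc2
```

with the closed-form solution `p2 = 100(1 − rc)/(rp − rc)`, `p1 = rp·p2`.
The solver is scale-invariant separately in the protein and carbohydrate
pairs (only the ratios enter), which also means the physical units of the
inputs are irrelevant. Two failure modes are reported as errors rather than
repaired: `rp = rc` makes the system degenerate (the proportions are not
identifiable), and a solution outside [0, 100] means the equal-volume /
equal-biomass assumption does not hold for these inputs — clamping would
fabricate a composition. Percentages are carried on the 0–100 scale.
`degradation_observations()` produces the inputs as day-over-day decreases
of the relative densities; intervals with net accumulation have no degraded
quantity and propagate as `NA` with a warning.

## Inversion-recovery T1 fitting

Relaxation series are fitted to the three-parameter model
`I(t) = A + B·e^(−t/T1)` (B < 0). The three-parameter form is used rather
than the two-parameter ideal-inversion form because it absorbs imperfect
inversion and receiver offsets, at the cost of one degree of freedom.
Fitting is Levenberg–Marquardt least squares; starting values come from the
plateau, the initial intensity, and the zero-crossing (`t₀ ≈ T1·ln 2`).
Constant series and series with fewer than four distinct delays are
rejected.

The default delay grid deserves a note. For this model the sensitivity
`∂I/∂T1 ∝ t·e^(−t/T1)` peaks at `t = T1`, so a grid that spreads points
log-uniformly wastes measurements: its Cramér–Rao bound for the relative
T1 error, with Gaussian noise at 2 % of the dynamic range and 12 delays,
is ~5 % (≈3.5 % median absolute error) — no estimator can beat that. The
default grid therefore places two baseline anchors near `t = 0`, seven
points across `0.6–1.7×T1` for a ~2.6 s target, and three plateau anchors,
bringing the bound to ~2.5 % median error. Users measuring sites with very
different T1 should scale the grid accordingly.

## DIPSHIFT simulation and order parameters

Under magic-angle spinning, a C–H pair whose internuclear vector has polar
angles `(β, γ)` in the rotor frame contributes the time-dependent dipolar
frequency

```
ω(t) = 2πδ [ (√2/2)·sin 2β·cos(ωr t + γ) − (1/2)·sin²β·cos(2ωr t + 2γ) ]
```

with `δ` the FSLG-scaled effective coupling and `ωr` the spinning
frequency. The accumulated phase over the dipolar evolution time `t₁`
integrates in closed form and is **linear in δ**; geometrically it
vanishes at `t₁ = 0` and at one full rotor period for every orientation
(rotor-echo refocusing), and the powder average is symmetric about the
half rotor period. Both properties are exact in the implementation and are
tested to 1e-3 against the curve itself.

The observed signal is the powder average of `cos Φ(t₁)` over orientations
with `sin β` weighting. For CH this is a two-angle `(β, γ)` average on a 5°
grid; grid refinement to 2° changes no point by more than 5e-3 for
couplings up to 25 kHz. CH₂ groups are modeled as the product of the two
C–H cosine terms with the tetrahedral (109.47°) inter-vector angle;
because the second vector's orientation is tied to the first, the powder
average needs the full three-angle crystallite orientation, taken on a 10°
grid to bound cost. C–H/C–H cross-correlation is neglected — the standard
independent-coupling approximation; it slightly distorts deep CH₂
dephasing but cancels in the fit-by-simulation loop, which uses the same
model.

Fitting inverts the simulation: a bounded one-dimensional least-squares
search over `δ_eff`, cheap because the phase is linear in the coupling so
the orientation geometry is precomputed once per curve. The search interval
is `[0, 1.2·δ_rigid]`; an optimum at the bound raises an error instead of
silently clamping, since it means the assumed rigid limit, scaling factor
or data are wrong. The order parameter `S = δ_eff/δ_rigid` uses a
rigid-limit one-bond coupling of 22.7 kHz (r_CH ≈ 1.1 Å) and the FSLG
theoretical scaling factor `1/√3 ≈ 0.577`; both are configurable because
instruments calibrate them, and neither is fixed by the emulated study
design. The MAS rate default (13.5 kHz) is likewise an assumption flagged
as configuration. Round-tripping `simulate → fit` recovers S within 0.01
noiselessly and within 0.03 at 2 % noise across S = 0.1…1.0 for both
multiplicities.

## Monosaccharide partition clustering

For each sugar, the biofilm/medium integral ratio on days 2–5 forms a
4-vector describing how that sugar partitions between matrix and medium
over the dispersal phase. Day 1 is excluded by default because medium data
can be incomplete there (the default scenario reproduces a day-1 gap for
glucuronic acid). Sugars with any missing value over the requested days are
dropped with a logged reason rather than imputed — with 4 features and
sugar counts in the single digits, imputation would manufacture cluster
structure. Missing measurements are `NA` throughout, never 0: a zero medium
integral is an error, because the ratio feature is then undefined.

Features are standardized column-wise with the population (divide-by-n)
standard deviation — the convention of the standard machine-learning
scaler — so each day is equally weighted. PCA is computed by SVD of the
centered matrix; component signs follow a fixed convention (largest-
magnitude loading positive) so scores are reproducible across row
orderings and LAPACK builds. K-means runs with 50 restarts under a fixed
seed for every candidate k (2–6 by default), scored by mean silhouette
width; k candidates exceeding the number of distinct score points are
reported with missing silhouettes. The selected k maximizes the silhouette
unless an explicit override is configured — the override is the mechanism
for incorporating prior biological knowledge (for the default scenario,
k = 4: the peptidoglycan amino sugars form their own class), exactly as
silhouette-plus-prior-knowledge selection works in practice.

When an externally published ratio table is supplied,
`reference_pca_variance()` runs the identical standardize-then-PCA path on
it and reports the two-component explained variance; without such a table
the check reports itself unavailable instead of silently passing.

## The synthetic-data generator

`scenario_preset()` encodes the study conditions the pipeline is designed
for: five days; total biomass peaking on day 2 and decaying to ~21 % of
maximum by day 5; a carbohydrate class (74–105 ppm) whose mobile fraction
falls from 94 % to 71 % and a protein class falling from 87 % to 74 %;
~30 mg samples; eight monosaccharides in four partition families, with
glucosamine absent from the medium; mobile T1 values from sub-second to 2.6 s and
rigid-site order parameters of 0.45–0.95. Lineshapes are Lorentzian only
(mobile-phase ssNMR lines are near-Lorentzian); peak positions, widths and
relative areas are configuration. Noise is additive i.i.d. Gaussian per
point, with every stream seeded deterministically from the scenario seed
plus the day/mode/site labels, so a fixed `(config, seed)` pair reproduces
every emitted file byte for byte.

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: baseline and phase distortions, spinning
sidebands, ¹³C–¹³C J-splittings, overlap between component classes beyond
Lorentzian tails, CP dynamics beyond a single efficiency scalar,
relaxation during the DIPSHIFT evolution period, and any correlated noise.
The recovery suite demonstrates that the estimators invert the stated
forward models at the stated noise levels; real-data performance
additionally depends on everything listed above being handled upstream.

Problem sizes used throughout the tests and examples — 1024–4096-point
spectra, 12-delay relaxation series, 16-point dephasing curves, 5°/10°
powder grids — match what the estimators need for their stated tolerances;
all were chosen as realistic working sizes for this class of data.

## Known limitations

* The proportion solver is a two-component model; generalizing beyond
  proteins/carbohydrates requires additional closure assumptions.
* The rate constant k is never estimated — the analysis only uses the
  proportionality between degraded quantity and average concentration, so
  k cancels; time series too short to test first-order behavior will not
  be flagged.
* Order parameters inherit any error in the assumed rigid-limit coupling
  and scaling factor multiplicatively.
* Silhouette-based k selection is unstable for very small n (here, 7–8
  sugars); the k override exists precisely because the statistic alone
  cannot settle the question at that sample size.
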