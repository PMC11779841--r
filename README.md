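# biofilmNMR

Quantitative analysis of time-resolved solid-state NMR (ssNMR) measurements
of bacterial biofilms, built around the study design used for *Bacillus
subtilis* pellicles: samples harvested daily over a five-day life cycle and
characterized by 1D ¹³C spectra under three polarization schemes, 2D
peak-volume tables, inversion-recovery relaxation series, DIPSHIFT dipolar
dephasing curves, and per-monosaccharide integral tables for the biofilm and
its spent medium.

The package is aimed at ssNMR spectroscopists and biofilm researchers who
have processed frequency-domain spectra and peak tables in hand and want the
downstream quantitative analysis to be reproducible and testable. It does
not process FIDs and does not assign chemical shifts; assignments, regions
and category maps are configuration.

## What it computes

**Carbon biomass density and phase fractions.** The integral of a
quantitative direct-polarization (qDP) spectrum, normalized by sample mass
and number of scans, is proportional to the sample's carbon weight
fraction — the *carbon biomass density*. Component classes are quantified
over their chemical-shift regions (carbohydrates 74–105 ppm; proteins
10–29, 34–48, 106–124, 132–160 ppm, excluding lipid signals), normalized to
a reference day. The *mobile fraction* is the density ratio of a 2 s
recycle-delay DP spectrum (which saturates slowly relaxing, rigid
components) to the qDP spectrum.

**Degraded-matrix composition.** For a first-order degradation process
d[S]/dt = −k[S], the quantity degraded in an interval is proportional to the
local substrate concentration:

    [S](t) = C₀ e^(−kt),   ⟨[S]⟩ = C₀(1 − e^(−kt))/(kt),
    D = C₀(1 − e^(−kt))·V = ⟨[S]⟩·kt·V.

With equal volume and total biomass in two consecutive intervals, the
protein/carbohydrate percentages of the degraded matrix (p₁ + c₁ = 100,
p₂ + c₂ = 100) follow from the measured degraded-quantity ratios
p₁/p₂ = Dp₁/Dp₂ and c₁/c₂ = Dc₁/Dc₂, solved in closed form by
`solve_proportions()`.

**Site-specific dynamics.** ¹³C spin-lattice relaxation times are fitted
with the three-parameter inversion-recovery model I(t) = A + B·e^(−t/T1).
DIPSHIFT dipolar dephasing curves are simulated by powder-averaging the
MAS-modulated C–H dipolar phase (FSLG-scaled; CH₂ as the product of two
tetrahedrally related C–H terms) and fitted by one-dimensional least squares
over the effective coupling δ_eff; the order parameter S = δ_eff/δ_rigid
(0 = isotropically mobile, 1 = rigid limit) is the rigidity metric.

**Monosaccharide clustering.** Per-sugar biofilm/medium integral ratios over
days 2–5 form a 4-vector per sugar; features are standardized (population
SD), reduced by 2-component PCA, and clustered with K-means, with the number
of clusters guided by silhouette scores and optionally forced by prior
knowledge.

**Synthetic data.** `scenario_preset()` / `build_scenario()` define a fully
ground-truth-annotated synthetic five-day scenario (biomass peaking on day
2 and decaying to ~20 % of maximum; a dominant mobile phase shrinking from
~90 % to the mid-70s; clustered sugar partition profiles; site-specific T1
values and order parameters) so the entire pipeline is testable end to end
without any experimental download.

## Worked example

```r
library(biofilmNMR)

# the composition of the degraded matrix from measured degraded quantities
sol <- solve_proportions(49.28, 31.31, 14.18, 33.43)
print(sol)
#> Degraded-matrix composition (first-order kinetics)
#>   interval 1: proteins 78.8%, carbohydrates 21.2%
#>   interval 2: proteins 50.1%, carbohydrates 49.9%
#>   input ratios: protein 1.5739, carbohydrate 0.4242
```

Roughly 79 % of the matrix degraded in the first interval is protein; a day
later degradation has shifted to an even protein/carbohydrate split —
proteins are consumed first, carbohydrates follow.

```r
# end-to-end synthetic run: simulate, analyze, compare with ground truth
res <- run_recovery_suite(default_config(), seed = 23)
print(res)
#> Recovery suite: 30/30 checks passed

# site dynamics on synthetic data
sc <- build_scenario(scenario_preset(), seed = 7)
fit_t1(emit_inversion_recovery(sc, "GlcA-C1", noise_sigma = 0))
#> Inversion-recovery fit [GlcA-C1]: T1 = 2.6 s (A = 1, B = -2)
#>   residual norm 0, 12 delays, converged: TRUE

fit_order_parameter(emit_dipshift(sc, "TasA-Ala-CA", noise_sigma = 0),
                    delta_rigid = sc$delta_rigid)
#> DIPSHIFT fit [TasA-Ala-CA] (CH): delta_eff = 21.56 kHz, S = 0.950 (rigid limit 22.7 kHz)
```

A thin command-line wrapper lives at `inst/scripts/biofilm-nmr.R`
(`simulate`, `analyze`, `recover` subcommands over a YAML configuration;
see `inst/extdata/bsubtilis-5day.yaml` for the shipped preset).

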