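# aggimmuno

Mechanistic simulators for asking how aggregates of therapeutic protein
products (TPP) — monoclonal antibodies, fusion proteins, cytokines — could
drive anti-drug-antibody (ADA) responses. The package is aimed at
quantitative pharmacologists and immunogenicity modelers who want to probe
the two canonical mechanisms *in silico*:

1. **T-cell-independent activation by BCR cross-linking.** A deterministic
   mass-action model of a multivalent aggregate (valency *n*) binding B-cell
   receptors sequentially,

   `Ag_a + BCR <-> Ag_aBCR_1`, `Ag_aBCR_1 + BCR <-> Ag_aBCR_2`, …,
   `Ag_aBCR_{n-1} + BCR <-> Ag_aBCR_n`,

   with binding flux `(n-i+1)·k_i·[BCR]·[Ag_aBCR_{i-1}]`, dissociation flux
   `i·k_{-i}·[Ag_aBCR_i]`, constant per-site `k_on` and
   `k_{-i} = (k_on/K_a)·0.5^{i-1}`. The readout is the signal-transducing
   complex (STC) count — aggregates cross-linking at least *s* receptors,
   `STC = Σ_{i≥s} [Ag_aBCR_i]` — expressed per antigen-specific B cell. An
   exact Gillespie simulator of the same network (`simulate_ssa()`)
   validates the ODE engine at small copy numbers.

2. **T-cell-dependent ADA production.** A minimal multiscale ODE model:
   two-compartment PK with biweekly dosing → endosomal uptake
   (`dE/dt = IR·C − DR·E`) and epitope peptide pools → competitive,
   saturable MHC class II loading with affinity-dependent surface loss →
   danger-signal (LPS-equivalent) Hill maturation of dendritic cells →
   T help driven by the best-presented epitope → activation of a 17-subgroup
   B-cell affinity ladder with maturation, plasma-cell differentiation, ADA
   secretion, and ADA-mediated drug clearance feeding back on PK.

The headline results: STC formation is confined to extreme corners of the
physiological parameter space (affinity-matured `K_a = 10⁻³ pM⁻¹` and
elevated antigen-specific B-cell fractions), so direct T-cell-independent
activation by aggregates is implausible; on the T-cell-dependent side,
faster internalization/degradation and extra epitopes do essentially
nothing when high-affinity epitopes are already presented, while an induced
high-affinity (38 nM) epitope or an increased danger signal raises
cumulative ADA by an order of magnitude.

## Worked example

```r
library(aggimmuno)

# an affinity-matured antibody (Ka = 1e-3 pM^-1) meeting a 100-valent
# aggregate at 12 pM, with 0.01% of B cells antigen-specific
p <- crosslink_params(n = 100, Ka = 1e-3, Aga0 = 12, specific_fraction = 1e-4)
sim <- simulate_crosslink(p)
sim
#> Cross-linking simulation: n = 100, t_final = 12.7 day (equilibrium reached)
#>   free aggregate 11.9991 pM, free BCR 0.00075476 pM, bound aggregate 0.000905711 pM
stc(sim, s = 2)
#> STC (s >= 2): 6.768e-08 pM, 4.076 per antigen-specific B cell
```

Four aggregates per cell cross-link at least two receptors — above the
one-STC line, but only because every sensitive parameter sits near its
upper physiological limit; at `Ka = 1e-5 pM⁻¹` or `s = 5` the count
collapses to far below one (`sweep_stc()` maps the full grid).

```r
# T-cell-dependent route: add an induced 38 nM epitope to a low-affinity
# (1230, 850 nM) baseline at 40 mg biweekly
pre <- build_preset("fig7")
fc <- ada_fold_change(pre$plus_high_affinity, pre$low_affinity)
round(fc$fold_change, 2)
#> [1] 19.21
```

The induced epitope multiplies cumulative ADA ~19-fold, whereas the
16.6-fold internalization-rate scenario in the same preset changes it by
less than 1%.

## The analyses

The numbered scripts under `analysis/` run the full set of studies and
write tidy tables (plus reproducibility manifests) under `results/`:

| script | question |
|---|---|
| `01_crosslink_sweep.R` | STC per cell over the affinity × aggregate × B-cell-fraction grid |
| `02_stc_thresholds.R` | smallest antigen-specific fraction reaching one STC per cell |
| `03_ada_danger_signal.R` | ADA vs danger-signal level, including the 5× increase |
| `04_ada_processing.R` | 16.6× internalization/degradation and epitope-number effects |
| `05_ada_epitope_affinity.R` | induced 38 nM epitope across doses; affinity maturation |

Run any of them from the repository root, e.g.
`Rscript analysis/03_ada_danger_signal.R`.

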