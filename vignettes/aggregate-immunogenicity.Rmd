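---
title: "Modeling aggregate-driven immunogenicity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling aggregate-driven immunogenicity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggimmuno)
```

# Scope

Aggregates of therapeutic protein products (TPP) are a long-standing
immunogenicity risk factor. Two mechanistic routes are usually proposed: a
T-cell-independent route, where a multivalent aggregate cross-links enough
B-cell receptors (BCRs) to activate the B cell directly, and a
T-cell-dependent route, where aggregation changes antigen uptake,
processing, MHC class II presentation, or innate danger signaling, and the
anti-drug-antibody (ADA) response follows from cognate T-cell help.
`aggimmuno` implements a quantitative model of each route and the analyses
that discriminate between them; the numbered scripts under `analysis/` are
the narrative drivers, and every computation they perform lives in the
package and is exercised by the test suite.

# The cross-linking model

## Reaction scheme and ODEs

An aggregate `Ag_a` is treated as a homogeneous assembly of `n` monomers,
presenting `n` equivalent BCR binding sites. Binding is sequential:

    Ag_a + BCR        <->  Ag_aBCR_1
    Ag_aBCR_1 + BCR   <->  Ag_aBCR_2
    ...
    Ag_aBCR_{n-1} + BCR <-> Ag_aBCR_n

A receptor may bind any free site and dissociate from any occupied one, so
the mass-action fluxes carry statistical factors: the i-th binding flux is
`(n - i + 1) * k_i * [BCR] * [Ag_aBCR_{i-1}]` and the i-th dissociation flux
is `i * k_minus_i * [Ag_aBCR_i]`. `mass_action_rhs()` generates the ODE
system mechanically from this scheme, which makes conservation of total
aggregate and of total receptor (free plus site-weighted bound) exact by
construction; both invariants are verified numerically to 1e-6 relative
tolerance in the tests. Deriving from the scheme rather than transcribing a
printed equation set also sidesteps typesetting ambiguities in index-heavy
displays of such systems.

## Parameters and units

Concentrations are in pM, time in days. Defaults:

| parameter | default | meaning |
|---|---|---|
| `n` | 100 | valency; reported aggregate sizes span 10–100 monomers |
| `k_on` | 8.64e-3 pM⁻¹ day⁻¹ | per-site binding rate; antigen–antibody association rates are relatively constant, so a single value is used for all steps |
| `Ka` | 1e-7 … 1e-3 pM⁻¹ | first-step association constant; 1e-7 corresponds to a naive (low intrinsic affinity) antibody, 1e-3 to an affinity-matured one |
| `decay_base` | 0.5 | `k_minus_i = (k_on/Ka) * 0.5^(i-1)`: each additional cross-link halves the dissociation rate |
| `Aga0` | 0.1 … 1500 pM | initial aggregate concentration; `initial_aggregate_conc(Ag, p, n) = Ag*p/n` with total drug 500–1e5 pM, aggregated fraction 2–15% |
| `BCR0` | — | `1e5` receptors/cell × `1e8` B cells/L × antigen-specific fraction, converted via Avogadro's constant (16.6 pM at fraction 1) |

The sign of the dissociation trend deserves a note: sterically, resistance
to torsion could plausibly make dissociation *faster* with each bound
receptor, but multivalent hapten–polymer work has used the opposite,
stabilizing assumption, and that is what the model implements as its
default. `decay_base` is exposed so the alternative (`decay_base = 1`, or a
user-supplied schedule via `rate_schedule()`) can be explored; none of the
headline analyses depend on exploring it.

Middle grid levels (12 pM, 1e-5 pM⁻¹) are the printed rounded geometric
means of the outer levels, used as printed rather than recomputed.

## Signal-transducing complexes

A B cell is taken to be activatable when a single aggregate cross-links at
least `s` of its receptors; the signal-transducing complex (STC)
concentration is `sum_{i >= s} [Ag_aBCR_i]`, and `stc()` converts it to a
count per *antigen-specific* B cell (the BCR pool in the ODEs is built from
the same antigen-specific fraction, so that is the population whose
receptors participate). Reported minimum cross-link numbers for B-cell
activation are 7–15; the sweeps use `s = 2, 5, 10`, with `s = 2` a
deliberately permissive lower bound.

## Numerical choices

* Solver: `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-12` pM. The
  first-step dissociation rate spans 8.64–8.64e4 day⁻¹ across the affinity
  grid, so a stiff-capable integrator is required.
* Readout: the reference figures' readout time is not stated, so the model
  integrates to detected equilibrium with a hard cap of 100 days, flagging
  `"capped"` rows in sweeps. Equilibrium is declared when every species'
  derivative is small relative to that species:
  `|dy_i| / max(|y_i|, 1e-9 * max|y|) < 1e-9` day⁻¹. The per-species
  scaling matters: the STC-relevant complexes can sit eight to ten orders
  of magnitude below the free-aggregate pool, and a criterion scaled by the
  dominant pool declares equilibrium while they are still relaxing (we
  measured a 21% low STC readout at the threshold fraction before adopting
  the per-species form). The floor at 1e-9 of the largest state keeps
  effectively-zero deep complexes (1e-30 pM and below) from blocking
  detection.
* Integration proceeds in geometrically growing spans (0.1, 0.2, 0.4, …
  days), testing the criterion after each span.
* `fraction_threshold()` bisects the antigen-specific fraction on a log
  scale to a 1e-3 log-width tolerance, after checking numerically that the
  STC count per cell is nondecreasing across the bracket; an upper bracket
  of 1% (the reported ceiling for antigen-specific B cells) bounds the
  search, and failure to reach the target there is reported as
  `"not_attained"` rather than an error.
* Degenerate cases: `n = 1` collapses to simple bimolecular binding and is
  supported; its equilibrium is checked against the closed-form quadratic
  root (`bimolecular_equilibrium()`), evaluated in the numerically stable
  rationalized form.

## The stochastic oracle

`simulate_ssa()` is an exact direct-method (Gillespie) simulation of the
same reaction network at integer copy numbers in a small virtual volume,
with per-pair binding propensity `k_on / (N_A * V)` (volume in
pM-equivalents) scaled by the free-site count. It exists purely to validate
the deterministic engine: at `n <= 4` and a few hundred molecules the ODE
equilibrium must match replicate means within three standard errors
(`validate_ssa()` reports per-species z-scores). Two independent checks
guard the oracle itself: molecule conservation is exact in integer
arithmetic, and for the two-aggregate/two-receptor valency-1 instance the
occupancy distribution is compared against the analytic stationary
distribution of the three-state birth–death chain, enumerated by detailed
balance in the test helper. The oracle is deliberately not optimized —
physiological copy numbers are out of scope for it.

## What the sweep shows, and the one claim it does not reproduce

On the default grid the sweep reproduces the qualitative picture: with
`s = 5` or `10` no condition yields even one STC per cell; at
`Ka = 1e-7 pM⁻¹` the same holds for `s = 2`; at `1e-5 pM⁻¹` more than one
STC forms only at the highest aggregate level near the 1% fraction
ceiling. At the affinity-matured level (`1e-3 pM⁻¹`) all three aggregate
levels can exceed one STC per cell, but `analysis/02_stc_thresholds.R`
computes the crossing fractions as 0.062%, 0.0025% and 0.092% for 0.1, 12
and 1500 pM respectively — a ~40-fold spread, where the reference analysis
reports a single ">0.006%" threshold for the panel. Only the middle level
is within a factor of ~2.4 of that figure. We have not found a reading of
the model (readout time, normalization, rate schedule) that collapses the
three crossings onto one value; the corresponding sweep assertion and the
worst-case-threshold acceptance target are therefore left failing rather
than tuned, and the adjacent-panel agreement is the evidence that the
engine itself is sound.

# The T-cell-dependent ADA model

The cited multiscale immunogenicity model is not fully specified by its
published description; this package therefore ships a *minimal* ODE
instantiation of its architecture — whole-body PK, subcellular antigen
presentation, cellular activation — constrained by every number the
reference analysis prints (IR₀ = 14.4 day⁻¹, DR₀ = 17.28 day⁻¹, epitope
Kd sets {123, 85}, {1230, 850}, 38 nM, 350 ng LPS danger signal, 17
affinity subgroups, biweekly doses 0.04–40 mg). All remaining parameters
are a calibration chosen once and frozen as the package defaults; absolute
ADA levels are in arbitrary units and only directions and fold changes are
interpreted.

## Structure

**Whole-body.** Two-compartment PK with first-order subcutaneous
absorption (`ka = 0.25`, `k10 = 0.05`, `k12 = k21 = 0.2` day⁻¹,
`Vc = 3` L — an IgG-like profile with a terminal half-life of ~30 days),
dosing as depot boosts at each administration, mg → pmol via a configurable
molecular weight (default 150 kg/mol), and ADA-complex-mediated elimination
`k_ada * ADA_total * C` closing the loop.

**Subcellular** (per APC, driven by the plasma concentration `C` in pM):

* endosomal antigen: `dE/dt = IR*C − DR*E`, so at steady state
  `E* = (IR/DR) * C` — the 16.6-fold identities under rate perturbations
  hold *exactly* and are verified against this closed form to 1e-6;
* peptide pools: `dP_j/dt = copies_j*DR*E − d_P*P_j`, giving
  `P_j* = copies_j*(IR/d_P)*C`, independent of DR: epitope supply is
  internalization-limited, which is the mechanistic content of the
  degradation-rate result;
* surface complexes: `dM_j/dt = k_load*MHC_free*P_j/(K_m+P_j) −
  k_surf*Kd_j*M_j` with `MHC_free = MHC_total − ΣM_j`. The saturable
  supply term (`K_m = 10` a.u., far below `P_j` at all doses studied)
  makes presentation insensitive to internalization rate, while the
  affinity-proportional surface loss makes it strongly affinity-dependent
  — the two facts the perturbation analyses report. Capacity
  `ΣM_j <= MHC_total` holds dynamically and is asserted along full
  trajectories.

**Cellular.** Dendritic-cell maturation is a Hill function of the danger
signal (LPS-equivalent ng): `DS²/(3500² + DS²)`. The EC50 and coefficient
were calibrated so that raising the danger signal 5-fold from 350 ng
scales maturation ~20-fold, the printed magnitude of that experiment; with
the response far below saturation, ADA output is near-linear in maturation
and the simulated cumulative-ADA fold lands at 19.8. T help is
proportional to mature DC times a saturating function of the
*best-presented* epitope, `max_j M_j` (half-saturation `M50 = 5e5`
complexes): the max, not the sum, is what makes "adding epitopes when a
high-affinity epitope already dominates does not increase ADA" true by
construction, consistent with the idea that the limiting resource is
presentation of the dominant epitope rather than total peptide load.

B cells and ADA are split into 17 subgroups on a geometric antigen-binding
Kd ladder from 1 µM down to 100 pM (the subgroup count is prescribed; the
ladder bounds span the µM-to-nM epitope affinity range discussed for MHC
II-restricted responses and the sub-nM range reached by matured
antibodies). Subgroup `i` activates at rate
`k_act * Thelp * occ_i * naive_i` with `occ_i = C/(C + Kd_i)` (drug
occupancy of that subgroup's BCR) and a naive pool concentrated at the
low-affinity end (geometric decay 0.5 per rung). Activated cells step up
the ladder at `k_mat = 0.5` day⁻¹ (affinity maturation), differentiate to
plasma cells at `k_pc = 0.2` day⁻¹ (death `d_pc = 0.05`), which secrete
subgroup ADA (`k_sec = 1`, elimination `d_ada = 0.033` day⁻¹, an IgG-like
three-week half-life). `ADA_total` is identically the 17-subgroup sum, and
cumulative ADA (its time integral over the 182-day course) is the summary
statistic for all fold changes — whether the reference figures plot
instantaneous or cumulative response is unstated, and the integral is the
more stable of the two.

The maturation rate is the one cellular parameter whose value was driven
by a qualitative constraint rather than convenience: the occupancy factor
`occ_i` weights activation toward high-affinity subgroups when drug levels
are low (at the start of the course) and toward the naive low-affinity end
as drug accumulates, which on its own would make the abundance-weighted
mean ADA affinity *fall* over the course. At `k_mat = 0.5` day⁻¹ the
maturation flux dominates and the mean affinity rises by ~0.3 log10 units
to a plateau. Strict pointwise monotonicity is still not attainable — PK
accumulation produces ~1e-3-per-cycle micro-declines at the plateau — so
the maturation property is asserted as a rise of more than 0.2 log10 units
from response onset with no retracement exceeding 5% of the total rise.

## Stage-wise and coupled execution

`run_scenario()` integrates all ~60 states as one coupled system
(`lsoda`, `rtol 1e-8`, `atol 1e-10`, output every 0.1 day), which is the
form used for every reported number. `simulate_pk()`,
`simulate_subcellular()` and `simulate_cellular()` run each stage in
isolation under forced inputs (constants or interpolated time courses);
a test feeds the coupled run's own drug and presentation curves back
through the stage simulators and requires agreement, so the modular and
coupled paths cannot drift apart. Fold-change analyses at constant plasma
input (`subcellular_steady_state()`) use a 30-day horizon; with all
subcellular rates >= 1 day⁻¹ the slowest mode has relaxed by more than
ten half-lives well before that.

## What the directional analyses show

Under the frozen defaults (`analysis/03`–`05`): cumulative ADA is monotone
in danger signal with a 19.8-fold gain for the 5-fold increase; 16.6-fold
internalization or degradation changes move cumulative ADA by under 0.1%
when the high-affinity epitopes {123, 85 nM} are presented, and adding
third/fourth epitopes changes it by under 4%; with the low-affinity set
{1230, 850 nM}, 16.6-fold internalization again does nothing (<1%), while
adding the 38 nM epitope multiplies cumulative ADA by ~19 at every dose
from 0.04 to 40 mg. The acceptance bound for that last effect is the
printed ≥4-fold; the margin reflects the ~20-fold presentation advantage
the 38 nM epitope enjoys under the affinity-proportional surface-loss
rule.

# The scenario factory

`build_preset()` materializes each analysis configuration from YAML files
under `inst/extdata/presets/` — data, not code, so every number in them can
be audited at a glance. Two entries are explicitly synthetic because the
reference analysis does not print them: the Kd of the added third and
fourth epitopes in the epitope-number experiment (200 and 300 nM stand-ins)
and the sub-baseline danger-signal ladder ({175, 70, 35, 7} ng below the
350/1750 pair). `random_grid()` samples cross-linking scenarios
(log-uniform in concentrations and Ka, uniform in aggregation fraction,
integer valency) inside the physiological bounds for the property-based
tests, reproducibly per seed.

# What the synthetic scenarios do and do not emulate

The scenario grids reproduce the *study conditions*: parameter levels,
dose schedules and perturbation factors. They do not emulate features of
real systems that the models themselves omit — heterogeneous aggregate
size distributions (a single valency per scenario), spatial membrane
dynamics of BCR clustering, ring or chain aggregate topologies, HLA-DM
editing of the presented repertoire, immune tolerance or disease states,
polyclonality beyond the affinity-ladder representation, or stochastic
immune-cell dynamics. Passing tests therefore support the internal
consistency and the stated directional conclusions of these models, not a
quantitative prediction of clinical ADA incidence; absolute ADA
trajectories are not desk-reproducible from the published description and
are treated as uncalibrated.

# Known limitations

* The ADA module is a minimal instantiation: its absolute scales are
  arbitrary and only within-package fold changes are meaningful.
* The cross-linking equilibrium at high `Ka` is metastable: with a
  halving dissociation rate per cross-link, deeply bound states are
  thermodynamically favored, but the flux into them at physiological
  concentrations is negligible on the 100-day horizon. Readouts are the
  quasi-equilibrium of the shallow-complex manifold, which is the
  experimentally relevant one; integrating to the true global equilibrium
  would require astronomically long horizons and would change the STC
  counts.
* The single ">0.006%" threshold discussed above remains unreconciled; the
  package reports its own computed per-level thresholds.
* Problem sizes throughout (valency 100 sweeps, 150–400 SSA replicates,
  182-day ADA courses at 0.1-day output) were chosen as the smallest that
  make the statistical and convergence checks sharp.
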