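---
title: "Community-scale metabolic modeling of SCFA production: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-scale metabolic modeling of SCFA production: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the tunable parameters, the numerical
choices, and the limits of what the synthetic-data tests demonstrate.

## The model

A community-scale metabolic model couples per-taxon genome-scale
metabolic models (GEMs) through one shared external environment. Each
taxon model is a stoichiometric matrix over its own metabolites, flux
bounds per reaction (mmol/gDW/h), and a biomass reaction whose flux is
the growth rate $\mu_i$ (1/h). During assembly, every taxon network is
namespaced into its own compartments, and each taxon exchange reaction
for metabolite $m$ becomes a transfer between the taxon and a shared
pool. The transfer carries the taxon's relative abundance $a_i$ on the
shared side, so that taxon-internal fluxes remain per gram dry weight
*of that taxon* while shared pools and community exchanges are per gram
dry weight *of community*; the shared mass balance for $m$ reads
$\sum_i a_i\, v_{i,EX_m} = v_{c,EX_m}$. One community exchange exists
per shared metabolite, with lower bound $-\mathrm{medium}(m)$ — the
medium is precisely the vector of maximum import fluxes — and an upper
bound of 1000 mmol/gDW/h, the conventional "unbounded" sentinel in
constraint-based modeling.

Relative abundance is used as a proxy for relative biomass. Abundances
below 0.001 (0.1%) are removed and the rest renormalized; taxa without a
model in the library are dropped and the remaining mass renormalized
over matched taxa (the retained fraction is recorded on the model as
`matched_fraction`, with a warning below 50%). Renormalizing over
matched taxa, rather than carrying unmatched mass as a dead sink, is a
design choice: the model should describe the community we can actually
represent.

## Cooperative tradeoff flux balance analysis

Maximizing community growth alone yields winner-takes-all solutions in
which most taxa do not grow. The two-step cooperative tradeoff scheme
avoids this:

1. **Step 1 (LP).** Maximize $\mu_c = \sum_i a_i \mu_i$ subject to
   steady state $S v = 0$ and all flux bounds, giving $\mu_c^\*$.
2. **Step 2 (QP).** Minimize $\sum_i \mu_i^2$ subject to the same
   constraints plus $\mu_c \ge \mathrm{tf} \cdot \mu_c^\*$.

The tradeoff parameter tf (default 0.7) sets how much community-level
optimality is sacrificed for individual growth. The conventional way to
choose it — implemented as `tradeoff_scan()` — is to take the highest
value at which most (>90%) taxa still grow. The step-2 objective
deliberately penalizes only growth rates, not all fluxes: residual flux
degeneracy is a real property of these models and is surfaced by
`flux_range_at_optimum()` (the min/max of a community exchange with all
$\mu_i$ fixed at their returned values) rather than hidden behind an
extra regularizer. Acetate is the canonical example: it is weakly
coupled to biomass, so its production flux can vary widely at the same
growth optimum, and the package reports that width rather than
pretending the point value is unique.

Production rates are the nonnegative part of the net community exchange
flux — what the community exports, i.e. what would reach the colonic
epithelium. Net-imported metabolites report zero.

## Medium construction

Diets are transformed into growth media by a fixed sequence of
operations, each of which appends to a per-metabolite provenance log
with its exact numeric arguments, so `replay_provenance()` reproduces
any built medium bit-exactly from the raw diet:

1. **Host absorption**: entries flagged `host_absorbable` are multiplied
   by the retained fraction (default 0.2, i.e. diluted to 20%) to
   account for small-intestine uptake.
2. **Host metabolites**: mucins, bile acids and similar secretions are
   added; entries already present keep the larger flux.
3. **Completion**: per model, a linear program finds nonnegative bound
   relaxations $e_m$ minimizing $\sum_m e_m$ such that growth reaches
   the floor (default 0.3 1/h); the union of supports across models is
   added. Minimal *total flux* (an LP) rather than minimal *metabolite
   count* (a MILP) is a deliberate choice: it is deterministic, fast,
   and its support is reported as the added set. Additions below 1e-6
   are treated as zero — the threshold sits above the solver's
   regularization noise.
4. **Carbon stripping** (ex-vivo recipe): entries whose formula contains
   carbon (or that carry `carbon_source_override`) are removed, *except*
   residual fiber (resistant starch, dextrin, cellulose) and
   host-supplied entries, which persist in stool. Metabolites without a
   formula count as carbon-free unless overridden; the flag exists
   precisely so users can reproduce judgment calls the formula rule
   cannot make.
5. **Dilution** (ex-vivo): everything is multiplied by 0.1 to mimic the
   fecal microenvironment — except residual-fiber entries, which are
   *set* to diet value divided by the study's slurry dilution factor
   (1:5 culture → factor 5). The rescale replaces, rather than composes
   with, the global dilution: residual fiber tracks the physical
   dilution of the sample, not of the medium.
6. **Fiber supplementation**: single-fiber additions at defaults
   reflecting carbon content — pectin 1.0, inulin 10.0, FOS 100
   mmol/gDW/h.

Completion runs *before* stripping, and the growth-floor guarantee is
asserted on the pre-strip medium only: stripping can legitimately push
growth below the floor (that is the point of the ex-vivo recipe), so
completion is not re-run afterwards.

## Interventions and classification

A probiotic is modeled compositionally: existing abundances are scaled
to $1 - f$ and the probiotic taxon added at $f$. The default $f = 0.05$;
5% and 10% both appear in the literature for this design, so the value
is an explicit config parameter rather than a constant. The butyrate
response to a high-fiber diet is classified from the production rates on
the two diets: *regressor* if high-fiber production is lower than
European-diet production; *non-responder* if European-diet production is
below 15 mmol/gDW/h **and** the relative increase is below 20%;
*responder* otherwise. The 15 mmol/gDW/h threshold is expressed in the
pipeline's native flux units — the only internally consistent reading.
Two conventions close the domain: zero production on both diets is a
non-responder; zero on the European diet with positive high-fiber
production counts as an infinite relative increase (responder).
`screen_interventions()` runs one full medium-build and solve per
specification, flags failures per cell rather than aborting, and marks
the argmax with ties broken by spec order.

## Validation statistics

Measured fluxes come from endpoint concentrations:
$(c_\mathrm{end} - c_\mathrm{start}) / \mathrm{hours}$, divided by OD600
when total biomass normalization applies (in-vitro cultures). Predicted
(mmol/gDW/h) and measured (mmol/L/h) fluxes live on different scales and
are expected to be proportional, so both are Z-scored within each study
before correlation, using the sample (n−1) standard deviation. Raw
values are used (no log transform before correlation) — a documented
choice. Group comparisons use the Mann-Whitney U test, exact for
combined n ≤ 20 without ties and the continuity-corrected normal
approximation (with midranks) otherwise. The clinical association scan
fits marker ~ flux + age + sex + vendor by OLS on z-standardized
continuous variables, so the reported β is a standardized coefficient;
sex enters as a binary indicator and vendor as a categorical indicator
set, BMI is deliberately excluded as a confounder (it is itself
downstream of butyrate production), and p-values are adjusted across
markers with Benjamini-Yekutieli, which controls the FDR under arbitrary
dependence.

## Numerical choices

All optimization goes through one wrapper over the dual active-set QP
solver in **quadprog**, with three devices that matter for correctness:

- **Null-space reduction.** The steady-state equalities $Sv=0$ are
  eliminated by parametrizing $v = Nz$ with $N$ an orthonormal basis of
  the null space of $S$. FBA feasible sets are routinely degenerate, and
  active-set methods are fragile on degenerate *equality* systems; after
  reduction the solver sees a bounds-only problem.
- **Exact regularization for LPs.** Linear objectives are solved as
  $\min \|z\|^2/2 - \gamma c^\top z$ along a ladder of increasing
  $\gamma$; for a polyhedron there is a finite $\gamma$ beyond which the
  solution is exactly the minimum-norm point of the optimal face, so the
  wrapper accepts once two consecutive rungs agree. This yields exact LP
  optima with deterministic, configuration-free tie-breaking on
  degenerate optimal faces (no seed, no pivot order).
- **Anti-degeneracy perturbation.** If a solve still fails, each
  inequality is loosened by a distinct multiple of 1e-9 and the solve
  retried; this breaks degenerate active sets while moving the solution
  well below the 1e-6 feasibility tolerances.

Reported solutions are rechecked at $\|Sv\|_\infty \le 10^{-6}$, one
order looser than the solve itself, to avoid false failures. The
tradeoff constraint is enforced to within the same $10^{-6}$.
Degenerate step-2 optima are accepted as the deterministic minimum-norm
point; production rates can be accompanied by flux-range widths where
degeneracy matters.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known
ground truth. Taxon archetypes are one or two catabolic pathways
(substrate → biomass precursor + SCFAs) plus exchanges and a biomass
drain — small enough for hand or grid verification, yet covering the
structurally hard cases: a fiber degrader with two substrates, an
acetogen/cross-feeder pair coupled through shared acetate, and a
producer with two isoenergetic pathways whose acetate/butyrate split is
undetermined at the optimum. Default study conditions: 20 samples,
symmetric Dirichlet(1) compositions over six archetypes, lognormal
multiplicative measurement noise with σ = 0.3 (fluxes are positive and
predicted/measured values are expected proportional, which makes
multiplicative error the natural model), study dilution 1:5, and control
vs inulin arms. Clinical markers are linear in the z-scored flux with
effects 0.2 (age), 0.1 (sex), 0.15 (vendor) and unit noise; null markers
(β = 0) calibrate the FDR machinery. Carbon-balanced archetype variants
attach formulas and re-derive yields so conservation checks are exact
(the default variants trade closure for the round numbers that make
optima verifiable by hand).

What the generator does **not** emulate: AGORA-scale networks (hundreds
of reactions and pathway redundancy), taxonomic misassignment,
compositional noise in sequencing, nonlinearity between abundance and
biomass, or measurement error structure beyond lognormal. Passing tests
therefore demonstrate the correctness of the machinery — assembly,
optimization, medium algebra, statistics — not the biological accuracy
of predictions on real cohorts, which depends on the quality of the
model database and medium curation.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path with tight oracles: communities of 2–6 taxa
(~30 reactions), cohorts of 20–50 samples, 200 randomized communities
for the solver-invariant sweep, 200 replicates of a 128-marker null
cohort at n = 500 for FDR calibration, one n = 2687 cohort for planted-
effect recovery, and 20 noise seeds for the attenuation check.

## Known limitations

- Exact-identifier model matching only; no taxonomy harmonization.
- The completion LP minimizes total added flux, so a single cheap
  metabolite can substitute for the "smallest set" a MILP would find.
- The carbon-stripping rule is mechanical (formula + override flags);
  it approximates curation decisions that were originally manual.
- Steady-state FBA: no dynamics, no thermodynamic constraints, no
  strain-level resolution.
- The dense solver is sized for toy models; AGORA-scale communities
  would need a sparse LP/QP backend behind the same interface.
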