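---
title: "Multi-tissue constraint-based modeling with mtfba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tissue constraint-based modeling with mtfba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfba)
```

## The model and its assumptions

`mtfba` works with constraint-based metabolic models: a stoichiometric
matrix $S \in \mathbb{R}^{m \times n}$ over $m$ metabolites and $n$
reactions, flux bounds $lb \le v \le ub$, and linear objectives. All
analyses assume **steady state**, $S\,v = 0$: metabolite concentrations are
never simulated, only flux distributions. Flux balance analysis solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S\,v = 0,\; lb \le v \le ub,$$

flux variability analysis (FVA) then minimizes and maximizes each $v_i$
independently over the same (optionally objective-constrained) space. The
*flux span* $\max v_i - \min v_i$ measures how much freedom the network
leaves a reaction; a *fixed* reaction has equal nonzero extremes, a *zero*
reaction is pinned at 0, and reactions that can carry flux with **all
exchanges closed** participate in thermodynamically infeasible internal
loops and are excluded from span statistics. Loop detection relaxes any
forced-throughput bounds (e.g. maintenance demands) before closing the
system, so that the all-zero flux is feasible and only cyclic capability
is probed.

### Multi-tissue integration

Tissue models are joined through a blood compartment that also stands in
for interstitial fluid and urine; no separate kidney compartment is
modeled, renal clearance is just a blood exchange. Integration does, in
order:

1. **Tagging.** Every compartment, metabolite and reaction id gets the
   tissue tag: `glc[c]` in the hepatocyte model becomes `glc[h_c]`,
   reaction `GNG` becomes `GNG[h]`. Tagging is deterministic and
   collision-free, and a provenance map back to `(tissue, original id)` is
   kept for every reaction.
2. **Blood identification.** Each tissue's extracellular species is
   identified with the blood species of the same base id (`glc[h_e]` →
   `glc[bl]`). The merged model therefore has a *single shared*
   extracellular space; we read the source material as permitting either
   this or per-tissue extracellular spaces bridged to blood, and chose
   identification because it adds no artificial transport steps.
3. **Exchange surgery.** All tissue-level exchange reactions are deleted;
   intercellular transport happens only through each tissue's existing
   gene-associated transporters and diffusion — no new transporters are
   synthesized. One blood exchange per whitelisted metabolite connects the
   system to the extra-system; by convention negative exchange flux is
   uptake.
4. **Bicarbonate buffer.** The reversible couple
   `co2[bl] + h2o[bl] ⇌ h[bl] + hco3[bl]` (plus co2/hco3 exchanges) is
   added. This is not cosmetic: proton-coupled transporters (lactate,
   pyruvate, fatty acids move as anion + H⁺; ammonium antiports against
   H⁺) and exchanges of charged species leave the blood proton without any
   source or sink, and the merged model is *infeasible* without the
   buffer. The package treats the buffer stoichiometry as fixed; only its
   existence is optional (`add_buffer()` is idempotent).
5. **Whole-body units.** Tissue masses differ by orders of magnitude, so
   per-gram-dry-weight fluxes would distort intercellular exchange.
   `rescale_biomass()` multiplies the biomass maintenance coefficients by
   the dry cell mass $D = \text{wet mass} \times \text{cell fraction}
   \times (1 - \text{water fraction})$, putting all fluxes on a
   mmol/h/body scale, and sets the biomass lower bound to the in-vitro
   growth rate so simulations always pay tissue turnover. The hepatocyte
   cell-mass fraction defaults to 0.8 (hepatocytes dominate liver mass);
   tissue wet masses and growth rates are configuration inputs, not
   constants, because no authoritative values ship with the package.

### Multi-objective states and carbon accounting

Physiological states with several simultaneous goals (the absorptive
state's fat/protein/glycogen storage) use **lexicographic FBA**: optimize
stage 1, fix its value, optimize stage 2, and so on. A stage with
`fix_fraction = 1` is fixed inside an equality band of
$\pm 10^{-6}\max(1, |\text{opt}|)$ — an exact equality stack is
numerically brittle — while `fix_fraction < 1` fixes a one-sided bound.
Carbon splits are computed from an optimal solution: input carbon is the
summed uptake flux times the carbon count of each source-exchange
metabolite, each named sink's fraction is its net carbon consumption over
that input, and the remainder is reported as maintenance. Because FBA
optima can be degenerate, the split is only computed after the scenario's
objective sequence has been fixed; span/classification statistics are
functions of FVA ranges and never of the arbitrary optimal vertex.

### Expression-driven context extraction

Presence/absence calls (P/A/M per tissue, group, sample, gene) are
summarized by a **unanimity consensus**: a gene is present iff called `P`
in *every* sample of its tissue and group. Marginal calls break the
consensus — the strict reading of the rule; genes missing from a state
map count as present (absence of evidence is not evidence of absence).
Reaction states come from evaluating each reaction's gene-protein-reaction
(GPR) boolean rule against the states of the reaction's tissue of origin.

`gimme_extract()` then solves the GIMME linear program: minimize the total
absolute flux of absent reactions subject to steady state, bounds, and the
required metabolic functionality (RMF) reaching at least `fraction` times
the parent optimum (absolute values by the usual forward/reverse variable
split). Absent reactions with zero flux in the minimizing solution are
removed; absent reactions that must carry flux are *retained despite
absent*. Penalties are binary (1 per unit flux on absent reactions): with
binary upstream calls the original expression-distance weighting
degenerates to exactly this. The RMF fraction defaults to 0.9 — the source
material does not state its value, so this is a declared package default,
configurable per call. Differential activity between two contexts runs
FVA under each context's RMF constraint and compares which reactions *can
carry flux* (|range| ≥ 1e−6, the same tolerance as the flux
classification), not which are merely present; reactions inactive in both
are dropped from the comparison.

`call_stability()` quantifies the robustness of the consensus by dropping
a fraction of samples uniformly at random (seeded) and recording per-gene
flip rates. Dropping samples can only move genes absent → present — a
unanimity cannot be broken by removal — which the test suite asserts as a
property.

## The toy fixtures: what they emulate, and what they do not

All tests run on a generated three-tissue world (`toy_tissue()`,
`toy_multitissue()`): a gluconeogenic "liver" (lactate/alanine to glucose,
lactate oxidation, urea synthesis), a glycolytic "muscle" (glucose to
lactate/alanine) and a lipogenic "fat" (glucose + fatty acids to stored
triacylglycerol, glycerol release). Design choices:

* **Integer yields** — 15 ATP per lactate oxidized, 6 ATP per glucose
  synthesized, 3 ATP per urea, 25 ATP per 2 pyruvate — chosen for hand
  verifiability, not biochemical precision.
* **Real chemistry elsewhere**: every internal and transport reaction is
  elementally and charge balanced against Hill-notation formulas
  (glucose C6H12O6, lactate C3H5O3⁻, ATP C10H12N5O13P3⁴⁻, ...), protons
  are explicit, and membrane transport moves net-zero charge (anion + H⁺
  symports, NH₄⁺/H⁺ antiport, neutral uniports). A consequence worth
  knowing: intracellular proton balance is then implied by the other
  species' balances, but the *blood* proton is not, because single-species
  exchanges break charge symmetry — that is precisely the buffer-necessity
  mechanism, and it is exercised by the Cori fixture (alanine, being
  neutral, crosses without H⁺ and balances on its own).
* **Frozen closed-form optima** (`toy_manifest()`): at the default stated
  conditions — 6 mmol/h lactate or alanine input, 30 mmol/h hepatic ATP
  maintenance — the Cori-like optimum is $g = (15\cdot6-30)/36 = 5/3$
  mmol/h glucose (carbon split 10/18 ≈ 55.6 % glucose), and the
  alanine-like optimum is $g = (15\cdot6-30-9)/36 = 17/12$ (split
  47.2 % glucose, 16.7 % urea, 36.1 % maintenance; the 9 is urea's ATP
  bill for six nitrogens). These numbers are properties of the toy
  stoichiometry, frozen from the hand LP before the solver ever ran.
* **Not emulated**: genome scale (dozens, not thousands, of reactions),
  alternate isoenzyme routes beyond one deliberate redundant glucose
  exporter, cofactor diversity (one NAD pool), lipoprotein transport, and
  realistic biomass compositions (biomass is an ATP-drain stub). A green
  test on the toys therefore establishes the *machinery* — merging,
  buffering, FVA classification, GIMME — not quantitative physiology.

## Numerical choices

* LP solver: dense two-phase bounded-variable primal simplex with Bland's
  rule (deterministic, immune to cycling); feasibility tolerance 1e−9.
  Infinite bounds are capped at ±1e9. Validated against an independent
  vertex-enumeration oracle in the test suite.
* Zero-flux / activity / span threshold: 1e−6 throughout, so Table-style
  counts, loop sets and differential-activity sets are mutually
  consistent.
* Defaults for unbounded reactions: ±1000 mmol/h/body; irreversible
  reactions get lower bound 0; reversibility is encoded purely as
  `lower_bound < 0`.
* Degenerate alternate optima: `fba()` returns an arbitrary optimal
  vertex; every reported statistic except the post-fix carbon split is
  vertex-independent.

## Known limitations

* No isotopomer (¹³C) flux computation; results are qualitative flux
  capabilities, not measured fluxes.
* No loop-law-constrained optimization — loops are detected and excluded
  from statistics, not forbidden from solutions.
* No automatic gap filling; dead ends are only reported.
* The SBML writer emits Level 3 + fbc only; the reader's Level 2 support
  covers the COBRA kineticLaw/notes convention but not every historical
  dialect.
* Scenario files reconstruct physiological states (uptake rates,
  maintenance demands) as configuration; where the literature gives only
  ranges (absorptive amino-acid scaling "two- to seven-fold"), the shipped
  toy scenarios pick single representative values and document them here.
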