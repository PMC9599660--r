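---
title: "Constructing and analyzing enzyme-constrained metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and analyzing enzyme-constrained metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgem)
```

## Scope and model

`ecgem` builds an enzyme-constrained genome-scale metabolic model (ecGEM)
from a stoichiometric model plus protein and kinetic data, and runs the
standard downstream analyses. The enzymatic limitation is expressed as a
**single aggregate pool constraint** added to ordinary flux balance
analysis (FBA):

$$\max\ c^\top v \quad \text{s.t.}\quad S v = 0,\quad lb \le v \le ub,\quad
\sum_i \frac{v_i\, MW_i}{\sigma_i\, k_{cat,i}} \le P_{total}\, f$$

Each enzyme-constrained reaction $i$ consumes enzyme mass proportional to
its flux: $MW_i$ is the molecular weight of the catalyzing complex (kDa,
equal to g per mmol of enzyme), $k_{cat,i}$ its turnover number (h⁻¹), and
$\sigma_i \in (0,1]$ a saturation coefficient discounting the in-vitro
$k_{cat}$. The right-hand side is the protein budget: total protein content
$P_{total}$ (g protein / gDCW) times the mass fraction $f$ of that protein
represented by model enzymes. No pseudo-metabolites or pseudo-reactions are
introduced; the pool is one extra LP row.

Defaults (changeable everywhere they appear): $P_{total} = 0.56$ g/gDCW,
$\sigma = 0.5$, similarity-screen threshold 20 % identity (strictly
greater flags a pair), target fold-change threshold 1.5 (boundary
included), glucose molar mass 0.18016 g/mmol for yields.

## Pipeline stages

1. **Normalization** (`normalize_model`): metabolite ids apply, longest
   pattern first, `"(e)"` → `"_e"`, `"-D"/"-L"/"-R"` → `"__D"/"__L"/"__R"`,
   residual `"-"` → `"_"`; reaction ids replace every `"-"` with `"__"`.
   Both maps are idempotent. The same dash rule is applied to exchange and
   non-exchange reaction ids alike.
2. **GPR curation** (`parse_gpr`, `screen_and_relationships`,
   `apply_gpr_corrections`): GPR rules are parsed to disjunctive normal
   form — each `or` alternative is a candidate enzyme, each `and` group a
   complex (a multiset of genes). Gene pairs inside an `and` complex are
   screened by global sequence identity (Needleman–Wunsch, BLOSUM62, gap
   open 10 / extend 0.5, identity = identical columns / alignment length);
   pairs above the threshold are *flagged* for conversion to `or`, never
   edited automatically. Reviewed edits are applied in a validated batch.
3. **Splitting** (`expand_model`): internal reversible reactions become a
   forward copy and a `_reverse` copy with negated stoichiometry; reactions
   with $k>1$ candidate enzymes become `_num1` … `_numk` copies with one
   enzyme each. Exchange reactions keep their native bounds and are never
   split, so uptake conditions are always set on the original `EX_*`
   bound. `aggregate_flux` maps split fluxes back (net = forward − reverse,
   isozyme copies sum).
4. **Parameterization** (`parse_subunit_count`, `complex_mw`,
   `match_kcat`, `build_enzyme_table`): subunit counts come from
   UniProt-style interaction text ("Homodimer" → 2, "Tetramer of two alpha
   and two beta chains" → {α: 2, β: 2}); unparseable text defaults to a
   monomer carrying an explicit `defaulted` flag. Complex MW is
   $\sum_j N_j MW_j$. $k_{cat}$ matching runs three levels — exact EC +
   organism, exact EC, EC class (last field wildcarded) — taking the
   maximum (or median) of the first non-empty level. Reactions with no EC
   number or no match are reported as unconstrained, not dropped. $f$ can
   be computed from an abundance table as
   $\sum_{\text{model}} A_i MW_i / \sum_{\text{measured}} A_j MW_j$.
5. **Calibration** (`calibrate_kcat`): while growth under a fixed uptake is
   below a measured target, the reaction with the largest enzyme cost share
   whose EC-class maximum exceeds its current $k_{cat}$ is raised to that
   maximum — one reaction per round, ties broken lexicographically, so runs
   are deterministic and the growth trajectory monotone.

## Analyses

* `fba` / `pfba`: plain and parsimonious FBA (two-stage LP; the second
  stage minimizes total absolute flux at the fixed optimum).
* `comparative_fva`: per-reaction flux ranges at a fixed growth rate in
  two models. Split ranges are aggregated back onto original reactions:
  isozyme copies contribute their **maximum** member range, and for
  reversible pairs the reverse range is **subtracted** from the forward
  range. That subtraction can produce negative aggregates; such rows are
  kept verbatim and flagged `review` rather than silently clamped.
* `phpp`: maximal growth over a glucose × oxygen uptake grid (default
  0–10 mmol/gDCW/h in steps of 0.5); infeasible points are recorded as 0
  with a flag.
* `overflow_scan`: for each uptake in 1–6.3 mmol/gDCW/h (default), fix the
  uptake, maximize growth, and report byproduct secretion, biomass yield
  $v_{bm}/(v_{glc}\cdot 0.18016)$, the minimum enzyme mass $E_{min}$
  supporting that growth, and the efficiency growth$/E_{min}$; rows are
  phased substrate-limited / switching / overflow at the first secreting
  uptake.
* `enzyme_cost`, `scenario_fluxes`, `find_targets`: per-reaction enzyme
  costs $v_i MW_i/(\sigma_i k_{cat,i})$ in a high-growth/low-product and a
  low-growth/high-product state (growth fixed, product maximized,
  degeneracy resolved by minimizing enzyme usage); reactions whose cost
  ratio between the states reaches 1.5 (boundary included; a 1e-9 relative
  slack guards the boundary against floating-point division) are classed
  `enhance` or `weaken`, zero denominators flag `infinite-fold`.

## Worked example

```{r example}
spec <- toy_gem_spec()          # the shipped study conditions
toy <- make_toy_gem(spec)
proteins <- make_protein_records(spec)
kinetics <- make_kinetics_table(toy$truth)

ex <- expand_model(toy$model)
comps <- setNames(lapply(proteins$interaction_text, parse_subunit_count),
                  proteins$gene_id)
mws <- setNames(proteins$monomer_mw_kda, proteins$gene_id)
tab <- build_enzyme_table(ex$model, comps, mws, kinetics)
ec <- build_ec_model(ex$model, tab$enzymes, ptotal = spec$pool, f = 1)
ec

fba(toy$model)$objective_value   # stoichiometric optimum
fba(ec)$objective_value          # enzyme-limited optimum

scan <- overflow_scan(ec, glucose_id = "EX_glc__D_e",
                      byproducts = "EX_ac_e")
attr(scan, "onset")              # first uptake with byproduct secretion
head(scan[c("uptake", "growth", "EX_ac_e", "biomass_yield", "phase")])
```

`run_pipeline()` chains all stages from files (JSON/SBML model, protein
TSV, kinetics TSV, optional abundance TSV), writes every intermediate plus
a manifest with MD5 checksums, and stops at the first failing stage naming
it.

## The toy system and what it shows

The shipped generator (`make_toy_gem` and friends) builds a mass-balanced
two-pathway system: a high-yield, enzyme-expensive respiratory route and a
low-yield, cheap fermentative route that secretes a byproduct, plus a
product pathway, an isozyme pair, a two-gene complex, a reversible
transporter and a disconnected futile cycle. Its default conditions — pool
bound 0.2576 g/gDCW (0.56 × 0.46), yields 0.1 and 0.05 gDCW/mmol, switch
point 4.5 mmol/gDCW/h, cost ratio 0.35, uptake cap 10 — are fixed study
conditions, not tuning knobs. Because the optimal allocation of the pool
between two pathways has a closed form, `overflow_switch_oracle` provides
analytic growth/byproduct/$E_{min}$ curves that the LP solution must match
to 1e-6; the test suite relies on that oracle, on ground truth carried in
a sidecar `truth` record, and on independently coded reference
implementations, never on the code under test.

What the toy system demonstrates: overflow onset exactly at the designed
switch point, strictly decreasing biomass yield and non-decreasing enzyme
usage efficiency past it, containment of the enzyme-constrained flux space
in the stoichiometric one, pool-cost conservation, and single-round
recovery of a deliberately undervalued $k_{cat}$. What it cannot show:
behavior at genome scale (hundreds of reactions), realistic kinetic-data
sparsity, or organism-specific headline numbers — those require a real
model and data snapshots supplied by the user.

## Numerical choices and limitations

* LP backend: GLPK simplex via a small bundled C++ wrapper; feasibility
  tolerance 1e-9, analysis comparisons use 1e-6. Solver status
  (`infeasible` / `unbounded`) is always surfaced, never returned as a
  silent zero.
* Degeneracy: wherever a flux *state* (not just an optimum) is reported,
  it is made deterministic by a secondary objective (pFBA total flux, or
  minimal enzyme usage in the scenario states).
* Subunit stoichiometry of multi-gene complexes: when every member's text
  labels the whole complex and the label count equals the gene count,
  sorted labels are assigned to sorted genes and the record is flagged
  `label_order_assumed`; otherwise every gene gets $N_j = 1$ and the
  record is flagged `stoichiometry_unknown`. Guesses are always
  distinguishable from parsed facts.
* Problem sizes exercised here are toy-scale (≈20 split reactions); the
  implementation is dense-free (sparse triplets) but FVA is serial — at
  genome scale expect minutes, not seconds.
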