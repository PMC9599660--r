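# ecgem

Construct and analyze **enzyme-constrained genome-scale metabolic models**
(ecGEMs) in R.

An ordinary stoichiometric model predicts fluxes from mass balance alone;
it cannot explain why cells secrete fermentation byproducts while oxygen is
still available. `ecgem` adds the missing resource: every catalyzed
reaction consumes enzyme mass in proportion to its flux, and the total is
capped by the cell's protein budget. The constraint is a single extra LP
row — no pseudo-metabolites, no model surgery:

```
max  cᵀv    s.t.  S v = 0,   lb ≤ v ≤ ub,
                  Σᵢ vᵢ · MWᵢ / (σᵢ · kcatᵢ)  ≤  Ptotal · f
```

with complex molecular weight `MW` (kDa), turnover number `kcat` (h⁻¹),
saturation coefficient `σ` (default 0.5), total protein content `Ptotal`
(default 0.56 g/gDCW) and `f` the mass fraction of that protein covered by
model enzymes.

The package implements the full construction pipeline and the standard
downstream analyses:

* **Model I/O and normalization** — COBRA-style JSON and SBML L3 (fbc)
  read/write; deterministic identifier normalization
  (`glc-D(e)` → `glc__D_e`).
* **GPR curation** — parse gene–protein–reaction rules to disjunctive
  normal form; screen `and`-linked gene pairs by global sequence identity
  (pairs that look like isozymes get flagged, never auto-edited); apply
  reviewed corrections in validated batches.
* **Reaction splitting** — reversible reactions into forward/reverse,
  isozyme alternatives into one reaction per enzyme; exchanges are never
  split.
* **Enzyme parameterization** — quantitative subunit stoichiometry parsed
  from UniProt-style text ("Homodimer" → 2 copies; "Tetramer of two alpha
  and two beta chains" → {α: 2, β: 2}); complex MW = Σ Nⱼ·MWⱼ; kcat
  matched from a local kinetics table at three levels (EC + organism, EC,
  EC class); `f` computed from abundance data.
* **kcat calibration** — deterministic cost-share-guided raising of
  undervalued turnover numbers until a measured growth rate is met.
* **Analyses** — FBA/pFBA, comparative flux variability at fixed growth,
  phenotype phase planes, overflow-metabolism scans with biomass yield and
  enzyme-usage efficiency, and enzyme-cost-based discovery of
  enhancement/weakening targets between production scenarios.

LPs are solved with GLPK through a small bundled C++ wrapper.

## Worked example

The package ships a seeded toy system — a high-yield, enzyme-expensive
respiratory pathway competing with a cheap fermentative one — whose
optimal behavior is known in closed form:

```r
library(ecgem)

spec <- toy_gem_spec()                 # fixed study conditions
toy <- make_toy_gem(spec)
proteins <- make_protein_records(spec)
kinetics <- make_kinetics_table(toy$truth)

ex <- expand_model(toy$model)          # split reversible + isozymes
comps <- setNames(lapply(proteins$interaction_text, parse_subunit_count),
                  proteins$gene_id)
mws <- setNames(proteins$monomer_mw_kda, proteins$gene_id)
tab <- build_enzyme_table(ex$model, comps, mws, kinetics)
ec <- build_ec_model(ex$model, tab$enzymes, ptotal = spec$pool, f = 1)
ec
#> ec_model: 17 reactions (4 enzyme-constrained), pool bound 0.2576 g/gDCW (Ptotal 0.258 x f 1)

fba(toy$model)$objective_value         # stoichiometric optimum
#> [1] 1
fba(ec)$objective_value                # enzyme-limited optimum
#> [1] 0.5769231

scan <- overflow_scan(ec, glucose_id = "EX_glc__D_e",
                      byproducts = "EX_ac_e")
attr(scan, "onset")                    # first uptake with secretion
#> [1] 4.75
scan[15:17, c("uptake", "growth", "EX_ac_e", "biomass_yield", "phase")]
#>    uptake growth EX_ac_e biomass_yield             phase
#> 15   4.50 0.4500  0.0000        0.5551 substrate-limited
#> 16   4.75 0.4558  0.3846        0.5326         switching
#> 17   5.00 0.4615  0.7692        0.5124          overflow
```

The enzyme pool makes the model secrete byproduct once uptake passes the
designed switch point (4.5 mmol/gDCW/h), with the biomass yield falling
exactly as the closed-form allocation predicts.

For file-based runs, `run_pipeline()` chains every stage (normalize →
curate → split → parameterize → build → calibrate → analyses) from a
config list or YAML file and writes all intermediates plus a checksummed
manifest. A thin command-line front end lives in `inst/cli/ecgem.R`.

See the vignette (`vignettes/enzyme-constrained-models.Rmd`) for the
methods, conventions and numerical choices in detail.

## Testing notes

Expected values in the test suite come from analytic oracles (a
closed-form two-pathway allocation LP), hand-computed sums, and
independently coded reference implementations — never from the code under
test. `tests/testthat/test-acceptance.R` contains one block per acceptance
criterion, including flux-space containment over 20 jittered model
instances and solver-vs-oracle agreement at 1e-6.
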