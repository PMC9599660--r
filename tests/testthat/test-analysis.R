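test_that("comparative FVA reports containment of the EC flux space", {
  toy <- build_toy()
  growth <- 0.5 * fba(toy$ec)$objective_value
  res <- comparative_fva(toy$model, toy$ec, fixed_growth = growth,
                         split_map_b = toy$split$split_map)
  expect_setequal(res$ranges$reaction_id, names(toy$model$reactions))
  # independently computed net-flux intervals: EC inside base
  base_rng <- net_flux_ranges(toy$model, identity_split_map(toy$model),
                              toy$model$objective, growth)
  ec_rng <- net_flux_ranges(toy$ec, toy$split$split_map,
                            toy$ec$model$objective, growth)
  m <- match(base_rng$reaction_id, ec_rng$reaction_id)
  expect_true(all(ec_rng$vmin[m] >= base_rng$vmin - TOL))
  expect_true(all(ec_rng$vmax[m] <= base_rng$vmax + TOL))
  # the cumulative table covers both models over all original reactions
  expect_equal(sum(res$cumulative$model == "a"), nrow(res$ranges))
  expect_equal(max(res$cumulative$cum_fraction), 1)
})

test_that("isozyme aggregation takes the maximum member range", {
  toy <- build_toy()
  growth <- 0.5 * fba(toy$ec)$objective_value
  core <- ecgem:::fva_core(toy$ec, growth, toy$ec$model$objective, list())
  agg <- ecgem:::aggregate_fva(core, toy$split$split_map)
  rng <- core$vmax - core$vmin
  expect_equal(agg$fv[agg$reaction_id == "FERM"],
               max(rng[c("FERM_num1", "FERM_num2")]), tolerance = 1e-9)
  # reversible pairs: forward range minus reverse range, review-flagged if < 0
  fv_act <- agg$fv[agg$reaction_id == "ACt"]
  expect_equal(fv_act, unname(rng["ACt"] - rng["ACt_reverse"]),
               tolerance = 1e-9)
  flag <- agg$flag[agg$reaction_id == "ACt"]
  expect_identical(flag, if (fv_act < 0) "review" else "")
})

test_that("the review flag fires exactly when the aggregate range is negative", {
  # synthetic core: forward range 1, reverse range 3 -> fv = -2, review
  core <- list(vmin = c(R = 0, R_reverse = 0),
               vmax = c(R = 1, R_reverse = 3),
               ref = list(fluxes = c(R = 0.5, R_reverse = 0)),
               lb = c(R = 0, R_reverse = 0),
               ub = c(R = 10, R_reverse = 10))
  map <- data.frame(split_id = c("R", "R_reverse"), original_id = "R",
                    direction = c("fwd", "rev"),
                    enzyme_index = NA_integer_, stringsAsFactors = FALSE)
  agg <- ecgem:::aggregate_fva(core, map)
  expect_equal(agg$fv, -2)
  expect_identical(agg$flag, "review")
})

test_that("phenotype phase plane has the expected boundary structure", {
  toy <- build_toy()
  grid <- seq(0, 6, by = 1)
  ph <- phpp(toy$ec, "EX_glc__D_e", "EX_o2_e", grid, grid)
  expect_equal(dim(ph$growth), c(7, 7))
  # zero glucose supports no growth, whatever the oxygen supply
  expect_true(all(ph$growth[1, ] == 0))
  # growth is non-decreasing in glucose at fixed oxygen and vice versa
  expect_true(all(apply(ph$growth, 2, function(col) all(diff(col) >= -TOL))))
  expect_true(all(apply(ph$growth, 1, function(row) all(diff(row) >= -TOL))))
  # zero oxygen forces fermentation-only growth: y2 * u capped by the pool
  u <- grid[3]
  expect_equal(ph$growth[3, 1],
               min(toy$truth$yield_ferm * u,
                   toy$truth$yield_ferm * toy$truth$pool /
                     toy$truth$cost_ferm), tolerance = 1e-6)
  # the EC surface never exceeds the purely stoichiometric surface
  ph_base <- phpp(toy$split$model, "EX_glc__D_e", "EX_o2_e", grid, grid)
  expect_true(all(ph$growth <= ph_base$growth + TOL))
  expect_false(any(ph$infeasible))
  expect_error(phpp(toy$ec, "EX_nope", "EX_o2_e", grid, grid),
               "missing exchange")
})

test_that("the overflow scan matches the analytic oracle", {
  toy <- build_toy()
  uptakes <- seq(1, 6.3, by = 0.25)
  sc <- overflow_scan(toy$ec, uptakes, glucose_id = "EX_glc__D_e",
                      byproducts = "EX_ac_e")
  orc <- toy$oracle
  expect_equal(sc$growth, vapply(uptakes, orc$growth, 0), tolerance = TOL)
  expect_equal(sc$EX_ac_e, vapply(uptakes, orc$byproduct, 0),
               tolerance = TOL)
  expect_equal(sc$emin, vapply(uptakes, orc$emin, 0), tolerance = TOL)
  expect_equal(sc$biomass_yield, vapply(uptakes, orc$yield, 0),
               tolerance = TOL)
  expect_equal(sc$enzyme_usage_efficiency,
               vapply(uptakes, orc$efficiency, 0), tolerance = TOL)
  # phase classification around the designed switch point
  onset <- attr(sc, "onset")
  expect_equal(onset, min(uptakes[uptakes > orc$u_star]))
  expect_identical(unique(sc$phase[sc$uptake < onset]), "substrate-limited")
  expect_identical(sc$phase[sc$uptake == onset], "switching")
  expect_identical(unique(sc$phase[sc$uptake > onset]), "overflow")
})

test_that("enzyme costs sum to the reported usage", {
  toy <- build_toy()
  sol <- pfba(toy$ec)
  costs <- enzyme_cost(sol, toy$ec)
  expect_setequal(costs$reaction_id, toy$ec$enzymes$reaction_id)
  expect_equal(attr(costs, "total"), sum(costs$cost), tolerance = 1e-12)
  expect_equal(attr(costs, "total"), sol$enzyme_usage, tolerance = 1e-9)
  expect_true(all(costs$cost >= -TOL))
})

test_that("scenario fluxes favor the product at low growth", {
  toy <- build_toy()
  sc <- scenario_fluxes(toy$ec, "EX_lys__L_e",
                        growth_hglp = 0.2, growth_lghp = 0.05)
  expect_identical(sc$hglp$status, "optimal")
  expect_equal(sc$hglp$objective_value, 0.2)
  expect_equal(sc$lghp$objective_value, 0.05)
  p_h <- attr(sc$hglp, "product_flux")
  p_l <- attr(sc$lghp, "product_flux")
  expect_gt(p_l, p_h - TOL)
  expect_equal(unname(sc$lghp$fluxes["EX_lys__L_e"]), p_l, tolerance = 1e-6)
  expect_error(scenario_fluxes(toy$ec, "EX_lys__L_e",
                               growth_hglp = 1e6, growth_lghp = 0.05),
               "HGLP")
})

test_that("target classification includes the 1.5 boundary and is symmetric", {
  cost <- function(ids, v) data.frame(reaction_id = ids, flux = v,
                                      cost = v, stringsAsFactors = FALSE)
  lg <- cost(c("r1", "r2", "r3", "r4", "r5"), c(1.5, 1.0, 1.49, 0.4, 0))
  hg <- cost(c("r1", "r2", "r3", "r4", "r5"), c(1.0, 1.0, 1.00, 0.6, 0))
  tg <- find_targets(lg, hg)
  got <- setNames(tg$class, tg$reaction_id)
  expect_identical(unname(got["r1"]), "enhance")  # ratio exactly 1.5
  expect_identical(unname(got["r2"]), "neutral")
  expect_identical(unname(got["r3"]), "neutral")  # just under the fold
  expect_identical(unname(got["r4"]), "weaken")   # hg/lg = 1.5 exactly
  expect_identical(unname(got["r5"]), "neutral")  # both zero
  # classes are disjoint by construction and swap under table exchange
  swapped <- find_targets(hg, lg)
  sw <- setNames(swapped$class, swapped$reaction_id)
  expect_identical(unname(sw["r1"]), "weaken")
  expect_identical(unname(sw["r4"]), "enhance")
  # zero denominator with positive numerator: infinite fold, flagged
  lg2 <- cost("rz", 0.3); hg2 <- cost("rz", 0)
  tz <- find_targets(lg2, hg2)
  expect_identical(tz$class, "enhance")
  expect_identical(tz$flag, "infinite-fold")
  expect_error(find_targets(lg, cost("other", 1)), "different reaction sets")
})

test_that("targets on the toy production system are internally consistent", {
  toy <- build_toy()
  sc <- scenario_fluxes(toy$ec, "EX_lys__L_e",
                        growth_hglp = 0.2, growth_lghp = 0.05)
  tg <- find_targets(enzyme_cost(sc$lghp, toy$ec),
                     enzyme_cost(sc$hglp, toy$ec))
  expect_false(any(tg$class == "enhance" & tg$class == "weaken"))
  # the product pathway's cost share rises when growth demand drops
  lys <- tg[tg$reaction_id == "LYS", ]
  expect_gt(lys$cost_lghp, lys$cost_hglp)
})

test_that("analysis tables serialize with 6-significant-digit rounding", {
  df <- data.frame(id = "x", value = 1.23456789, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_analysis_tsv(df, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$value, 1.23457)
})
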