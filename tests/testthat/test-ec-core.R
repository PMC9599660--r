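# A 2-reaction chain used for closed-form LP checks:
#   EX_a (uptake of a, lb = -10), A2B (a -> b), EX_b (secretion of b)
chain_model <- function(uptake = 10) {
  gem_model(
    id = "chain",
    metabolites = list(
      a = list(id = "a", name = "a", compartment = "c", formula = NULL),
      b = list(id = "b", name = "b", compartment = "c", formula = NULL)),
    reactions = list(
      EX_a = list(id = "EX_a", name = "EX_a", stoichiometry = c(a = -1),
                  lower_bound = -uptake, upper_bound = 0,
                  gene_reaction_rule = "", ec_numbers = character(0),
                  annotation = list()),
      A2B = list(id = "A2B", name = "A2B",
                 stoichiometry = c(a = -1, b = 1),
                 lower_bound = 0, upper_bound = 1000,
                 gene_reaction_rule = "gA", ec_numbers = "1.1.1.1",
                 annotation = list()),
      EX_b = list(id = "EX_b", name = "EX_b", stoichiometry = c(b = -1),
                  lower_bound = 0, upper_bound = 1000,
                  gene_reaction_rule = "", ec_numbers = character(0),
                  annotation = list())),
    genes = "gA", objective = c(EX_b = 1))
}

chain_ec <- function(mw = 100, kcat_h = 1000, sigma = 0.5, pool = 0.2) {
  enz <- data.frame(reaction_id = "A2B", genes = "gA", nj = "1",
                    mw_kda = mw, kcat_per_h = kcat_h, sigma = sigma,
                    kcat_source = "test", flags = "",
                    stringsAsFactors = FALSE)
  build_ec_model(chain_model(), enz, ptotal = pool, f = 1)
}

test_that("FBA solves the chain model to its closed form", {
  sol <- fba(chain_model())
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_a"]), -10, tolerance = 1e-9)
  expect_true(is.na(sol$enzyme_usage))
  # direction = "min" gives zero flux
  expect_equal(fba(chain_model(), direction = "min")$objective_value, 0,
               tolerance = 1e-9)
  expect_error(fba(chain_model(), objective = numeric(0)), "no objective")
  expect_error(fba(chain_model(), objective = c(NOPE = 1)),
               "unknown reactions")
})

test_that("the pool constraint caps flux at pool * sigma * kcat / MW", {
  # coef = MW / (sigma * kcat) = 100 / 500 = 0.2; cap = pool / coef = 1
  ec <- chain_ec(mw = 100, kcat_h = 1000, sigma = 0.5, pool = 0.2)
  expect_equal(ec$enzymes$coef, 0.2)
  expect_equal(ec$pool_bound, 0.2)
  sol <- fba(ec)
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  expect_equal(sol$enzyme_usage, ec$pool_bound, tolerance = 1e-9)
  # doubling kcat doubles the cap
  ec2 <- chain_ec(mw = 100, kcat_h = 2000, sigma = 0.5, pool = 0.2)
  expect_equal(fba(ec2)$objective_value, 2, tolerance = 1e-9)
  # a loose pool leaves the stoichiometric cap binding
  ec3 <- chain_ec(pool = 1e6)
  expect_equal(fba(ec3)$objective_value, 10, tolerance = 1e-9)
})

test_that("build_ec_model validates inputs", {
  enz <- data.frame(reaction_id = "GHOST", genes = "g", nj = "1",
                    mw_kda = 1, kcat_per_h = 1, sigma = 0.5,
                    kcat_source = "t", flags = "", stringsAsFactors = FALSE)
  expect_error(build_ec_model(chain_model(), enz, f = 0.5),
               "unknown reactions")
  good <- enz; good$reaction_id <- "A2B"
  expect_error(build_ec_model(chain_model(), good, f = 0), "f > 0")
  bad <- good; bad$sigma <- 1.5
  expect_error(build_ec_model(chain_model(), bad, f = 0.5))
})

test_that("EC growth is contained in base growth and monotone in the pool", {
  toy <- build_toy()
  base_opt <- fba(toy$split$model)$objective_value
  ec_opt <- fba(toy$ec)$objective_value
  expect_lte(ec_opt, base_opt + TOL)
  # growing the pool can only help
  pools <- c(0.5, 1, 2, 10) * toy$spec$pool
  opts <- vapply(pools, function(p) {
    ec <- build_ec_model(toy$split$model, toy$table$enzymes,
                         ptotal = p, f = 1)
    fba(ec)$objective_value
  }, 0)
  expect_true(all(diff(opts) >= -TOL))
  # enormous pool recovers the purely stoichiometric optimum
  ec_inf <- build_ec_model(toy$split$model, toy$table$enzymes,
                           ptotal = 1e6, f = 1)
  expect_equal(fba(ec_inf)$objective_value, base_opt, tolerance = 1e-6)
})

test_that("pFBA preserves the optimum and removes futile cycling", {
  toy <- build_toy()
  # force flux through the disconnected futile cycle to be possible: plain
  # FBA may or may not use it, pFBA must not
  sol <- pfba(toy$ec)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, fba(toy$ec)$objective_value,
               tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["CYCA"]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["CYCB"]), 0, tolerance = 1e-9)
  expect_lte(attr(sol, "total_flux"),
             sum(abs(fba(toy$ec)$fluxes)) + TOL)
})

test_that("pFBA handles models with reversible (negative-bound) reactions", {
  # unsplit toy model: ACt and the exchanges still run negative
  toy <- build_toy()
  sol <- pfba(toy$model)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, fba(toy$model)$objective_value,
               tolerance = 1e-9)
  # solution covers exactly the model's reactions (no auxiliary leakage)
  expect_setequal(names(sol$fluxes), names(toy$model$reactions))
})

test_that("min_enzyme reproduces hand-computed sums", {
  ec <- chain_ec(mw = 100, kcat_h = 1000, sigma = 0.5, pool = 0.2)
  # fixing throughput v = 0.5 needs coef * v = 0.1 g/gDCW
  res <- min_enzyme(ec, fixed_fluxes = c(A2B = 0.5))
  expect_equal(res$emin, 0.1, tolerance = 1e-9)
  expect_equal(res$solution$enzyme_usage, 0.1, tolerance = 1e-9)
  # interval fixing form
  res2 <- min_enzyme(ec, fixed_fluxes = list(EX_b = c(0.5, 0.5)))
  expect_equal(res2$emin, 0.1, tolerance = 1e-9)
  # infeasible fixings surface as errors, not silent zeros
  expect_error(min_enzyme(ec, fixed_fluxes = c(A2B = 50)), "infeasible")
})

test_that("infeasible and unbounded LPs report their status faithfully", {
  m <- chain_model()
  # demand secretion beyond the uptake limit -> infeasible
  m$reactions$EX_b$lower_bound <- 50
  sol <- fba(m)
  expect_identical(sol$status, "infeasible")
  # unbounded objective
  m2 <- chain_model()
  m2$reactions$A2B$upper_bound <- Inf
  m2$reactions$EX_b$upper_bound <- Inf
  m2$reactions$EX_a$lower_bound <- -Inf
  sol2 <- fba(m2)
  expect_identical(sol2$status, "unbounded")
})

test_that("ec models serialize to a JSON bundle and back", {
  toy <- build_toy()
  path <- withr::local_tempfile(fileext = ".json")
  write_ec_model(toy$ec, path)
  back <- read_ec_model(path)
  expect_equal(back$pool_bound, toy$ec$pool_bound)
  expect_identical(back$enzymes$reaction_id, toy$ec$enzymes$reaction_id)
  expect_equal(back$enzymes$coef, toy$ec$enzymes$coef, tolerance = 1e-12)
  expect_equal(fba(back)$objective_value, fba(toy$ec)$objective_value,
               tolerance = 1e-9)
})
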