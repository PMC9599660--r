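test_that("metabolite id normalization applies the rule table", {
  expect_identical(normalize_metabolite_id("glc-D(e)"), "glc__D_e")
  expect_identical(normalize_metabolite_id("atp"), "atp")
  expect_identical(normalize_metabolite_id("abc-x-D"), "abc_x__D")
  expect_identical(normalize_metabolite_id("mal-L"), "mal__L")
  expect_identical(normalize_metabolite_id("x-R(e)"), "x__R_e")
  expect_identical(normalize_metabolite_id(c("a-b", "c-D")),
                   c("a_b", "c__D"))
  expect_identical(normalize_metabolite_id(character(0)), character(0))
})

test_that("metabolite id normalization is idempotent", {
  raw <- c("glc-D(e)", "abc-x-D", "atp", "mal-L", "co2(e)", "a-b-c")
  once <- normalize_metabolite_id(raw)
  expect_identical(normalize_metabolite_id(once), once)
})

test_that("reaction id normalization replaces every dash with a double underscore", {
  expect_identical(normalize_reaction_id("EX_glc-D"), "EX_glc__D")
  expect_identical(normalize_reaction_id("PGI"), "PGI")
  expect_identical(normalize_reaction_id("R-1-a"), "R__1__a")
  once <- normalize_reaction_id(c("EX_glc-D", "R-1-a"))
  expect_identical(normalize_reaction_id(once), once)
})

test_that("empty identifiers are rejected", {
  expect_error(normalize_metabolite_id(""), "empty metabolite id")
  expect_error(normalize_reaction_id(""), "empty reaction id")
  expect_error(normalize_metabolite_id(c("ok", NA)), "empty metabolite id")
})

test_that("normalize_model rewrites ids consistently and reports changes", {
  m <- gem_model(
    metabolites = list(
      `glc-D(e)` = list(id = "glc-D(e)", name = "g", compartment = "e",
                        formula = NULL),
      atp = list(id = "atp", name = "atp", compartment = "c",
                 formula = NULL)),
    reactions = list(
      `EX_glc-D` = list(id = "EX_glc-D", name = "ex",
                        stoichiometry = c(`glc-D(e)` = -1),
                        lower_bound = -10, upper_bound = 0,
                        gene_reaction_rule = "", ec_numbers = character(0),
                        annotation = list())),
    objective = c(`EX_glc-D` = 1))
  norm <- normalize_model(m)
  expect_identical(names(norm$model$metabolites), c("glc__D_e", "atp"))
  expect_identical(names(norm$model$reactions), "EX_glc__D")
  expect_identical(names(norm$model$reactions[[1]]$stoichiometry),
                   "glc__D_e")
  expect_identical(names(norm$model$objective), "EX_glc__D")
  expect_equal(nrow(norm$report), 2)
  # idempotent: a second pass reports no changes
  norm2 <- normalize_model(norm$model)
  expect_equal(nrow(norm2$report), 0)
})

test_that("validate_model itemizes all violations", {
  m <- gem_model(
    metabolites = list(a = list(id = "a", name = "a", compartment = "c",
                                formula = NULL)),
    reactions = list(
      R1 = list(id = "R1", name = "r", stoichiometry = c(a = -1, ghost = 1),
                lower_bound = 5, upper_bound = 1,
                gene_reaction_rule = "gX", ec_numbers = character(0),
                annotation = list())),
    genes = character(0), objective = c(R9 = 1), validate = FALSE)
  issues <- validate_model(m, stop_on_error = FALSE)
  expect_length(issues, 4)
  expect_true(any(grepl("lower_bound > upper_bound", issues)))
  expect_true(any(grepl("unknown metabolites: ghost", issues)))
  expect_true(any(grepl("unlisted genes: gX", issues)))
  expect_true(any(grepl("objective references unknown reactions", issues)))
  expect_error(validate_model(m), "model validation failed")
})

test_that("JSON round trip preserves the model exactly", {
  toy <- make_toy_gem(toy_gem_spec())
  path <- withr::local_tempfile(fileext = ".json")
  write_model(toy$model, path)
  back <- read_model(path)
  expect_identical(names(back$reactions), names(toy$model$reactions))
  expect_identical(names(back$metabolites), names(toy$model$metabolites))
  expect_identical(back$genes, toy$model$genes)
  expect_equal(back$objective, toy$model$objective)
  for (rid in names(toy$model$reactions)) {
    a <- toy$model$reactions[[rid]]; b <- back$reactions[[rid]]
    expect_identical(b$stoichiometry[names(a$stoichiometry)],
                     a$stoichiometry)
    expect_identical(b$lower_bound, a$lower_bound)
    expect_identical(b$upper_bound, a$upper_bound)
    expect_identical(b$gene_reaction_rule, a$gene_reaction_rule)
    expect_identical(b$ec_numbers, a$ec_numbers)
  }
})

test_that("SBML round trip and cross-format equality hold", {
  toy <- make_toy_gem(toy_gem_spec())
  p_xml <- withr::local_tempfile(fileext = ".xml")
  p_json <- withr::local_tempfile(fileext = ".json")
  write_model(toy$model, p_xml)
  write_model(toy$model, p_json)
  from_xml <- read_model(p_xml)
  from_json <- read_model(p_json)
  expect_identical(names(from_xml$reactions), names(from_json$reactions))
  expect_identical(sort(from_xml$genes), sort(from_json$genes))
  for (rid in names(from_json$reactions)) {
    a <- from_json$reactions[[rid]]; b <- from_xml$reactions[[rid]]
    expect_equal(b$stoichiometry[names(a$stoichiometry)], a$stoichiometry)
    expect_equal(b$lower_bound, a$lower_bound)
    expect_equal(b$upper_bound, a$upper_bound)
    expect_identical(parsed_signatures(parse_gpr(b$gene_reaction_rule)),
                     parsed_signatures(parse_gpr(a$gene_reaction_rule)))
    expect_identical(b$ec_numbers, a$ec_numbers)
  }
  expect_equal(from_xml$objective[names(from_json$objective)],
               from_json$objective)
})

test_that("reading a model with a GPR over unlisted genes fails validation", {
  toy <- make_toy_gem(toy_gem_spec())
  path <- withr::local_tempfile(fileext = ".json")
  broken <- toy$model
  broken$reactions$RESP$gene_reaction_rule <- "g01 and g99"
  # bypass construction-time validation to exercise the read path
  class(broken) <- "gem_model"
  expect_error(write_model(broken, path), NA)
  expect_error(read_model(path), "unlisted genes: g99")
})

test_that("attach_annotations stores accessions and warns on unknown genes", {
  toy <- make_toy_gem(toy_gem_spec())
  m <- attach_annotations(toy$model, c(g01 = "P00001", g02 = "P00002"))
  expect_identical(m$gene_annotation$g01$uniprot, "P00001")
  expect_identical(m$gene_annotation$g02$uniprot, "P00002")
  expect_length(attr(m, "unmapped"), 0)
  expect_warning(m2 <- attach_annotations(toy$model,
                                          c(g01 = "P1", zz9 = "P2")),
                 "zz9")
  expect_identical(attr(m2, "unmapped"), "zz9")
  expect_identical(m2$gene_annotation$g01$uniprot, "P1")
  # empty mapping leaves the model unchanged
  m3 <- attach_annotations(toy$model, setNames(character(0), character(0)))
  expect_null(m3$gene_annotation$g01)
})

test_that("gene annotations survive a JSON round trip", {
  toy <- make_toy_gem(toy_gem_spec())
  m <- attach_annotations(toy$model, c(g01 = "P00001"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back$gene_annotation$g01$uniprot, "P00001")
})
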