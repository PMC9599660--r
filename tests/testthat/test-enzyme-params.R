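test_that("complex MW reproduces the worked heteromer and homodimer sums", {
  expect_equal(complex_mw(c(a = 30.26, b = 41.76), c(a = 2L, b = 2L)),
               144.04)
  expect_equal(complex_mw(c(g = 52.6), c(g = 2L)), 105.2)
  # linearity in the copy numbers
  mws <- c(a = 10, b = 20, c = 30)
  expect_equal(complex_mw(mws, c(a = 1L, b = 2L, c = 3L)), 10 + 40 + 90)
  expect_equal(complex_mw(mws, c(a = 2L, b = 4L, c = 6L)),
               2 * complex_mw(mws, c(a = 1L, b = 2L, c = 3L)))
  expect_error(complex_mw(c(a = 10), c(a = 1L, zz = 2L)), "zz")
  expect_error(complex_mw(c(a = 10), c(a = 0L)), "positive integers")
  expect_error(complex_mw(c(a = 10), c(a = 1.5)), "positive integers")
})

test_that("kinetics tables validate EC syntax and positivity", {
  tab <- data.frame(ec = c("1.1.1.1", "2.7.2.4"),
                    substrate = c("s1", "s2"), organism = c("o", "o"),
                    kcat_per_s = c(10, 20), source = c("a", "b"),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kinetics_tsv(tab, path)
  back <- read_kinetics_tsv(path)
  expect_equal(back$kcat_per_s, tab$kcat_per_s)

  bad <- tab; bad$kcat_per_s[1] <- 0
  write_kinetics_tsv(bad, path)
  expect_error(read_kinetics_tsv(path), "must be positive")
  bad <- tab; bad$ec[2] <- "not-an-ec"
  write_kinetics_tsv(bad, path)
  expect_error(read_kinetics_tsv(path), "malformed EC")
})

test_that("kcat matching honors the three priority levels", {
  tab <- data.frame(
    ec = c("1.1.1.1", "1.1.1.1", "1.1.1.2"),
    substrate = "s",
    organism = c("Corynebacterium glutamicum", "Escherichia coli",
                 "Corynebacterium glutamicum"),
    kcat_per_s = c(10, 50, 33.3),
    source = c("brenda", "sabio-rk", "brenda"),
    stringsAsFactors = FALSE)

  # level 1: exact EC restricted to the requested organism
  hit <- match_kcat("1.1.1.1", tab,
                    policy = list(aggregate = "max",
                                  organism = "Corynebacterium glutamicum"))
  expect_equal(hit$kcat_per_s, 10)
  expect_equal(hit$level, 1)

  # level 2: exact EC over all organisms (no organism given)
  hit <- match_kcat("1.1.1.1", tab)
  expect_equal(hit$kcat_per_s, 50)
  expect_equal(hit$level, 2)

  # level 3: class fallback when the exact EC is absent
  hit <- match_kcat("1.1.1.9", tab)
  expect_equal(hit$kcat_per_s, 50)
  expect_equal(hit$level, 3)
  expect_setequal(hit$ec, c("1.1.1.1", "1.1.1.2"))

  # wildcarded query matches on the leading fields
  hit <- match_kcat("1.1.1.-", tab)
  expect_equal(hit$kcat_per_s, 50)

  # median aggregation
  hit <- match_kcat("1.1.1.-", tab,
                    policy = list(aggregate = "median"))
  expect_equal(hit$kcat_per_s, 33.3)

  # no match at any level
  expect_null(match_kcat("9.9.9.9", tab))
  expect_null(match_kcat(character(0), tab))
})

test_that("kcat unit conversion multiplies by 3600 and rejects nonpositive", {
  expect_equal(kcat_to_per_hour(1), 3600)
  expect_equal(kcat_to_per_hour(c(0.5, 2)), c(1800, 7200))
  expect_error(kcat_to_per_hour(0), "positive")
  expect_error(kcat_to_per_hour(-3), "positive")
})

test_that("compute_f matches a hand-computed mass fraction and its properties", {
  abund <- data.frame(gene_id = c("g1", "g2", "x1"),
                      abundance = c(10, 20, 30), stringsAsFactors = FALSE)
  mws <- c(g1 = 2, g2 = 4, x1 = 8)
  # hand sum: (10*2 + 20*4) / (10*2 + 20*4 + 30*8) = 100/340
  expect_equal(compute_f(abund, mws, c("g1", "g2")), 100 / 340)
  # scale invariance in abundances
  abund2 <- abund; abund2$abundance <- abund2$abundance * 7.3
  expect_equal(compute_f(abund2, mws, c("g1", "g2")), 100 / 340)
  # monotone in model coverage, with the full-coverage limit f = 1
  expect_lt(compute_f(abund, mws, "g1"),
            compute_f(abund, mws, c("g1", "g2")))
  expect_equal(compute_f(abund, mws, c("g1", "g2", "x1")), 1)
  expect_error(compute_f(abund, mws[-3], c("g1")), "x1")
})

test_that("subunit copy numbers resolve singles, labeled pairs and unknowns", {
  comps <- list(
    solo = parse_subunit_count("Homodimer"),
    alpha_gene = parse_subunit_count("Tetramer of two alpha and two beta chains"),
    beta_gene = parse_subunit_count("Tetramer of two alpha and two beta chains"),
    vague = parse_subunit_count("Heterotetramer"),
    none = parse_subunit_count(""))

  one <- complex_subunit_counts("solo", comps)
  expect_identical(one$counts, c(solo = 2L))
  expect_length(one$flags, 0)

  lab <- complex_subunit_counts(c("alpha_gene", "beta_gene"), comps)
  expect_identical(lab$counts, c(alpha_gene = 2L, beta_gene = 2L))
  expect_identical(lab$flags, "label_order_assumed")

  unk <- complex_subunit_counts(c("vague", "none"), comps)
  expect_identical(unk$counts, c(none = 1L, vague = 1L))
  expect_identical(unk$flags, "stoichiometry_unknown")

  def <- complex_subunit_counts("none", comps)
  expect_identical(def$counts, c(none = 1L))
  expect_identical(def$flags, "defaulted")

  miss <- complex_subunit_counts("ghost", comps)
  expect_identical(miss$counts, c(ghost = 1L))
  expect_identical(miss$flags, "composition_missing")
})

test_that("the enzyme table carries designed MWs, kcats and reports the rest", {
  toy <- build_toy()
  enz <- toy$table$enzymes
  expect_setequal(enz$reaction_id,
                  c("RESP", "FERM_num1", "FERM_num2", "LYS"))
  get <- function(rid, col) enz[enz$reaction_id == rid, col]
  # heterotetramer: 2 x 30.26 + 2 x 41.76
  expect_equal(get("RESP", "mw_kda"), 144.04)
  expect_identical(get("RESP", "nj"), "2;2")
  expect_match(get("RESP", "flags"), "label_order_assumed")
  # homodimer isozymes: 2 x 52.6 each
  expect_equal(get("FERM_num1", "mw_kda"), 105.2)
  expect_equal(get("FERM_num2", "mw_kda"), 105.2)
  # kcats match the designed ground truth (per hour)
  expect_equal(get("RESP", "kcat_per_h"),
               toy$truth$kcat_per_s[["RESP"]] * 3600, tolerance = 1e-12)
  expect_equal(get("LYS", "kcat_per_h"),
               toy$truth$kcat_per_s[["LYS"]] * 3600, tolerance = 1e-12)
  expect_true(all(enz$sigma == 0.5))
  # reactions without EC or kcat end up in the unconstrained report
  uncon <- toy$table$unconstrained
  expect_true("CYCA" %in% uncon$reaction_id)
  expect_identical(uncon$reason[uncon$reaction_id == "CYCA"],
                   "no kcat match")
  expect_true(all(c("GLCt_num1", "O2t", "ACt", "ACt_reverse") %in%
                    uncon$reaction_id))
  expect_true(all(uncon$reason[uncon$reaction_id == "O2t"] ==
                    "no EC number"))
  # exchanges and the biomass sink appear in neither table
  expect_false(any(grepl("^EX_", c(enz$reaction_id, uncon$reaction_id))))
  expect_false("BIOMASS" %in% c(enz$reaction_id, uncon$reaction_id))
})

test_that("build_enzyme_table refuses a model that is not fully split", {
  toy <- build_toy()
  expect_error(
    build_enzyme_table(toy$model, toy$compositions, toy$monomer_mws,
                       toy$kinetics),
    "not fully split")
})

test_that("enzyme tables round trip through TSV at 6 significant digits", {
  toy <- build_toy()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enzyme_tsv(toy$table$enzymes, path)
  back <- read_enzyme_tsv(path)
  expect_identical(back$reaction_id, toy$table$enzymes$reaction_id)
  expect_identical(back$nj, toy$table$enzymes$nj)
  expect_equal(back$kcat_per_h, toy$table$enzymes$kcat_per_h,
               tolerance = 1e-5)
})
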