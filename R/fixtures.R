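# Synthetic toy-scale fixtures: a mass-balanced metabolic model with a
# respiration/fermentation branch point, a product pathway, a protein
# complex, an isozyme pair and a reversible transporter, together with
# matching protein records, kinetics and abundance tables and an analytic
# overflow oracle. Ground truth is carried in a sidecar record so that tests
# never re-derive expectations from the code under test.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic toy metabolic model
#'
#' The defaults encode the study conditions of the shipped toy system: total
#' protein content 0.56 g/gDCW with enzyme fraction 0.46 (pool bound 0.2576
#' g/gDCW), a respiration-like pathway with biomass yield 0.1 gDCW/mmol
#' glucose, a fermentation-like pathway with yield 0.05 secreting an
#' acetate-like byproduct, an overflow switch point at 4.5 mmol/gDCW/h
#' glucose uptake, a fermentation/respiration enzyme-cost ratio of 0.35 and
#' a glucose uptake cap of 10 mmol/gDCW/h. With \code{vary = TRUE} the
#' quantitative parameters are jittered by up to +/-15 percent (seeded,
#' order-preserving) to sample model instances for property tests.
#'
#' @param seed integer seed controlling sequences, abundances and jitter.
#' @param pool enzyme pool bound Ptotal * f, g/gDCW.
#' @param yield_resp,yield_ferm biomass yields of the two pathways,
#'   gDCW/mmol glucose (respiration > fermentation).
#' @param u_star glucose uptake at which the pool saturates on pure
#'   respiration (the overflow switch point), mmol/gDCW/h.
#' @param cost_ratio fermentation/respiration enzyme cost ratio in (0, 1).
#' @param product_cost enzyme cost of the product pathway per unit uptake.
#' @param uptake_max glucose uptake bound, mmol/gDCW/h.
#' @param sigma saturation coefficient used for all toy enzymes.
#' @param include_product_pathway,include_complexes,include_isozymes
#'   structural toggles.
#' @param vary jitter quantitative parameters (seeded) by +/-15 percent.
#' @return list of class \code{toy_gem_spec}.
#' @export
toy_gem_spec <- function(seed = 1, pool = 0.56 * 0.46, yield_resp = 0.1,
                         yield_ferm = 0.05, u_star = 4.5,
                         cost_ratio = 0.35, product_cost = 0.03,
                         uptake_max = 10, sigma = 0.5,
                         include_product_pathway = TRUE,
                         include_complexes = TRUE,
                         include_isozymes = TRUE, vary = FALSE) {
  if (vary) {
    j <- with_seed(seed, stats::runif(5, 0.85, 1.15))
    pool <- pool * j[1]
    yield_resp <- yield_resp * j[2]
    yield_ferm <- yield_ferm * j[3]
    u_star <- u_star * j[4]
    cost_ratio <- cost_ratio * j[5]
  }
  stopifnot(pool > 0, yield_resp > yield_ferm, yield_ferm > 0,
            u_star > 0, cost_ratio > 0, cost_ratio < 1, uptake_max > 0)
  structure(list(seed = seed, pool = pool, yield_resp = yield_resp,
                 yield_ferm = yield_ferm, u_star = u_star,
                 cost_ratio = cost_ratio, product_cost = product_cost,
                 uptake_max = uptake_max, sigma = sigma,
                 include_product_pathway = include_product_pathway,
                 include_complexes = include_complexes,
                 include_isozymes = include_isozymes),
            class = "toy_gem_spec")
}

toy_monomer_mws <- function() {
  c(g01 = 30.26, g02 = 41.76, g03 = 52.6, g04 = 52.6, g05 = 45.0,
    g06 = 40.0, g07 = 35.0, g08 = 28.0, g09 = 33.0, g10 = 50.0,
    g11 = 48.0, g12 = 46.0)
}

#' Generate a synthetic toy metabolic model with ground truth
#'
#' Builds a mass-balanced model: glucose exchange and transport into a
#' branch point with a respiration-like pathway (high yield, high enzyme
#' cost, requires oxygen), a fermentation-like pathway (lower yield, lower
#' cost, secretes an acetate-like byproduct), an optional lysine-like
#' product pathway, a reversible acetate transporter, an isozyme-catalyzed
#' transport step and a disconnected futile two-reaction cycle. The GPR
#' rules contain one true complex ("g01 and g02"), isozyme pairs and a
#' reversible reaction. Deterministic for a fixed spec.
#'
#' @param spec a \code{\link{toy_gem_spec}}.
#' @return list with \code{model} (a \code{gem_model}) and \code{truth}
#'   (pathway yields/costs, per-reaction kcats in 1/s, monomer MWs, the
#'   pool bound, the analytic switch point, and the ids of the key
#'   reactions).
#' @export
make_toy_gem <- function(spec) {
  stopifnot(inherits(spec, "toy_gem_spec"))
  y1 <- spec$yield_resp; y2 <- spec$yield_ferm
  a1 <- spec$pool / spec$u_star
  a2 <- a1 * spec$cost_ratio
  a3 <- spec$product_cost
  mws <- toy_monomer_mws()
  mw_resp <- if (spec$include_complexes) 2 * mws["g01"] + 2 * mws["g02"]
             else mws["g01"]
  mw_ferm <- 2 * mws["g03"]
  mw_lys <- mws["g06"]
  # kcat (1/h) giving the designed per-unit-flux enzyme costs a = MW/(sigma*kcat)
  kcat_resp_s <- unname(mw_resp / (spec$sigma * a1)) / 3600
  kcat_ferm_s <- unname(mw_ferm / (spec$sigma * a2)) / 3600
  kcat_lys_s <- unname(mw_lys / (spec$sigma * a3)) / 3600

  mets <- list(
    new_metabolite("glc__D_e", "D-glucose", "e"),
    new_metabolite("glc__D_c", "D-glucose", "c"),
    new_metabolite("o2_e", "oxygen", "e"),
    new_metabolite("o2_c", "oxygen", "c"),
    new_metabolite("ac_c", "acetate", "c"),
    new_metabolite("ac_e", "acetate", "e"),
    new_metabolite("bm_c", "biomass precursor", "c"),
    new_metabolite("cycA_c", "cycle metabolite A", "c"),
    new_metabolite("cycB_c", "cycle metabolite B", "c"))
  rxns <- list(
    new_reaction("EX_glc__D_e", c(glc__D_e = -1), -spec$uptake_max, 0,
                 name = "glucose exchange"),
    new_reaction("EX_o2_e", c(o2_e = -1), -1000, 0, name = "oxygen exchange"),
    new_reaction("EX_ac_e", c(ac_e = -1), 0, 1000, name = "acetate exchange"),
    new_reaction("GLCt", c(glc__D_e = -1, glc__D_c = 1), 0, 1000,
                 gene_reaction_rule = if (spec$include_isozymes)
                   "g05 or g12" else "g05",
                 name = "glucose transport"),
    new_reaction("O2t", c(o2_e = -1, o2_c = 1), 0, 1000,
                 gene_reaction_rule = "g08", name = "oxygen transport"),
    new_reaction("RESP", setNames(c(-1, -2, y1),
                                  c("glc__D_c", "o2_c", "bm_c")), 0, 1000,
                 gene_reaction_rule = if (spec$include_complexes)
                   "g01 and g02" else "g01",
                 ec_numbers = "1.1.1.1", name = "respiratory pathway"),
    new_reaction("FERM", setNames(c(-1, y2, 1),
                                  c("glc__D_c", "bm_c", "ac_c")), 0, 1000,
                 gene_reaction_rule = if (spec$include_isozymes)
                   "g03 or g04" else "g03",
                 ec_numbers = "4.1.1.1", name = "fermentative pathway"),
    new_reaction("ACt", c(ac_c = -1, ac_e = 1), -1000, 1000,
                 gene_reaction_rule = "g07", name = "acetate transport"),
    new_reaction("BIOMASS", c(bm_c = -1), 0, 1000, name = "biomass sink"),
    new_reaction("CYCA", c(cycA_c = -1, cycB_c = 1), 0, 1000,
                 gene_reaction_rule = "g10", ec_numbers = "5.3.1.9",
                 name = "futile cycle A"),
    new_reaction("CYCB", c(cycB_c = -1, cycA_c = 1), 0, 1000,
                 gene_reaction_rule = "g11", name = "futile cycle B"))
  if (spec$include_product_pathway) {
    mets <- c(mets, list(new_metabolite("lys__L_c", "L-lysine", "c"),
                         new_metabolite("lys__L_e", "L-lysine", "e")))
    rxns <- c(rxns, list(
      new_reaction("LYS", c(glc__D_c = -1, lys__L_c = 0.5), 0, 1000,
                   gene_reaction_rule = "g06", ec_numbers = "2.7.2.4",
                   name = "lysine pathway"),
      new_reaction("LYSt", c(lys__L_c = -1, lys__L_e = 1), 0, 1000,
                   gene_reaction_rule = "g09", name = "lysine transport"),
      new_reaction("EX_lys__L_e", c(lys__L_e = -1), 0, 1000,
                   name = "lysine exchange")))
  }
  names(mets) <- vapply(mets, `[[`, "", "id")
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  genes <- sort(unique(unlist(lapply(rxns, function(r)
    if (nzchar(r$gene_reaction_rule))
      gpr_genes(parse_gpr(r$gene_reaction_rule)) else character(0)))))
  model <- gem_model(id = sprintf("toy_ec_seed%d", spec$seed),
                     metabolites = mets, reactions = rxns, genes = genes,
                     objective = c(BIOMASS = 1))
  truth <- list(
    yield_resp = y1, yield_ferm = y2,
    cost_resp = unname(a1), cost_ferm = unname(a2),
    cost_product = a3, pool = spec$pool,
    u_star = spec$pool / a1, sigma = spec$sigma,
    kcat_per_s = c(RESP = kcat_resp_s, FERM = kcat_ferm_s,
                   LYS = kcat_lys_s),
    mw_kda = c(RESP = unname(mw_resp), FERM = unname(mw_ferm),
               LYS = unname(mw_lys)),
    monomer_mws = mws,
    uptake_max = spec$uptake_max,
    glucose_exchange = "EX_glc__D_e", oxygen_exchange = "EX_o2_e",
    byproduct_exchange = "EX_ac_e",
    product_exchange = if (spec$include_product_pathway)
      "EX_lys__L_e" else NA_character_,
    biomass = "BIOMASS")
  list(model = model, truth = truth)
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

#' Generate synthetic protein records for the toy model
#'
#' Every toy gene (plus a set of off-model genes standing in for the rest of
#' the proteome) receives an accession, a monomer molecular weight, a seeded
#' random sequence and an interaction description with known intended
#' subunit counts. The isozyme pair g03/g04 is a deliberate decoy for the
#' similarity screen: g04's sequence is g03's with point mutations at 10
#' percent of positions. The acetate transporter g07 carries deliberately
#' unparseable interaction text, exercising the monomer default.
#'
#' @param spec a \code{\link{toy_gem_spec}}.
#' @param n_extra_genes off-model genes to include (default 8).
#' @param seq_length sequence length (default 60).
#' @return data.frame of protein records (see
#'   \code{\link{read_protein_tsv}}) with attribute
#'   \code{"intended_counts"} (named integer vector: the total subunit count
#'   described by each record's interaction text).
#' @export
make_protein_records <- function(spec, n_extra_genes = 8, seq_length = 60) {
  mws <- toy_monomer_mws()
  with_seed(spec$seed + 1000L, {
    extra <- if (n_extra_genes > 0) sprintf("x%02d", seq_len(n_extra_genes))
             else character(0)
    extra_mws <- setNames(round(stats::runif(length(extra), 20, 80), 2), extra)
    genes <- c(names(mws), extra)
    allmw <- c(mws, extra_mws)
    seqs <- setNames(vapply(genes, function(g) random_aa(seq_length), ""),
                     genes)
    # decoy isozyme pair: g04 = g03 mutated at 10% of sites
    s3 <- strsplit(seqs[["g03"]], "")[[1]]
    at <- sample(seq_along(s3), max(1L, round(0.1 * length(s3))))
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (p in at) s3[p] <- sample(setdiff(alphabet, s3[p]), 1)
    seqs[["g04"]] <- paste(s3, collapse = "")
    interaction <- setNames(rep("Monomer", length(genes)), genes)
    if (spec$include_complexes) {
      interaction["g01"] <- "Heterotetramer of two alpha and two beta chains"
      interaction["g02"] <- "Heterotetramer of two alpha and two beta chains"
    }
    interaction["g03"] <- "Homodimer"
    interaction["g04"] <- "Homodimer"
    interaction["g07"] <- "Interacts with the membrane translocation machinery"
    pname <- setNames(paste("protein", genes), genes)
    pname["g01"] <- "Respiratory oxidoreductase component 1"
    pname["g02"] <- "Respiratory oxidoreductase component 2"
    pname["g03"] <- "Acetate-forming decarboxylase 1"
    pname["g04"] <- "Acetate-forming decarboxylase 2"
    pname["g06"] <- "Lysine pathway kinase"
    df <- data.frame(
      accession = sprintf("P%05d", seq_along(genes)),
      gene_id = genes,
      protein_name = unname(pname),
      monomer_mw_kda = unname(allmw[genes]),
      interaction_text = unname(interaction),
      sequence = unname(seqs),
      stringsAsFactors = FALSE)
    intended <- setNames(rep(1L, length(genes)), genes)
    if (spec$include_complexes)
      intended[c("g01", "g02")] <- 4L  # whole-complex total in each record
    intended[c("g03", "g04")] <- 2L
    attr(df, "intended_counts") <- intended
    attr(df, "mutated_fraction") <- length(at) / seq_length
    df
  })
}

#' Generate a synthetic kinetics table for the toy model
#'
#' One true entry per toy EC number (matching the designed per-pathway
#' enzyme costs) plus lower-valued decoys in other organisms and a same-class
#' sibling EC. With \code{calibration_fixture = TRUE} the exact-EC entry for
#' the respiratory pathway is undervalued tenfold while the true maximum is
#' only present at class level (a sibling EC), which is the single-bottleneck
#' fixture for \code{\link{calibrate_kcat}}.
#'
#' @param truth ground-truth record from \code{\link{make_toy_gem}}.
#' @param calibration_fixture build the undervalued-kcat variant.
#' @return kinetics data.frame (see \code{\link{read_kinetics_tsv}}).
#' @export
make_kinetics_table <- function(truth, calibration_fixture = FALSE) {
  org <- "Corynebacterium glutamicum"
  k <- truth$kcat_per_s
  rows <- list(
    data.frame(ec = "4.1.1.1", substrate = "pyruvate", organism = org,
               kcat_per_s = k[["FERM"]], source = "brenda"),
    data.frame(ec = "4.1.1.1", substrate = "pyruvate",
               organism = "Escherichia coli",
               kcat_per_s = k[["FERM"]] * 0.4, source = "sabio-rk"),
    data.frame(ec = "2.7.2.4", substrate = "aspartate", organism = org,
               kcat_per_s = k[["LYS"]], source = "brenda"))
  if (calibration_fixture) {
    rows <- c(rows, list(
      data.frame(ec = "1.1.1.1", substrate = "glucose", organism = org,
                 kcat_per_s = k[["RESP"]] / 10, source = "brenda"),
      data.frame(ec = "1.1.1.2", substrate = "glucose", organism = org,
                 kcat_per_s = k[["RESP"]], source = "brenda")))
  } else {
    rows <- c(rows, list(
      data.frame(ec = "1.1.1.1", substrate = "glucose", organism = org,
                 kcat_per_s = k[["RESP"]], source = "brenda"),
      data.frame(ec = "1.1.1.1", substrate = "glucose",
                 organism = "Escherichia coli",
                 kcat_per_s = k[["RESP"]] * 0.5, source = "sabio-rk"),
      data.frame(ec = "1.1.1.2", substrate = "gluconate", organism = org,
                 kcat_per_s = k[["RESP"]] * 0.8, source = "brenda")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_kinetics(out)
  out
}

#' Generate a synthetic gene-abundance table
#'
#' Seeded random abundances for every toy model gene and every off-model
#' gene in the protein records, standing in for an expression dataset used
#' to compute the enzyme mass fraction f.
#'
#' @param spec a \code{\link{toy_gem_spec}}.
#' @param proteins protein records from \code{\link{make_protein_records}}.
#' @return data.frame with \code{gene_id}, \code{abundance}.
#' @export
make_abundance_table <- function(spec, proteins) {
  with_seed(spec$seed + 2000L, {
    data.frame(gene_id = proteins$gene_id,
               abundance = round(stats::runif(nrow(proteins), 5, 500), 2),
               stringsAsFactors = FALSE)
  })
}

#' Analytic oracle for the two-pathway overflow system
#'
#' Closed-form solution of the two-variable allocation LP: route glucose
#' uptake u through a high-yield pathway (yield y1, enzyme cost a1 per unit
#' uptake) and a low-yield pathway (y2 < y1, a2 < a1) to maximize growth
#' \eqn{y_1 u_1 + y_2 u_2} under \eqn{u_1 + u_2 = u} and the pool bound
#' \eqn{a_1 u_1 + a_2 u_2 \le pool}. Below the switch point
#' \eqn{u^* = pool / a_1} everything is routed through the high-yield
#' pathway; above it the pool binds and flux spills into the low-yield
#' pathway, secreting byproduct.
#'
#' @param y1,y2 pathway biomass yields, y1 > y2 > 0.
#' @param a1,a2 pathway enzyme costs per unit uptake, a1 > a2 > 0.
#' @param pool enzyme pool bound.
#' @return list with \code{u_star}, \code{u_max} (= pool/a2, the uptake
#'   beyond which the forced-uptake system is infeasible), and functions of
#'   uptake: \code{growth}, \code{byproduct}, \code{yield}, \code{emin},
#'   \code{efficiency}.
#' @export
overflow_switch_oracle <- function(y1, y2, a1, a2, pool) {
  if (!(y1 > y2 && y2 > 0)) stop("need y1 > y2 > 0")
  if (!(a1 > a2 && a2 > 0)) stop("need a1 > a2 > 0")
  if (pool <= 0) stop("need pool > 0")
  u_star <- pool / a1
  u_max <- pool / a2
  alloc <- function(u) {
    if (u <= u_star) c(u1 = u, u2 = 0)
    else {
      u1 <- (pool - a2 * u) / (a1 - a2)
      c(u1 = max(u1, 0), u2 = u - max(u1, 0))
    }
  }
  growth <- function(u) {
    a <- alloc(u)
    y1 * a[["u1"]] + y2 * a[["u2"]]
  }
  byproduct <- function(u) alloc(u)[["u2"]]
  yield <- function(u) if (u > 0) growth(u) / (u * GLUCOSE_MW_G_PER_MMOL) else 0
  emin <- function(u) if (u <= u_star) a1 * u else pool
  efficiency <- function(u) growth(u) / emin(u)
  list(u_star = u_star, u_max = u_max, growth = growth,
       byproduct = byproduct, yield = yield, emin = emin,
       efficiency = efficiency)
}

#' Write the full toy fixture set to a directory
#'
#' Emits \code{model.json}, \code{proteins.tsv}, \code{kinetics.tsv},
#' \code{abundance.tsv} and \code{ground_truth.json}.
#'
#' @param spec a \code{\link{toy_gem_spec}}.
#' @param dir output directory (created if needed).
#' @param calibration_fixture see \code{\link{make_kinetics_table}}.
#' @return invisibly, a named list of the written paths.
#' @export
write_toy_fixtures <- function(spec, dir, calibration_fixture = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_gem(spec)
  proteins <- make_protein_records(spec)
  kin <- make_kinetics_table(toy$truth, calibration_fixture)
  abund <- make_abundance_table(spec, proteins)
  paths <- c(model = file.path(dir, "model.json"),
             proteins = file.path(dir, "proteins.tsv"),
             kinetics = file.path(dir, "kinetics.tsv"),
             abundance = file.path(dir, "abundance.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_model(toy$model, paths[["model"]], format = "json")
  write_protein_tsv(proteins, paths[["proteins"]])
  write_kinetics_tsv(kin, paths[["kinetics"]])
  utils::write.table(abund, paths[["abundance"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(toy$truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(as.list(paths))
}
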