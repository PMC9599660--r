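#' Default pipeline configuration
#'
#' Returns the default run configuration as a named list; values can be
#' overridden by a YAML config file and by arguments to
#' \code{\link{run_pipeline}}. Defaults: total protein content
#' \code{ptotal = 0.56} g/gDCW, saturation coefficient \code{sigma = 0.5},
#' fold-change threshold \code{fold = 1.5} for target classification,
#' similarity screen threshold 20 percent.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    model = NULL, proteins = NULL, kinetics = NULL, abundance = NULL,
    f = NULL, ptotal = 0.56, sigma = 0.5,
    screen_threshold = 20, gpr_edits = NULL,
    kcat_policy = "max", organism = NULL,
    target_growth = NULL, max_rounds = 20, uptake_fix = NULL,
    glucose_exchange = NULL, oxygen_exchange = NULL,
    byproducts = NULL, product_exchange = NULL,
    growth_hglp = 0.46, growth_lghp = 0.1, fold = 1.5,
    fva_growth = NULL,
    phpp_max = 10, phpp_step = 0.5,
    overflow_from = 1, overflow_to = 6.3, overflow_step = 0.25,
    analyses = character(0),  # subset of fva, phpp, overflow, targets
    out_dir = "ecgem_run", seed = 1)
}

read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Run the full enzyme-constrained model construction pipeline
#'
#' Executes the stages in order: read and normalize the model, parse protein
#' records and screen suspect 'and' GPR relationships, apply reviewed GPR
#' edits, split reversible and isozyme reactions, parameterize enzymes
#' (complex MW, kcat matching, f), build the enzyme-constrained model,
#' optionally calibrate kcat values against a target growth rate, and run
#' the requested analyses. Every stage's outputs are written under
#' \code{out_dir} and recorded (with md5 checksums and wall time) in a run
#' manifest; a stage failure halts the run naming the stage.
#'
#' @param config a config list (see \code{\link{default_config}}), or a
#'   path to a YAML file with the same keys.
#' @param ... individual config overrides.
#' @return the manifest (list), invisibly also written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(config = default_config(), ...) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(config, list(...))
  for (key in c("model", "proteins", "kinetics")) {
    if (is.null(config[[key]]))
      stop("config is missing required input: ", key)
    if (!file.exists(config[[key]]))
      stop("config input does not exist: ", key, " = ", config[[key]])
  }
  if (is.null(config$f) && is.null(config$abundance))
    stop("config must provide either f or an abundance table")
  if (!is.null(config$abundance) && !file.exists(config$abundance))
    stop("config input does not exist: abundance = ", config$abundance)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(config = config, stages = list())
  outpath <- function(name) file.path(config$out_dir, name)
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    files <- out$files %||% character(0)
    manifest$stages[[name]] <<- list(
      outputs = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  st <- stage("normalize", function() {
    model <- read_model(config$model)
    norm <- normalize_model(model)
    p1 <- outpath("model_normalized.json")
    p2 <- outpath("normalization_report.tsv")
    write_model(norm$model, p1, format = "json")
    write_analysis_tsv(norm$report, p2)
    list(model = norm$model, files = c(p1, p2))
  })
  model <- st$model

  st <- stage("curate_gpr", function() {
    proteins <- read_protein_tsv(config$proteins)
    screen <- screen_and_relationships(model, proteins,
                                       threshold = config$screen_threshold)
    p1 <- outpath("gpr_screen.tsv")
    write_analysis_tsv(screen, p1)
    files <- p1
    if (!is.null(config$gpr_edits)) {
      edits <- utils::read.delim(config$gpr_edits, stringsAsFactors = FALSE)
      res <- apply_gpr_corrections(model, edits)
      model <- res$model
      p2 <- outpath("gpr_edit_log.tsv")
      write_analysis_tsv(res$log, p2)
      files <- c(files, p2)
    }
    list(model = model, proteins = proteins, files = files)
  })
  model <- st$model
  proteins <- st$proteins

  st <- stage("expand", function() {
    ex <- expand_model(model)
    p1 <- outpath("model_split.json")
    p2 <- outpath("split_map.tsv")
    write_model(ex$model, p1, format = "json")
    write_split_map(ex$split_map, p2)
    list(expanded = ex, files = c(p1, p2))
  })
  split <- st$expanded

  st <- stage("parameterize", function() {
    kinetics <- read_kinetics_tsv(config$kinetics)
    compositions <- setNames(lapply(proteins$interaction_text,
                                    parse_subunit_count), proteins$gene_id)
    mws <- setNames(proteins$monomer_mw_kda, proteins$gene_id)
    tab <- build_enzyme_table(split$model, compositions, mws, kinetics,
                              sigma_default = config$sigma,
                              policy = list(aggregate = config$kcat_policy,
                                            organism = config$organism))
    f <- config$f
    if (is.null(f)) {
      abund <- read_abundance_tsv(config$abundance)
      f <- compute_f(abund, mws, model$genes)
    }
    p1 <- outpath("enzymes.tsv")
    p2 <- outpath("unconstrained_reactions.tsv")
    p3 <- outpath("f.txt")
    write_enzyme_tsv(tab$enzymes, p1)
    write_analysis_tsv(tab$unconstrained, p2)
    writeLines(format(f, digits = 10), p3)
    list(enzymes = tab$enzymes, f = f, kinetics = kinetics,
         files = c(p1, p2, p3))
  })
  enzymes <- st$enzymes
  f <- st$f
  kinetics <- st$kinetics

  st <- stage("build_ec", function() {
    ec <- build_ec_model(split$model, enzymes, ptotal = config$ptotal, f = f)
    p1 <- outpath("ec_model.json")
    write_ec_model(ec, p1)
    list(ec = ec, files = p1)
  })
  ec <- st$ec

  if (!is.null(config$target_growth)) {
    st <- stage("calibrate", function() {
      fix <- unlist(config$uptake_fix) %||% NULL
      cal <- calibrate_kcat(ec, target_growth = config$target_growth,
                            kinetics = kinetics,
                            max_rounds = config$max_rounds,
                            uptake_fix = fix)
      p1 <- outpath("calibration_log.tsv")
      p2 <- outpath("ec_model_calibrated.json")
      write_analysis_tsv(cal$log, p1)
      write_ec_model(cal$model, p2)
      list(ec = cal$model, files = c(p1, p2))
    })
    ec <- st$ec
  }

  if ("fva" %in% config$analyses) {
    stage("fva", function() {
      growth <- config$fva_growth %||%
        (0.95 * fba(ec)$objective_value)
      res <- comparative_fva(model, ec, fixed_growth = growth,
                             split_map_b = split$split_map)
      p1 <- outpath("fva.tsv")
      write_analysis_tsv(res$ranges, p1)
      list(files = p1)
    })
  }
  if ("phpp" %in% config$analyses) {
    stage("phpp", function() {
      grid <- seq(0, config$phpp_max, by = config$phpp_step)
      res <- phpp(ec, config$glucose_exchange, config$oxygen_exchange,
                  grid, grid)
      long <- data.frame(glucose = rep(res$glucose, times = length(res$oxygen)),
                         oxygen = rep(res$oxygen, each = length(res$glucose)),
                         growth = as.vector(res$growth))
      p1 <- outpath("phpp.tsv")
      write_analysis_tsv(long, p1)
      list(files = p1)
    })
  }
  if ("overflow" %in% config$analyses) {
    stage("overflow", function() {
      res <- overflow_scan(ec,
                           uptakes = seq(config$overflow_from,
                                         config$overflow_to,
                                         by = config$overflow_step),
                           glucose_id = config$glucose_exchange,
                           byproducts = config$byproducts)
      p1 <- outpath("overflow.tsv")
      write_analysis_tsv(res, p1)
      list(files = p1)
    })
  }
  if ("targets" %in% config$analyses) {
    stage("targets", function() {
      sc <- scenario_fluxes(ec, config$product_exchange,
                            growth_hglp = config$growth_hglp,
                            growth_lghp = config$growth_lghp)
      tg <- find_targets(enzyme_cost(sc$lghp, ec),
                         enzyme_cost(sc$hglp, ec), fold = config$fold)
      p1 <- outpath("targets.tsv")
      write_analysis_tsv(tg, p1)
      list(files = p1)
    })
  }

  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(manifest)
}
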