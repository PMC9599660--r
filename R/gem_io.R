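#' @useDynLib ecgem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames median
#' @importFrom utils read.delim write.table
NULL

DEFAULT_BOUND <- 1000

#' Normalize a metabolite identifier
#'
#' Applies the identifier substitutions used when preparing a stoichiometric
#' model for enzyme-constrained reconstruction: \code{"(e)"} becomes
#' \code{"_e"}, the stereo-descriptor suffixes \code{"-D"}, \code{"-L"} and
#' \code{"-R"} become \code{"__D"}, \code{"__L"} and \code{"__R"}, and any
#' remaining \code{"-"} becomes \code{"_"}. Longest patterns are replaced
#' first so that e.g. \code{"-D(e)"} cannot be corrupted. The function is
#' idempotent.
#'
#' @param raw character vector of metabolite ids.
#' @return character vector of normalized ids.
#' @examples
#' normalize_metabolite_id("glc-D(e)")  # "glc__D_e"
#' @export
normalize_metabolite_id <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (any(is.na(raw)) || any(!nzchar(raw)))
    stop("invalid identifier: empty metabolite id")
  x <- gsub("(e)", "_e", raw, fixed = TRUE)
  # protect already-normalized '__D' etc. from the residual '-' rule by
  # replacing the longest patterns first
  x <- gsub("-D", "__D", x, fixed = TRUE)
  x <- gsub("-L", "__L", x, fixed = TRUE)
  x <- gsub("-R", "__R", x, fixed = TRUE)
  x <- gsub("-", "_", x, fixed = TRUE)
  x
}

#' Normalize a reaction identifier
#'
#' Every \code{"-"} in a reaction id becomes \code{"__"} (the same rule is
#' applied to exchange \code{EX_} reactions and all other reactions).
#' Idempotent on its own outputs.
#'
#' @param raw character vector of reaction ids.
#' @return character vector of normalized ids.
#' @examples
#' normalize_reaction_id("EX_glc-D")  # "EX_glc__D"
#' @export
normalize_reaction_id <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (any(is.na(raw)) || any(!nzchar(raw)))
    stop("invalid identifier: empty reaction id")
  gsub("-", "__", raw, fixed = TRUE)
}

#' Construct a metabolic model object
#'
#' A \code{gem_model} is the in-memory form of a COBRA-style stoichiometric
#' model: metabolites, reactions with bounds and gene-protein-reaction (GPR)
#' rules, genes and a linear objective.
#'
#' @param id model id.
#' @param metabolites named list of metabolite records (fields \code{id},
#'   \code{name}, \code{compartment}, \code{formula}).
#' @param reactions named list of reaction records (fields \code{id},
#'   \code{name}, \code{stoichiometry} (named numeric, metabolite ids to
#'   signed coefficients), \code{lower_bound}, \code{upper_bound},
#'   \code{gene_reaction_rule}, \code{ec_numbers}, \code{annotation}).
#' @param genes character vector of gene ids.
#' @param objective named numeric vector, reaction id to objective
#'   coefficient.
#' @param validate validate invariants (default TRUE).
#' @return object of class \code{gem_model}.
#' @export
gem_model <- function(id = "model", metabolites = list(), reactions = list(),
                      genes = character(0), objective = numeric(0),
                      validate = TRUE) {
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions, genes = genes,
                      objective = objective),
                 class = "gem_model")
  if (validate) validate_model(m)
  m
}

#' @export
print.gem_model <- function(x, ...) {
  cat(sprintf("gem_model '%s': %d metabolites, %d reactions, %d genes\n",
              x$id, length(x$metabolites), length(x$reactions),
              length(x$genes)))
  if (length(x$objective))
    cat("objective:", paste(names(x$objective), collapse = " + "), "\n")
  invisible(x)
}

new_metabolite <- function(id, name = id, compartment = "", formula = NULL) {
  list(id = id, name = name, compartment = compartment, formula = formula)
}

new_reaction <- function(id, stoichiometry, lower_bound = 0,
                         upper_bound = DEFAULT_BOUND, gene_reaction_rule = "",
                         name = id, ec_numbers = character(0),
                         annotation = list()) {
  list(id = id, name = name, stoichiometry = stoichiometry,
       lower_bound = lower_bound, upper_bound = upper_bound,
       gene_reaction_rule = gene_reaction_rule, ec_numbers = ec_numbers,
       annotation = annotation)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants of a \code{gem_model}: unique non-empty
#' ids, every metabolite referenced by a reaction exists, every gene used in a
#' GPR rule is listed, objective coefficients reference existing reactions,
#' and \code{lower_bound <= upper_bound}.
#'
#' @param model a \code{gem_model}.
#' @param stop_on_error if TRUE (default), signal an error listing all
#'   violations; if FALSE, return the character vector of violations.
#' @return invisibly, a character vector of violations (empty when valid).
#' @export
validate_model <- function(model, stop_on_error = TRUE) {
  issues <- character(0)
  mids <- vapply(model$metabolites, `[[`, "", "id")
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (any(!nzchar(mids))) issues <- c(issues, "empty metabolite id")
  if (anyDuplicated(mids))
    issues <- c(issues, paste("duplicate metabolite ids:",
                              paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  if (anyDuplicated(rids))
    issues <- c(issues, paste("duplicate reaction ids:",
                              paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound)
      issues <- c(issues, sprintf("reaction %s: lower_bound > upper_bound", r$id))
    missing <- setdiff(names(r$stoichiometry), mids)
    if (length(missing))
      issues <- c(issues, sprintf("reaction %s references unknown metabolites: %s",
                                  r$id, paste(missing, collapse = ", ")))
    if (nzchar(r$gene_reaction_rule)) {
      gg <- tryCatch(gpr_genes(parse_gpr(r$gene_reaction_rule)),
                     error = function(e) {
                       issues <<- c(issues, sprintf("reaction %s: GPR parse error: %s",
                                                    r$id, conditionMessage(e)))
                       character(0)
                     })
      unknown <- setdiff(gg, model$genes)
      if (length(unknown))
        issues <- c(issues, sprintf("reaction %s: GPR uses unlisted genes: %s",
                                    r$id, paste(unknown, collapse = ", ")))
    }
  }
  bad_obj <- setdiff(names(model$objective), rids)
  if (length(bad_obj))
    issues <- c(issues, paste("objective references unknown reactions:",
                              paste(bad_obj, collapse = ", ")))
  if (length(issues) && stop_on_error)
    stop("model validation failed:\n  ", paste(issues, collapse = "\n  "))
  invisible(issues)
}

#' Normalize all identifiers in a model
#'
#' Applies \code{\link{normalize_metabolite_id}} to every metabolite id (and
#' to the keys of each reaction's stoichiometry) and
#' \code{\link{normalize_reaction_id}} to every reaction id, including the
#' objective's keys.
#'
#' @param model a \code{gem_model}.
#' @return list with elements \code{model} (the normalized model) and
#'   \code{report} (data.frame of old/new ids for ids that changed).
#' @export
normalize_model <- function(model) {
  old_m <- vapply(model$metabolites, `[[`, "", "id")
  new_m <- normalize_metabolite_id(old_m)
  old_r <- vapply(model$reactions, `[[`, "", "id")
  new_r <- normalize_reaction_id(old_r)
  map_m <- setNames(new_m, old_m)
  model$metabolites <- lapply(model$metabolites, function(m) {
    m$id <- map_m[[m$id]]
    m
  })
  names(model$metabolites) <- new_m
  model$reactions <- lapply(model$reactions, function(r) {
    r$id <- normalize_reaction_id(r$id)
    names(r$stoichiometry) <- unname(map_m[names(r$stoichiometry)])
    r
  })
  names(model$reactions) <- new_r
  if (length(model$objective))
    names(model$objective) <- normalize_reaction_id(names(model$objective))
  report <- rbind(
    data.frame(kind = "metabolite", old = old_m, new = new_m,
               stringsAsFactors = FALSE)[old_m != new_m, ],
    data.frame(kind = "reaction", old = old_r, new = new_r,
               stringsAsFactors = FALSE)[old_r != new_r, ])
  rownames(report) <- NULL
  validate_model(model)
  list(model = model, report = report)
}

#' Attach protein accessions to model genes
#'
#' Stores a protein accession (e.g. a UniProt id) in each mapped gene's
#' annotation slot; the mapping is the basis for looking up kinetic and
#' molecular-weight data. Unknown genes in the mapping are reported as
#' warnings, not errors.
#'
#' @param model a \code{gem_model}.
#' @param mapping named character vector, gene id to protein accession.
#' @return the model with a \code{gene_annotation} element (named list gene ->
#'   list(uniprot = accession)) and attribute \code{"unmapped"} listing
#'   mapping keys that are not model genes.
#' @export
attach_annotations <- function(model, mapping) {
  unknown <- setdiff(names(mapping), model$genes)
  if (length(unknown))
    warning("mapping contains genes not in the model: ",
            paste(unknown, collapse = ", "))
  known <- intersect(names(mapping), model$genes)
  ann <- if (is.null(model$gene_annotation)) list() else model$gene_annotation
  for (g in known) ann[[g]] <- utils::modifyList(
    if (is.null(ann[[g]])) list() else ann[[g]],
    list(uniprot = unname(mapping[[g]])))
  model$gene_annotation <- ann
  attr(model, "unmapped") <- unknown
  model
}

is_exchange <- function(reaction) {
  length(reaction$stoichiometry) <= 1L || startsWith(reaction$id, "EX_")
}

#' Read a metabolic model from file
#'
#' Reads COBRA-style JSON or SBML Level 3 (with the fbc package for bounds,
#' GPR rules and the objective) and returns a validated \code{gem_model}.
#'
#' @param path file path.
#' @param format "json", "sbml", or "auto" (default; by file extension).
#' @return a \code{gem_model}.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  model <- switch(format,
                  json = read_model_json(path),
                  sbml = read_model_sbml(path))
  validate_model(model)
  model
}

#' Write a metabolic model to file
#'
#' @param model a \code{gem_model}.
#' @param path output path.
#' @param format "json", "sbml", or "auto" (by extension).
#' @return invisibly, \code{path}.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  mets <- lapply(doc$metabolites, function(m)
    new_metabolite(m$id, name = m$name %||% m$id,
                   compartment = m$compartment %||% "",
                   formula = m$formula))
  names(mets) <- vapply(mets, `[[`, "", "id")
  objective <- numeric(0)
  rxns <- lapply(doc$reactions, function(r) {
    ann <- r$annotation %||% list()
    ec <- ann[["ec-code"]] %||% character(0)
    st <- unlist(r$metabolites) %||% setNames(numeric(0), character(0))
    storage.mode(st) <- "double"
    new_reaction(r$id,
                 stoichiometry = st,
                 lower_bound = as.numeric(r$lower_bound %||% -DEFAULT_BOUND),
                 upper_bound = as.numeric(r$upper_bound %||% DEFAULT_BOUND),
                 gene_reaction_rule = r$gene_reaction_rule %||% "",
                 name = r$name %||% r$id,
                 ec_numbers = as.character(ec),
                 annotation = ann)
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  for (r in doc$reactions) {
    oc <- r$objective_coefficient %||% 0
    if (!is.null(oc) && oc != 0) objective[r$id] <- oc
  }
  genes <- vapply(doc$genes, function(g)
    if (is.list(g)) g$id else as.character(g), "")
  gene_ann <- list()
  for (g in doc$genes) {
    if (is.list(g) && !is.null(g$annotation) && length(g$annotation))
      gene_ann[[g$id]] <- as.list(g$annotation)
  }
  m <- gem_model(id = doc$id %||% "model", metabolites = mets,
                 reactions = rxns, genes = genes, objective = objective,
                 validate = FALSE)
  if (length(gene_ann)) m$gene_annotation <- gene_ann
  m
}

write_model_json <- function(model, path) {
  mets <- unname(lapply(model$metabolites, function(m) {
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.null(m$formula)) out$formula <- m$formula
    out
  }))
  rxns <- unname(lapply(model$reactions, function(r) {
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(r$stoichiometry),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gene_reaction_rule)
    ann <- r$annotation
    if (length(r$ec_numbers)) ann[["ec-code"]] <- as.list(r$ec_numbers)
    if (length(ann)) out$annotation <- ann
    oc <- model$objective[r$id]
    if (!is.na(oc) && length(oc) && oc != 0) out$objective_coefficient <- unname(oc)
    out
  }))
  genes <- lapply(model$genes, function(g) {
    out <- list(id = g, name = g)
    if (!is.null(model$gene_annotation[[g]]))
      out$annotation <- model$gene_annotation[[g]]
    out
  })
  doc <- list(id = model$id, metabolites = mets, reactions = rxns,
              genes = genes, version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
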