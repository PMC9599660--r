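FLUX_TOL <- 1e-6

identity_split_map <- function(model) {
  rids <- names(as_base_model(model)$reactions)
  data.frame(split_id = rids, original_id = rids, direction = "fwd",
             enzyme_index = NA_integer_, stringsAsFactors = FALSE)
}

growth_row <- function(objective, value) {
  list(coefs = objective, lb = value, ub = value)
}

# min/max flux of every reaction at fixed growth; returns per split reaction
# vmin, vmax plus a parsimonious reference solution
fva_core <- function(model, fixed_growth, objective, overrides) {
  base <- as_base_model(model)
  rxn_ids <- names(base$reactions)
  grow <- growth_row(objective, fixed_growth)

  ref <- lp_run(model, setNames(rep(1, length(rxn_ids)), rxn_ids),
                maximize = FALSE, extra_rows = list(grow),
                bounds_override = overrides)
  if (ref$status != "optimal")
    stop("fixing growth at ", fixed_growth, " leaves the model ", ref$status)

  vmin <- vmax <- setNames(numeric(length(rxn_ids)), rxn_ids)
  for (rid in rxn_ids) {
    obj <- setNames(1, rid)
    lo <- lp_run(model, obj, maximize = FALSE, extra_rows = list(grow),
                 bounds_override = overrides)
    hi <- lp_run(model, obj, maximize = TRUE, extra_rows = list(grow),
                 bounds_override = overrides)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem failed for reaction ", rid)
    vmin[rid] <- lo$objective_value
    vmax[rid] <- hi$objective_value
  }
  list(vmin = vmin, vmax = vmax, ref = ref,
       lb = vapply(base$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(base$reactions, `[[`, 0, "upper_bound"))
}

# aggregate split-level FVA ranges onto original reactions:
# isozymes take the maximum member range; reversible pairs subtract the
# reverse range from the forward range (flagged for review when negative)
aggregate_fva <- function(core, split_map) {
  agg <- list()
  for (oid in unique(split_map$original_id)) {
    mem <- split_map[split_map$original_id == oid, ]
    rng <- core$vmax[mem$split_id] - core$vmin[mem$split_id]
    fwd <- rng[mem$direction == "fwd"]
    rev <- rng[mem$direction == "rev"]
    fv_fwd <- if (length(fwd)) max(fwd) else 0
    fv_rev <- if (length(rev)) max(rev) else 0
    fv <- fv_fwd - fv_rev
    span <- core$ub[mem$split_id] - core$lb[mem$split_id]
    fully <- any(span > 0 & rng >= 0.999 * span)
    net_ref <- sum(core$ref$fluxes[mem$split_id] *
                     ifelse(mem$direction == "rev", -1, 1))
    agg[[oid]] <- data.frame(
      reaction_id = oid, fv = fv,
      flag = if (fv < 0) "review" else "",
      active = abs(net_ref) > FLUX_TOL,
      fully_variable = fully, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Comparative flux variability analysis at fixed growth
#'
#' Fixes the growth rate in two models (typically the base stoichiometric
#' model and its enzyme-constrained counterpart), computes each reaction's
#' flux range by LP minimization/maximization, and aggregates split-model
#' ranges back onto original reactions: isozyme copies contribute the
#' maximum member range, and for reversible pairs the reverse range is
#' subtracted from the forward range (rows where this is negative are
#' flagged "review"). Also reports, per model, the fraction of active
#' reactions whose flux range spans (>= 99.9\% of) their bound span, and the
#' cumulative distribution of the ranges.
#'
#' @param model_a,model_b \code{gem_model} or \code{ec_model}.
#' @param fixed_growth growth rate (1/h) at which both models are compared.
#' @param uptake_fix optional named numeric vector of fluxes fixed in both
#'   models (e.g. glucose exchange).
#' @param split_map_a,split_map_b split maps (see \code{\link{expand_model}});
#'   identity when NULL.
#' @param objective_a,objective_b growth objectives (default: each model's
#'   stored objective).
#' @return list with \code{ranges} (data.frame reaction_id, fv_a, fv_b,
#'   flags), \code{fraction_fully_variable} (named numeric, a and b),
#'   \code{cumulative} (data.frame model, fv, cum_fraction).
#' @export
comparative_fva <- function(model_a, model_b, fixed_growth,
                            uptake_fix = NULL,
                            split_map_a = NULL, split_map_b = NULL,
                            objective_a = NULL, objective_b = NULL) {
  overrides <- if (is.null(uptake_fix)) list() else
    setNames(lapply(uptake_fix, function(v) c(v, v)), names(uptake_fix))
  obj_a <- objective_a %||% as_base_model(model_a)$objective
  obj_b <- objective_b %||% as_base_model(model_b)$objective
  map_a <- split_map_a %||% identity_split_map(model_a)
  map_b <- split_map_b %||% identity_split_map(model_b)

  core_a <- withCallingHandlers(
    fva_core(model_a, fixed_growth, obj_a, overrides),
    error = function(e) stop("model_a: ", conditionMessage(e), call. = FALSE))
  core_b <- withCallingHandlers(
    fva_core(model_b, fixed_growth, obj_b, overrides),
    error = function(e) stop("model_b: ", conditionMessage(e), call. = FALSE))
  agg_a <- aggregate_fva(core_a, map_a)
  agg_b <- aggregate_fva(core_b, map_b)

  ids <- union(agg_a$reaction_id, agg_b$reaction_id)
  ranges <- data.frame(
    reaction_id = ids,
    fv_a = agg_a$fv[match(ids, agg_a$reaction_id)],
    fv_b = agg_b$fv[match(ids, agg_b$reaction_id)],
    flag_a = agg_a$flag[match(ids, agg_a$reaction_id)],
    flag_b = agg_b$flag[match(ids, agg_b$reaction_id)],
    stringsAsFactors = FALSE)
  frac <- c(a = with(agg_a, if (any(active)) mean(fully_variable[active]) else NA_real_),
            b = with(agg_b, if (any(active)) mean(fully_variable[active]) else NA_real_))
  cum <- rbind(
    data.frame(model = "a", fv = sort(agg_a$fv),
               cum_fraction = seq_along(agg_a$fv) / nrow(agg_a)),
    data.frame(model = "b", fv = sort(agg_b$fv),
               cum_fraction = seq_along(agg_b$fv) / nrow(agg_b)))
  list(ranges = ranges, fraction_fully_variable = frac, cumulative = cum,
       split = list(a = core_a, b = core_b))
}

#' Phenotype phase plane
#'
#' Maximal growth over a 2-D grid of glucose and oxygen uptake rates. At
#' each grid point the two exchange lower bounds are set to minus the grid
#' value (uptake at most that rate), biomass is maximized and resolved with
#' pFBA. Infeasible points are recorded as growth 0 with a flag.
#'
#' @param model \code{gem_model} or \code{ec_model}.
#' @param glucose_id,oxygen_id exchange reaction ids.
#' @param glucose_grid,oxygen_grid uptake rates (mmol/gDCW/h), default
#'   \code{seq(0, 10, by = 0.5)}.
#' @param objective growth objective (default: the model's).
#' @return object of class \code{phpp_grid}: list with \code{glucose},
#'   \code{oxygen}, \code{growth} (matrix, rows = glucose axis) and
#'   \code{infeasible} (logical matrix).
#' @export
phpp <- function(model, glucose_id, oxygen_id,
                 glucose_grid = seq(0, 10, by = 0.5),
                 oxygen_grid = seq(0, 10, by = 0.5),
                 objective = NULL) {
  base <- as_base_model(model)
  for (rid in c(glucose_id, oxygen_id))
    if (!rid %in% names(base$reactions))
      stop("missing exchange reaction: ", rid)
  objective <- objective %||% base$objective
  growth <- matrix(0, length(glucose_grid), length(oxygen_grid),
                   dimnames = list(glucose_grid, oxygen_grid))
  infeasible <- matrix(FALSE, length(glucose_grid), length(oxygen_grid))
  for (i in seq_along(glucose_grid)) {
    for (j in seq_along(oxygen_grid)) {
      ov <- list(c(-glucose_grid[i], 0), c(-oxygen_grid[j], 0))
      names(ov) <- c(glucose_id, oxygen_id)
      sol <- pfba_fixed(model, objective, ov)
      if (sol$status == "optimal") {
        growth[i, j] <- sol$objective_value
      } else {
        infeasible[i, j] <- TRUE
      }
    }
  }
  structure(list(glucose = glucose_grid, oxygen = oxygen_grid,
                 growth = growth, infeasible = infeasible),
            class = "phpp_grid")
}

#' @export
print.phpp_grid <- function(x, ...) {
  cat(sprintf("phpp_grid: %d x %d points, growth %.4g-%.4g 1/h\n",
              length(x$glucose), length(x$oxygen), min(x$growth),
              max(x$growth)))
  invisible(x)
}

GLUCOSE_MW_G_PER_MMOL <- 0.18016

#' Overflow-metabolism scan over substrate uptake
#'
#' For each glucose uptake rate: fix the uptake, maximize biomass with pFBA,
#' then compute the biomass yield (gDCW per g glucose,
#' \eqn{v_{biomass} / (v_{glc} \cdot 0.18016)}), the minimum enzyme amount
#' \eqn{E_{min}} supporting the achieved growth, and the enzyme usage
#' efficiency \eqn{v_{biomass}/E_{min}}. Rows are classified into the
#' substrate-limited phase, the switch point, and the overflow phase by the
#' first uptake with nonzero byproduct secretion.
#'
#' @param model an \code{ec_model}.
#' @param uptakes glucose uptake rates, mmol/gDCW/h (default 1 to 6.3).
#' @param glucose_id glucose exchange reaction id.
#' @param byproducts character vector of byproduct exchange ids (e.g. the
#'   acetate exchange).
#' @param objective growth objective (default: the model's).
#' @return data.frame with columns uptake, growth, one column per byproduct,
#'   biomass_yield, emin, enzyme_usage_efficiency, phase; the attribute
#'   \code{"onset"} holds the first uptake with byproduct secretion (NA if
#'   none).
#' @export
overflow_scan <- function(model, uptakes = seq(1, 6.3, by = 0.25),
                          glucose_id, byproducts, objective = NULL) {
  stopifnot(is_ec_model(model))
  objective <- objective %||% model$model$objective
  rows <- list()
  for (u in uptakes) {
    ov <- setNames(list(c(-u, -u)), glucose_id)
    sol <- pfba_fixed(model, objective, ov)
    if (sol$status != "optimal")
      stop("overflow scan infeasible at uptake ", u)
    growth <- sol$objective_value
    byp <- vapply(byproducts, function(b) unname(sol$fluxes[b]), 0)
    em <- min_enzyme_at_growth(model, objective, growth, glucose_id, u)
    yield <- if (u > 0) growth / (u * GLUCOSE_MW_G_PER_MMOL) else 0
    eff <- if (growth <= FLUX_TOL) 0 else growth / em
    rows[[length(rows) + 1L]] <- data.frame(
      uptake = u, growth = growth, t(byp), biomass_yield = yield,
      emin = em, enzyme_usage_efficiency = eff, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + length(byproducts))] <- byproducts
  secreting <- rowSums(as.matrix(out[byproducts])) > FLUX_TOL
  onset <- if (any(secreting)) out$uptake[which(secreting)[1]] else NA_real_
  out$phase <- if (is.na(onset)) "substrate-limited" else
    ifelse(out$uptake < onset, "substrate-limited",
           ifelse(out$uptake == onset, "switching", "overflow"))
  attr(out, "onset") <- onset
  out
}

# Emin at a given growth with uptake capped (not forced)
min_enzyme_at_growth <- function(model, objective, growth, glucose_id, u) {
  rxn_ids <- names(model$model$reactions)
  coefs <- ec_coef_vector(model, rxn_ids)
  sol <- lp_run(model, coefs[coefs != 0], maximize = FALSE,
                extra_rows = list(growth_row(objective, growth)),
                bounds_override = setNames(list(c(-u, 0)), glucose_id))
  if (sol$status != "optimal")
    stop("minimum-enzyme LP ", sol$status, " at growth ", growth)
  sol$objective_value
}

#' Enzyme cost of each constrained reaction in a flux solution
#'
#' \eqn{\text{cost}_i = v_i MW_i / (\sigma_i k_{cat,i})} in g enzyme/gDCW.
#' The costs sum to the solution's total enzyme usage.
#'
#' @param solution a \code{flux_solution} over the ec model.
#' @param model the \code{ec_model} the solution was computed on.
#' @return data.frame with reaction_id, flux, cost; attribute
#'   \code{"total"} is the summed cost.
#' @export
enzyme_cost <- function(solution, model) {
  stopifnot(is_ec_model(model))
  enz <- model$enzymes
  flux <- solution$fluxes[enz$reaction_id]
  out <- data.frame(reaction_id = enz$reaction_id,
                    flux = unname(flux),
                    cost = unname(enz$coef * flux),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(out$cost)
  out
}

#' Flux states of the high-growth and low-growth production scenarios
#'
#' Computes the two reference states used for enzyme-cost target discovery:
#' high growth / low product (HGLP, growth fixed at 0.46 1/h by default) and
#' low growth / high product (LGHP, 0.1 1/h). In each scenario the growth
#' rate is fixed, the product exchange flux is maximized, and the remaining
#' degeneracy is resolved by minimizing total enzyme usage at the product
#' optimum, giving a deterministic flux state.
#'
#' @param model an \code{ec_model}.
#' @param product_exchange product exchange reaction id.
#' @param growth_hglp,growth_lghp fixed growth rates (1/h).
#' @param objective growth objective (default: the model's).
#' @return list with \code{hglp} and \code{lghp} \code{flux_solution}s; each
#'   carries attribute \code{"product_flux"}.
#' @export
scenario_fluxes <- function(model, product_exchange, growth_hglp = 0.46,
                            growth_lghp = 0.1, objective = NULL) {
  stopifnot(is_ec_model(model))
  objective <- objective %||% model$model$objective
  one <- function(growth, label) {
    grow <- growth_row(objective, growth)
    pmax <- lp_run(model, setNames(1, product_exchange), maximize = TRUE,
                   extra_rows = list(grow))
    if (pmax$status != "optimal")
      stop("scenario ", label, ": growth fixing at ", growth,
           " is ", pmax$status)
    popt <- pmax$objective_value
    rxn_ids <- names(model$model$reactions)
    coefs <- ec_coef_vector(model, rxn_ids)
    sol <- lp_run(model, coefs[coefs != 0], maximize = FALSE,
                  extra_rows = list(
                    grow,
                    list(coefs = setNames(1, product_exchange),
                         lb = popt - 1e-9, ub = Inf)))
    if (sol$status != "optimal")
      stop("scenario ", label, ": enzyme minimization ", sol$status)
    sol$enzyme_usage <- sol$objective_value
    sol$objective_value <- growth
    attr(sol, "product_flux") <- popt
    sol
  }
  list(hglp = one(growth_hglp, "HGLP"), lghp = one(growth_lghp, "LGHP"))
}

#' Classify metabolic-engineering targets from enzyme-cost tables
#'
#' Compares the per-reaction enzyme cost between the low-growth/high-product
#' (LGHP) and high-growth/low-product (HGLP) states. A reaction is an
#' enhancement target when \eqn{cost_{LGHP}/cost_{HGLP} \ge fold} and a
#' weakening target when \eqn{cost_{HGLP}/cost_{LGHP} \ge fold} (default
#' fold 1.5, boundary included). A zero denominator with a positive
#' numerator classifies at infinite fold (flagged); both costs zero is
#' neutral. The two classes are disjoint and swap exactly when the input
#' tables are swapped.
#'
#' @param cost_lghp,cost_hglp enzyme-cost data.frames from
#'   \code{\link{enzyme_cost}} over the same reaction set.
#' @param fold fold-change threshold (default 1.5).
#' @return data.frame with reaction_id, cost_lghp, cost_hglp, log2_fold
#'   (log2 of LGHP/HGLP), class ("enhance", "weaken", "neutral") and flag
#'   ("infinite-fold" where a cost was zero).
#' @export
find_targets <- function(cost_lghp, cost_hglp, fold = 1.5) {
  if (!setequal(cost_lghp$reaction_id, cost_hglp$reaction_id))
    stop("cost tables cover different reaction sets")
  ids <- cost_lghp$reaction_id
  lg <- cost_lghp$cost
  hg <- cost_hglp$cost[match(ids, cost_hglp$reaction_id)]
  tol <- 1e-12
  class <- character(length(ids))
  flag <- character(length(ids))
  for (k in seq_along(ids)) {
    a <- lg[k]; b <- hg[k]
    if (a <= tol && b <= tol) {
      class[k] <- "neutral"
    } else if (b <= tol) {
      class[k] <- "enhance"; flag[k] <- "infinite-fold"
    } else if (a <= tol) {
      class[k] <- "weaken"; flag[k] <- "infinite-fold"
    } else if (a / b >= fold * (1 - 1e-9)) {
      # relative slack so that the included boundary (ratio == fold) is not
      # lost to floating-point division
      class[k] <- "enhance"
    } else if (b / a >= fold * (1 - 1e-9)) {
      class[k] <- "weaken"
    } else {
      class[k] <- "neutral"
    }
  }
  data.frame(reaction_id = ids, cost_lghp = lg, cost_hglp = hg,
             log2_fold = log2(lg / hg), class = class, flag = flag,
             stringsAsFactors = FALSE)
}

#' Write an analysis table to TSV
#'
#' Numeric columns are rounded to 6 significant digits at output only.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_analysis_tsv <- function(table, path) {
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
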