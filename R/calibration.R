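#' Calibrate underestimated kcat values against a target growth rate
#'
#' Iterative enzyme-usage-guided correction: solve pFBA for growth under the
#' fixed uptake condition; while growth is below the target, rank the
#' enzyme-constrained reactions by their enzyme cost share
#' \eqn{(v_i MW_i / (\sigma_i k_{cat,i})) / (P_{total} f)} in the current
#' solution, take the highest-ranked reaction whose EC-class maximum kcat in
#' the kinetics table exceeds its current value, substitute that maximum
#' (class level: last EC field wildcarded), and re-solve. Stops when the
#' target is reached, when \code{max_rounds} is exhausted, or when no
#' raisable candidate remains. One reaction is modified per round; a reaction
#' may be selected again only if the table still offers a higher value. Ties
#' in cost share break lexicographically on reaction id, making the run
#' deterministic.
#'
#' @param model an \code{ec_model}.
#' @param target_growth target growth rate (1/h), > 0.
#' @param kinetics kinetics data.frame.
#' @param max_rounds maximum calibration rounds (default 20).
#' @param uptake_fix named numeric vector of fluxes to fix (lb = ub =
#'   value), e.g. the glucose exchange at its measured uptake.
#' @param objective growth objective (default: the model's objective).
#' @return list with \code{model} (calibrated \code{ec_model}) and
#'   \code{log} (data.frame: round, reaction_id, ec, old_kcat_per_h,
#'   new_kcat_per_h, growth_before, growth_after).
#' @export
calibrate_kcat <- function(model, target_growth, kinetics, max_rounds = 20,
                           uptake_fix = NULL, objective = NULL) {
  stopifnot(is_ec_model(model), target_growth > 0)
  objective <- objective %||% model$model$objective
  overrides <- if (is.null(uptake_fix)) list() else
    setNames(lapply(uptake_fix, function(v) c(v, v)), names(uptake_fix))

  solve_growth <- function(ec) {
    sol <- pfba_fixed(ec, objective, overrides)
    if (sol$status != "optimal")
      stop("calibration: growth LP is ", sol$status,
           " under the fixed uptake")
    sol
  }
  empty_log <- data.frame(round = integer(0), reaction_id = character(0),
                          ec = character(0), old_kcat_per_h = numeric(0),
                          new_kcat_per_h = numeric(0),
                          growth_before = numeric(0),
                          growth_after = numeric(0), stringsAsFactors = FALSE)
  log <- empty_log
  sol <- solve_growth(model)
  round_i <- 0L
  while (sol$objective_value < target_growth - 1e-9 &&
         round_i < max_rounds) {
    enz <- model$enzymes
    if (!nrow(enz)) break
    share <- enz$coef * sol$fluxes[enz$reaction_id] / model$pool_bound
    ord <- order(-share, enz$reaction_id)
    pick <- NA_integer_
    new_kcat_h <- NA_real_
    for (k in ord) {
      rid <- enz$reaction_id[k]
      ecs <- model$model$reactions[[rid]]$ec_numbers
      if (!length(ecs)) next
      # class-level maximum (includes exact matches)
      class_ecs <- unique(vapply(ecs, function(e) {
        fl <- ec_fields(e)[[1]]
        paste(c(fl[1:3], "-"), collapse = ".")
      }, ""))
      hit <- match_kcat(class_ecs, kinetics,
                        policy = list(aggregate = "max"))
      if (is.null(hit)) next
      cand <- kcat_to_per_hour(hit$kcat_per_s)
      if (cand > enz$kcat_per_h[k] * (1 + 1e-9)) {
        pick <- k
        new_kcat_h <- cand
        break
      }
    }
    if (is.na(pick)) break
    round_i <- round_i + 1L
    old <- enz$kcat_per_h[pick]
    growth_before <- sol$objective_value
    model$enzymes$kcat_per_h[pick] <- new_kcat_h
    model$enzymes$coef[pick] <- model$enzymes$mw_kda[pick] /
      (model$enzymes$sigma[pick] * new_kcat_h)
    model$enzymes$kcat_source[pick] <-
      paste0("calibrated:", model$enzymes$kcat_source[pick])
    sol <- solve_growth(model)
    log <- rbind(log, data.frame(
      round = round_i, reaction_id = enz$reaction_id[pick],
      ec = paste(model$model$reactions[[enz$reaction_id[pick]]]$ec_numbers,
                 collapse = ";"),
      old_kcat_per_h = old, new_kcat_per_h = new_kcat_h,
      growth_before = growth_before, growth_after = sol$objective_value,
      stringsAsFactors = FALSE))
  }
  list(model = model, log = log, growth = sol$objective_value)
}

# pFBA with bound overrides applied to the model before solving
pfba_fixed <- function(model, objective, overrides) {
  base <- as_base_model(model)
  for (rid in names(overrides)) {
    if (!rid %in% names(base$reactions))
      stop("flux fixing on unknown reaction: ", rid)
    base$reactions[[rid]]$lower_bound <- overrides[[rid]][1]
    base$reactions[[rid]]$upper_bound <- overrides[[rid]][2]
  }
  m <- if (is_ec_model(model)) { model$model <- base; model } else base
  pfba(m, objective)
}

#' Manually override the kcat of one constrained reaction
#'
#' Replaces the turnover number of an enzyme entry (value given in 1/s,
#' stored in 1/h) and records a manual-override provenance. Used for
#' judgment-call corrections outside the automatic calibration loop, e.g.
#' when an exceptionally large complex distorts fluxes.
#'
#' @param model an \code{ec_model}.
#' @param reaction_id a constrained reaction id.
#' @param kcat_per_s new turnover number, 1/s.
#' @return the updated \code{ec_model}.
#' @export
override_kcat <- function(model, reaction_id, kcat_per_s) {
  stopifnot(is_ec_model(model))
  k <- match(reaction_id, model$enzymes$reaction_id)
  if (is.na(k))
    stop("reaction is not enzyme-constrained: ", reaction_id)
  model$enzymes$kcat_per_h[k] <- kcat_to_per_hour(kcat_per_s)
  model$enzymes$coef[k] <- model$enzymes$mw_kda[k] /
    (model$enzymes$sigma[k] * model$enzymes$kcat_per_h[k])
  model$enzymes$kcat_source[k] <-
    paste0("manual-override:", model$enzymes$kcat_source[k])
  model
}
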