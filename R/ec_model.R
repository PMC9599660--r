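#' Build an enzyme-constrained model
#'
#' Adds the single total-enzyme pool constraint
#' \deqn{\sum_i \frac{v_i \, MW_i}{\sigma_i \, k_{cat,i}} \le P_{total} \, f}
#' to a fully split model. Each constrained reaction i contributes with
#' coefficient \eqn{MW_i / (\sigma_i k_{cat,i})} (g enzyme per mmol/gDCW/h of
#' flux); unconstrained reactions have coefficient zero. \eqn{P_{total}} is
#' the total protein content (g protein / gDCW, default 0.56) and f the mass
#' fraction of model enzymes in total protein.
#'
#' @param model_split a fully split \code{gem_model}.
#' @param enzyme_table enzyme data.frame from
#'   \code{\link{build_enzyme_table}} (needs reaction_id, mw_kda,
#'   kcat_per_h, sigma).
#' @param ptotal total protein content, g/gDCW.
#' @param f enzyme mass fraction in (0, 1].
#' @return object of class \code{ec_model}: list with \code{model},
#'   \code{enzymes} (with an added \code{coef} column, g per flux unit),
#'   \code{ptotal}, \code{f}, \code{pool_bound}.
#' @export
build_ec_model <- function(model_split, enzyme_table, ptotal = 0.56, f) {
  stopifnot(f > 0, f <= 1, ptotal > 0)
  unknown <- setdiff(enzyme_table$reaction_id, names(model_split$reactions))
  if (length(unknown))
    stop("enzyme entries reference unknown reactions: ",
         paste(unknown, collapse = ", "))
  if (nrow(enzyme_table)) {
    stopifnot(all(enzyme_table$mw_kda > 0), all(enzyme_table$kcat_per_h > 0),
              all(enzyme_table$sigma > 0), all(enzyme_table$sigma <= 1))
    enzyme_table$coef <- enzyme_table$mw_kda /
      (enzyme_table$sigma * enzyme_table$kcat_per_h)
  } else {
    enzyme_table$coef <- numeric(0)
  }
  structure(list(model = model_split, enzymes = enzyme_table,
                 ptotal = ptotal, f = f, pool_bound = ptotal * f),
            class = "ec_model")
}

#' @export
print.ec_model <- function(x, ...) {
  cat(sprintf(paste0("ec_model: %d reactions (%d enzyme-constrained), ",
                     "pool bound %.4g g/gDCW (Ptotal %.3g x f %.3g)\n"),
              length(x$model$reactions), nrow(x$enzymes), x$pool_bound,
              x$ptotal, x$f))
  invisible(x)
}

is_ec_model <- function(x) inherits(x, "ec_model")

as_base_model <- function(x) if (is_ec_model(x)) x$model else x

# enzyme pool coefficients aligned to the reaction order of the model
ec_coef_vector <- function(ec, rxn_ids) {
  coefs <- setNames(numeric(length(rxn_ids)), rxn_ids)
  if (nrow(ec$enzymes))
    coefs[ec$enzymes$reaction_id] <- ec$enzymes$coef
  coefs
}

# Assemble and solve the LP for a (possibly enzyme-constrained) model.
# extra_rows: list of list(coefs = named numeric, lb, ub) appended below S.
# bounds_override: named list rid -> c(lb, ub).
lp_run <- function(model, objective, maximize = TRUE, extra_rows = list(),
                   bounds_override = list()) {
  ec <- if (is_ec_model(model)) model else NULL
  base <- as_base_model(model)
  rxn_ids <- names(base$reactions)
  met_ids <- names(base$metabolites)
  nr <- length(rxn_ids)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- setNames(seq_along(met_ids), met_ids)
  for (k in seq_len(nr)) {
    st <- base$reactions[[k]]$stoichiometry
    if (length(st)) {
      ii <- c(ii, met_index[names(st)])
      jj <- c(jj, rep(k, length(st)))
      xx <- c(xx, unname(st))
    }
  }
  row_lb <- rep(0, length(met_ids))
  row_ub <- rep(0, length(met_ids))
  nrow_total <- length(met_ids)

  if (!is.null(ec) && nrow(ec$enzymes)) {
    coefs <- ec_coef_vector(ec, rxn_ids)
    nz <- which(coefs != 0)
    nrow_total <- nrow_total + 1L
    ii <- c(ii, rep(nrow_total, length(nz)))
    jj <- c(jj, nz)
    xx <- c(xx, unname(coefs[nz]))
    row_lb <- c(row_lb, -Inf)
    row_ub <- c(row_ub, ec$pool_bound)
  }
  for (er in extra_rows) {
    idx <- match(names(er$coefs), rxn_ids)
    if (anyNA(idx))
      stop("extra constraint references unknown reactions: ",
           paste(names(er$coefs)[is.na(idx)], collapse = ", "))
    nrow_total <- nrow_total + 1L
    ii <- c(ii, rep(nrow_total, length(idx)))
    jj <- c(jj, idx)
    xx <- c(xx, unname(er$coefs))
    row_lb <- c(row_lb, er$lb)
    row_ub <- c(row_ub, er$ub)
  }

  col_lb <- vapply(base$reactions, `[[`, 0, "lower_bound")
  col_ub <- vapply(base$reactions, `[[`, 0, "upper_bound")
  for (rid in names(bounds_override)) {
    k <- match(rid, rxn_ids)
    if (is.na(k)) stop("bounds override on unknown reaction: ", rid)
    col_lb[k] <- bounds_override[[rid]][1]
    col_ub[k] <- bounds_override[[rid]][2]
  }

  obj <- setNames(numeric(nr), rxn_ids)
  bad <- setdiff(names(objective), rxn_ids)
  if (length(bad))
    stop("objective references unknown reactions: ",
         paste(bad, collapse = ", "))
  obj[names(objective)] <- objective

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow_total, nr))
  res <- solve_lp(obj, A, row_lb, row_ub, col_lb, col_ub,
                  maximize = maximize)
  fluxes <- setNames(res$x, rxn_ids)
  usage <- if (!is.null(ec) && res$status == "optimal")
    sum(ec_coef_vector(ec, rxn_ids) * fluxes) else NA_real_
  structure(list(status = res$status,
                 objective_value = res$objective,
                 fluxes = fluxes,
                 enzyme_usage = usage),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: status %s, objective %.6g", x$status,
              x$objective_value))
  if (!is.na(x$enzyme_usage))
    cat(sprintf(", enzyme usage %.6g g/gDCW", x$enzyme_usage))
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Solves \eqn{\max (\text{or} \min) \; c^T v} subject to \eqn{S v = 0},
#' \eqn{lb \le v \le ub}, and — for an \code{ec_model} — the enzyme pool
#' constraint. Solver status is reported faithfully (never silent zeros).
#'
#' @param model a \code{gem_model} or \code{ec_model}.
#' @param objective named numeric vector (reaction -> coefficient); defaults
#'   to the model's stored objective.
#' @param direction "max" or "min".
#' @return a \code{flux_solution}: status, objective_value, fluxes,
#'   enzyme_usage (NA for plain models).
#' @export
fba <- function(model, objective = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  objective <- objective %||% as_base_model(model)$objective
  if (!length(objective)) stop("no objective given and model has none")
  lp_run(model, objective, maximize = direction == "max")
}

#' Parsimonious flux balance analysis (pFBA)
#'
#' Two-stage LP: first optimize the primary objective, then fix it at (a
#' fraction of) its optimum and minimize the total absolute flux
#' \eqn{\sum_i |v_i|}. On a fully split model all fluxes are non-negative and
#' the second stage is a plain linear objective; reactions that can still run
#' negative get auxiliary absolute-value variables.
#'
#' @param model a \code{gem_model} or \code{ec_model}.
#' @param objective named numeric (default: the model's objective).
#' @param fraction fraction of the stage-1 optimum to retain (default 1.0).
#' @param direction direction of the primary objective.
#' @return a \code{flux_solution} whose \code{objective_value} is the
#'   stage-1 optimum recomputed from the parsimonious fluxes; the attribute
#'   \code{"total_flux"} holds the minimized sum of absolute fluxes.
#' @export
pfba <- function(model, objective = NULL, fraction = 1.0,
                 direction = c("max", "min")) {
  direction <- match.arg(direction)
  objective <- objective %||% as_base_model(model)$objective
  s1 <- fba(model, objective, direction)
  if (s1$status != "optimal") return(s1)
  opt <- s1$objective_value

  base <- as_base_model(model)
  rxn_ids <- names(base$reactions)
  col_lb <- vapply(base$reactions, `[[`, 0, "lower_bound")
  free <- which(col_lb < 0)

  # fix the primary objective (>= fraction * optimum for max)
  fixrow <- if (direction == "max")
    list(coefs = objective, lb = fraction * opt, ub = Inf)
  else
    list(coefs = objective, lb = -Inf,
         ub = if (fraction == 1) opt else opt / fraction)

  if (!length(free)) {
    min_obj <- setNames(rep(1, length(rxn_ids)), rxn_ids)
    s2 <- lp_run(model, min_obj, maximize = FALSE,
                 extra_rows = list(fixrow))
  } else {
    # augment with t_i >= |v_i| for reactions that may run negative
    aug <- augment_abs(model, free)
    min_obj <- setNames(rep(1, length(aug$rxn_ids)), aug$rxn_ids)
    min_obj[rxn_ids[free]] <- 0
    s2 <- lp_run(aug$model, min_obj, maximize = FALSE,
                 extra_rows = c(list(fixrow), aug$rows))
    s2$fluxes <- s2$fluxes[rxn_ids]
  }
  if (s2$status != "optimal") return(s2)
  total_flux <- s2$objective_value
  s2$objective_value <- sum(objective * s2$fluxes[names(objective)])
  if (is_ec_model(model))
    s2$enzyme_usage <- sum(ec_coef_vector(model, rxn_ids) *
                             s2$fluxes[rxn_ids])
  attr(s2, "total_flux") <- total_flux
  s2
}

# add unconstrained auxiliary reactions t_i with rows t_i - v_i >= 0 and
# t_i + v_i >= 0 (so t_i >= |v_i|) for the given reaction indices
augment_abs <- function(model, free) {
  base <- as_base_model(model)
  rxn_ids <- names(base$reactions)
  rows <- list()
  for (k in free) {
    tid <- paste0(".abs_", rxn_ids[k])
    base$reactions[[tid]] <- new_reaction(
      tid, stoichiometry = setNames(numeric(0), character(0)),
      lower_bound = 0, upper_bound = Inf)
    rows[[length(rows) + 1L]] <- list(
      coefs = setNames(c(1, -1), c(tid, rxn_ids[k])), lb = 0, ub = Inf)
    rows[[length(rows) + 1L]] <- list(
      coefs = setNames(c(1, 1), c(tid, rxn_ids[k])), lb = 0, ub = Inf)
  }
  model2 <- if (is_ec_model(model)) {
    m <- model; m$model <- base; m
  } else base
  list(model = model2, rxn_ids = names(base$reactions), rows = rows)
}

#' Minimum enzyme amount supporting a fixed flux state
#'
#' Minimizes the total enzyme mass \eqn{\sum_i v_i MW_i / (\sigma_i
#' k_{cat,i})} subject to steady state, bounds, the pool constraint and the
#' supplied flux fixings. This is the quantity \eqn{E_{min}} used in the
#' enzyme-usage-efficiency measure growth/\eqn{E_{min}}.
#'
#' @param model an \code{ec_model}.
#' @param fixed_fluxes named numeric vector of fluxes to fix (lb = ub =
#'   value), or named list rid -> c(lb, ub) for interval fixings.
#' @return list with \code{emin} (g/gDCW) and \code{solution} (the
#'   minimizing \code{flux_solution}).
#' @export
min_enzyme <- function(model, fixed_fluxes = NULL) {
  stopifnot(is_ec_model(model))
  rxn_ids <- names(model$model$reactions)
  coefs <- ec_coef_vector(model, rxn_ids)
  overrides <- list()
  if (!is.null(fixed_fluxes)) {
    if (is.list(fixed_fluxes)) {
      overrides <- fixed_fluxes
    } else {
      overrides <- lapply(fixed_fluxes, function(v) c(v, v))
      names(overrides) <- names(fixed_fluxes)
    }
  }
  sol <- lp_run(model, coefs[coefs != 0], maximize = FALSE,
                bounds_override = overrides)
  if (sol$status != "optimal")
    stop("minimum-enzyme LP is ", sol$status,
         " under the supplied flux fixings")
  emin <- sol$objective_value
  sol$objective_value <- emin
  sol$enzyme_usage <- emin
  list(emin = emin, solution = sol)
}

#' Serialize an enzyme-constrained model to a single JSON bundle
#' @param ec an \code{ec_model}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_ec_model <- function(ec, path) {
  tmp_model <- tempfile(fileext = ".json")
  on.exit(unlink(tmp_model))
  write_model_json(ec$model, tmp_model)
  bundle <- list(
    model = jsonlite::fromJSON(tmp_model, simplifyVector = FALSE),
    enzymes = ec$enzymes,
    ptotal = ec$ptotal, f = ec$f)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an enzyme-constrained model from a JSON bundle
#' @param path path written by \code{\link{write_ec_model}}.
#' @return an \code{ec_model}.
#' @export
read_ec_model <- function(path) {
  bundle <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                               simplifyVector = TRUE)
  tmp_model <- tempfile(fileext = ".json")
  on.exit(unlink(tmp_model))
  jsonlite::write_json(
    jsonlite::fromJSON(path, simplifyVector = FALSE)$model,
    tmp_model, auto_unbox = TRUE, digits = NA, null = "null")
  model <- read_model(tmp_model, format = "json")
  enz <- as.data.frame(bundle$enzymes, stringsAsFactors = FALSE)
  enz$coef <- NULL
  build_ec_model(model, enz, ptotal = bundle$ptotal, f = bundle$f)
}
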