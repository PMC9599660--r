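#' Split reversible reactions into forward and reverse parts
#'
#' Every reaction with \code{lower_bound < 0} is replaced by the original id
#' with bounds \code{[0, ub]} and a new reaction \code{<id>_reverse} with
#' negated stoichiometry and bounds \code{[0, -lb]}. GPR rules and EC numbers
#' are copied to both directions (forward and reverse catalysis may later
#' receive different kcat values). Irreversible reactions are untouched.
#' Objective coefficients on a reversible reaction are carried with opposite
#' sign on the reverse part so that net objective value is preserved.
#' Exchange reactions keep their native (possibly negative) bounds and are
#' never split: uptake conditions are expressed directly on the exchange
#' bound, and exchanges carry no enzyme.
#'
#' @param model a \code{gem_model}.
#' @return list with \code{model} (split) and \code{split_map} (data.frame
#'   \code{split_id}, \code{original_id}, \code{direction},
#'   \code{enzyme_index}) covering every reaction of the split model.
#' @export
split_reversible <- function(model) {
  new_rxns <- list()
  map <- list()
  objective <- model$objective
  for (r in model$reactions) {
    if (r$lower_bound < 0 && !is_exchange(r)) {
      fwd <- r
      fwd$lower_bound <- 0
      fwd$upper_bound <- max(r$upper_bound, 0)
      rev <- r
      rev$id <- paste0(r$id, "_reverse")
      rev$name <- paste0(r$name, " (reverse)")
      rev$stoichiometry <- -r$stoichiometry
      rev$lower_bound <- 0
      rev$upper_bound <- -r$lower_bound
      new_rxns[[fwd$id]] <- fwd
      new_rxns[[rev$id]] <- rev
      map[[length(map) + 1L]] <- data.frame(
        split_id = c(fwd$id, rev$id), original_id = r$id,
        direction = c("fwd", "rev"), enzyme_index = NA_integer_,
        stringsAsFactors = FALSE)
      oc <- objective[r$id]
      if (!is.na(oc)) objective[rev$id] <- -oc
    } else {
      new_rxns[[r$id]] <- r
      map[[length(map) + 1L]] <- data.frame(
        split_id = r$id, original_id = r$id, direction = "fwd",
        enzyme_index = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  model$reactions <- new_rxns
  model$objective <- objective
  validate_model(model)
  split_map <- do.call(rbind, map)
  rownames(split_map) <- NULL
  list(model = model, split_map = split_map)
}

#' Split isozyme-catalyzed reactions into one reaction per enzyme
#'
#' Every non-exchange reaction whose GPR expands to k > 1 candidate enzymes
#' (complexes in the disjunctive normal form) is replaced by k copies named
#' \code{<id>_num1} ... \code{<id>_numk}, each carrying a single complex as
#' its GPR and identical stoichiometry and bounds. Enzyme order follows the
#' deterministic DNF ordering of \code{\link{parse_gpr}}. Exchange reactions
#' are never split. Objective coefficients are copied to every isozyme copy
#' (copies sum to the original flux).
#'
#' @param model a \code{gem_model} (typically after
#'   \code{\link{split_reversible}}).
#' @return list with \code{model} and \code{split_map} as in
#'   \code{\link{split_reversible}}; \code{enzyme_index} holds the isozyme
#'   number for split copies.
#' @export
split_isozymes <- function(model) {
  new_rxns <- list()
  map <- list()
  objective <- model$objective
  for (r in model$reactions) {
    enzymes <- if (nzchar(r$gene_reaction_rule) && !is_exchange(r))
      parse_gpr(r$gene_reaction_rule)$enzymes else list()
    if (length(enzymes) > 1L) {
      oc <- objective[r$id]
      objective <- objective[names(objective) != r$id]
      for (k in seq_along(enzymes)) {
        cp <- r
        cp$id <- sprintf("%s_num%d", r$id, k)
        cp$gene_reaction_rule <- gpr_to_text(
          structure(list(enzymes = enzymes[k]), class = "gpr"))
        new_rxns[[cp$id]] <- cp
        map[[length(map) + 1L]] <- data.frame(
          split_id = cp$id, original_id = r$id, direction = "fwd",
          enzyme_index = k, stringsAsFactors = FALSE)
        if (!is.na(oc)) objective[cp$id] <- oc
      }
    } else {
      new_rxns[[r$id]] <- r
      map[[length(map) + 1L]] <- data.frame(
        split_id = r$id, original_id = r$id, direction = "fwd",
        enzyme_index = if (length(enzymes)) 1L else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  model$reactions <- new_rxns
  model$objective <- objective
  validate_model(model)
  split_map <- do.call(rbind, map)
  rownames(split_map) <- NULL
  list(model = model, split_map = split_map)
}

#' Expand a model: split reversible reactions, then isozymes
#'
#' Composes \code{\link{split_reversible}} and \code{\link{split_isozymes}}
#' (in that order, so a reversible isozyme reaction yields ids like
#' \code{R_num1} and \code{R_reverse_num1}) and returns the combined split
#' map back to the original reaction ids.
#'
#' @param model a \code{gem_model}.
#' @return list with \code{model} and \code{split_map}.
#' @export
expand_model <- function(model) {
  s1 <- split_reversible(model)
  s2 <- split_isozymes(s1$model)
  # compose: s2 split ids -> s1 split ids -> original ids
  m1 <- s1$split_map
  m2 <- s2$split_map
  idx <- match(m2$original_id, m1$split_id)
  combined <- data.frame(
    split_id = m2$split_id,
    original_id = m1$original_id[idx],
    direction = m1$direction[idx],
    enzyme_index = m2$enzyme_index,
    stringsAsFactors = FALSE)
  list(model = s2$model, split_map = combined)
}

#' Aggregate split-model fluxes back onto original reactions
#'
#' The net flux of an original reaction is the sum of its forward split
#' members minus the sum of its reverse members.
#'
#' @param fluxes named numeric vector of fluxes over the split model.
#' @param split_map combined split map (see \code{\link{expand_model}}).
#' @return named numeric vector of net fluxes per original reaction.
#' @export
aggregate_flux <- function(fluxes, split_map) {
  unknown <- setdiff(names(fluxes), split_map$split_id)
  if (length(unknown))
    stop("fluxes contain unknown split reactions: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(split_map$split_id, names(fluxes))
  if (length(missing))
    stop("solution does not cover split reactions: ",
         paste(missing, collapse = ", "))
  sgn <- ifelse(split_map$direction == "rev", -1, 1)
  contrib <- fluxes[split_map$split_id] * sgn
  out <- tapply(contrib, split_map$original_id, sum)
  setNames(as.numeric(out), names(out))[unique(split_map$original_id)]
}

#' Write a split map to TSV
#' @param split_map split map data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_split_map <- function(split_map, path) {
  utils::write.table(split_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
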