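# Shared helpers for the test suite. Everything here builds on exported
# generators; expected values come from the analytic ground truth carried in
# the fixture's `truth` record or from independent oracles defined below.

TOL <- 1e-6

# Build the complete enzyme-constrained toy system from a spec.
# The spec's `pool` is the final pool bound, so it is passed as ptotal with
# f = 1 (the product is all the LP ever sees).
build_toy <- function(spec = toy_gem_spec(), calibration_fixture = FALSE) {
  toy <- make_toy_gem(spec)
  ex <- expand_model(toy$model)
  proteins <- make_protein_records(spec)
  kinetics <- make_kinetics_table(toy$truth, calibration_fixture)
  comps <- setNames(lapply(proteins$interaction_text, parse_subunit_count),
                    proteins$gene_id)
  mws <- setNames(proteins$monomer_mw_kda, proteins$gene_id)
  tab <- build_enzyme_table(ex$model, comps, mws, kinetics)
  ec <- build_ec_model(ex$model, tab$enzymes, ptotal = spec$pool, f = 1)
  list(spec = spec, model = toy$model, truth = toy$truth, split = ex,
       proteins = proteins, kinetics = kinetics, compositions = comps,
       monomer_mws = mws, table = tab, ec = ec,
       oracle = overflow_switch_oracle(toy$truth$yield_resp,
                                       toy$truth$yield_ferm,
                                       toy$truth$cost_resp,
                                       toy$truth$cost_ferm,
                                       toy$truth$pool))
}

# Net flux range of each original reaction at fixed growth: minimize and
# maximize sum(+/- v over split members) with a growth-equality row. This is
# an independent route to FVA intervals used for containment checks.
net_flux_ranges <- function(model, split_map, objective, growth,
                            bounds_override = list()) {
  grow <- list(coefs = objective, lb = growth, ub = growth)
  ids <- unique(split_map$original_id)
  out <- data.frame(reaction_id = ids, vmin = NA_real_, vmax = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    mem <- split_map[split_map$original_id == ids[k], ]
    obj <- setNames(ifelse(mem$direction == "rev", -1, 1), mem$split_id)
    lo <- ecgem:::lp_run(model, obj, maximize = FALSE,
                         extra_rows = list(grow),
                         bounds_override = bounds_override)
    hi <- ecgem:::lp_run(model, obj, maximize = TRUE,
                         extra_rows = list(grow),
                         bounds_override = bounds_override)
    stopifnot(lo$status == "optimal", hi$status == "optimal")
    out$vmin[k] <- lo$objective_value
    out$vmax[k] <- hi$objective_value
  }
  out
}

# Independent DNF oracle: evaluates a nested list tree (leaf = gene string,
# node = list(op = "and"/"or", children)) to a sorted, deduplicated set of
# complex signatures "gene:count;...". Structured differently from the
# recursive-descent parser on purpose.
dnf_oracle <- function(node) {
  if (is.character(node)) return(list(setNames(1L, node)))
  parts <- lapply(node$children, dnf_oracle)
  if (node$op == "or") {
    terms <- do.call(c, parts)
  } else {
    terms <- Reduce(function(acc, nxt) {
      do.call(c, lapply(acc, function(a) lapply(nxt, function(b) {
        genes <- union(names(a), names(b))
        v <- setNames(integer(length(genes)), genes)
        v[names(a)] <- v[names(a)] + a
        v[names(b)] <- v[names(b)] + b
        v
      })))
    }, parts)
  }
  terms
}

dnf_signatures <- function(terms) {
  sig <- vapply(terms, function(e) {
    e <- e[order(names(e))]
    paste(names(e), e, sep = ":", collapse = ";")
  }, "")
  sort(unique(sig))
}

# Seeded random GPR tree over a small gene pool, with its rule text.
random_gpr_tree <- function(depth, genes) {
  if (depth == 0L || runif(1) < 0.4)
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  n <- sample(2:3, 1)
  list(op = op, children = lapply(seq_len(n), function(i)
    random_gpr_tree(depth - 1L, genes)))
}

gpr_tree_text <- function(node) {
  if (is.character(node)) return(node)
  inner <- vapply(node$children, gpr_tree_text, "")
  paste0("(", paste(inner, collapse = paste0(" ", node$op, " ")), ")")
}

parsed_signatures <- function(gpr) {
  vapply(gpr$enzymes, function(e)
    paste(names(e), e, sep = ":", collapse = ";"), "")
}
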