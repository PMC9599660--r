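#' Molecular weight of an enzyme complex
#'
#' \eqn{MW = \sum_j N_j \, MW_j} over the m distinct subunits of the complex,
#' where \eqn{N_j} is the copy number of subunit j and \eqn{MW_j} its monomer
#' molecular weight in kDa.
#'
#' @param monomer_mws named numeric vector, gene -> monomer MW (kDa).
#' @param counts named integer vector, gene -> subunit copy number
#'   (\eqn{N_j \ge 1}).
#' @return total complex MW in kDa.
#' @examples
#' complex_mw(c(a = 30.26, b = 41.76), c(a = 2, b = 2))  # 144.04
#' @export
complex_mw <- function(monomer_mws, counts) {
  missing <- setdiff(names(counts), names(monomer_mws))
  if (length(missing))
    stop("no monomer MW for gene(s): ", paste(missing, collapse = ", "))
  if (any(counts != round(counts)) || any(counts < 1))
    stop("subunit counts must be positive integers")
  sum(counts * monomer_mws[names(counts)])
}

#' Read a kinetics table from TSV
#'
#' Expected columns: \code{ec}, \code{substrate}, \code{organism},
#' \code{kcat_per_s}, \code{source} (a local extract with the information
#' content of BRENDA / SABIO-RK turnover-number queries).
#'
#' @param path TSV path.
#' @return data.frame of kinetic entries.
#' @export
read_kinetics_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("ec", "substrate", "organism", "kcat_per_s", "source")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("kinetics TSV is missing columns: ", paste(missing, collapse = ", "))
  df$kcat_per_s <- as.numeric(df$kcat_per_s)
  validate_kinetics(df)
  df
}

validate_kinetics <- function(table) {
  if (any(!is.finite(table$kcat_per_s)) || any(table$kcat_per_s <= 0))
    stop("kcat_per_s must be positive for every kinetic entry")
  ok <- grepl("^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9n-]+$", table$ec)
  if (any(!ok))
    stop("malformed EC numbers: ", paste(unique(table$ec[!ok]), collapse = ", "))
  invisible(table)
}

#' Write a kinetics table to TSV
#' @param table kinetics data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_kinetics_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

ec_fields <- function(ec) strsplit(ec, ".", fixed = TRUE)

#' Match a turnover number for a set of EC numbers
#'
#' Searches a local kinetics table in three priority levels: (1) exact EC
#' number and matching organism, (2) exact EC number in any organism, (3) EC
#' class match with the last field wildcarded. The first non-empty level
#' wins; within it the policy aggregate (default: maximum) is returned.
#' Query EC numbers may themselves carry a trailing wildcard field
#' (\code{"1.1.1.-"}), which matches any entry sharing the leading fields.
#'
#' @param ec_list character vector of EC numbers for the reaction.
#' @param table kinetics data.frame (see \code{\link{read_kinetics_tsv}}).
#' @param policy list with \code{aggregate} ("max" or "median") and
#'   \code{organism} (string or NULL).
#' @return NULL when nothing matches at any level; otherwise list with
#'   \code{kcat_per_s}, \code{level} (1-3), \code{ec}, and \code{sources}
#'   (the source strings of the rows aggregated over).
#' @export
match_kcat <- function(ec_list, table,
                       policy = list(aggregate = "max", organism = NULL)) {
  if (!length(ec_list) || is.null(table) || nrow(table) == 0L) return(NULL)
  agg <- match.arg(policy$aggregate %||% "max", c("max", "median"))
  exact_rows <- function(q) {
    qf <- ec_fields(q)[[1]]
    if (qf[length(qf)] == "-") {
      # wildcarded query: match on the leading fields
      lead <- paste(qf[seq_len(length(qf) - 1L)], collapse = ".")
      which(startsWith(table$ec, paste0(lead, ".")))
    } else which(table$ec == q)
  }
  class_rows <- function(q) {
    qf <- ec_fields(q)[[1]]
    lead <- paste(qf[1:3], collapse = ".")
    which(startsWith(table$ec, paste0(lead, ".")))
  }
  levels <- list(
    function(q) {
      rows <- exact_rows(q)
      if (is.null(policy$organism)) integer(0)
      else rows[table$organism[rows] == policy$organism]
    },
    exact_rows,
    class_rows)
  for (lvl in 1:3) {
    rows <- unique(unlist(lapply(ec_list, levels[[lvl]])))
    if (length(rows)) {
      k <- switch(agg,
                  max = max(table$kcat_per_s[rows]),
                  median = stats::median(table$kcat_per_s[rows]))
      used <- if (agg == "max")
        rows[which.max(table$kcat_per_s[rows])] else rows
      return(list(kcat_per_s = k, level = lvl,
                  ec = unique(table$ec[rows]),
                  sources = unique(table$source[used])))
    }
  }
  NULL
}

#' Convert a turnover number from per-second to per-hour
#' @param kcat_per_s turnover number in 1/s (> 0).
#' @return turnover number in 1/h.
#' @export
kcat_to_per_hour <- function(kcat_per_s) {
  if (any(!is.finite(kcat_per_s)) || any(kcat_per_s <= 0))
    stop("kcat must be positive")
  kcat_per_s * 3600
}

#' Read a gene-abundance table from TSV
#' @param path TSV with columns \code{gene_id}, \code{abundance}.
#' @return data.frame.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene_id", "abundance"), names(df))
  if (length(missing))
    stop("abundance TSV is missing columns: ", paste(missing, collapse = ", "))
  df$abundance <- as.numeric(df$abundance)
  if (any(df$abundance < 0)) stop("abundances must be non-negative")
  df
}

#' Enzyme mass fraction f of the model's genes
#'
#' \deqn{f = \sum_{i \in \text{model}} A_i MW_i \; / \; \sum_{j \in
#'   \text{measured}} A_j MW_j}
#' where \eqn{A_i} is the measured abundance (any proportional proxy, e.g.
#' transcript abundance) and \eqn{MW_i} the monomer molecular weight. The
#' numerator runs over measured genes that are in the model, the denominator
#' over all measured genes; f is scale-invariant in the abundances.
#'
#' @param abundances data.frame with \code{gene_id} and \code{abundance}.
#' @param monomer_mws named numeric vector, gene -> kDa; must cover every
#'   measured gene.
#' @param model_genes character vector of genes in the model.
#' @return f in [0, 1].
#' @export
compute_f <- function(abundances, monomer_mws, model_genes) {
  missing <- setdiff(abundances$gene_id, names(monomer_mws))
  if (length(missing))
    stop("no monomer MW for measured gene(s): ",
         paste(missing, collapse = ", "))
  w <- abundances$abundance * monomer_mws[abundances$gene_id]
  denom <- sum(w)
  if (denom == 0) stop("denominator is zero: all abundance-weighted masses vanish")
  sum(w[abundances$gene_id %in% model_genes]) / denom
}

#' Subunit copy numbers for a complex
#'
#' Resolves per-gene copy numbers \eqn{N_j} for the genes of one enzyme
#' complex from parsed subunit compositions:
#' \itemize{
#'   \item single-gene enzyme: \eqn{N} = that gene's parsed total (e.g. 2 for
#'     a homodimer);
#'   \item multi-gene complex with labeled counts whose number of labels
#'     equals the number of genes: labels are assigned to genes in
#'     lexicographic order (alpha -> first gene, beta -> second, ...), and
#'     the record is flagged \code{label_order_assumed};
#'   \item otherwise each gene gets \eqn{N_j = 1} and the record is flagged
#'     \code{stoichiometry_unknown} — surfacing, not guessing.
#' }
#'
#' @param genes character vector of the complex's distinct genes.
#' @param compositions named list, gene ->
#'   \code{\link{parse_subunit_count}} result.
#' @return list with \code{counts} (named integer, per gene) and
#'   \code{flags} (character vector).
#' @export
complex_subunit_counts <- function(genes, compositions) {
  genes <- sort(unique(genes))
  flags <- character(0)
  if (length(genes) == 1L) {
    comp <- compositions[[genes]]
    if (is.null(comp)) {
      flags <- "composition_missing"
      counts <- setNames(1L, genes)
    } else {
      counts <- setNames(comp$total, genes)
      if (comp$defaulted) flags <- "defaulted"
    }
    return(list(counts = counts, flags = flags))
  }
  comps <- compositions[genes]
  labeled <- !vapply(comps, is.null, logical(1)) &
    vapply(comps, function(cpp)
      !is.null(cpp) && isTRUE(cpp$labels_known) && !cpp$defaulted &&
        length(cpp$counts) == length(genes), logical(1))
  if (all(labeled)) {
    # every member's record describes the whole complex the same way; use the
    # first and assign sorted labels to sorted genes
    comp <- comps[[1]]
    lab <- comp$counts[order(names(comp$counts))]
    counts <- setNames(as.integer(lab), genes)
    flags <- "label_order_assumed"
  } else {
    counts <- setNames(rep(1L, length(genes)), genes)
    flags <- "stoichiometry_unknown"
  }
  list(counts = counts, flags = flags)
}

#' Build the enzyme parameter table for a fully split model
#'
#' For every catalyzed, non-exchange reaction of a split model (one enzyme
#' complex per reaction), computes the complex molecular weight from subunit
#' compositions and monomer MWs, matches a turnover number from the kinetics
#' table via the reaction's EC numbers, and assembles one enzyme entry with
#' the saturation coefficient sigma. Reactions without an EC number or
#' without any kcat match are returned in the \code{unconstrained} report
#' rather than silently dropped.
#'
#' @param model_split a fully split \code{gem_model} (see
#'   \code{\link{expand_model}}).
#' @param compositions named list, gene -> \code{\link{parse_subunit_count}}
#'   result.
#' @param monomer_mws named numeric vector, gene -> kDa.
#' @param kinetics kinetics data.frame.
#' @param sigma_default default saturation coefficient (0.5).
#' @param policy kcat match policy, see \code{\link{match_kcat}}.
#' @return list with \code{enzymes} (data.frame: reaction_id, genes, nj,
#'   mw_kda, kcat_per_h, sigma, kcat_source, flags) and \code{unconstrained}
#'   (data.frame: reaction_id, reason).
#' @export
build_enzyme_table <- function(model_split, compositions, monomer_mws,
                               kinetics, sigma_default = 0.5,
                               policy = list(aggregate = "max",
                                             organism = NULL)) {
  entries <- list()
  uncon <- list()
  for (r in model_split$reactions) {
    if (is_exchange(r) || !nzchar(r$gene_reaction_rule)) next
    gpr <- parse_gpr(r$gene_reaction_rule)
    if (length(gpr$enzymes) != 1L)
      stop("model is not fully split: reaction ", r$id,
           " still has multiple candidate enzymes")
    if (!length(r$ec_numbers)) {
      uncon[[length(uncon) + 1L]] <- data.frame(
        reaction_id = r$id, reason = "no EC number",
        stringsAsFactors = FALSE)
      next
    }
    hit <- match_kcat(r$ec_numbers, kinetics, policy)
    if (is.null(hit)) {
      uncon[[length(uncon) + 1L]] <- data.frame(
        reaction_id = r$id, reason = "no kcat match",
        stringsAsFactors = FALSE)
      next
    }
    genes <- names(gpr$enzymes[[1]])
    sc <- complex_subunit_counts(genes, compositions)
    mw <- complex_mw(monomer_mws, sc$counts)
    entries[[length(entries) + 1L]] <- data.frame(
      reaction_id = r$id,
      genes = paste(names(sc$counts), collapse = ";"),
      nj = paste(sc$counts, collapse = ";"),
      mw_kda = mw,
      kcat_per_h = kcat_to_per_hour(hit$kcat_per_s),
      sigma = sigma_default,
      kcat_source = sprintf("level%d:%s", hit$level,
                            paste(hit$sources, collapse = ",")),
      flags = paste(sc$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  enzymes <- if (length(entries)) do.call(rbind, entries) else
    data.frame(reaction_id = character(0), genes = character(0),
               nj = character(0), mw_kda = numeric(0),
               kcat_per_h = numeric(0), sigma = numeric(0),
               kcat_source = character(0), flags = character(0),
               stringsAsFactors = FALSE)
  unconstrained <- if (length(uncon)) do.call(rbind, uncon) else
    data.frame(reaction_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(enzymes) <- rownames(unconstrained) <- NULL
  list(enzymes = enzymes, unconstrained = unconstrained)
}

#' Write an enzyme table to TSV
#' @param enzymes enzyme data.frame from \code{\link{build_enzyme_table}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_enzyme_tsv <- function(enzymes, path) {
  out <- enzymes
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enzyme table from TSV
#' @param path TSV path.
#' @return enzyme data.frame.
#' @export
read_enzyme_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(reaction_id = "character",
                                         genes = "character",
                                         nj = "character"))
  df$mw_kda <- as.numeric(df$mw_kda)
  df$kcat_per_h <- as.numeric(df$kcat_per_h)
  df$sigma <- as.numeric(df$sigma)
  df
}
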