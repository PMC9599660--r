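#' Read protein records from a TSV file
#'
#' Expected columns: \code{accession}, \code{gene_id}, \code{protein_name},
#' \code{monomer_mw_kda}, \code{interaction_text}, \code{sequence}.
#'
#' @param path TSV path.
#' @return data.frame of protein records (one row per protein).
#' @export
read_protein_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("accession", "gene_id", "protein_name", "monomer_mw_kda",
              "interaction_text", "sequence")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("protein TSV is missing columns: ", paste(missing, collapse = ", "))
  df$monomer_mw_kda <- as.numeric(df$monomer_mw_kda)
  if (any(!is.finite(df$monomer_mw_kda)) || any(df$monomer_mw_kda <= 0))
    stop("monomer_mw_kda must be positive for every record")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(df$sequence))
  if (any(bad & nzchar(df$sequence)))
    stop("sequences contain non-amino-acid letters: ",
         paste(df$gene_id[bad], collapse = ", "))
  df$sequence <- toupper(df$sequence)
  df
}

#' Write protein records to TSV
#' @param proteins data.frame as returned by \code{\link{read_protein_tsv}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_protein_tsv <- function(proteins, path) {
  utils::write.table(proteins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read protein records from a SwissProt-like flat text file
#'
#' A minimal reader for records of the form used by SwissProt text dumps:
#' \code{ID} (entry name), \code{AC} (accession), \code{GN   Name=...}
#' (gene), \code{DE   RecName: Full=...} (protein name),
#' \code{CC   -!- SUBUNIT: ...} (interaction text), \code{SQ} followed by
#' sequence lines, records separated by \code{//}. Molecular weight is taken
#' from the \code{SQ} header (\code{... MW;}) in Daltons and converted to
#' kDa.
#'
#' @param path file path.
#' @return data.frame with the same columns as
#'   \code{\link{read_protein_tsv}}.
#' @export
read_swissprot_text <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(TRUE, head(lines, -1) == "//")))
  out <- lapply(recs, function(rl) {
    rl <- rl[rl != "//"]
    if (!length(rl)) return(NULL)
    field <- function(code) sub(sprintf("^%s\\s+", code), "",
                                rl[startsWith(rl, paste0(code, " "))])
    ac <- sub(";.*", "", field("AC")[1] %||% NA_character_)
    gn <- field("GN")
    gene <- if (length(gn)) sub(";.*", "", sub(".*Name=", "", gn[1])) else ""
    de <- field("DE")
    pname <- if (length(de)) sub(";\\s*$", "", sub(".*Full=", "", de[1])) else ""
    cc <- field("CC")
    sub_idx <- grep("-!- SUBUNIT:", cc)
    interaction <- if (length(sub_idx)) {
      # continuation CC lines until the next -!- topic belong to SUBUNIT
      stopat <- grep("-!-", cc)
      nxt <- stopat[stopat > sub_idx[1]]
      last <- if (length(nxt)) nxt[1] - 1L else length(cc)
      txt <- paste(cc[sub_idx[1]:last], collapse = " ")
      trimws(sub(".*-!- SUBUNIT:\\s*", "", txt))
    } else ""
    sq_at <- grep("^SQ ", rl)
    seq <- ""
    mw_kda <- NA_real_
    if (length(sq_at)) {
      mw <- regmatches(rl[sq_at], regexec("([0-9.]+)\\s+MW", rl[sq_at]))[[1]]
      if (length(mw) == 2L) mw_kda <- as.numeric(mw[2]) / 1000
      body <- rl[seq(sq_at + 1L, length(rl))]
      seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    data.frame(accession = ac, gene_id = gene, protein_name = pname,
               monomer_mw_kda = mw_kda, interaction_text = interaction,
               sequence = seq, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(df) <- NULL
  df
}

#' Screen 'and' GPR relationships by protein sequence similarity
#'
#' Gene pairs joined by \code{and} in a GPR rule should be subunits of one
#' complex; when the two proteins are highly similar in sequence they are
#' more likely to be isozymes mistakenly encoded as a complex. For every gene
#' pair inside an \code{and} complex, the global percent identity is computed
#' and pairs above the threshold are flagged for conversion to \code{or}
#' (advisory — see \code{\link{apply_gpr_corrections}} to execute edits).
#'
#' @param model a \code{gem_model}.
#' @param proteins protein record data.frame (needs \code{gene_id} and
#'   \code{sequence}).
#' @param threshold percent identity above which (strictly greater than) a
#'   pair is suspect; default 20.
#' @return data.frame with columns \code{reaction_id}, \code{gene_a},
#'   \code{gene_b}, \code{identity} and \code{verdict} ("suspect: convert
#'   and->or (manual check advised)", "keep", or "unscreened" when a sequence
#'   is missing), sorted by identity descending.
#' @export
screen_and_relationships <- function(model, proteins, threshold = 20) {
  seqs <- setNames(proteins$sequence, proteins$gene_id)
  rows <- list()
  for (r in model$reactions) {
    if (!nzchar(r$gene_reaction_rule)) next
    gpr <- parse_gpr(r$gene_reaction_rule)
    for (cx in gpr$enzymes) {
      genes <- sort(names(cx))
      if (length(genes) < 2L) next
      pairs <- utils::combn(genes, 2L)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        sa <- seqs[a]; sb <- seqs[b]
        if (is.na(sa) || is.na(sb) || !nzchar(sa) || !nzchar(sb)) {
          rows[[length(rows) + 1L]] <- data.frame(
            reaction_id = r$id, gene_a = a, gene_b = b, identity = NA_real_,
            verdict = "unscreened", stringsAsFactors = FALSE)
        } else {
          idy <- pairwise_identity(sa, sb)
          rows[[length(rows) + 1L]] <- data.frame(
            reaction_id = r$id, gene_a = a, gene_b = b, identity = idy,
            verdict = if (idy > threshold)
              "suspect: convert and->or (manual check advised)" else "keep",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(reaction_id = character(0), gene_a = character(0),
                      gene_b = character(0), identity = numeric(0),
                      verdict = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("reaction_id", "gene_a", "gene_b")]), ]
  df <- df[order(-xtfrm(df$identity), df$reaction_id, df$gene_a, na.last = TRUE), ]
  rownames(df) <- NULL
  df
}

#' Apply explicit GPR edits to a model
#'
#' Executes reviewed corrections (e.g. converting a suspect \code{and}
#' relationship to \code{or}). All edits are validated before any is applied;
#' on error the model is unchanged. Genes newly introduced by an edit are
#' appended to the model's gene list.
#'
#' @param model a \code{gem_model}.
#' @param edits data.frame with columns \code{reaction_id} and
#'   \code{new_gpr}.
#' @return list with \code{model} (edited) and \code{log} (data.frame of
#'   reaction_id, old_gpr, new_gpr).
#' @export
apply_gpr_corrections <- function(model, edits) {
  if (is.null(edits) || nrow(edits) == 0L)
    return(list(model = model,
                log = data.frame(reaction_id = character(0),
                                 old_gpr = character(0),
                                 new_gpr = character(0),
                                 stringsAsFactors = FALSE)))
  unknown <- setdiff(edits$reaction_id, names(model$reactions))
  if (length(unknown))
    stop("edits reference unknown reactions: ", paste(unknown, collapse = ", "))
  parsed <- lapply(edits$new_gpr, parse_gpr)  # errors abort before any edit
  log <- data.frame(reaction_id = edits$reaction_id,
                    old_gpr = vapply(edits$reaction_id, function(rid)
                      model$reactions[[rid]]$gene_reaction_rule, ""),
                    new_gpr = edits$new_gpr, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(edits))) {
    rid <- edits$reaction_id[k]
    model$reactions[[rid]]$gene_reaction_rule <- edits$new_gpr[k]
    new_genes <- setdiff(gpr_genes(parsed[[k]]), model$genes)
    if (length(new_genes)) model$genes <- c(model$genes, new_genes)
  }
  validate_model(model)
  list(model = model, log = log)
}
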