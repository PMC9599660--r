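#' Parse a gene-protein-reaction (GPR) rule into disjunctive normal form
#'
#' A GPR rule is a boolean expression over gene ids with \code{and} (protein
#' complex), \code{or} (isozymes) and parentheses. The parsed form is a set of
#' candidate enzymes, each a multiset of genes: \code{"a or b"} yields two
#' single-gene enzymes, \code{"a and (b or c)"} expands to the complexes
#' \{a,b\} and \{a,c\}. Operators are case-insensitive. Complexes are
#' deduplicated and ordered deterministically (genes sorted within a complex,
#' complexes sorted by their signature), which fixes the enzyme order used
#' when splitting isozyme reactions.
#'
#' @param text GPR rule text; empty string gives an empty expression.
#' @return object of class \code{gpr}: list with \code{enzymes}, a list of
#'   named integer vectors (gene -> copy count, 1 unless stated otherwise).
#' @examples
#' parse_gpr("Cgl2565 and Cgl2566")
#' parse_gpr("a and (b or c)")
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text)))
    return(structure(list(enzymes = list()), class = "gpr"))
  toks <- gpr_tokenize(text)
  st <- list(toks = toks, pos = 1L)
  res <- gpr_parse_or(st)
  st <- res$state
  if (st$pos <= nrow(st$toks))
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 st$toks$start[st$pos], st$toks$value[st$pos]))
  enzymes <- canonical_enzymes(res$enzymes)
  structure(list(enzymes = enzymes), class = "gpr")
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:'-]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("GPR parse error: no tokens in '", text, "'")
  vals <- regmatches(text, gregexpr(pat, text))[[1]]
  starts <- as.integer(m)
  # anything between tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (k in seq_along(vals))
    covered[starts[k]:(starts[k] + nchar(vals[k]) - 1L)] <- TRUE
  rest <- strsplit(text, "")[[1]][!covered]
  if (any(!grepl("^\\s$", rest)))
    stop("GPR parse error: unexpected character '",
         rest[!grepl("^\\s$", rest)][1], "'")
  type <- ifelse(vals == "(", "lparen",
          ifelse(vals == ")", "rparen",
          ifelse(tolower(vals) == "and", "and",
          ifelse(tolower(vals) == "or", "or", "gene"))))
  data.frame(value = vals, type = type, start = starts,
             stringsAsFactors = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

# grammar: or_expr := and_expr ('or' and_expr)*
#          and_expr := atom ('and' atom)*
#          atom := gene | '(' or_expr ')'
gpr_parse_or <- function(st) {
  res <- gpr_parse_and(st)
  st <- res$state
  enzymes <- res$enzymes
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    res <- gpr_parse_and(st)
    st <- res$state
    enzymes <- c(enzymes, res$enzymes)
  }
  list(enzymes = enzymes, state = st)
}

gpr_parse_and <- function(st) {
  res <- gpr_parse_atom(st)
  st <- res$state
  enzymes <- res$enzymes
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    res <- gpr_parse_atom(st)
    st <- res$state
    # distribute: every complex on the left joins every complex on the right
    enzymes <- unlist(lapply(enzymes, function(a)
      lapply(res$enzymes, function(b) merge_multiset(a, b))), recursive = FALSE)
  }
  list(enzymes = enzymes, state = st)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.null(tk))
    stop("GPR parse error at end of input: expected gene or '('")
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(list(enzymes = list(setNames(1L, tk$value)), state = st))
  }
  if (tk$type == "lparen") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_or(st)
    st <- res$state
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != "rparen")
      stop(sprintf("GPR parse error at position %d: unbalanced parenthesis",
                   tk$start))
    st$pos <- st$pos + 1L
    return(list(enzymes = res$enzymes, state = st))
  }
  stop(sprintf("GPR parse error at position %d: dangling operator '%s'",
               tk$start, tk$value))
}

merge_multiset <- function(a, b) {
  genes <- union(names(a), names(b))
  out <- setNames(integer(length(genes)), genes)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

canonical_enzymes <- function(enzymes) {
  enzymes <- lapply(enzymes, function(e) e[order(names(e))])
  sig <- vapply(enzymes, function(e)
    paste(names(e), e, sep = ":", collapse = ";"), "")
  enzymes <- enzymes[!duplicated(sig)]
  enzymes[order(sig[!duplicated(sig)])]
}

#' @export
print.gpr <- function(x, ...) {
  cat(gpr_to_text(x), "\n")
  invisible(x)
}

#' Render a parsed GPR back to rule text
#'
#' @param gpr a \code{gpr} object.
#' @return GPR rule text in DNF (\code{"(a and b) or c"}).
#' @export
gpr_to_text <- function(gpr) {
  if (!length(gpr$enzymes)) return("")
  parts <- vapply(gpr$enzymes, function(e) {
    genes <- rep(names(e), times = e)
    if (length(genes) == 1L) genes else
      paste0("(", paste(unique(genes), collapse = " and "), ")")
  }, "")
  paste(parts, collapse = " or ")
}

#' Genes referenced by a parsed GPR
#' @param gpr a \code{gpr} object.
#' @return character vector of distinct gene ids.
#' @export
gpr_genes <- function(gpr) {
  unique(unlist(lapply(gpr$enzymes, names))) %||% character(0)
}

#' Default lexicon of protein-complex description terms
#'
#' Terms whose presence in a protein name or description suggests the protein
#' is one part of a multi-subunit complex (and hence that an \code{and} GPR
#' relationship may be warranted). User-extensible.
#'
#' @return character vector of terms.
#' @export
complex_term_lexicon <- function() {
  c("subunit", "chain", "component", "binding protein", "assembly factor",
    "large subunit", "small subunit", "alpha chain", "beta chain",
    "regulatory protein", "accessory protein")
}

#' Detect complex-indicating terms in a protein name or description
#'
#' Case-insensitive, word-boundary-aware scan for terms such as "subunit",
#' "chain", "component", "binding protein" or "assembly factor" that indicate
#' a protein participates in a multi-subunit complex.
#'
#' @param text protein name or description.
#' @param lexicon character vector of terms (default
#'   \code{\link{complex_term_lexicon}()}).
#' @return list with \code{is_complex} (logical) and \code{terms} (matched
#'   lexicon entries).
#' @examples
#' detect_complex_terms("Anthranilate synthase component 1")
#' @export
detect_complex_terms <- function(text, lexicon = complex_term_lexicon()) {
  stopifnot(length(lexicon) > 0)
  hit <- vapply(lexicon, function(term) {
    grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term), "\\b"),
          text, ignore.case = TRUE)
  }, logical(1))
  list(is_complex = any(hit), terms = lexicon[hit])
}

#' Default multiplicity word table for subunit-composition parsing
#'
#' Maps Greek numeral stems and spelled-out English numerals to integers,
#' used to translate description strings like "Homodimer" or "Tetramer of two
#' alpha and two beta chains" into subunit counts.
#'
#' @return named integer vector.
#' @export
multiplicity_word_table <- function() {
  c(mono = 1L, di = 2L, tri = 3L, tetra = 4L, penta = 5L, hexa = 6L,
    hepta = 7L, octa = 8L, nona = 9L, deca = 10L, undeca = 11L, dodeca = 12L,
    one = 1L, two = 2L, three = 3L, four = 4L, five = 5L, six = 6L,
    seven = 7L, eight = 8L, nine = 9L, ten = 10L, eleven = 11L, twelve = 12L)
}

#' Parse quantitative subunit composition from interaction text
#'
#' Translates UniProt-style "Interaction" descriptions into subunit counts:
#' \itemize{
#'   \item \code{"Homodimer"} (homo-<stem>-mer) gives total k with a single
#'     subunit label;
#'   \item \code{"Heterotrimer"} gives total k with unspecified labels;
#'   \item \code{"Tetramer of two alpha and two beta chains"} gives labeled
#'     counts \{alpha: 2, beta: 2\}, total 4;
#'   \item anything unparseable defaults to a monomer (total 1) with the
#'     \code{defaulted} flag set — the flag is part of the contract so that
#'     guessed stoichiometry is always distinguishable from parsed
#'     stoichiometry.
#' }
#'
#' @param interaction_text description string (may be empty).
#' @param word_table multiplicity word table; see
#'   \code{\link{multiplicity_word_table}}.
#' @return object of class \code{subunit_composition}: list with
#'   \code{counts} (named integer), \code{total}, \code{defaulted},
#'   \code{labels_known}.
#' @examples
#' parse_subunit_count("Homodimer")$total  # 2
#' parse_subunit_count("Tetramer of two alpha and two beta chains")$counts
#' @export
parse_subunit_count <- function(interaction_text,
                                word_table = multiplicity_word_table()) {
  text <- tolower(trimws(interaction_text %||% ""))
  comp <- function(counts, total, defaulted = FALSE, labels_known = TRUE)
    structure(list(counts = counts, total = as.integer(total),
                   defaulted = defaulted, labels_known = labels_known),
              class = "subunit_composition")
  stems <- names(word_table)
  stem_pat <- paste(stems, collapse = "|")

  # "Xmer of <n1> <label1> and <n2> <label2> chains/subunits" (optionally
  # prefixed hetero-); the explicit member list wins over the stem count
  m <- regmatches(text, regexec(
    sprintf("(?:hetero|homo)?(%s)mer(?:ic)? (?:of|formed by|composed of) (.+)",
            stem_pat), text))[[1]]
  if (length(m) == 3L) {
    members <- strsplit(m[3], ",| and ")[[1]]
    members <- trimws(gsub("\\b(chains?|subunits?)\\b\\.?", "", members))
    members <- members[nzchar(members)]
    counts <- integer(0)
    ok <- TRUE
    for (mem in members) {
      mm <- regmatches(mem, regexec(sprintf("^(%s|[0-9]+)\\s+([a-z0-9'-]+)$",
                                            stem_pat), mem))[[1]]
      if (length(mm) != 3L) { ok <- FALSE; break }
      n <- if (grepl("^[0-9]+$", mm[2])) as.integer(mm[2]) else
        word_table[[mm[2]]]
      counts[mm[3]] <- n
    }
    if (ok && length(counts))
      return(comp(counts, sum(counts)))
  }

  # "Homodimer", "Homotetramer" ...
  m <- regmatches(text, regexec(sprintf("\\bhomo(%s)mer", stem_pat), text))[[1]]
  if (length(m) == 2L) {
    k <- word_table[[m[2]]]
    return(comp(setNames(as.integer(k), "subunit"), k))
  }
  # "Heterotrimer", "Heterotetramer" ... labels unknown
  m <- regmatches(text, regexec(sprintf("\\bhetero(%s)mer", stem_pat), text))[[1]]
  if (length(m) == 2L) {
    k <- word_table[[m[2]]]
    return(comp(setNames(as.integer(k), "unspecified"), k,
                labels_known = FALSE))
  }
  # bare "Monomer"
  if (grepl("\\bmonomer(ic)?\\b", text))
    return(comp(setNames(1L, "subunit"), 1L))
  # bare "Dimer", "Tetramer" without homo/hetero: total known, labels not
  m <- regmatches(text, regexec(sprintf("\\b(%s)mer(ic)?\\b", stem_pat), text))[[1]]
  if (length(m) >= 2L && m[2] != "mono") {
    k <- word_table[[m[2]]]
    return(comp(setNames(as.integer(k), "unspecified"), k,
                labels_known = FALSE))
  }
  comp(setNames(1L, "subunit"), 1L, defaulted = TRUE)
}

#' Percent identity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment under BLOSUM62 with affine gap costs
#' (opening 10, extension 0.5); identity is the number of identical aligned
#' positions divided by the alignment length (columns, including gaps), times
#' 100. Symmetric in its arguments; 100 iff the sequences are identical.
#'
#' @param seq_a,seq_b amino-acid strings (20-letter alphabet plus X).
#' @return percent identity in [0, 100].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("invalid input: empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  # PID1: identities / (aligned positions + internal gaps); under a global
  # alignment this is identities / alignment columns
  Biostrings::pid(aln, type = "PID1")
}
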