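# Minimal SBML Level 3 Version 1 + fbc-v2 I/O.
#
# Covers the subset needed for flux-balance models: compartments, species,
# reactions with stoichiometry, flux bounds as fbc parameters, gene product
# associations (nested and/or), the active linear objective, and EC numbers /
# UniProt accessions carried in legacy-style <notes> paragraphs. Identifier
# prefixes R_/M_/G_ follow the COBRA convention and are stripped on read.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

check_sid <- function(id) {
  bad <- grepl("[^A-Za-z0-9_]", id)
  if (any(bad))
    stop("ids not expressible as SBML SIds (normalize the model first): ",
         paste(id[bad], collapse = ", "))
  invisible(id)
}

num_attr <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

write_model_sbml <- function(model, path) {
  mids <- vapply(model$metabolites, `[[`, "", "id")
  rids <- vapply(model$reactions, `[[`, "", "id")
  check_sid(c(mids, rids, model$genes))
  comps <- unique(vapply(model$metabolites, function(m)
    if (nzchar(m$compartment)) m$compartment else "c", ""))

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1"',
                   ' fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', xml_escape(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', comps),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (m in model$metabolites) {
    comp <- if (nzchar(m$compartment)) m$compartment else "c"
    extra <- if (!is.null(m$formula))
      sprintf(' fbc:chemicalFormula="%s"', xml_escape(m$formula)) else ""
    lines <- c(lines, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s"',
             ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
             ' constant="false"%s/>'),
      m$id, xml_escape(m$name), comp, extra))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (r in model$reactions) {
    lines <- c(lines,
      sprintf('      <parameter id="R_%s_lower_bound" value="%s" constant="true"/>',
              r$id, num_attr(r$lower_bound)),
      sprintf('      <parameter id="R_%s_upper_bound" value="%s" constant="true"/>',
              r$id, num_attr(r$upper_bound)))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    rev <- if (r$lower_bound < 0) "true" else "false"
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="R_%s_lower_bound"',
             ' fbc:upperFluxBound="R_%s_upper_bound">'),
      r$id, xml_escape(r$name), rev, r$id, r$id))
    if (length(r$ec_numbers)) {
      lines <- c(lines,
        '        <notes>',
        '          <body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf('            <p>EC Number: %s</p>',
                xml_escape(paste(r$ec_numbers, collapse = "; "))),
        '          </body>',
        '        </notes>')
    }
    neg <- r$stoichiometry[r$stoichiometry < 0]
    pos <- r$stoichiometry[r$stoichiometry > 0]
    if (length(neg)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf(paste0('          <speciesReference species="M_%s"',
                       ' stoichiometry="%s" constant="true"/>'),
                names(neg), num_attr(-unname(neg))),
        '        </listOfReactants>')
    }
    if (length(pos)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf(paste0('          <speciesReference species="M_%s"',
                       ' stoichiometry="%s" constant="true"/>'),
                names(pos), num_attr(unname(pos))),
        '        </listOfProducts>')
    }
    if (nzchar(r$gene_reaction_rule)) {
      gpr <- parse_gpr(r$gene_reaction_rule)
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpa_xml(gpr, indent = "          "),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  lines <- c(lines,
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>')
  for (rid in names(model$objective)) {
    lines <- c(lines, sprintf(
      '          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="%s"/>',
      rid, num_attr(unname(model$objective[[rid]]))))
  }
  lines <- c(lines,
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '    <fbc:listOfGeneProducts>')
  for (g in model$genes) {
    acc <- model$gene_annotation[[g]]$uniprot
    if (!is.null(acc)) {
      lines <- c(lines, sprintf(
        '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s" fbc:name="%s">', g, g, g),
        '        <notes>',
        '          <body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf('            <p>UNIPROT: %s</p>', xml_escape(acc)),
        '          </body>',
        '        </notes>',
        '      </fbc:geneProduct>')
    } else {
      lines <- c(lines, sprintf(
        '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s" fbc:name="%s"/>',
        g, g, g))
    }
  }
  lines <- c(lines,
    '    </fbc:listOfGeneProducts>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

# render a DNF gpr as an fbc geneProductAssociation fragment
gpa_xml <- function(gpr, indent) {
  complex_xml <- function(cx, ind) {
    genes <- rep(names(cx), times = cx)
    refs <- sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                    paste0(ind, "  "), unique(genes))
    if (length(unique(genes)) == 1L)
      sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', ind, unique(genes))
    else
      c(sprintf("%s<fbc:and>", ind), refs, sprintf("%s</fbc:and>", ind))
  }
  if (length(gpr$enzymes) == 1L) {
    complex_xml(gpr$enzymes[[1]], indent)
  } else {
    c(sprintf("%s<fbc:or>", indent),
      unlist(lapply(gpr$enzymes, complex_xml, ind = paste0(indent, "  "))),
      sprintf("%s</fbc:or>", indent))
  }
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in ", path, ": ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_attr(mod, "id")) && inherits(mod, "xml_missing"))
    stop("SBML parse failure: no <model> element in ", path)

  params <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  mets <- lapply(sp, function(s) {
    id <- strip_prefix(xml2::xml_attr(s, "id"), "M_")
    new_metabolite(id,
                   name = xml2::xml_attr(s, "name") %|na|% id,
                   compartment = xml2::xml_attr(s, "compartment") %|na|% "",
                   formula = {
                     f <- xml2::xml_attr(s, "chemicalFormula")
                     if (is.na(f)) NULL else f
                   })
  })
  names(mets) <- vapply(mets, `[[`, "", "id")

  gps <- xml2::xml_find_all(mod, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_id <- xml2::xml_attr(gps, "id")
  gp_label <- xml2::xml_attr(gps, "label")
  gp_label[is.na(gp_label)] <- strip_prefix(gp_id[is.na(gp_label)], "G_")
  gp_map <- setNames(gp_label, gp_id)
  gene_ann <- list()
  for (k in seq_along(gps)) {
    note <- xml2::xml_text(xml2::xml_find_first(gps[[k]], ".//s:notes", ns))
    if (!is.na(note) && grepl("UNIPROT:", note)) {
      acc <- trimws(sub(".*UNIPROT:\\s*", "", note))
      gene_ann[[gp_label[k]]] <- list(uniprot = acc)
    }
  }

  rx <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(r) {
    id <- strip_prefix(xml2::xml_attr(r, "id"), "R_")
    reac <- xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference", ns)
    stoich <- c(
      setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
               strip_prefix(xml2::xml_attr(reac, "species"), "M_")),
      setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
               strip_prefix(xml2::xml_attr(prod, "species"), "M_")))
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else -DEFAULT_BOUND
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else DEFAULT_BOUND
    gpa <- xml2::xml_find_first(r, "./fbc:geneProductAssociation", ns)
    gpr_text <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gpa_to_text(kids[[1]], gp_map, ns) else ""
    }
    ec <- character(0)
    note <- xml2::xml_text(xml2::xml_find_first(r, "./s:notes", ns))
    if (!is.na(note) && grepl("EC Number:", note)) {
      ec <- trimws(strsplit(sub(".*EC Number:\\s*", "", note), ";")[[1]])
      ec <- ec[nzchar(ec)]
    }
    new_reaction(id, stoichiometry = stoich, lower_bound = lb,
                 upper_bound = ub, gene_reaction_rule = gpr_text,
                 name = xml2::xml_attr(r, "name") %|na|% id, ec_numbers = ec)
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")

  fo <- xml2::xml_find_all(
    mod, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                        strip_prefix(xml2::xml_attr(fo, "reaction"), "R_"))

  m <- gem_model(id = xml2::xml_attr(mod, "id") %|na|% "model",
                 metabolites = mets, reactions = rxns,
                 genes = unname(gp_label), objective = objective,
                 validate = FALSE)
  if (length(gene_ann)) m$gene_annotation <- gene_ann
  m
}

# recursively flatten an fbc and/or node into GPR text
gpa_to_text <- function(node, gp_map, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gp <- xml2::xml_attr(node, "geneProduct")
    return(unname(gp_map[gp] %|na|% strip_prefix(gp, "G_")))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, gpa_to_text, "", gp_map = gp_map, ns = ns)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

`%|na|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a
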