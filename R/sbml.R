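## SBML Level 3 + FBC v2 reader/writer (the subset used for GEM
## exchange: species, reactions with stoichiometry, flux-bound
## parameters, objectives, gene products and gene-product associations).

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

num17 <- function(x) sprintf("%.17g", x)

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(mod))) stop("no <model> element in ", path)

  sp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(mod, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gps, "fbc:label", ns),
                            xml2::xml_attr(gps, "fbc:id", ns))

  objs <- xml2::xml_find_all(
    mod, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  obj_rxn <- xml2::xml_attr(objs, "fbc:reaction", ns)
  obj_coef <- as.numeric(xml2::xml_attr(objs, "fbc:coefficient", ns))

  rxn_nodes <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  nr <- length(rxn_nodes)
  ids <- xml2::xml_attr(rxn_nodes, "id")
  S <- matrix(0, nrow(mets), nr, dimnames = list(mets$id, ids))
  gpr <- character(nr)
  lbs <- ubs <- numeric(nr)

  gpa_to_ast <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "fbc:geneProduct", ns)
      lab <- glabel[[gid]]
      return(list(gene = if (is.null(lab) || is.na(lab)) gid else lab))
    }
    kids <- xml2::xml_children(node)
    list(op = nm, args = lapply(kids, gpa_to_ast))
  }

  for (k in seq_len(nr)) {
    node <- rxn_nodes[[k]]
    for (role in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, paste0("./s:", role, "/s:speciesReference"), ns)
      if (length(refs) == 0) next
      sgn <- if (role == "listOfReactants") -1 else 1
      met <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      mi <- match(met, mets$id)
      if (anyNA(mi)) stop("reaction '", ids[k], "': unknown species '",
                          met[is.na(mi)][1], "'")
      S[mi, k] <- S[mi, k] + sgn * coef
    }
    lb_id <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
    ub_id <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
    if (is.na(lb_id) || is.na(ub_id) ||
        is.na(parval[lb_id]) || is.na(parval[ub_id]))
      stop("reaction '", ids[k], "': missing flux bound parameter")
    lbs[k] <- parval[[lb_id]]
    ubs[k] <- parval[[ub_id]]
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    if (!is.na(xml2::xml_name(gpa))) {
      gpr[k] <- gpr_to_string(gpa_to_ast(xml2::xml_child(gpa)))
    }
  }
  oc <- numeric(nr)
  oc[match(obj_rxn, ids)] <- obj_coef
  rx <- data.frame(
    id = ids,
    name = ifelse(is.na(xml2::xml_attr(rxn_nodes, "name")), ids,
                  xml2::xml_attr(rxn_nodes, "name")),
    lower_bound = lbs, upper_bound = ubs, gene_reaction_rule = gpr,
    objective_coefficient = oc, stringsAsFactors = FALSE)
  new_metabolic_model(xml2::xml_attr(mod, "id") %||% basename(path), rx, mets, S)
}

#' Write a model as SBML Level 3 + FBC v2
#' @param model a [metabolic_model].
#' @param path output path.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
      '" level="3" version="1" fbc:required="false">')
  add('  <model id="', esc(model$id), '" fbc:strict="true">')
  add('    <listOfCompartments>')
  for (cp in unique(model$metabolites$compartment))
    add('      <compartment id="', esc(cp), '" constant="true"/>')
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (k in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[k, ]
    add('      <species id="', esc(m$id), '" name="', esc(m$name),
        '" compartment="', esc(m$compartment),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>')
  }
  add('    </listOfSpecies>')
  add('    <listOfParameters>')
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    add('      <parameter id="bnd_', esc(r$id), '_lb" value="',
        num17(r$lower_bound), '" constant="true"/>')
    add('      <parameter id="bnd_', esc(r$id), '_ub" value="',
        num17(r$upper_bound), '" constant="true"/>')
  }
  add('    </listOfParameters>')
  genes <- unique(unlist(lapply(model$reactions$gene_reaction_rule,
                                function(r) gpr_genes(gpr_parse(r)))))
  gid <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))
  if (length(genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in genes)
      add('      <fbc:geneProduct fbc:id="', gid(g), '" fbc:label="',
          esc(g), '"/>')
    add('    </fbc:listOfGeneProducts>')
  }
  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('        <fbc:listOfFluxObjectives>')
  for (k in which(model$reactions$objective_coefficient != 0))
    add('          <fbc:fluxObjective fbc:reaction="',
        esc(model$reactions$id[k]), '" fbc:coefficient="',
        num17(model$reactions$objective_coefficient[k]), '"/>')
  add('        </fbc:listOfFluxObjectives>')
  add('      </fbc:objective>')
  add('    </fbc:listOfObjectives>')
  ast_to_xml <- function(ast, indent) {
    pad <- strrep(" ", indent)
    if (!is.null(ast$gene))
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="',
                    gid(ast$gene), '"/>'))
    kids <- vapply(ast$args, ast_to_xml, "", indent + 2L)
    paste0(pad, "<fbc:", ast$op, ">\n",
           paste(kids, collapse = "\n"), "\n", pad, "</fbc:", ast$op, ">")
  }
  add('    <listOfReactions>')
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    st <- model$S[, k]
    add('      <reaction id="', esc(r$id), '" name="', esc(r$name),
        '" reversible="', if (r$lower_bound < 0) "true" else "false",
        '" fast="false" fbc:lowerFluxBound="bnd_', esc(r$id),
        '_lb" fbc:upperFluxBound="bnd_', esc(r$id), '_ub">')
    ast <- gpr_parse(r$gene_reaction_rule)
    if (!is.null(ast)) {
      add('        <fbc:geneProductAssociation>')
      add(ast_to_xml(ast, 10L))
      add('        </fbc:geneProductAssociation>')
    }
    reac <- which(st < 0); prod <- which(st > 0)
    if (length(reac)) {
      add('        <listOfReactants>')
      for (i in reac)
        add('          <speciesReference species="',
            esc(model$metabolites$id[i]), '" stoichiometry="',
            num17(-st[i]), '" constant="true"/>')
      add('        </listOfReactants>')
    }
    if (length(prod)) {
      add('        <listOfProducts>')
      for (i in prod)
        add('          <speciesReference species="',
            esc(model$metabolites$id[i]), '" stoichiometry="',
            num17(st[i]), '" constant="true"/>')
      add('        </listOfProducts>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('  </model>')
  add('</sbml>')
  writeLines(unlist(L), path)
  invisible(path)
}
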