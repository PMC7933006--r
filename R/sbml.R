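# SBML Level 3 serialization. Kinetic laws are written as genuine MathML so
# third-party simulators can consume the document; a small trpflux
# annotation on each reaction records the rate-law class and driving gene so
# the document round-trips losslessly through read_sbml().

sbml_num <- function(x) sprintf("%.17g", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

mathml_for <- function(r, p, oxygen_term) {
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  times <- function(...) sprintf("<apply><times/>%s</apply>",
                                 paste0(..., collapse = ""))
  plus <- function(...) sprintf("<apply><plus/>%s</apply>",
                                paste0(..., collapse = ""))
  minus <- function(a, b) sprintf("<apply><minus/>%s%s</apply>", a, b)
  divide <- function(a, b) sprintf("<apply><divide/>%s%s</apply>", a, b)
  core <- switch(r$rate_law,
    irreversible_mm = {
      s <- names(r$substrates)[1L]
      divide(times(ci("vmax"), ci(s)), plus(ci(paste0("km_", s)), ci(s)))
    },
    antiport_exchange = {
      s_out <- names(r$substrates)[1L]; c_in <- names(r$substrates)[2L]
      s_in <- names(r$products)[1L]; c_out <- names(r$products)[2L]
      divide(minus(times(ci(s_out), ci(c_in)),
                   times(ci("keq_bias"), ci(s_in), ci(c_out))),
             times(plus(ci(paste0("km_", s_out)), ci(s_out), ci(s_in)),
                   plus(ci(paste0("km_", c_in)), ci(c_in), ci(c_out))))
    },
    first_order_clearance =
      times(ci("kclear"), ci(names(r$substrates)[1L])))
  if (r$rate_law == "antiport_exchange")
    core <- times(ci("vmax"), core)
  if (oxygen_term && isTRUE(r$oxygen_dependent))
    core <- times(core, divide(ci("oxygen"),
                               plus(ci("km_oxygen"), ci("oxygen"))))
  sprintf('<math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>', core)
}

#' Export a model to SBML Level 3
#'
#' Writes species (boundary species clamped via
#' \code{boundaryCondition="true" constant="true"}), reactions with
#' stoichiometries, kinetic laws as MathML with local parameters, and the
#' global oxygen parameter. The generated document re-imports via
#' \code{\link{read_sbml}} with identical species/reaction counts and
#' parameter values.
#'
#' @param model a \code{trp_model}.
#' @param params a \code{trp_params}; defaults to the model's.
#' @param file output path.
#' @return the path, invisibly.
#' @export
export_sbml <- function(model, params = model$params, file) {
  validate_trp_model(model)
  validate_trp_params(params)
  sp <- model$species
  species_xml <- vapply(seq_len(nrow(sp)), function(i) sprintf(
    '      <species id="%s" name="%s" compartment="%s" initialConcentration="%s" boundaryCondition="%s" constant="%s" hasOnlySubstanceUnits="false"/>',
    sp$id[i], xml_escape(sp$display_name[i]), sp$compartment[i],
    sbml_num(sp$initial_concentration[i]),
    tolower(sp$is_boundary[i]), tolower(sp$is_boundary[i])), character(1))

  rxn_xml <- vapply(model$reactions, function(r) {
    p <- params$reactions[[r$id]]
    refs <- function(set, tag) {
      if (!length(set)) return(sprintf("        <listOf%ss/>", tag))
      inner <- paste(vapply(names(set), function(s) sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        s, sbml_num(set[[s]])), character(1)), collapse = "\n")
      sprintf("        <listOf%ss>\n%s\n        </listOf%ss>", tag, inner, tag)
    }
    locals <- c(
      if (!is.null(p$vmax)) sprintf(
        '            <localParameter id="vmax" value="%s"/>', sbml_num(p$vmax)),
      if (!is.null(p$km)) vapply(names(p$km), function(s) sprintf(
        '            <localParameter id="km_%s" value="%s"/>',
        s, sbml_num(p$km[[s]])), character(1)),
      if (!is.null(p$keq_bias)) sprintf(
        '            <localParameter id="keq_bias" value="%s"/>',
        sbml_num(p$keq_bias)),
      if (!is.null(p$kclear)) sprintf(
        '            <localParameter id="kclear" value="%s"/>',
        sbml_num(p$kclear)),
      if (!is.null(p$km_oxygen)) sprintf(
        '            <localParameter id="km_oxygen" value="%s"/>',
        sbml_num(p$km_oxygen)))
    sprintf(paste0(
      '      <reaction id="%s" reversible="%s">\n',
      '        <annotation><trpflux:info xmlns:trpflux="https://example.org/trpflux" rateLaw="%s" gene="%s" oxygenDependent="%s"/></annotation>\n',
      '%s\n%s\n',
      '        <kineticLaw>\n          %s\n',
      '          <listOfLocalParameters>\n%s\n          </listOfLocalParameters>\n',
      '        </kineticLaw>\n      </reaction>'),
      r$id, tolower(r$rate_law == "antiport_exchange"),
      r$rate_law, if (is.na(r$gene)) "" else r$gene,
      tolower(isTRUE(r$oxygen_dependent)),
      refs(r$substrates, "Reactant"), refs(r$products, "Product"),
      mathml_for(r, p, model$oxygen_term),
      paste(locals, collapse = "\n"))
  }, character(1))

  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
    '  <model id="trpflux_model" name="Hepatic tryptophan metabolism" substanceUnits="item" timeUnits="second" extentUnits="item">\n',
    '    <annotation><trpflux:model xmlns:trpflux="https://example.org/trpflux" oxygenTerm="%s" concentrationUnit="%s" timeUnit="%s"/></annotation>\n',
    '    <listOfCompartments>\n',
    '      <compartment id="extracellular" constant="true" size="1"/>\n',
    '      <compartment id="intracellular" constant="true" size="1"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n%s\n    </listOfSpecies>\n',
    '    <listOfParameters>\n',
    '      <parameter id="oxygen" value="%s" constant="true"/>\n',
    '    </listOfParameters>\n',
    '    <listOfReactions>\n%s\n    </listOfReactions>\n',
    '  </model>\n</sbml>\n'),
    tolower(model$oxygen_term), model$units$concentration, model$units$time,
    paste(species_xml, collapse = "\n"),
    sbml_num(params$oxygen_level),
    paste(rxn_xml, collapse = "\n"))
  xml2::read_xml(doc)  # fail early on malformed output
  writeLines(doc, file, useBytes = TRUE)
  invisible(file)
}

#' Import a trpflux SBML document
#'
#' Re-reads a document written by \code{\link{export_sbml}} into a
#' \code{trp_model}; species and reaction sets, stoichiometries and all
#' kinetic parameter values round-trip exactly.
#'
#' @param file SBML path.
#' @return a \code{trp_model}.
#' @export
read_sbml <- function(file) {
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  ann <- xml2::xml_find_first(mnode, "./annotation/*")
  oxygen_term <- identical(xml2::xml_attr(ann, "oxygenTerm"), "true")
  units <- list(concentration = xml2::xml_attr(ann, "concentrationUnit"),
                time = xml2::xml_attr(ann, "timeUnit"))

  spn <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- data.frame(
    id = xml2::xml_attr(spn, "id"),
    display_name = xml2::xml_attr(spn, "name"),
    compartment = xml2::xml_attr(spn, "compartment"),
    is_boundary = xml2::xml_attr(spn, "boundaryCondition") == "true",
    initial_concentration = as.numeric(xml2::xml_attr(spn,
                                                      "initialConcentration")),
    stringsAsFactors = FALSE)

  oxygen_level <- as.numeric(xml2::xml_attr(
    xml2::xml_find_first(doc, ".//listOfParameters/parameter[@id='oxygen']"),
    "value"))

  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- list()
  par_list <- list()
  for (rn in rxn_nodes) {
    id <- xml2::xml_attr(rn, "id")
    info <- xml2::xml_find_first(rn, "./annotation/*")
    gene <- xml2::xml_attr(info, "gene")
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(rn, xp)
      stats::setNames(as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
                      xml2::xml_attr(nodes, "species"))
    }
    lp <- xml2::xml_find_all(rn, ".//localParameter")
    vals <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                            xml2::xml_attr(lp, "id"))
    p <- list()
    if ("vmax" %in% names(vals)) p$vmax <- vals[["vmax"]]
    kms <- grep("^km_(?!oxygen$)", names(vals), value = TRUE, perl = TRUE)
    if (length(kms))
      p$km <- stats::setNames(vals[kms], sub("^km_", "", kms))
    if ("keq_bias" %in% names(vals)) p$keq_bias <- vals[["keq_bias"]]
    if ("kclear" %in% names(vals)) p$kclear <- vals[["kclear"]]
    if ("km_oxygen" %in% names(vals)) p$km_oxygen <- vals[["km_oxygen"]]
    reactions[[id]] <- list(
      id = id,
      gene = if (is.na(gene) || !nzchar(gene)) NA_character_ else gene,
      substrates = refs("./listOfReactants/speciesReference"),
      products = refs("./listOfProducts/speciesReference"),
      rate_law = xml2::xml_attr(info, "rateLaw"),
      oxygen_dependent = identical(xml2::xml_attr(info, "oxygenDependent"),
                                   "true"))
    par_list[[id]] <- p
  }
  trp_model(species, reactions,
            trp_params(par_list, oxygen_level = oxygen_level),
            units = units, oxygen_term = oxygen_term)
}
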