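TS_NS <- "https://twinscreen.r-pkg.invalid/sbml-annotations"
SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a network model to file
#'
#' Two equivalent serializations are supported and chosen by file extension:
#' an SBML Level 3 subset (`.sbml`/`.xml`; species, reactions, modifiers,
#' kinetic laws with local parameters and MathML) and a human-editable YAML
#' mirror (`.yaml`/`.yml`) with identical content. Both round-trip exactly
#' through [read_model()].
#'
#' @param model A `NetworkModel`.
#' @param path Output file path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    sbml = , xml = write_model_sbml(model, path),
    yaml = , yml = write_model_yaml(model, path),
    ts_error("unknown_format", sprintf("unsupported model extension '%s'", ext)))
  invisible(path)
}

#' Read a network model from file
#'
#' @param path An SBML (`.sbml`/`.xml`) or YAML (`.yaml`/`.yml`) model file
#'   written by [write_model()].
#' @return A `NetworkModel`.
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    sbml = , xml = read_model_sbml(path),
    yaml = , yml = read_model_yaml(path),
    ts_error("unknown_format", sprintf("unsupported model extension '%s'", ext)))
}

model_as_list <- function(model) {
  sp <- model$species
  list(
    species = lapply(seq_len(nrow(sp)), function(i) {
      r <- as.list(sp[i, ])
      if (is.na(r$gene)) r$gene <- NULL
      r
    }),
    reactions = lapply(model$reactions, function(rx) {
      list(id = rx$id, kind = rx$kind,
           reactants = as.list(rx$reactants), products = as.list(rx$products),
           modifiers = as.list(rx$modifiers), params = as.list(rx$params))
    }),
    input_species = as.list(model$input_species),
    readout_positive = model$readout_positive,
    readout_negative = model$readout_negative)
}

model_from_list <- function(x) {
  sp <- do.call(rbind, lapply(x$species, function(r)
    species(r$id, r$name, r$compartment, as.numeric(r$initial_concentration),
            isTRUE(as.logical(r$is_gene_representative)),
            r$gene %||% NA_character_, as.numeric(r$degradation_rate),
            r$pathway)))
  rxs <- lapply(x$reactions, function(r) {
    unlist_num <- function(v) if (length(v)) unlist(v) else NULL
    reaction(r$id, r$kind, reactants = unlist_num(r$reactants),
             products = unlist_num(r$products),
             modifiers = unlist(r$modifiers) %||% character(),
             params = unlist(r$params))
  })
  network_model(sp, rxs, unlist(x$input_species),
                x$readout_positive, x$readout_negative)
}

write_model_yaml <- function(model, path) {
  yaml::write_yaml(model_as_list(model), path, precision = 15L)
  invisible(path)
}

read_model_yaml <- function(path) {
  model_from_list(yaml::read_yaml(path))
}

# ---- SBML subset ----------------------------------------------------------

mathml_for <- function(rx) {
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  times <- function(...) {
    args <- c(...)
    if (length(args) == 1L) args
    else paste0("<apply><times/>", paste(args, collapse = ""), "</apply>")
  }
  mods <- vapply(rx$modifiers, ci, "")
  reacs <- vapply(names(rx$reactants), ci, "")
  body <- switch(rx$kind,
    synthesis = ci("k_syn"),
    degradation = times(ci("k_deg"), reacs),
    mass_action_activation = times(ci("k_cat"), mods, reacs),
    michaelis_menten = paste0("<apply><divide/>",
      times(ci("k_cat"), mods, reacs),
      "<apply><plus/>", ci("Km"), reacs, "</apply></apply>"),
    complex_formation = times(ci("k_on"), reacs),
    complex_dissociation = times(ci("k_off"), reacs))
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">", body, "</math>")
}

write_model_sbml <- function(model, path) {
  sp <- model$species
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" xmlns:ts=\"%s\" level=\"3\" version=\"2\">",
            SBML_NS, TS_NS),
    "  <model id=\"twinscreen_model\">",
    sprintf("    <annotation><ts:network inputSpecies=\"%s\" readoutPositive=\"%s\" readoutNegative=\"%s\"/></annotation>",
            paste(model$input_species, collapse = " "),
            model$readout_positive, model$readout_negative),
    "    <listOfCompartments>",
    sprintf("      <compartment id=\"%s\" size=\"1\" constant=\"true\"/>",
            unique(sp$compartment)),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(sp))) {
    out <- c(out, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\"",
             " initialConcentration=\"%s\" hasOnlySubstanceUnits=\"false\"",
             " boundaryCondition=\"%s\" constant=\"false\"",
             " ts:geneRepresentative=\"%s\" ts:gene=\"%s\"",
             " ts:degradationRate=\"%s\" ts:pathway=\"%s\"/>"),
      sp$id[i], esc(sp$name[i]), sp$compartment[i],
      fmt_num(sp$initial_concentration[i]),
      tolower(sp$id[i] %in% model$input_species),
      tolower(sp$is_gene_representative[i]),
      ifelse(is.na(sp$gene[i]), "", sp$gene[i]),
      fmt_num(sp$degradation_rate[i]), sp$pathway[i]))
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfReactions>")
  for (rx in model$reactions) {
    out <- c(out, sprintf("      <reaction id=\"%s\" reversible=\"false\" ts:kind=\"%s\">",
                          rx$id, rx$kind))
    if (length(rx$reactants)) {
      out <- c(out, "        <listOfReactants>",
               sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                       names(rx$reactants), fmt_num(unname(rx$reactants))),
               "        </listOfReactants>")
    }
    if (length(rx$products)) {
      out <- c(out, "        <listOfProducts>",
               sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                       names(rx$products), fmt_num(unname(rx$products))),
               "        </listOfProducts>")
    }
    if (length(rx$modifiers)) {
      out <- c(out, "        <listOfModifiers>",
               sprintf("          <modifierSpeciesReference species=\"%s\"/>",
                       rx$modifiers),
               "        </listOfModifiers>")
    }
    out <- c(out,
      "        <kineticLaw>",
      paste0("          ", mathml_for(rx)),
      "          <listOfLocalParameters>",
      sprintf("            <localParameter id=\"%s\" value=\"%s\"/>",
              names(rx$params), fmt_num(unname(rx$params))),
      "          </listOfLocalParameters>",
      "        </kineticLaw>",
      "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  q <- function(node, xp) xml2::xml_find_all(node, xp)
  attr1 <- function(node, a) xml2::xml_attr(node, a)

  net <- q(doc, ".//*[local-name()='network']")
  if (length(net) != 1L) ts_error("bad_sbml", "missing network annotation")
  inputs <- strsplit(attr1(net, "inputSpecies"), " ", fixed = TRUE)[[1]]

  sp_nodes <- q(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp <- do.call(rbind, lapply(sp_nodes, function(nd) {
    gene <- attr1(nd, "gene")
    species(attr1(nd, "id"), attr1(nd, "name"), attr1(nd, "compartment"),
            as.numeric(attr1(nd, "initialConcentration")),
            identical(attr1(nd, "geneRepresentative"), "true"),
            if (is.na(gene) || !nzchar(gene)) NA_character_ else gene,
            as.numeric(attr1(nd, "degradationRate")), attr1(nd, "pathway"))
  }))

  rx_nodes <- q(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxs <- lapply(rx_nodes, function(nd) {
    refs <- function(xp, what = "species") {
      nodes <- q(nd, xp)
      if (!length(nodes)) return(NULL)
      stats::setNames(as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
                      xml2::xml_attr(nodes, what))
    }
    reacts <- refs(".//*[local-name()='listOfReactants']/*")
    prods <- refs(".//*[local-name()='listOfProducts']/*")
    mods <- xml2::xml_attr(q(nd, ".//*[local-name()='listOfModifiers']/*"), "species")
    pnodes <- q(nd, ".//*[local-name()='localParameter']")
    params <- stats::setNames(as.numeric(xml2::xml_attr(pnodes, "value")),
                              xml2::xml_attr(pnodes, "id"))
    reaction(attr1(nd, "id"), attr1(nd, "kind"), reactants = reacts,
             products = prods, modifiers = mods, params = params)
  })

  network_model(sp, rxs, inputs, attr1(net, "readoutPositive"),
                attr1(net, "readoutNegative"))
}
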