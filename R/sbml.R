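# SBML Level 3 export of the whole-body and subcellular reaction systems.
#
# The export is an interchange convenience: the simulator's native engine
# integrates the transcribed ODEs directly and never depends on an SBML
# engine at run time.  Species are exported in amount units for the
# whole-body model (mmol in volume-bearing compartments) and in
# concentration units (mmol/L) for the single-compartment cell model;
# kinetic laws transcribe the package's rate equations as MathML built
# from the same R expressions the solver uses.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"

# R arithmetic call -> MathML node tree (times, divide, plus, minus)
.expr_to_mathml <- function(e) {
  if (is.name(e)) return(list(tag = "ci", text = as.character(e)))
  if (is.numeric(e)) return(list(tag = "cn", text = format(e, digits = 17)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.expr_to_mathml(e[[2]]))
    tag <- switch(op, `*` = "times", `/` = "divide", `+` = "plus",
                  `-` = "minus",
                  stop("unsupported operator in rate law: ", op))
    return(list(tag = "apply",
                children = c(list(list(tag = tag)),
                             lapply(as.list(e)[-1], .expr_to_mathml))))
  }
  stop("cannot translate rate-law term of class ", class(e)[1])
}

.mathml_node <- function(parent, node) {
  child <- xml2::xml_add_child(parent, node$tag)
  if (!is.null(node$text)) xml2::xml_set_text(child, node$text)
  for (sub in node$children) .mathml_node(child, sub)
  parent
}

.pbpk_reactions <- function() {
  list(
    list(id = "gut_absorption", from = "AGutlumen", to = "CGut",
         law = quote(pbpk_kGutabs * AGutlumen)),
    list(id = "gut_to_liver", from = "CGut", to = "CLiver",
         law = quote(pbpk_QGut * CGut / pbpk_VGut)),
    list(id = "liver_to_vein", from = "CLiver", to = "CVen",
         law = quote((pbpk_QLiver + pbpk_QGut) * CLiver * pbpk_Rb2p /
                       (pbpk_Kl2p * pbpk_Fup * pbpk_VLiver))),
    list(id = "liver_metabolism", from = "CLiver", to = "CMetabolized",
         law = quote(pbpk_CLmetab * CLiver / (pbpk_Kl2p * pbpk_Fup))),
    list(id = "vein_to_lung", from = "CVen", to = "CLung",
         law = quote(pbpk_QCardiac * CVen / pbpk_VVen)),
    list(id = "lung_to_artery", from = "CLung", to = "CArt",
         law = quote(pbpk_QCardiac * CLung / pbpk_VLung)),
    list(id = "artery_to_gut", from = "CArt", to = "CGut",
         law = quote(pbpk_QGut * CArt / pbpk_VArt)),
    list(id = "artery_to_liver", from = "CArt", to = "CLiver",
         law = quote(pbpk_QLiver * CArt / pbpk_VArt)),
    list(id = "artery_to_kidney", from = "CArt", to = "CKidney",
         law = quote(pbpk_QKidney * CArt / pbpk_VArt)),
    list(id = "artery_to_rest", from = "CArt", to = "CRest",
         law = quote(pbpk_QRest * CArt / pbpk_VArt)),
    list(id = "kidney_to_vein", from = "CKidney", to = "CVen",
         law = quote(pbpk_QKidney * CKidney * pbpk_Rb2p /
                       (pbpk_Kk2p * pbpk_Fup * pbpk_VKidney))),
    list(id = "filtration", from = "CKidney", to = "CTubules",
         law = quote(pbpk_Qgfr * CKidney / (pbpk_Kk2p * pbpk_VKidney))),
    list(id = "rest_to_vein", from = "CRest", to = "CVen",
         law = quote(pbpk_QRest * CRest * pbpk_Rb2p /
                       (pbpk_Kr2p * pbpk_Fup * pbpk_VRest)))
  )
}

.subcell_reactions <- function() {
  list(
    list(id = "cyp2e1_oxidation", react = "APAP", prod = "NAPQI",
         law = quote(sc_Vmax_2E1_APAP * APAP / (sc_Km_2E1_APAP + APAP))),
    list(id = "napqi_gsh_conjugation", react = c("NAPQI", "GSH"),
         prod = "NAPQI_GSH",
         law = quote(sc_kNAPQIGSH * NAPQI * GSH)),
    list(id = "glucuronidation", react = "APAP", prod = "APAPG",
         law = quote(sc_Vmax_GLUC * APAP / (sc_Km_GLUC + APAP))),
    list(id = "sulfation", react = "APAP", prod = "APAPS",
         law = quote(sc_Vmax_SULF * APAP / (sc_Km_SULF + APAP))),
    list(id = "gsh_synthesis", react = character(0), prod = "GSH",
         law = quote(sc_kGsh * (sc_GSHmax - GSH)))
  )
}

.pbpk_compartments <- function() {
  c(AGutlumen = "gut_lumen", CGut = "gut", CLiver = "liver", CVen = "vein",
    CLung = "lung", CArt = "artery", CKidney = "kidney", CRest = "rest",
    CTubules = "tubules", CMetabolized = "metabolized_pool")
}

#' Export a sub-model as SBML Level 3
#'
#' @param model `"pbpk"` (ten species, thirteen transfer reactions) or
#'   `"subcell"` (six species, five reactions).
#' @param params Parameter set providing the values embedded in the
#'   document.
#' @param path Optional file to write; the XML document is returned
#'   (invisibly when written).
#' @return An `xml2` document.
#' @export
#' @examples
#' doc <- export_sbml("subcell")
export_sbml <- function(model = c("pbpk", "subcell"),
                        params = refsim_params(), path = NULL) {
  model <- match.arg(model)
  validate_params(params)
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3",
                            version = "1")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = paste0("hepapk_", model),
                             name = if (model == "pbpk")
                               "Whole-body PBPK model (per compound)"
                             else "Hepatocyte Phase I/II metabolism")
  # units
  uds <- xml2::xml_add_child(mdl, "listOfUnitDefinitions")
  add_unit <- function(id, kinds) {
    ud <- xml2::xml_add_child(uds, "unitDefinition", id = id)
    lst <- xml2::xml_add_child(ud, "listOfUnits")
    for (k in kinds) {
      xml2::xml_add_child(lst, "unit", kind = k$kind,
                          exponent = as.character(k$exp),
                          scale = as.character(k$scale),
                          multiplier = as.character(k$mult))
    }
  }
  add_unit("mmol", list(list(kind = "mole", exp = 1, scale = -3, mult = 1)))
  add_unit("litre_unit", list(list(kind = "litre", exp = 1, scale = 0,
                                   mult = 1)))
  if (model == "pbpk") {
    add_unit("per_hour", list(list(kind = "second", exp = -1, scale = 0,
                                   mult = 3600)))
  } else {
    add_unit("per_second", list(list(kind = "second", exp = -1, scale = 0,
                                     mult = 1)))
  }

  if (model == "pbpk") {
    comps <- .pbpk_compartments()
    vols <- c(gut_lumen = 1, gut = params[["pbpk_VGut"]],
              liver = params[["pbpk_VLiver"]], vein = params[["pbpk_VVen"]],
              lung = params[["pbpk_VLung"]], artery = params[["pbpk_VArt"]],
              kidney = params[["pbpk_VKidney"]],
              rest = params[["pbpk_VRest"]],
              tubules = 1, metabolized_pool = 1)
    lc <- xml2::xml_add_child(mdl, "listOfCompartments")
    for (cid in unique(comps)) {
      xml2::xml_add_child(lc, "compartment", id = cid,
                          size = format(vols[[cid]], digits = 17),
                          units = "litre_unit", constant = "true",
                          spatialDimensions = "3")
    }
    ls <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (sp in names(comps)) {
      xml2::xml_add_child(ls, "species", id = sp,
                          compartment = comps[[sp]],
                          initialAmount = "0",
                          substanceUnits = "mmol",
                          hasOnlySubstanceUnits = "true",
                          boundaryCondition = "false", constant = "false")
    }
    par_names <- grep("^pbpk_", names(params), value = TRUE)
    rxns <- .pbpk_reactions()
  } else {
    lc <- xml2::xml_add_child(mdl, "listOfCompartments")
    xml2::xml_add_child(lc, "compartment", id = "hepatocyte",
                        size = format(8e-12, digits = 17),
                        units = "litre_unit", constant = "true",
                        spatialDimensions = "3")
    ls <- xml2::xml_add_child(mdl, "listOfSpecies")
    inits <- c(APAP = 0, NAPQI = 0, GSH = params[["sc_GSH0"]],
               NAPQI_GSH = 0, APAPG = 0, APAPS = 0)
    for (sp in names(inits)) {
      xml2::xml_add_child(ls, "species", id = sp, compartment = "hepatocyte",
                          initialConcentration =
                            format(inits[[sp]], digits = 17),
                          substanceUnits = "mmol",
                          hasOnlySubstanceUnits = "false",
                          boundaryCondition = "false", constant = "false")
    }
    par_names <- grep("^sc_", names(params), value = TRUE)
    rxns <- .subcell_reactions()
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (pn in par_names) {
    xml2::xml_add_child(lp, "parameter", id = pn,
                        value = format(params[[pn]], digits = 17),
                        constant = "true")
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rx in rxns) {
    r <- xml2::xml_add_child(lr, "reaction", id = rx$id,
                             reversible = "false")
    reacts <- if (!is.null(rx$react)) rx$react else rx$from
    prods <- if (!is.null(rx$prod)) rx$prod else rx$to
    if (length(reacts)) {
      lrx <- xml2::xml_add_child(r, "listOfReactants")
      for (sp in reacts) {
        xml2::xml_add_child(lrx, "speciesReference", species = sp,
                            stoichiometry = "1", constant = "true")
      }
    }
    lpx <- xml2::xml_add_child(r, "listOfProducts")
    for (sp in prods) {
      xml2::xml_add_child(lpx, "speciesReference", species = sp,
                          stoichiometry = "1", constant = "true")
    }
    kl <- xml2::xml_add_child(r, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    .mathml_node(math, .expr_to_mathml(rx$law))
  }
  # re-parse so namespace prefixes resolve for downstream XPath queries
  doc <- xml2::read_xml(as.character(doc))
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Read parameter values back from an exported SBML document
#'
#' @param x Path to an SBML file or an `xml2` document.
#' @return Named numeric vector of the document's parameters.
#' @export
read_sbml_params <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  ns <- c(s = .sbml_ns)
  nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  stats::setNames(as.numeric(xml2::xml_attr(nodes, "value")),
                  xml2::xml_attr(nodes, "id"))
}

#' Structural validation of an exported SBML document
#'
#' Parses the document and checks the structural requirements the package
#' relies on: SBML Level 3 namespace, a model element, non-empty species,
#' parameter and reaction lists, every reaction referencing declared
#' species and carrying a kinetic law with MathML content.
#'
#' @param x Path or `xml2` document.
#' @return `TRUE` (invisibly) if valid; otherwise an error listing
#'   problems.
#' @export
validate_sbml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  problems <- character()
  if (!identical(xml2::xml_ns(doc)[[1]], .sbml_ns)) {
    problems <- c(problems, "root namespace is not SBML Level 3 core")
  }
  ns <- c(s = .sbml_ns)
  model <- xml2::xml_find_first(doc, "./s:model", ns)
  if (is.na(xml2::xml_name(model, ns))) {
    problems <- c(problems, "missing <model>")
  }
  species <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")
  if (!length(species)) problems <- c(problems, "no species declared")
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rxns)) problems <- c(problems, "no reactions declared")
  for (r in rxns) {
    refs <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//s:speciesReference", ns), "species")
    if (!all(refs %in% species)) {
      problems <- c(problems,
                    paste0("reaction ", xml2::xml_attr(r, "id"),
                           " references undeclared species"))
    }
    if (!length(xml2::xml_find_all(
      r, ".//s:kineticLaw//*[local-name() = 'math']", ns))) {
      problems <- c(problems, paste0("reaction ", xml2::xml_attr(r, "id"),
                                     " lacks a kinetic law"))
    }
  }
  if (length(problems)) {
    stop("invalid SBML document:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}
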