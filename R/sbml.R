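# Minimal SBML Level 3 export/import of the trafficking model variants:
# species, first-order mass-action kinetic laws, and a boundary-condition
# species holding the constant extracellular Epo concentration. The reader
# targets documents written by this package (and files following the same
# id conventions); it is not a general SBML toolkit.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

.sbml_reactions <- function(v) {
  rx <- list(
    list(id = "R_EpoR_syn", k = "k_EpoR_syn", from = character(0),
         to = "EpoR_i", species = NULL),
    list(id = "R_EpoR_deg", k = "k_EpoR_deg", from = "EpoR_i",
         to = character(0), species = "EpoR_i"),
    list(id = "R_EpoR_ItoM", k = "k_EpoR_ItoM", from = "EpoR_i",
         to = "EpoR_m", species = "EpoR_i"),
    list(id = "R_EpoR_MtoI", k = "k_EpoR_MtoI", from = "EpoR_m",
         to = "EpoR_i", species = "EpoR_m"),
    list(id = "R_Epo_bind", k = "k_on_Epo", from = "EpoR_m",
         to = "EpoRstar_m", species = c("Epo", "EpoR_m")),
    list(id = "R_Epo_unbind", k = "k_off_Epo", from = "EpoRstar_m",
         to = "EpoR_m", species = "EpoRstar_m"),
    list(id = "R_EpoRstar_MtoRE", k = "k_EpoRstar_MtoRE",
         from = "EpoRstar_m", to = "EpoRstar_RE", species = "EpoRstar_m"))
  if (v$has_A) rx <- c(rx, list(list(id = "R_EpoRstar_REtoM",
    k = "k_EpoRstar_REtoM", from = "EpoRstar_RE", to = "EpoR_m",
    species = "EpoRstar_RE")))
  if (v$has_B) rx <- c(rx, list(list(id = "R_EpoRstar_REtoI",
    k = "k_EpoRstar_REtoI", from = "EpoRstar_RE",
    to = c("EpoR_i", "Epo_deg_i"), species = "EpoRstar_RE")))
  if (v$has_C) rx <- c(rx, list(list(id = "R_EpoRstar_deg_REtoEx",
    k = "k_EpoRstar_deg_REtoEx", from = "EpoRstar_RE", to = "Epo_deg_ext",
    species = "EpoRstar_RE")))
  if (v$has_D) rx <- c(rx, list(list(id = "R_EpoRstar_deg_REtoI",
    k = "k_EpoRstar_deg_REtoI", from = "EpoRstar_RE", to = "Epo_deg_i",
    species = "EpoRstar_RE")))
  rx
}

#' Export a model variant as SBML
#'
#' Writes an SBML Level 3 document with the variant's species, kinetic
#' parameters and first-order reactions; extracellular Epo is a
#' boundary-condition species (constant concentration, set via the initial
#' amount), so ligand binding appears as pseudo-first-order mass action.
#'
#' @param variant Model variant.
#' @param params Named kinetic parameters of the variant's Epo-condition
#'   model.
#' @param file Output path (`.xml`).
#' @param init Optional named initial concentrations (nM) for the species;
#'   defaults to the pre-stimulus steady state with Epo at 4.2 nM.
#' @param epo_conc Constant Epo concentration (nM) if `init` lacks `Epo`.
#' @return The file path, invisibly.
#' @export
write_sbml <- function(variant, params, file, init = NULL, epo_conc = 4.2) {
  v <- epor_variant(variant)
  p <- params[kinetic_param_names(v, "epo")]
  if (any(is.na(p))) stop("missing kinetic parameter(s)")
  if (is.null(init)) {
    ss <- prestimulus_steady_state(p)
    init <- c(EpoR_i = unname(ss["EpoR_i"]), EpoR_m = unname(ss["EpoR_m"]),
              EpoRstar_m = 0, EpoRstar_RE = 0, Epo_deg_i = 0,
              Epo_deg_ext = 0, Epo = epo_conc)
  }
  if (is.na(init["Epo"])) init["Epo"] <- epo_conc

  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS, level = "3",
                            version = "1")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("EpoR_traffic_",
                                           if (nzchar(v$name)) v$name
                                           else "basic"))
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  spl <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in c(.STATE_NAMES, "Epo"))
    xml2::xml_add_child(spl, "species", id = s, compartment = "cell",
                        initialConcentration =
                          format(unname(init[s]), digits = 15),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (s == "Epo") "true" else "false",
                        constant = if (s == "Epo") "true" else "false")
  pl <- xml2::xml_add_child(model, "listOfParameters")
  for (k in names(p))
    xml2::xml_add_child(pl, "parameter", id = k,
                        value = format(unname(p[k]), digits = 15),
                        constant = "true")
  rl <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in .sbml_reactions(v)) {
    rn <- xml2::xml_add_child(rl, "reaction", id = rx$id,
                              reversible = "false")
    if (length(rx$from) > 0) {
      lo <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in rx$from)
        xml2::xml_add_child(lo, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
    }
    if (length(rx$to) > 0) {
      lo <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in rx$to)
        xml2::xml_add_child(lo, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = .MATHML_NS)
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", rx$k)
    for (s in rx$species) xml2::xml_add_child(ap, "ci", s)
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

#' @rdname write_sbml
#' @param file SBML file to read.
#' @return `read_sbml()`: list with `variant`, `params` (named), `init`
#'   (named initial concentrations including `Epo`).
#' @export
read_sbml <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  doc <- xml2::read_xml(file)
  ns <- c(s = .SBML_NS)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  params <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  sps <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  init <- setNames(as.numeric(xml2::xml_attr(sps, "initialConcentration")),
                   xml2::xml_attr(sps, "id"))
  letters_in <- c(
    if ("k_EpoRstar_REtoM" %in% names(params)) "A",
    if ("k_EpoRstar_REtoI" %in% names(params)) "B",
    if ("k_EpoRstar_deg_REtoEx" %in% names(params)) "C",
    if ("k_EpoRstar_deg_REtoI" %in% names(params)) "D")
  v <- epor_variant(paste(letters_in, collapse = ""))
  expected <- kinetic_param_names(v, "epo")
  miss <- setdiff(expected, names(params))
  if (length(miss) > 0)
    stop("SBML model lacks parameter(s): ", paste(miss, collapse = ", "))
  list(variant = v, params = params[expected], init = init)
}
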