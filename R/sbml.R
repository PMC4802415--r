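# SBML Level 3 export / import of the network. The exporter writes a full
# standalone model (species, global parameters, reactions with MathML
# kinetic laws); the importer reads documents written by this exporter,
# reconstructing the network from the global parameters and the species'
# initial concentrations.

.mml_ci <- function(x) paste0("<ci> ", x, " </ci>")
.mml_cn <- function(x) paste0("<cn> ", format(x, digits = 17), " </cn>")
.mml <- function(op, ...) {
  paste0("<apply> <", op, "/> ", paste(c(...), collapse = " "), " </apply>")
}

# MathML body of each reaction's rate law
.sbml_rate_math <- function() {
  ci <- .mml_ci; ap <- .mml
  mm <- function(vmax, s, km) ap("divide", ap("times", vmax, ci(s)),
                                 ap("plus", ci(km), ci(s)))
  list(
    RAC_ACT   = mm(ci("Vb_racgef"), "Rac1_GDP", "Km_r1"),
    RAC_DEACT = mm(ap("plus", ap("times", ci("kcat_gap"), ci("GAPa")),
                      ci("Vb_racgap")), "Rac1_GTP", "Km_r2"),
    RHO_ACT   = mm(ap("plus", ap("times", ci("kcat_gef"), ci("GEFH1")),
                      ci("Vb_rhogef")), "RhoA_GDP", "Km_r3"),
    RHO_DEACT = mm(ci("Vb_rhogap"), "RhoA_GTP", "Km_r4"),
    PAK_BIND  = ap("minus",
                   ap("times", ci("kon_pak"), ci("Rac1_GTP"), ci("iPAK")),
                   ap("times", ci("koff_pak"), ci("cPAK"))),
    PAK_AUTOPH = ap("times", ci("k_auto"), ci("cPAK")),
    PAK_DEPH  = mm(ci("V_ppase"), "pPAK", "Km_p"),
    GEF_PHOS  = ap("divide",
                   ap("times", ci("kcat_pakgef"), ci("pPAK"), ci("GEFH1")),
                   ap("plus", ci("Km_g"), ci("GEFH1"))),
    GEF_DEPH  = mm(ci("V_gppase"), "pGEFH1", "Km_gp"),
    SEQ_BIND  = ap("minus",
                   ap("times", ci("kon_14"), ci("pGEFH1"), ci("F1433")),
                   ap("times", ci("koff_14"), ci("pGEFH1_1433"))),
    GAP_ACT   = ap("divide",
                   ap("times", ci("kcat_rho"), ci("RhoA_GTP"), ci("GAPi")),
                   ap("plus", ci("Km_ga"), ci("GAPi"))),
    GAP_DEACT = mm(ci("V_gapoff"), "GAPa", "Km_gd"),
    INH_BIND  = ap("times", ci("kon_i"), ci("u"), ci("iPAK")),
    INH_UNBIND = ap("times", ci("koff_i"), ci("iPAK_I"))
  )
}

#' Export a network as an SBML Level 3 document
#'
#' Writes a standards-compliant SBML Level 3 Version 2 model: one
#' compartment, the 14 species with initial concentrations taken from the
#' all-inactive corner state, all kinetic constants and the clamped
#' inhibitor level as global parameters, and all 14 reactions with full
#' MathML kinetic laws. The document round-trips through [import_sbml()].
#'
#' @param network an `rr_network`.
#' @param path output file path (`.xml`).
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path) {
  sp <- species_names()
  init <- state_inactive(network)
  S <- network$stoichiometry
  math <- .sbml_rate_math()

  species_xml <- paste(vapply(sp, function(s) {
    sprintf(paste0('      <species id="%s" compartment="cell" ',
                   'initialConcentration="%.17g" substanceUnits="nanomole" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'), s, init[[s]])
  }, character(1)), collapse = "\n")

  pars <- c(setNames(as.numeric(network$kinetics), kinetics_names()),
            u = network$u)
  params_xml <- paste(vapply(names(pars), function(p) {
    sprintf('      <parameter id="%s" value="%.17g" constant="true"/>',
            p, pars[[p]])
  }, character(1)), collapse = "\n")

  reactions_xml <- paste(vapply(reaction_names(), function(rx) {
    col <- S[, rx]
    reac <- names(col)[col < 0]
    prod <- names(col)[col > 0]
    refs <- function(tag, set) {
      if (length(set) == 0) return("")
      inner <- paste(vapply(set, function(s) {
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%g" constant="true"/>'),
                s, abs(col[[s]]))
      }, character(1)), collapse = "\n")
      sprintf("        <listOf%s>\n%s\n        </listOf%s>",
              tag, inner, tag)
    }
    rev <- rx %in% c("PAK_BIND", "SEQ_BIND")
    paste0(
      sprintf('      <reaction id="%s" reversible="%s">\n', rx,
              tolower(rev)),
      refs("Reactants", reac), "\n",
      refs("Products", prod), "\n",
      "        <kineticLaw>\n",
      '          <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
      "            ", math[[rx]], "\n",
      "          </math>\n",
      "        </kineticLaw>\n",
      "      </reaction>")
  }, character(1)), collapse = "\n")

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">\n',
    '  <model id="rac1_rhoa_pak" name="Rac1-RhoA-PAK network" ',
    'substanceUnits="nanomole" timeUnits="minute" volumeUnits="litre" ',
    'extentUnits="nanomole">\n',
    "    <listOfCompartments>\n",
    '      <compartment id="cell" spatialDimensions="3" size="1" ',
    'constant="true"/>\n',
    "    </listOfCompartments>\n",
    "    <listOfSpecies>\n", species_xml, "\n    </listOfSpecies>\n",
    "    <listOfParameters>\n", params_xml, "\n    </listOfParameters>\n",
    "    <listOfReactions>\n", reactions_xml, "\n    </listOfReactions>\n",
    "  </model>\n",
    "</sbml>\n"
  )
  # parse before writing: guarantees well-formed XML output
  parsed <- xml2::read_xml(doc)
  xml2::write_xml(parsed, path)
  invisible(path)
}

#' Import a network from an SBML document written by [export_sbml()]
#'
#' Reads the global parameters (kinetic constants and the clamped inhibitor
#' level) and the species' initial concentrations, rebuilding the network;
#' moiety totals are recovered from the initial concentrations. The
#' imported network's right-hand side is identical to the exported one.
#'
#' @param path path to the SBML file.
#' @return An `rr_network`.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  level <- xml2::xml_attr(doc, "level")
  if (root != "sbml" || is.na(level) || level != "3") {
    stop("not an SBML Level 3 document")
  }
  xml2::xml_ns_strip(doc)
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  vals <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  names(vals) <- xml2::xml_attr(par_nodes, "id")
  missing <- setdiff(kinetics_names(), names(vals))
  if (length(missing) > 0) {
    stop("SBML document lacks kinetic parameter(s): ",
         paste(missing, collapse = ", "))
  }
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  conc <- as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))
  names(conc) <- xml2::xml_attr(sp_nodes, "id")
  missing_sp <- setdiff(species_names(), names(conc))
  if (length(missing_sp) > 0) {
    stop("SBML document lacks species: ", paste(missing_sp, collapse = ", "))
  }
  state <- setNames(conc[species_names()], species_names())
  ab <- structure(moiety_totals(state), class = "rr_abundances")
  u <- if ("u" %in% names(vals)) vals[["u"]] else 0
  build_network(ab, as_kinetics(vals[kinetics_names()]), u = u)
}
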