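# SBML Level 3 Version 2 export. Metabolite dynamics are encoded as
# reactions with Michaelis-Menten kinetic laws; the HIF-1 driven enzyme
# levels are species governed by rate rules (mass-action induction), with
# HIF-1 itself a constant model parameter; boundary species carry
# boundaryCondition="true". Output is deterministic: stable ids and
# ordering, round-trip number formatting.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version2/core"
.mathml_ns <- "http://www.w3.org/1998/Math/MathML"

.ml_num <- function(x) sprintf("<cn> %.17g </cn>", x)
.ml_ci <- function(id) sprintf("<ci> %s </ci>", id)
.ml_apply <- function(op, ...) {
  sprintf("<apply><%s/>%s</apply>", op, paste0(..., collapse = ""))
}

# MathML for the rate of one compiled reaction.
.sbml_rate_math <- function(rx) {
  lvl <- if (is.na(rx$rate_law$enzyme_id)) NULL else
    .ml_ci(rx$rate_law$enzyme_id)
  p <- rx$rate_law$parameters
  S <- names(rx$substrates)[1L]
  core <- switch(rx$rate_law$kind,
    irreversible_mm = .ml_apply("divide",
      .ml_apply("times", .ml_num(p[["Vmax"]]), .ml_ci(S)),
      .ml_apply("plus", .ml_num(p[["Km"]]), .ml_ci(S))),
    reversible_mm = {
      P <- names(rx$products)[1L]
      sKs <- .ml_apply("divide", .ml_ci(S), .ml_num(p[["Ks"]]))
      pKp <- .ml_apply("divide", .ml_ci(P), .ml_num(p[["Kp"]]))
      .ml_apply("divide",
        .ml_apply("minus",
          .ml_apply("times", .ml_num(p[["Vf"]]), sKs),
          .ml_apply("times", .ml_num(p[["Vr"]]), pKp)),
        .ml_apply("plus", .ml_num(1), sKs, pKp))
    },
    first_order = .ml_apply("times", .ml_num(p[["k"]]), .ml_ci(S)),
    mass_action = do.call(.ml_apply, c(list("times", .ml_num(p[["k"]])),
      lapply(seq_along(rx$substrates), function(i) {
        id <- names(rx$substrates)[i]
        co <- rx$substrates[[i]]
        if (co == 1) .ml_ci(id) else
          .ml_apply("power", .ml_ci(id), .ml_num(co))
      }))))
  if (!is.null(lvl)) core <- .ml_apply("times", lvl, core)
  sprintf('<math xmlns="%s">%s</math>', .mathml_ns, core)
}

#' Export a pathway model as SBML Level 3 Version 2
#'
#' Writes the model as an SBML document: one compartment, all species (the
#' 26 states plus boundary species with `boundaryCondition="true"`),
#' reactions with Michaelis-Menten/mass-action kinetic laws, rate rules
#' `dE/dt = sign * K_Eh * HIF1` for the HIF-coupled enzyme species and the
#' PDK/PDP rate rule for active PDH, with HIF-1 as a constant parameter.
#' The document is deterministic across repeated exports.
#'
#' @param model a `glyco_model`.
#' @param path optional output file; when `NULL` the `xml2` document is
#'   returned.
#' @return the path (invisibly) or an `xml_document`.
#' @export
export_sbml <- function(model, path = NULL) {
  stopifnot(inherits(model, "glyco_model"))
  if (length(model$species) == 0L || length(model$reactions) == 0L) {
    stop("export error: model has no species or no reactions",
         call. = FALSE)
  }
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  out <- character()
  w <- function(...) out <<- c(out, sprintf(...))

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="%s" level="3" version="2">', .sbml_ns)
  w('<model id="glycohif" name="HIF-1 coupled glycolysis pathway" timeUnits="time" substanceUnits="substance" extentUnits="substance">')
  w('<listOfUnitDefinitions>')
  w('<unitDefinition id="time"><listOfUnits><unit kind="second" exponent="1" scale="0" multiplier="60"/></listOfUnits></unitDefinition>')
  w('<unitDefinition id="substance"><listOfUnits><unit kind="mole" exponent="1" scale="-3" multiplier="1"/></listOfUnits></unitDefinition>')
  w('</listOfUnitDefinitions>')
  w('<listOfCompartments><compartment id="cytosol" size="1" constant="true"/></listOfCompartments>')

  w('<listOfSpecies>')
  for (s in model$species) {
    boundary <- s$role == "boundary"
    w(paste0('<species id="%s" name="%s" compartment="cytosol" ',
             'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
             'boundaryCondition="%s" constant="%s"/>'),
      s$id, esc(s$name), s$initial_value,
      if (boundary) "true" else "false",
      if (boundary) "true" else "false")
  }
  w('</listOfSpecies>')

  w('<listOfParameters>')
  w('<parameter id="HIF1" name="HIF-1 concentration (uM)" value="%.17g" constant="true"/>',
    model$hif_level)
  for (cp in model$couplings) {
    w('<parameter id="K_Eh_%s" value="%.17g" constant="true"/>',
      cp$enzyme_id, cp$sign * cp$K_Eh)
  }
  if (!is.null(model$pdh_cycle)) {
    pc <- model$pdh_cycle
    w('<parameter id="k_pdk" value="%.17g" constant="true"/>', pc$k_pdk)
    w('<parameter id="k_pdp" value="%.17g" constant="true"/>', pc$k_pdp)
    w('<parameter id="pdh_total" value="%.17g" constant="true"/>', pc$total)
  }
  w('</listOfParameters>')

  w('<listOfRules>')
  for (cp in model$couplings) {
    w('<rateRule variable="%s"><math xmlns="%s">%s</math></rateRule>',
      cp$enzyme_id, .mathml_ns,
      .ml_apply("times", .ml_ci(paste0("K_Eh_", cp$enzyme_id)),
                .ml_ci("HIF1")))
  }
  if (!is.null(model$pdh_cycle)) {
    pc <- model$pdh_cycle
    w('<rateRule variable="%s"><math xmlns="%s">%s</math></rateRule>',
      pc$active_id, .mathml_ns,
      .ml_apply("minus",
        .ml_apply("times", .ml_ci("k_pdp"),
          .ml_apply("minus", .ml_ci("pdh_total"), .ml_ci(pc$active_id))),
        .ml_apply("times", .ml_ci("k_pdk"), .ml_ci(pc$pdk_id),
                  .ml_ci(pc$active_id))))
  }
  w('</listOfRules>')

  w('<listOfReactions>')
  for (rx in model$reactions) {
    reversible <- rx$rate_law$kind == "reversible_mm"
    w('<reaction id="%s" reversible="%s">', rx$id,
      if (reversible) "true" else "false")
    w('<listOfReactants>')
    for (i in seq_along(rx$substrates)) {
      w('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
        names(rx$substrates)[i], as.integer(rx$substrates[[i]]))
    }
    w('</listOfReactants>')
    w('<listOfProducts>')
    for (i in seq_along(rx$products)) {
      w('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
        names(rx$products)[i], as.integer(rx$products[[i]]))
    }
    w('</listOfProducts>')
    eid <- rx$rate_law$enzyme_id
    if (!is.na(eid)) {
      w('<listOfModifiers><modifierSpeciesReference species="%s"/></listOfModifiers>',
        eid)
    }
    w('<kineticLaw>%s</kineticLaw>', .sbml_rate_math(rx))
    w('</reaction>')
  }
  w('</listOfReactions>')
  w('</model>')
  w('</sbml>')

  doc <- xml2::read_xml(paste(out, collapse = "\n"))
  .sbml_check_consistency(doc)
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(path)
}

# Structural consistency: every species referenced by a reaction, rule or
# modifier must be declared; rate-rule variables must not also be reaction
# products (enzyme levels are forced, not produced).
.sbml_check_consistency <- function(doc) {
  ns <- c(s = .sbml_ns)
  declared <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:speciesReference | .//s:modifierSpeciesReference",
                       ns), "species")
  rule_vars <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:rateRule", ns), "variable")
  bad <- setdiff(c(refs, rule_vars), declared)
  if (length(bad) > 0L) {
    stop("export error: undeclared species referenced: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
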