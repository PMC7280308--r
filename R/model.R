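# Assembly of the HIF-1 coupled glycolysis network and its ODE right-hand
# side. The reference model has 26 state variables: 13 metabolites and 13
# enzyme states (12 enzymes/transporters whose levels are driven by HIF-1
# through mass-action induction, plus the active fraction of pyruvate
# dehydrogenase governed by the PDK/PDP phosphorylation cycle).

.metabolite_ids <- c("GLC", "G6P", "F6P", "FBP", "DHAP", "GA3P", "BPG13",
                     "PG3", "PG2", "PEP", "PYR", "ACCOA", "LAC")

.coupled_enzyme_ids <- c("GLUT", "HK", "PGI", "PFK1", "TPI", "GAPDH", "PGK",
                         "PGM", "ENO", "PDK", "LDH", "PGCM")

.boundary_ids <- c("GLC_EXT", "G1P", "PPP_SINK", "GLYC_SINK", "TCA_SINK",
                   "LAC_EXT")

.metabolite_names <- c(
  GLC = "intracellular glucose", G6P = "glucose 6-phosphate",
  F6P = "fructose 6-phosphate", FBP = "fructose 1,6-bisphosphate",
  DHAP = "dihydroxyacetone phosphate", GA3P = "glyceraldehyde 3-phosphate",
  BPG13 = "1,3-bisphosphoglycerate", PG3 = "3-phosphoglycerate",
  PG2 = "2-phosphoglycerate", PEP = "phosphoenolpyruvate",
  PYR = "pyruvate", ACCOA = "acetyl-CoA", LAC = "lactate")

.enzyme_names <- c(
  GLUT = "glucose transporter", HK = "hexokinase",
  PGI = "phosphoglucoisomerase", PFK1 = "phosphofructokinase-1",
  TPI = "triosephosphate isomerase",
  GAPDH = "glyceraldehyde 3-phosphate dehydrogenase",
  PGK = "phosphoglycerate kinase", PGM = "phosphoglycerate mutase",
  ENO = "enolase", PDK = "pyruvate dehydrogenase kinase",
  LDH = "lactate dehydrogenase", PGCM = "phosphoglucomutase",
  PDHA = "active pyruvate dehydrogenase")

.rate_law_kinds <- c("irreversible_mm", "reversible_mm", "mass_action",
                     "first_order")

#' Define a species
#'
#' @param id short symbol, unique within a model (e.g. `"G6P"`).
#' @param name human-readable name.
#' @param role one of `"metabolite"`, `"enzyme"`, `"boundary"`. Boundary
#'   species hold a fixed value during integration and carry no ODE.
#' @param initial_value nonnegative initial concentration (mM for
#'   metabolites) or relative level (dimensionless, baseline 1 for enzymes).
#' @param unit measurement unit, `"mM"` or `"level"`.
#' @return a `glyco_species` record.
#' @export
species <- function(id, name = id, role = c("metabolite", "enzyme",
                                            "boundary"),
                    initial_value = 0, unit = NULL) {
  role <- match.arg(role)
  if (!is.numeric(initial_value) || length(initial_value) != 1L ||
      is.na(initial_value) || initial_value < 0) {
    stop("model-consistency error: initial_value of '", id,
         "' must be a single nonnegative number", call. = FALSE)
  }
  if (is.null(unit)) unit <- if (role == "enzyme") "level" else "mM"
  structure(list(id = id, name = name, role = role,
                 initial_value = initial_value, unit = unit),
            class = "glyco_species")
}

#' Define a rate law
#'
#' @param kind one of `"irreversible_mm"` (parameters `Vmax`, `Km`),
#'   `"reversible_mm"` (`Vf`, `Ks`, `Vr`, `Kp`), `"mass_action"` (`k`) or
#'   `"first_order"` (`k`).
#' @param parameters named nonnegative numeric vector of kinetic constants.
#' @param enzyme_id optional id of the enzyme species whose relative level
#'   scales the rate; `NA` means the catalyst level is constant and folded
#'   into the rate constants.
#' @return a `rate_law` record.
#' @export
rate_law <- function(kind, parameters, enzyme_id = NA_character_) {
  if (!kind %in% .rate_law_kinds) {
    stop("model-consistency error: unknown rate-law kind '", kind, "'",
         call. = FALSE)
  }
  parameters <- unlist(parameters)
  if (any(is.na(parameters)) || any(parameters < 0)) {
    stop("parameter-domain error: rate-law parameters must be >= 0",
         call. = FALSE)
  }
  needed <- switch(kind,
                   irreversible_mm = c("Vmax", "Km"),
                   reversible_mm = c("Vf", "Ks", "Vr", "Kp"),
                   mass_action = "k",
                   first_order = "k")
  missing_par <- setdiff(needed, names(parameters))
  if (length(missing_par) > 0L) {
    stop("named-parameter error: rate law '", kind, "' requires ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  structure(list(kind = kind, parameters = parameters,
                 enzyme_id = enzyme_id), class = "rate_law")
}

#' Define a reaction
#'
#' @param id reaction id.
#' @param substrates,products named integer vectors mapping species ids to
#'   positive stoichiometric coefficients (e.g. `c(FBP = 1)`).
#' @param law a [rate_law()]. For `reversible_mm` the first substrate and
#'   first product supply the S and P of the rate law.
#' @return a `glyco_reaction` record.
#' @export
reaction <- function(id, substrates, products, law) {
  stopifnot(inherits(law, "rate_law"))
  for (side in list(substrates, products)) {
    if (length(side) > 0L) {
      if (is.null(names(side)) || any(names(side) == "")) {
        stop("model-consistency error: stoichiometry must be a named vector",
             call. = FALSE)
      }
      if (any(side <= 0) || any(side != round(side))) {
        stop("model-consistency error: stoichiometric coefficients must be ",
             "positive integers", call. = FALSE)
      }
    }
  }
  structure(list(id = id, substrates = substrates, products = products,
                 rate_law = law), class = "glyco_reaction")
}

#' Assemble a pathway model
#'
#' Validates and assembles species, reactions and HIF-1 couplings into a
#' simulatable model. The state vector consists of all non-boundary species;
#' boundary species are held fixed. Enzyme species named in a coupling
#' follow `dE/dt = sign * K_Eh * [HIF-1]`; an optional PDK/PDP cycle governs
#' the active pyruvate dehydrogenase state
#' `dPDHA/dt = k_pdp * (total - PDHA) - k_pdk * E_PDK * PDHA`, so the
#' phosphorylated fraction is the derived complement `total - PDHA` and the
#' sum is conserved.
#'
#' @param species_list list of [species()] records.
#' @param reactions list of [reaction()] records.
#' @param couplings list of [hif_coupling()] records.
#' @param pdh_cycle `NULL`, or `list(active_id, pdk_id, k_pdk, k_pdp, total)`.
#' @param hif_level current HIF-1 concentration (uM); the forcing input,
#'   not a state.
#' @param oxygen_map optional [oxygen_hif_map()] used to translate oxygen
#'   scenarios into HIF-1 levels.
#' @return an object of class `glyco_model`.
#' @export
pathway_model <- function(species_list, reactions, couplings = list(),
                          pdh_cycle = NULL, hif_level = 0,
                          oxygen_map = NULL) {
  ids <- vapply(species_list, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop("model-consistency error: duplicated species id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  roles <- vapply(species_list, function(s) s$role, character(1))
  names(roles) <- ids
  state_ids <- ids[roles != "boundary"]
  boundary_ids <- ids[roles == "boundary"]

  check_ref <- function(ref, ctx) {
    unknown <- setdiff(ref, ids)
    if (length(unknown) > 0L) {
      stop("model-consistency error: unknown species '", unknown[1L],
           "' referenced by ", ctx, call. = FALSE)
    }
  }
  for (rx in reactions) {
    check_ref(names(rx$substrates), paste0("reaction '", rx$id, "'"))
    check_ref(names(rx$products), paste0("reaction '", rx$id, "'"))
    eid <- rx$rate_law$enzyme_id
    if (!is.na(eid)) {
      check_ref(eid, paste0("rate law of reaction '", rx$id, "'"))
      if (roles[[eid]] != "enzyme") {
        stop("model-consistency error: rate-law catalyst '", eid,
             "' of reaction '", rx$id, "' is not an enzyme species",
             call. = FALSE)
      }
    }
  }
  for (cp in couplings) {
    check_ref(cp$enzyme_id, "a HIF coupling")
    if (roles[[cp$enzyme_id]] != "enzyme") {
      stop("model-consistency error: HIF coupling target '", cp$enzyme_id,
           "' is not an enzyme species", call. = FALSE)
    }
  }
  if (!is.null(pdh_cycle)) {
    check_ref(c(pdh_cycle$active_id, pdh_cycle$pdk_id), "the PDH cycle")
  }
  if (!is.numeric(hif_level) || length(hif_level) != 1L || hif_level < 0) {
    stop("input-domain error: hif_level must be a single number >= 0",
         call. = FALSE)
  }

  initial <- vapply(species_list, function(s) s$initial_value, numeric(1))
  names(initial) <- ids

  model <- structure(list(
    species = species_list,
    reactions = reactions,
    couplings = couplings,
    pdh_cycle = pdh_cycle,
    hif_level = hif_level,
    oxygen_map = oxygen_map,
    species_ids = ids,
    roles = roles,
    state_ids = state_ids,
    boundary_ids = boundary_ids,
    initial = initial
  ), class = "glyco_model")
  model$compiled <- .compile_model(model)
  model
}

# Precompute index-based reaction bookkeeping for fast rhs evaluation.
.compile_model <- function(model) {
  ids <- model$species_ids
  idx <- seq_along(ids)
  names(idx) <- ids
  n_state <- length(model$state_ids)
  state_idx <- idx[model$state_ids]

  rx_list <- lapply(model$reactions, function(rx) {
    law <- rx$rate_law
    list(
      id = rx$id,
      kind = law$kind,
      par = law$parameters,
      enz = if (is.na(law$enzyme_id)) NA_integer_ else idx[[law$enzyme_id]],
      sub_i = unname(idx[names(rx$substrates)]),
      sub_c = unname(as.numeric(rx$substrates)),
      prod_i = unname(idx[names(rx$products)]),
      prod_c = unname(as.numeric(rx$products))
    )
  })
  coup <- model$couplings
  coup_idx <- vapply(coup, function(cp) idx[[cp$enzyme_id]], integer(1))
  coup_keh <- vapply(coup, function(cp) cp$K_Eh, numeric(1))
  coup_sign <- vapply(coup, function(cp) cp$sign, numeric(1))
  pdh <- model$pdh_cycle
  list(idx = idx, state_idx = state_idx, n_state = n_state,
       reactions = rx_list, coup_idx = coup_idx, coup_keh = coup_keh,
       coup_sign = coup_sign,
       pdh_active = if (is.null(pdh)) NA_integer_ else idx[[pdh$active_id]],
       pdh_pdk = if (is.null(pdh)) NA_integer_ else idx[[pdh$pdk_id]],
       pdh_par = if (is.null(pdh)) NULL else
         c(pdh$k_pdk, pdh$k_pdp, pdh$total))
}

# Rate of a single compiled reaction given the full species-value vector.
.reaction_rate <- function(rx, v) {
  level <- if (is.na(rx$enz)) 1 else max(v[rx$enz], 0)
  p <- rx$par
  switch(rx$kind,
    irreversible_mm = {
      S <- v[rx$sub_i[1L]]
      level * p[["Vmax"]] * S / (p[["Km"]] + S)
    },
    reversible_mm = {
      S <- v[rx$sub_i[1L]]
      P <- v[rx$prod_i[1L]]
      sKs <- S / p[["Ks"]]
      pKp <- P / p[["Kp"]]
      level * (p[["Vf"]] * sKs - p[["Vr"]] * pKp) / (1 + sKs + pKp)
    },
    mass_action = level * p[["k"]] * prod(v[rx$sub_i]^rx$sub_c),
    first_order = level * p[["k"]] * v[rx$sub_i[1L]]
  )
}

#' Evaluate the ODE right-hand side of a pathway model
#'
#' For each metabolite the derivative is the stoichiometry-weighted sum of
#' its producing reaction rates minus its consuming reaction rates; for each
#' HIF-coupled enzyme it is the mass-action drift `sign * K_Eh * [HIF-1]`;
#' for the active pyruvate dehydrogenase state it is the PDP reactivation
#' minus the PDK-level-scaled inactivation. State entries are clipped at
#' zero before rate evaluation.
#'
#' @param model a `glyco_model`.
#' @param state numeric state vector in the order of `model$state_ids`.
#' @param t time in minutes (the system is autonomous under constant HIF-1
#'   forcing; `t` is accepted for solver compatibility).
#' @param hif HIF-1 forcing (uM); defaults to `model$hif_level`.
#' @return named derivative vector (mM/min for metabolites, level/min for
#'   enzyme states).
#' @export
pathway_rhs <- function(model, state, t = 0, hif = model$hif_level) {
  cm <- model$compiled
  if (length(state) != cm$n_state) {
    stop("state-shape error: expected ", cm$n_state, " states, got ",
         length(state), call. = FALSE)
  }
  v <- model$initial
  v[cm$state_idx] <- pmax(as.numeric(state), 0)
  dv <- numeric(length(v))
  for (rx in cm$reactions) {
    r <- .reaction_rate(rx, v)
    dv[rx$sub_i] <- dv[rx$sub_i] - rx$sub_c * r
    dv[rx$prod_i] <- dv[rx$prod_i] + rx$prod_c * r
  }
  # HIF-coupled enzyme levels are forced, not produced by reactions.
  if (length(cm$coup_idx) > 0L) {
    dv[cm$coup_idx] <- cm$coup_sign * cm$coup_keh * hif
  }
  if (!is.na(cm$pdh_active)) {
    pp <- cm$pdh_par  # k_pdk, k_pdp, total
    a <- v[cm$pdh_active]
    dv[cm$pdh_active] <- pp[2L] * (pp[3L] - a) - pp[1L] * v[cm$pdh_pdk] * a
  }
  out <- dv[cm$state_idx]
  names(out) <- model$state_ids
  out
}

#' Build the reference 26-state glycolysis model
#'
#' Assembles the pathway topology — glucose uptake, the glycolytic chain
#' down to pyruvate, the pyruvate branch point (lactate dehydrogenase vs.
#' pyruvate dehydrogenase), the pentose-phosphate drain on glucose
#' 6-phosphate, the glycogenolysis entry through phosphoglucomutase, a
#' glycerol-phosphate shunt on dihydroxyacetone phosphate, and first-order
#' export/consumption sinks for lactate and acetyl-CoA — and wires twelve
#' HIF-1 couplings (GLUT, HK, PGI, PFK-1, TPI, GAPDH, PGK, PGM, ENO, PDK,
#' LDH, PGCM) plus the PDK/PDP cycle on active pyruvate dehydrogenase.
#' All constants and initial values are taken from `params`.
#'
#' The assembled model has exactly 26 state variables (13 metabolites and
#' 13 enzyme states); extracellular glucose, the glucose 1-phosphate pool
#' and the pathway sinks are fixed boundary species.
#'
#' @param params a [parameter_set()] supplying every constant and initial
#'   value the reference topology requires; missing entries raise a
#'   named-parameter error.
#' @return a `glyco_model`.
#' @export
build_reference_model <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  p <- function(id, parameter) ps_value(params, "reaction", id, parameter)

  sp <- list()
  for (id in .metabolite_ids) {
    sp[[id]] <- species(id, .metabolite_names[[id]], "metabolite",
                        ps_value(params, "species", id, "initial"))
  }
  for (id in c(.coupled_enzyme_ids, "PDHA")) {
    sp[[id]] <- species(id, .enzyme_names[[id]], "enzyme",
                        ps_value(params, "species", id, "initial"))
  }
  for (id in .boundary_ids) {
    val <- if (ps_has(params, "boundary", id, "value")) {
      ps_value(params, "boundary", id, "value")
    } else 0
    sp[[id]] <- species(id, id, "boundary", val)
  }

  irr <- function(id, from, to, enzyme = NA_character_) {
    reaction(id, stats::setNames(1L, from), stats::setNames(1L, to),
             rate_law("irreversible_mm",
                      c(Vmax = p(id, "Vmax"), Km = p(id, "Km")), enzyme))
  }
  rev <- function(id, from, to, enzyme = NA_character_) {
    reaction(id, stats::setNames(1L, from), stats::setNames(1L, to),
             rate_law("reversible_mm",
                      c(Vf = p(id, "Vf"), Ks = p(id, "Ks"),
                        Vr = p(id, "Vr"), Kp = p(id, "Kp")), enzyme))
  }
  fo <- function(id, from, to) {
    reaction(id, stats::setNames(1L, from), stats::setNames(1L, to),
             rate_law("first_order", c(k = p(id, "k"))))
  }

  rxs <- list(
    rev("GLUT", "GLC_EXT", "GLC", "GLUT"),
    irr("HK", "GLC", "G6P", "HK"),
    irr("PGCM", "G1P", "G6P", "PGCM"),
    irr("PPP", "G6P", "PPP_SINK"),           # G6PDH level constant
    rev("PGI", "G6P", "F6P", "PGI"),
    irr("PFK1", "F6P", "FBP", "PFK1"),
    # Aldolase: FBP <-> GA3P + DHAP; the reversible law uses GA3P as the
    # product-side ligand, DHAP is carried by stoichiometry only.
    reaction("ALDO", c(FBP = 1L), c(GA3P = 1L, DHAP = 1L),
             rate_law("reversible_mm",
                      c(Vf = p("ALDO", "Vf"), Ks = p("ALDO", "Ks"),
                        Vr = p("ALDO", "Vr"), Kp = p("ALDO", "Kp")))),
    rev("TPI", "DHAP", "GA3P", "TPI"),
    fo("G3PS", "DHAP", "GLYC_SINK"),         # glycerol-phosphate shunt
    rev("GAPDH", "GA3P", "BPG13", "GAPDH"),
    rev("PGK", "BPG13", "PG3", "PGK"),
    rev("PGM", "PG3", "PG2", "PGM"),
    rev("ENO", "PG2", "PEP", "ENO"),
    irr("PK", "PEP", "PYR"),                 # pyruvate kinase constant
    rev("LDH", "PYR", "LAC", "LDH"),
    irr("PDH", "PYR", "ACCOA", "PDHA"),
    fo("LACX", "LAC", "LAC_EXT"),
    fo("ACOX", "ACCOA", "TCA_SINK")
  )

  coup <- lapply(.coupled_enzyme_ids, function(id) {
    sgn <- if (ps_has(params, "coupling", id, "sign")) {
      ps_value(params, "coupling", id, "sign")
    } else 1
    hif_coupling(id, ps_value(params, "coupling", id, "K_Eh"),
                 sign = if (sgn >= 0) 1 else -1)
  })

  pdh_cycle <- list(
    active_id = "PDHA", pdk_id = "PDK",
    k_pdk = ps_value(params, "pdh_cycle", "PDH", "k_pdk"),
    k_pdp = ps_value(params, "pdh_cycle", "PDH", "k_pdp"),
    total = ps_value(params, "pdh_cycle", "PDH", "total"))

  map <- oxygen_hif_map(
    H_max = ps_value(params, "oxygen_map", "map", "H_max"),
    H_basal = ps_value(params, "oxygen_map", "map", "H_basal"),
    o2_half = ps_value(params, "oxygen_map", "map", "o2_half"),
    hill_n = ps_value(params, "oxygen_map", "map", "hill_n"))

  model <- pathway_model(sp, rxs, coup, pdh_cycle = pdh_cycle,
                         hif_level = 0, oxygen_map = map)
  model$params <- params
  model
}

#' @export
print.glyco_model <- function(x, ...) {
  cat("<glyco_model> HIF-1 coupled glycolysis pathway\n")
  cat("  state variables: ", length(x$state_ids), " (",
      sum(x$roles[x$state_ids] == "metabolite"), " metabolites, ",
      sum(x$roles[x$state_ids] == "enzyme"), " enzyme states)\n", sep = "")
  cat("  boundary species: ", length(x$boundary_ids), "\n", sep = "")
  cat("  reactions: ", length(x$reactions), "; HIF-1 couplings: ",
      length(x$couplings), "\n", sep = "")
  cat("  HIF-1 forcing: ", format(x$hif_level), " uM\n", sep = "")
  invisible(x)
}

#' @export
summary.glyco_model <- function(object, ...) {
  cat("HIF-1 coupled glycolysis model\n\n")
  print(object)
  cat("\nHIF-1 couplings (dE/dt = sign * K_Eh * [HIF-1]):\n")
  cp <- data.frame(
    enzyme = vapply(object$couplings, function(c) c$enzyme_id, character(1)),
    K_Eh = vapply(object$couplings, function(c) c$K_Eh, numeric(1)),
    sign = vapply(object$couplings, function(c) c$sign, numeric(1)))
  print(cp, row.names = FALSE)
  if (!is.null(object$pdh_cycle)) {
    pc <- object$pdh_cycle
    cat(sprintf("\nPDK/PDP cycle: k_pdk = %g /min per PDK level, k_pdp = %g /min, total PDH = %g\n",
                pc$k_pdk, pc$k_pdp, pc$total))
  }
  invisible(object)
}

#' @export
coef.glyco_model <- function(object, ...) {
  out <- list()
  for (rx in object$reactions) {
    pars <- rx$rate_law$parameters
    names(pars) <- paste(rx$id, names(pars), sep = ".")
    out[[rx$id]] <- pars
  }
  keh <- vapply(object$couplings, function(c) c$K_Eh, numeric(1))
  names(keh) <- paste0("K_Eh.", vapply(object$couplings,
                                       function(c) c$enzyme_id, character(1)))
  c(unlist(unname(out)), keh)
}
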