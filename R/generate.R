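# Synthetic parameter-set generation. The generator stands in for a
# published table of initial conditions and kinetic constants: it fixes a
# physiologically plausible normoxic operating point (metabolite
# concentrations and a consistent flux distribution) and solves each
# reaction's limiting rates so that the operating point is an exact steady
# state of the assembled ODE system. Kinetic constants and HIF-1 induction
# constants can be jittered/drawn at random (log-uniformly, seeded) to
# produce families of plausible parameterizations.

# Normoxic operating concentrations (mM); lactate is set by the generator
# target.
.design_conc <- c(GLC = 1.0, G6P = 0.5, F6P = 0.15, FBP = 0.3, DHAP = 0.15,
                  GA3P = 0.06, BPG13 = 0.06, PG3 = 0.4, PG2 = 0.06,
                  PEP = 0.12, PYR = 0.1, ACCOA = 0.06)

.design_boundary <- c(GLC_EXT = 5.0, G1P = 0.1)

# Half-saturation constants (mM) and the reverse/forward disequilibrium
# ratio r = (Vr*P/Kp)/(Vf*S/Ks) at the operating point for reversible steps.
# r close to 1 puts a step near equilibrium (little flux control by its
# enzyme, strong transmission of downstream pulls); r close to 0 makes the
# step effectively irreversible.
.design_rev <- list(
  GLUT = c(Ks = 0.3, Kp = 20, r = 0.02),
  PGI = c(Ks = 0.6, Kp = 0.2, r = 0.65),
  ALDO = c(Ks = 0.5, Kp = 0.1, r = 0.90),
  TPI = c(Ks = 0.02, Kp = 0.015, r = 0.85),
  GAPDH = c(Ks = 0.25, Kp = 2.0, r = 0.05),
  PGK = c(Ks = 0.3, Kp = 2.0, r = 0.10),
  PGM = c(Ks = 1.2, Kp = 0.3, r = 0.15),
  ENO = c(Ks = 0.25, Kp = 0.6, r = 0.15),
  LDH = c(Ks = 0.3, Kp = 10, r = 0.30))

.design_irr <- c(HK = 1.0, PGCM = 0.05, PPP = 5.0, PFK1 = 1.0, PK = 1.5,
                 PDH = 0.01)

# Default HIF-1 induction constants, level/(uM*min). Expressed through the
# fractional enzyme-level rise after 30 min of severe hypoxia at the default
# H_max = 1 uM: e = K_Eh * 30. These defaults are the calibration starting
# point; the shipped fixture refines them (see calibrate_reference_fixture).
.design_keh30 <- c(GLUT = 0.0005, HK = 0.03, PGI = 0.08, PFK1 = 0.05,
                   TPI = 0.09, GAPDH = 0.04, PGK = 0.095, PGM = 0.045,
                   ENO = 0.045, PDK = 0.012, LDH = 0.09, PGCM = 0.05)

#' Specification for the synthetic parameter generator
#'
#' @param seed integer RNG seed; identical seed and spec give an identical
#'   parameter set.
#' @param target_lactate normoxic steady-state lactate (mM); the plateau
#'   value of the lactate-oxygen curve at and above 6% oxygen.
#' @param lactate_turnover first-order lactate export constant (1/min);
#'   sets the intracellular lactate residence time and thereby how quickly
#'   lactate tracks a flux perturbation.
#' @param pdh_flux normoxic flux through pyruvate dehydrogenase (mM/min).
#' @param ppp_flux normoxic pentose-phosphate drain on G6P (mM/min).
#' @param glycogenolysis_flux normoxic phosphoglucomutase flux from the
#'   glucose 1-phosphate pool into G6P (mM/min).
#' @param shunt_flux normoxic glycerol-phosphate drain on DHAP (mM/min).
#' @param km_jitter multiplicative log-uniform jitter half-range applied to
#'   all half-saturation constants (1 = none; 2 = factors in [1/2, 2]).
#' @param conc_jitter same, for the operating metabolite concentrations.
#' @param randomize_keh draw the twelve `K_Eh` log-uniformly from
#'   `keh_range` instead of using the calibration defaults.
#' @param keh_range range for the `K_Eh` draw, level/(uM*min).
#' @param ss_tol maximal steady-state residual accepted by the generator.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 42L, target_lactate = 5.66,
                           lactate_turnover = 0.6, pdh_flux = 3.4,
                           ppp_flux = 2.6, glycogenolysis_flux = 1.2,
                           shunt_flux = 1.6, km_jitter = 1, conc_jitter = 1,
                           randomize_keh = FALSE,
                           keh_range = c(1e-3, 1e-1), ss_tol = 1e-8) {
  stopifnot(target_lactate > 0, lactate_turnover > 0, pdh_flux > 0,
            ppp_flux > 0, glycogenolysis_flux > 0, shunt_flux > 0,
            km_jitter >= 1, conc_jitter >= 1,
            length(keh_range) == 2L, keh_range[1L] > 0,
            keh_range[1L] < keh_range[2L], ss_tol > 0)
  structure(list(seed = as.integer(seed), target_lactate = target_lactate,
                 lactate_turnover = lactate_turnover, pdh_flux = pdh_flux,
                 ppp_flux = ppp_flux,
                 glycogenolysis_flux = glycogenolysis_flux,
                 shunt_flux = shunt_flux, km_jitter = km_jitter,
                 conc_jitter = conc_jitter, randomize_keh = randomize_keh,
                 keh_range = keh_range, ss_tol = ss_tol),
            class = "generator_spec")
}

.lu <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Generate a parameter set at an exact normoxic steady state
#'
#' Draws (or takes from the design defaults) metabolite operating
#' concentrations and half-saturation constants, lays out a consistent
#' normoxic flux distribution over the pathway, and solves every reaction's
#' limiting rate(s) and every sink constant so that the operating point is
#' an exact root of the ODE right-hand side with the target baseline
#' lactate. The result always builds a valid 26-state reference model whose
#' normoxic simulation stays at its initial state.
#'
#' @param spec a [generator_spec()].
#' @return a [parameter_set()]; deterministic given `spec`.
#' @export
generate_parameters <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)

  conc <- .design_conc
  if (spec$conc_jitter > 1) {
    conc <- conc * .lu(length(conc), 1 / spec$conc_jitter, spec$conc_jitter)
  }
  conc <- c(conc, LAC = spec$target_lactate)
  bnd <- .design_boundary

  rev_des <- .design_rev
  irr_km <- .design_irr
  if (spec$km_jitter > 1) {
    for (id in names(rev_des)) {
      rev_des[[id]][c("Ks", "Kp")] <- rev_des[[id]][c("Ks", "Kp")] *
        .lu(2, 1 / spec$km_jitter, spec$km_jitter)
    }
    irr_km <- irr_km * .lu(length(irr_km), 1 / spec$km_jitter,
                           spec$km_jitter)
  }

  keh <- .design_keh30 / 30
  if (spec$randomize_keh) {
    keh[] <- .lu(length(keh), spec$keh_range[1L], spec$keh_range[2L])
  }

  # Consistent normoxic flux layout (mM/min). Triose-unit flux through the
  # lower chain is the lactate export plus the PDH flux; aldolase supplies
  # it together with the glycerol-phosphate shunt.
  J_ldh <- spec$lactate_turnover * spec$target_lactate
  J_low <- J_ldh + spec$pdh_flux
  if (J_low <= spec$shunt_flux) {
    stop("generation error: shunt_flux must be smaller than the lower-chain",
         " flux", call. = FALSE)
  }
  J_aldo <- (J_low + spec$shunt_flux) / 2
  J_tpi <- J_aldo - spec$shunt_flux
  J_hk <- J_aldo + spec$ppp_flux - spec$glycogenolysis_flux
  if (J_hk <= 0) {
    stop("generation error: glycogenolysis_flux exceeds the glucose demand",
         call. = FALSE)
  }
  flux <- c(GLUT = J_hk, HK = J_hk, PGCM = spec$glycogenolysis_flux,
            PPP = spec$ppp_flux, PGI = J_aldo, PFK1 = J_aldo,
            ALDO = J_aldo, TPI = J_tpi, GAPDH = J_low, PGK = J_low,
            PGM = J_low, ENO = J_low, PK = J_low, LDH = J_ldh,
            PDH = spec$pdh_flux)

  # Ligand pairs of each reaction at the operating point.
  SP <- list(GLUT = c("GLC_EXT", "GLC"), HK = c("GLC", "G6P"),
             PGCM = c("G1P", "G6P"), PPP = c("G6P", NA),
             PGI = c("G6P", "F6P"), PFK1 = c("F6P", "FBP"),
             ALDO = c("FBP", "GA3P"), TPI = c("DHAP", "GA3P"),
             GAPDH = c("GA3P", "BPG13"), PGK = c("BPG13", "PG3"),
             PGM = c("PG3", "PG2"), ENO = c("PG2", "PEP"),
             PK = c("PEP", "PYR"), LDH = c("PYR", "LAC"),
             PDH = c("PYR", "ACCOA"))
  val <- c(conc, bnd)

  rows <- list()
  add <- function(scope, id, parameter, value, unit, provenance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scope = scope, id = id, parameter = parameter, value = value,
      unit = unit, provenance = provenance, stringsAsFactors = FALSE)
  }

  for (id in names(flux)) {
    S <- val[[SP[[id]][1L]]]
    if (id %in% names(rev_des)) {
      d <- rev_des[[id]]
      P <- val[[SP[[id]][2L]]]
      D <- 1 + S / d[["Ks"]] + P / d[["Kp"]]
      Fwd <- flux[[id]] * D / (1 - d[["r"]])
      add("reaction", id, "Vf", Fwd * d[["Ks"]] / S, "mM/min", "calibrated")
      add("reaction", id, "Ks", d[["Ks"]], "mM", "database")
      add("reaction", id, "Vr", d[["r"]] * Fwd * d[["Kp"]] / P, "mM/min",
          "calibrated")
      add("reaction", id, "Kp", d[["Kp"]], "mM", "database")
    } else {
      Km <- irr_km[[id]]
      add("reaction", id, "Vmax", flux[[id]] * (Km + S) / S, "mM/min",
          "calibrated")
      add("reaction", id, "Km", Km, "mM", "database")
    }
  }
  add("reaction", "LACX", "k", spec$lactate_turnover, "1/min", "calibrated")
  add("reaction", "ACOX", "k", spec$pdh_flux / conc[["ACCOA"]], "1/min",
      "calibrated")
  add("reaction", "G3PS", "k", spec$shunt_flux / conc[["DHAP"]], "1/min",
      "calibrated")

  for (id in names(conc)) {
    add("species", id, "initial", conc[[id]], "mM", "literature")
  }
  for (id in .coupled_enzyme_ids) {
    add("species", id, "initial", 1, "level", "literature")
  }
  add("species", "PDHA", "initial", 1, "level", "literature")
  for (id in names(bnd)) add("boundary", id, "value", bnd[[id]], "mM",
                             "literature")
  for (id in c("PPP_SINK", "GLYC_SINK", "TCA_SINK", "LAC_EXT")) {
    add("boundary", id, "value", 0, "mM", "literature")
  }
  for (id in names(keh)) {
    add("coupling", id, "K_Eh", keh[[id]], "level/(uM*min)", "calibrated")
    add("coupling", id, "sign", 1, "dimensionless", "literature")
  }
  # PDK/PDP cycle; the total is solved so that active PDH = 1 is its
  # normoxic fixed point at PDK level 1.
  k_pdk <- 1.0
  k_pdp <- 0.5
  add("pdh_cycle", "PDH", "k_pdk", k_pdk, "1/min", "database")
  add("pdh_cycle", "PDH", "k_pdp", k_pdp, "1/min", "database")
  add("pdh_cycle", "PDH", "total", 1 + k_pdk / k_pdp, "level", "calibrated")

  add("oxygen_map", "map", "H_max", 1.0, "uM", "calibrated")
  add("oxygen_map", "map", "H_basal", 0.0, "uM", "calibrated")
  add("oxygen_map", "map", "o2_half", 1.2, "percent", "calibrated")
  add("oxygen_map", "map", "hill_n", 2.8, "dimensionless", "calibrated")

  ps <- parameter_set(do.call(rbind, rows))
  model <- build_reference_model(ps)
  res <- max(abs(pathway_rhs(model, model$initial[model$state_ids],
                             hif = 0)))
  if (res > spec$ss_tol) {
    stop("generation error: steady-state residual ", format(res),
         " exceeds ss_tol = ", format(spec$ss_tol), call. = FALSE)
  }
  ps
}

#' Recover HIF-1 induction constants from enzyme trajectories
#'
#' Under constant HIF-1 forcing each coupled enzyme level follows the
#' closed form `E(t) = E(0) + sign * K_Eh * hif * t`; the induction
#' constant is therefore the least-squares slope of the trajectory divided
#' by the HIF-1 level. On noiseless simulated trajectories this recovers
#' the generating constants to numerical precision.
#'
#' @param sim a `glyco_sim` from a constant-HIF scenario with `hif > 0`.
#' @param enzymes enzyme ids; default: all enzyme states in the result
#'   except the PDK/PDP-governed active PDH.
#' @return named vector of estimated `K_Eh` in level/(uM*min).
#' @export
estimate_keh <- function(sim, enzymes = NULL) {
  stopifnot(inherits(sim, "glyco_sim"))
  if (is.na(sim$hif_uM) || sim$hif_uM <= 0) {
    stop("input-domain error: K_Eh recovery requires a scenario with ",
         "hif > 0", call. = FALSE)
  }
  if (is.null(enzymes)) {
    enzymes <- intersect(.coupled_enzyme_ids, sim$species_ids)
  }
  tt <- sim$times - mean(sim$times)
  vapply(enzymes, function(e) {
    y <- sim$states[, e]
    sum(tt * (y - mean(y))) / sum(tt * tt) / sim$hif_uM
  }, numeric(1))
}
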