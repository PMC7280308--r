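# Shared fixtures: cached reference model/simulations and an independent
# brute-force rhs oracle used to cross-check the packaged implementation.

.cache <- new.env(parent = emptyenv())

ref_params <- function() {
  if (is.null(.cache$ps)) .cache$ps <- reference_parameters()
  .cache$ps
}

ref_model <- function() {
  if (is.null(.cache$model)) .cache$model <- build_reference_model(ref_params())
  .cache$model
}

ref_run <- function(o2) {
  key <- paste0("run_", o2)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- run_scenario(ref_model(),
                                  hypoxia_scenario(o2_percent = o2))
  }
  .cache[[key]]
}

# Independent stoichiometry oracle: accumulates each species derivative by
# looping over reactions and evaluating each rate law from first
# principles, without touching the package's compiled bookkeeping.
brute_force_rhs <- function(model, state, hif = model$hif_level) {
  vals <- model$initial
  vals[model$state_ids] <- pmax(state, 0)
  dv <- setNames(numeric(length(vals)), names(vals))
  for (rx in model$reactions) {
    law <- rx$rate_law
    p <- law$parameters
    lvl <- if (is.na(law$enzyme_id)) 1 else max(vals[[law$enzyme_id]], 0)
    S <- vals[[names(rx$substrates)[1L]]]
    rate <- switch(law$kind,
      irreversible_mm = lvl * p[["Vmax"]] * S / (p[["Km"]] + S),
      reversible_mm = {
        P <- vals[[names(rx$products)[1L]]]
        lvl * (p[["Vf"]] * S / p[["Ks"]] - p[["Vr"]] * P / p[["Kp"]]) /
          (1 + S / p[["Ks"]] + P / p[["Kp"]])
      },
      first_order = lvl * p[["k"]] * S,
      mass_action = {
        prodS <- 1
        for (i in seq_along(rx$substrates)) {
          prodS <- prodS * vals[[names(rx$substrates)[i]]]^rx$substrates[[i]]
        }
        lvl * p[["k"]] * prodS
      })
    for (i in seq_along(rx$substrates)) {
      id <- names(rx$substrates)[i]
      dv[[id]] <- dv[[id]] - rx$substrates[[i]] * rate
    }
    for (i in seq_along(rx$products)) {
      id <- names(rx$products)[i]
      dv[[id]] <- dv[[id]] + rx$products[[i]] * rate
    }
  }
  for (cp in model$couplings) {
    dv[[cp$enzyme_id]] <- cp$sign * cp$K_Eh * hif
  }
  if (!is.null(model$pdh_cycle)) {
    pc <- model$pdh_cycle
    a <- vals[[pc$active_id]]
    dv[[pc$active_id]] <- pc$k_pdp * (pc$total - a) -
      pc$k_pdk * vals[[pc$pdk_id]] * a
  }
  dv[model$state_ids]
}

# Small random pathway models exercising every rate-law kind.
random_small_model <- function(seed) {
  set.seed(seed)
  n_met <- sample(3:5, 1)
  mets <- paste0("M", seq_len(n_met))
  sp <- lapply(mets, function(id) species(id, role = "metabolite",
                                          initial_value = runif(1, 0.1, 2)))
  sp <- c(sp, list(species("E1", role = "enzyme", initial_value = 1),
                   species("X", role = "boundary",
                           initial_value = runif(1, 1, 5))))
  ids <- c(mets, "X")
  rxs <- list(
    reaction("inflow", c(X = 1L), setNames(1L, mets[1]),
             rate_law("irreversible_mm",
                      c(Vmax = runif(1, 0.5, 2), Km = runif(1, 0.2, 1)),
                      "E1")),
    reaction("conv", setNames(1L, mets[1]), setNames(1L, mets[2]),
             rate_law("reversible_mm",
                      c(Vf = runif(1, 0.5, 2), Ks = runif(1, 0.2, 1),
                        Vr = runif(1, 0.1, 0.5), Kp = runif(1, 0.2, 1)))),
    reaction("join", setNames(c(1L, 2L), mets[1:2]),
             setNames(1L, mets[n_met]),
             rate_law("mass_action", c(k = runif(1, 0.1, 1)))),
    reaction("drain", setNames(1L, mets[n_met]), c(X = 1L),
             rate_law("first_order", c(k = runif(1, 0.1, 1)))))
  coup <- list(hif_coupling("E1", K_Eh = runif(1, 0.001, 0.05)))
  pathway_model(sp, rxs, coup, hif_level = runif(1, 0, 2))
}
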