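# Scenario definition and stiff ODE integration of the pathway model.
# A scenario applies a constant HIF-1 forcing (step hypoxia), either given
# directly in uM or derived from an oxygen percentage through the model's
# oxygen map, and integrates the 26 ODEs over the scenario duration.

#' Define a hypoxia scenario
#'
#' Exactly one of `o2_percent` and `hif_uM` must be given; the forcing is
#' held constant for the whole scenario (step hypoxia).
#'
#' @param o2_percent ambient oxygen percentage in `[0, 21]`.
#' @param hif_uM HIF-1 concentration in uM, >= 0.
#' @param duration simulation horizon in minutes (> 0).
#' @param dt output-grid resolution in minutes; ignored when `times` is
#'   supplied.
#' @param times optional explicit output grid (sorted, within
#'   `[0, duration]`).
#' @return an object of class `hypoxia_scenario`.
#' @export
hypoxia_scenario <- function(o2_percent = NULL, hif_uM = NULL,
                             duration = 30, dt = 0.1, times = NULL) {
  if (is.null(o2_percent) == is.null(hif_uM)) {
    stop("input-domain error: exactly one of o2_percent and hif_uM must be ",
         "set", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("input-domain error: duration must be > 0", call. = FALSE)
  }
  if (!is.null(hif_uM) && (!is.numeric(hif_uM) || hif_uM < 0)) {
    stop("input-domain error: hif_uM must be >= 0", call. = FALSE)
  }
  if (!is.null(o2_percent) &&
      (!is.numeric(o2_percent) || o2_percent < 0 || o2_percent > 21)) {
    stop("input-domain error: o2_percent must lie in [0, 21]", call. = FALSE)
  }
  if (is.null(times)) {
    times <- seq(0, duration, by = dt)
    if (times[length(times)] < duration) times <- c(times, duration)
  } else {
    if (is.unsorted(times, strictly = TRUE) || times[1L] < 0 ||
        times[length(times)] > duration) {
      stop("input-domain error: times must be strictly increasing within ",
           "[0, duration]", call. = FALSE)
    }
  }
  structure(list(o2_percent = o2_percent, hif_uM = hif_uM,
                 duration = duration, times = times),
            class = "hypoxia_scenario")
}

#' @export
print.hypoxia_scenario <- function(x, ...) {
  forcing <- if (!is.null(x$hif_uM)) {
    sprintf("HIF-1 = %g uM", x$hif_uM)
  } else {
    sprintf("O2 = %g%%", x$o2_percent)
  }
  cat(sprintf("<hypoxia_scenario> %s, duration %g min, %d output points\n",
              forcing, x$duration, length(x$times)))
  invisible(x)
}

# Resolve the constant HIF-1 forcing of a scenario against a model.
scenario_hif <- function(model, scenario) {
  if (!is.null(scenario$hif_uM)) return(scenario$hif_uM)
  if (is.null(model$oxygen_map)) {
    stop("input-domain error: scenario given as o2_percent but the model ",
         "carries no oxygen_hif_map", call. = FALSE)
  }
  o2_to_hif(model$oxygen_map, scenario$o2_percent)
}

#' Integrate a hypoxia scenario
#'
#' Integrates the model ODEs from the model's initial conditions under the
#' scenario's constant HIF-1 forcing with a stiff-capable adaptive solver
#' (relative tolerance 1e-8, absolute tolerance 1e-10 by default).
#'
#' @param model a `glyco_model` (see [build_reference_model()]).
#' @param scenario a [hypoxia_scenario()].
#' @param rtol,atol solver tolerances.
#' @param method a `deSolve` integration method; the default `"lsoda"`
#'   switches automatically between stiff and non-stiff regimes.
#' @return an object of class `glyco_sim` with fields `times` (min),
#'   `states` (time x species matrix, mM or level), `species_ids`,
#'   `scenario`, `hif_uM` and `solver_stats`.
#' @export
run_scenario <- function(model, scenario, rtol = 1e-8, atol = 1e-10,
                         method = "lsoda") {
  stopifnot(inherits(model, "glyco_model"),
            inherits(scenario, "hypoxia_scenario"))
  hif <- scenario_hif(model, scenario)
  y0 <- model$initial[model$state_ids]
  func <- function(t, y, parms) list(pathway_rhs(model, y, t, hif = hif))
  sol <- deSolve::ode(y = y0, times = scenario$times, func = func,
                      parms = NULL, method = method, rtol = rtol,
                      atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1L] < 0) {
    stop("solver error: integration failed at t = ",
         format(sol[nrow(sol), 1L]), " min", call. = FALSE)
  }
  states <- unclass(sol)[, -1L, drop = FALSE]
  if (min(states) < -1e-9) {
    warning("negative concentrations beyond -1e-9 in solution (min = ",
            format(min(states)), ")")
  }
  diag <- attr(sol, "istate")
  structure(list(times = as.numeric(sol[, 1L]), states = states,
                 species_ids = colnames(states), scenario = scenario,
                 hif_uM = hif,
                 solver_stats = list(method = method, rtol = rtol,
                                     atol = atol, n_steps = diag[3L],
                                     n_rhs = diag[4L])),
            class = "glyco_sim")
}

#' Run a family of constant-HIF scenarios
#'
#' Convenience batch for trajectory families across HIF-1 levels.
#'
#' @param model a `glyco_model`.
#' @param hif_levels nonnegative, nondecreasing HIF-1 concentrations (uM).
#' @param duration horizon in minutes.
#' @param dt output resolution in minutes.
#' @param ... passed to [run_scenario()].
#' @return a list with one `glyco_sim` per level, named by level.
#' @export
run_hif_grid <- function(model, hif_levels, duration = 30, dt = 0.1, ...) {
  if (length(hif_levels) == 0L) return(list())
  if (any(hif_levels < 0) || is.unsorted(hif_levels)) {
    stop("input-domain error: hif_levels must be nonnegative and sorted",
         call. = FALSE)
  }
  out <- lapply(hif_levels, function(h) {
    run_scenario(model, hypoxia_scenario(hif_uM = h, duration = duration,
                                         dt = dt), ...)
  })
  names(out) <- as.character(hif_levels)
  out
}

#' Simulate method for the glycolysis model
#'
#' `simulate()` on a `glyco_model` integrates one hypoxia scenario (the
#' model is deterministic; `nsim` and `seed` are accepted for generic
#' compatibility and must be left at their defaults).
#'
#' @param object a `glyco_model`.
#' @param nsim number of simulations (must be 1; the model is deterministic).
#' @param seed ignored.
#' @param scenario a [hypoxia_scenario()]; defaults to normoxia for 30 min.
#' @param ... passed to [run_scenario()].
#' @return a `glyco_sim`.
#' @export
simulate.glyco_model <- function(object, nsim = 1, seed = NULL,
                                 scenario = hypoxia_scenario(o2_percent = 21),
                                 ...) {
  if (nsim != 1) {
    stop("input-domain error: the model is deterministic; nsim must be 1",
         call. = FALSE)
  }
  run_scenario(object, scenario, ...)
}

#' @export
print.glyco_sim <- function(x, ...) {
  cat("<glyco_sim> ", length(x$times), " time points over ",
      format(max(x$times)), " min, ", ncol(x$states), " states\n", sep = "")
  cat("  forcing: HIF-1 = ", format(x$hif_uM), " uM",
      if (!is.null(x$scenario$o2_percent)) {
        sprintf(" (O2 = %g%%)", x$scenario$o2_percent)
      } else "", "\n", sep = "")
  if ("LAC" %in% x$species_ids) {
    cat(sprintf("  lactate: %.4f mM at t = 0, %.4f mM at t = %g min\n",
                x$states[1L, "LAC"], x$states[nrow(x$states), "LAC"],
                max(x$times)))
  }
  invisible(x)
}

#' @export
as.data.frame.glyco_sim <- function(x, ..., long = FALSE) {
  wide <- data.frame(time = x$times, x$states, check.names = FALSE)
  if (!long) return(wide)
  data.frame(
    time = rep(x$times, times = ncol(x$states)),
    species = rep(x$species_ids, each = length(x$times)),
    value = as.vector(x$states),
    stringsAsFactors = FALSE)
}

#' State value at a time point, by linear interpolation on the output grid.
#' @param sim a `glyco_sim`.
#' @param species species id.
#' @param t time in minutes.
#' @return interpolated value.
#' @export
state_at <- function(sim, species, t) {
  stopifnot(inherits(sim, "glyco_sim"), species %in% sim$species_ids)
  stats::approx(sim$times, sim$states[, species], xout = t, rule = 2)$y
}

#' Plot a simulated trajectory
#'
#' @param x a `glyco_sim`.
#' @param species character vector of species to draw (default: lactate).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.glyco_sim <- function(x, species = "LAC", ...) {
  stopifnot(all(species %in% x$species_ids))
  graphics::matplot(x$times, x$states[, species, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (min)",
                    ylab = "concentration (mM) / level", ...)
  if (length(species) > 1L) {
    graphics::legend("topleft", legend = species, lty = 1,
                     col = seq_along(species), bty = "n")
  }
  invisible(x)
}

#' Write a simulation result to CSV
#'
#' @param sim a `glyco_sim`.
#' @param path output path.
#' @param long write the tidy `(time, species, value)` layout instead of the
#'   wide time-by-species layout.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path, long = FALSE) {
  df <- as.data.frame(sim, long = long)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(df), list(sep = ","))), con)
  invisible(path)
}

#' Read back a wide-format simulation CSV
#'
#' @param path CSV written by [write_simulation()] (wide layout).
#' @return a `glyco_sim` carrying times and states (scenario metadata is
#'   not stored in the CSV and is left `NULL`).
#' @export
read_simulation <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(list(times = df$time,
                 states = as.matrix(df[, -1L, drop = FALSE]),
                 species_ids = colnames(df)[-1L], scenario = NULL,
                 hif_uM = NA_real_, solver_stats = NULL),
            class = "glyco_sim")
}
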