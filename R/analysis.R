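# Result computations on simulated trajectories: percent-change
# classification of metabolites under hypoxia, the hypoxia-onset delay of
# lactate accumulation, oxygen sweeps of the 30-min lactate level, and the
# one-at-a-time sensitivity scan of the HIF-1 induction constants.

#' Classify metabolite concentration changes under hypoxia
#'
#' Computes, for every metabolite except lactate, the percent change of the
#' hypoxic concentration at time `t` relative to the normoxic baseline at
#' the same time, `100 * (hyp - base) / base`, and assigns each metabolite
#' to one of three groups: `unchanged` (|change| below
#' `thresholds["unchanged"]`), `B` (up to `thresholds["group_a"]`) and `A`
#' (at or above it). Lactate, the pathway product, is reported separately
#' as an attribute.
#'
#' @param hypoxic,baseline `glyco_sim` results sharing species and grids.
#' @param t evaluation time in minutes (default 30).
#' @param thresholds named vector `c(unchanged = 0.5, group_a = 5)` in
#'   percent.
#' @return a data.frame of class `metabolite_change_report` with columns
#'   `species, name, baseline, hypoxic, change_pct, group`, and attributes
#'   `lactate` (named vector: baseline, hypoxic, change_pct), `t` and
#'   `thresholds`.
#' @export
percent_changes <- function(hypoxic, baseline, t = 30,
                            thresholds = c(unchanged = 0.5, group_a = 5)) {
  stopifnot(inherits(hypoxic, "glyco_sim"), inherits(baseline, "glyco_sim"))
  if (!identical(hypoxic$species_ids, baseline$species_ids)) {
    stop("state-shape error: results do not share species", call. = FALSE)
  }
  stopifnot(all(c("unchanged", "group_a") %in% names(thresholds)),
            thresholds[["unchanged"]] < thresholds[["group_a"]])
  mets <- intersect(.metabolite_ids, hypoxic$species_ids)
  base <- vapply(mets, function(s) state_at(baseline, s, t), numeric(1))
  hyp <- vapply(mets, function(s) state_at(hypoxic, s, t), numeric(1))
  if (any(base <= 0)) {
    stop("division-domain error: zero baseline concentration for ",
         paste(mets[base <= 0], collapse = ", "), call. = FALSE)
  }
  change <- 100 * (hyp - base) / base
  lac <- c(baseline = unname(base["LAC"]), hypoxic = unname(hyp["LAC"]),
           change_pct = unname(change["LAC"]))
  keep <- mets != "LAC"
  grp <- ifelse(abs(change[keep]) < thresholds[["unchanged"]], "unchanged",
                ifelse(abs(change[keep]) < thresholds[["group_a"]], "B",
                       "A"))
  out <- data.frame(species = mets[keep],
                    name = unname(.metabolite_names[mets[keep]]),
                    baseline = unname(base[keep]),
                    hypoxic = unname(hyp[keep]),
                    change_pct = unname(change[keep]),
                    group = unname(grp),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, lactate = lac, t = t, thresholds = thresholds,
            class = c("metabolite_change_report", "data.frame"))
}

#' @export
print.metabolite_change_report <- function(x, ...) {
  cat(sprintf("Metabolite changes at t = %g min (thresholds: unchanged < %g%%, A >= %g%%)\n",
              attr(x, "t"), attr(x, "thresholds")[["unchanged"]],
              attr(x, "thresholds")[["group_a"]]))
  df <- as.data.frame(x)
  df$change_pct <- sprintf("%+.2f", df$change_pct)
  print(df[order(df$group, -abs(as.numeric(df$change_pct))),
           c("species", "change_pct", "group")], row.names = FALSE)
  lac <- attr(x, "lactate")
  cat(sprintf("lactate (reported separately): %.3f -> %.3f mM (%+.2f%%)\n",
              lac[["baseline"]], lac[["hypoxic"]], lac[["change_pct"]]))
  invisible(x)
}

#' Plot a metabolite change report
#' @param x a `metabolite_change_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.metabolite_change_report <- function(x, ...) {
  cols <- c(A = "firebrick", B = "steelblue", unchanged = "grey70")
  ord <- order(x$change_pct)
  graphics::barplot(x$change_pct[ord], names.arg = x$species[ord],
                    col = cols[x$group[ord]], las = 2,
                    ylab = "change at 30 min (%)", ...)
  graphics::legend("topleft", legend = names(cols), fill = cols, bty = "n")
  invisible(x)
}

#' Hypoxia-onset delay of lactate accumulation
#'
#' Returns the first time at which the relative lactate excess over the
#' baseline trajectory, `(L_hyp(t) - L_base(t)) / L_base(t)`, exceeds
#' `threshold_fraction`, with linear interpolation between output grid
#' points; `NA` if the threshold is never exceeded.
#'
#' @param hypoxic,baseline `glyco_sim` results on a common grid.
#' @param threshold_fraction relative excess defining "appearance" of the
#'   hypoxia effect (default 0.01, i.e. 1%).
#' @return delay in minutes, or `NA_real_`.
#' @export
lactate_delay <- function(hypoxic, baseline, threshold_fraction = 0.01) {
  stopifnot(threshold_fraction > 0)
  tt <- hypoxic$times
  if (!isTRUE(all.equal(tt, baseline$times))) {
    stop("state-shape error: results do not share a time grid",
         call. = FALSE)
  }
  excess <- (hypoxic$states[, "LAC"] - baseline$states[, "LAC"]) /
    baseline$states[, "LAC"]
  above <- excess > threshold_fraction
  if (!any(above)) return(NA_real_)
  i <- which(above)[1L]
  if (i == 1L) return(tt[1L])
  # linear interpolation of the crossing between grid points i-1 and i
  f <- (threshold_fraction - excess[i - 1L]) / (excess[i] - excess[i - 1L])
  tt[i - 1L] + f * (tt[i] - tt[i - 1L])
}

#' Lactate level versus oxygen availability
#'
#' Runs one constant-oxygen scenario per level and records the lactate
#' concentration at the end of the exposure.
#'
#' @param model a `glyco_model` carrying an oxygen map.
#' @param o2_levels oxygen percentages within `[0, 21]`.
#' @param duration exposure in minutes (default 30).
#' @param ... passed to [run_scenario()].
#' @return data.frame `(o2_percent, hif_uM, lactate_mM)`.
#' @export
oxygen_sweep <- function(model, o2_levels, duration = 30, ...) {
  if (length(o2_levels) == 0L) {
    stop("input-domain error: o2_levels must be non-empty", call. = FALSE)
  }
  rows <- lapply(o2_levels, function(o2) {
    sim <- run_scenario(model,
                        hypoxia_scenario(o2_percent = o2,
                                         duration = duration), ...)
    data.frame(o2_percent = o2, hif_uM = sim$hif_uM,
               lactate_mM = state_at(sim, "LAC", duration))
  })
  do.call(rbind, rows)
}

#' Normalized lactate after different hypoxia exposures
#'
#' Entry `(t, o2)` is the lactate concentration after `t` minutes at oxygen
#' level `o2`, normalized to the lactate after `t` minutes at normoxia
#' (21%).
#'
#' @param model a `glyco_model` carrying an oxygen map.
#' @param o2_levels oxygen percentages within `[0, 21]`.
#' @param exposure_times positive times in minutes.
#' @param ... passed to [run_scenario()].
#' @return matrix with one row per exposure time and one column per oxygen
#'   level (dimnames give the values).
#' @export
normalized_lactate_curves <- function(model, o2_levels,
                                      exposure_times = c(10, 20, 30), ...) {
  stopifnot(length(o2_levels) > 0L, all(exposure_times > 0))
  horizon <- max(exposure_times)
  base <- run_scenario(model,
                       hypoxia_scenario(o2_percent = 21,
                                        duration = horizon), ...)
  base_lac <- vapply(exposure_times, function(t) state_at(base, "LAC", t),
                     numeric(1))
  out <- vapply(o2_levels, function(o2) {
    sim <- run_scenario(model,
                        hypoxia_scenario(o2_percent = o2,
                                         duration = horizon), ...)
    vapply(exposure_times, function(t) state_at(sim, "LAC", t),
           numeric(1)) / base_lac
  }, numeric(length(exposure_times)))
  out <- matrix(out, nrow = length(exposure_times),
                dimnames = list(as.character(exposure_times),
                                as.character(o2_levels)))
  out
}

# Rebuild a model with one coupling's K_Eh rescaled.
.scale_coupling <- function(model, enzyme_id, factor) {
  coup <- lapply(model$couplings, function(cp) {
    if (cp$enzyme_id == enzyme_id) {
      hif_coupling(cp$enzyme_id, cp$K_Eh * factor, cp$sign)
    } else cp
  })
  pathway_model(model$species, model$reactions, coup,
                pdh_cycle = model$pdh_cycle, hif_level = model$hif_level,
                oxygen_map = model$oxygen_map)
}

#' One-at-a-time sensitivity scan of the HIF-1 induction constants
#'
#' For each selected enzyme, its `K_Eh` is rescaled by each factor (0.1x,
#' 1x and 10x by default) with all remaining parameters held constant, the
#' severe-hypoxia scenario is re-integrated, and the lactate concentration
#' at the end of the scan horizon is recorded. Each enzyme is classified by
#' the maximum absolute percent deviation of lactate from the reference
#' (factor 1) run: `insensitive` below `thresholds["slight"]`, `slight` up
#' to `thresholds["strong"]`, `strong` at or above it.
#'
#' @param model a `glyco_model`.
#' @param enzymes enzyme ids to scan; default: all HIF-coupled enzymes.
#' @param factors scale factors applied to `K_Eh` (must include 1).
#' @param duration scan horizon in minutes (default 30).
#' @param o2_percent oxygen level of the scan scenario (default 0, severe
#'   hypoxia).
#' @param thresholds named percent cutoffs `c(slight = 1, strong = 5)`.
#' @param ... passed to [run_scenario()].
#' @return a data.frame of class `sensitivity_report` with one row per
#'   enzyme (`enzyme`, one `lactate_<factor>` column per factor,
#'   `max_abs_dev_pct`, `class`), plus attribute `scan` holding the long
#'   `(enzyme, factor, lactate_mM, deviation_pct)` table and attribute
#'   `reference` (the factor-1 lactate).
#' @export
sensitivity_scan <- function(model, enzymes = NULL,
                             factors = c(0.1, 1, 10), duration = 30,
                             o2_percent = 0,
                             thresholds = c(slight = 1, strong = 5), ...) {
  coupled <- vapply(model$couplings, function(cp) cp$enzyme_id, character(1))
  if (is.null(enzymes)) enzymes <- coupled
  unknown <- setdiff(enzymes, coupled)
  if (length(unknown) > 0L) {
    stop("scan-domain error: no HIF coupling for enzyme(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!any(factors == 1)) {
    stop("scan-domain error: factors must include 1 (the reference)",
         call. = FALSE)
  }
  stopifnot(all(c("slight", "strong") %in% names(thresholds)),
            thresholds[["slight"]] < thresholds[["strong"]])
  scen <- hypoxia_scenario(o2_percent = o2_percent, duration = duration)
  ref_lac <- state_at(run_scenario(model, scen, ...), "LAC", duration)

  long <- list()
  for (e in enzymes) {
    for (f in factors) {
      lac <- if (f == 1) {
        ref_lac  # identity scaling reproduces the reference run
      } else {
        state_at(run_scenario(.scale_coupling(model, e, f), scen, ...),
                 "LAC", duration)
      }
      long[[length(long) + 1L]] <-
        data.frame(enzyme = e, factor = f, lactate_mM = lac,
                   deviation_pct = 100 * (lac - ref_lac) / ref_lac,
                   stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, long)

  wide <- lapply(enzymes, function(e) {
    rows <- long[long$enzyme == e, ]
    dev <- max(abs(rows$deviation_pct))
    cls <- if (dev < thresholds[["slight"]]) "insensitive"
           else if (dev < thresholds[["strong"]]) "slight" else "strong"
    out <- data.frame(enzyme = e, stringsAsFactors = FALSE)
    for (f in factors) {
      out[[paste0("lactate_", format(f, trim = TRUE))]] <-
        rows$lactate_mM[rows$factor == f]
    }
    out$max_abs_dev_pct <- dev
    out$class <- cls
    out
  })
  wide <- do.call(rbind, wide)
  structure(wide, scan = long, reference = ref_lac,
            thresholds = thresholds, duration = duration,
            o2_percent = o2_percent,
            class = c("sensitivity_report", "data.frame"))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("K_Eh sensitivity scan (O2 = %g%%, lactate at %g min; reference %.4f mM)\n",
              attr(x, "o2_percent"), attr(x, "duration"),
              attr(x, "reference")))
  df <- as.data.frame(x)
  df$max_abs_dev_pct <- sprintf("%.2f", df$max_abs_dev_pct)
  print(df[order(-as.numeric(df$max_abs_dev_pct)), ], row.names = FALSE)
  cat("classes: ",
      paste(sprintf("%s (%d)", names(table(x$class)),
                    as.integer(table(x$class))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Plot a sensitivity report
#' @param x a `sensitivity_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sensitivity_report <- function(x, ...) {
  cols <- c(strong = "firebrick", slight = "orange",
            insensitive = "grey70")
  ord <- order(-x$max_abs_dev_pct)
  graphics::barplot(x$max_abs_dev_pct[ord], names.arg = x$enzyme[ord],
                    col = cols[x$class[ord]], las = 2,
                    ylab = "max |lactate deviation| (%)", ...)
  graphics::abline(h = attr(x, "thresholds"), lty = 2)
  graphics::legend("topright", legend = names(cols), fill = cols, bty = "n")
  invisible(x)
}
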