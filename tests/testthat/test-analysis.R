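# Synthetic glyco_sim builders for the analytic analysis checks.
fake_sim <- function(times, lac, extra = NULL) {
  states <- cbind(LAC = lac)
  if (!is.null(extra)) states <- cbind(states, extra)
  structure(list(times = times, states = states,
                 species_ids = colnames(states), scenario = NULL,
                 hif_uM = NA_real_, solver_stats = NULL),
            class = "glyco_sim")
}

test_that("percent change of a run against itself is identically zero", {
  base <- ref_run(21)
  rep <- percent_changes(base, base)
  expect_true(all(rep$change_pct == 0))
  expect_true(all(rep$group == "unchanged"))
  expect_identical(attr(rep, "lactate")[["change_pct"]], 0)
})

test_that("group thresholds partition the 12 non-lactate metabolites", {
  rep <- percent_changes(ref_run(0), ref_run(21))
  expect_equal(nrow(rep), 12L)
  expect_false("LAC" %in% rep$species)
  expect_setequal(unique(rep$group), c("A", "B", "unchanged"))
  th <- attr(rep, "thresholds")
  expect_true(all(abs(rep$change_pct[rep$group == "unchanged"]) <
                    th[["unchanged"]]))
  expect_true(all(abs(rep$change_pct[rep$group == "A"]) >= th[["group_a"]]))
})

test_that("lactate delay matches the analytic linear-ramp solution", {
  tt <- seq(0, 30, by = 0.1)
  base <- fake_sim(tt, rep(2, length(tt)))
  ramp <- fake_sim(tt, 2 * (1 + 0.002 * tt))
  # 0.002 * t = 0.01  =>  t = 5 exactly
  expect_equal(lactate_delay(ramp, base, threshold_fraction = 0.01), 5,
               tolerance = 1e-9)
  expect_true(is.na(lactate_delay(base, base)))
})

test_that("oxygen sweep reproduces the lactate-oxygen curve shape", {
  m <- ref_model()
  sweep <- oxygen_sweep(m, c(0, 0.5, 1, 1.5, 2, 4, 6, 10, 21))
  expect_equal(nrow(sweep), 9L)
  # monotone nonincreasing in oxygen
  expect_true(all(diff(sweep$lactate_mM) <= 1e-9))
  lac <- setNames(sweep$lactate_mM, sweep$o2_percent)
  # flat above 6%, gentle 6 -> 1.5%, steep below 1.5%
  expect_lt(abs(lac[["21"]] - lac[["6"]]) / lac[["21"]], 0.005)
  gentle <- (lac[["1.5"]] - lac[["6"]]) / (6 - 1.5)
  steep <- (lac[["0"]] - lac[["1.5"]]) / 1.5
  expect_gt(steep, 2 * gentle)
  expect_gt(gentle, 0)
  expect_error(oxygen_sweep(m, numeric(0)), "non-empty")
})

test_that("normalized lactate grows with exposure time at fixed hypoxia", {
  m <- ref_model()
  norm <- normalized_lactate_curves(m, o2_levels = c(0, 1.5, 21),
                                    exposure_times = c(10, 30))
  expect_equal(dim(norm), c(2L, 3L))
  expect_equal(unname(norm[, "21"]), c(1, 1), tolerance = 1e-9)
  # longer exposure dominates at every hypoxic oxygen level
  expect_true(all(norm["30", c("0", "1.5")] >= norm["10", c("0", "1.5")]))
  # a 1x1 matrix is consistent with the oxygen_sweep ratio
  one <- normalized_lactate_curves(m, 0, 30)
  sw <- oxygen_sweep(m, c(0, 21), duration = 30)
  expect_equal(unname(one[1, 1]),
               sw$lactate_mM[1] / sw$lactate_mM[2], tolerance = 1e-8)
})

test_that("factor-1 scan rows reproduce the reference lactate bit-for-bit",
{
  m <- ref_model()
  rep <- sensitivity_scan(m, enzymes = c("PFK1", "GLUT"),
                          duration = 10)
  long <- attr(rep, "scan")
  ref <- attr(rep, "reference")
  expect_identical(long$lactate_mM[long$factor == 1], rep(ref, 2L))
  expect_identical(long$deviation_pct[long$factor == 1], c(0, 0))
  expect_error(sensitivity_scan(m, enzymes = "ALDO"), "scan-domain")
  expect_error(sensitivity_scan(m, enzymes = "PFK1", factors = c(0.1, 10)),
               "must include 1")
})

test_that("tenfold induction of the strong regulators accelerates lactate",
{
  m <- ref_model()
  rep <- sensitivity_scan(m, enzymes = c("PGCM", "PFK1", "PGI"),
                          duration = 30)
  long <- attr(rep, "scan")
  ref <- attr(rep, "reference")
  up <- long$lactate_mM[long$factor == 10]
  expect_true(all(up > ref))
})
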