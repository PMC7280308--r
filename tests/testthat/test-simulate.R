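test_that("scenario validation enforces the one-forcing contract", {
  expect_error(hypoxia_scenario(), "exactly one")
  expect_error(hypoxia_scenario(o2_percent = 5, hif_uM = 1), "exactly one")
  expect_error(hypoxia_scenario(o2_percent = 30), "input-domain")
  expect_error(hypoxia_scenario(hif_uM = -1), "input-domain")
  expect_error(hypoxia_scenario(hif_uM = 1, duration = 0), "input-domain")
  s <- hypoxia_scenario(o2_percent = 0, duration = 30, dt = 0.1)
  expect_length(s$times, 301L)
})

test_that("a normoxic run stays at the steady state (drift < 0.1%)", {
  m <- ref_model()
  sim <- run_scenario(m, hypoxia_scenario(hif_uM = 0))
  y0 <- m$initial[m$state_ids]
  rel <- abs(t(sim$states) - y0) / y0
  expect_lt(max(rel), 0.001)
  # the 21%-oxygen scenario sits near the basal map value and also holds
  sim21 <- ref_run(21)
  rel21 <- abs(t(sim21$states) - y0) / y0
  expect_lt(max(rel21), 0.001)
})

test_that("duplicate runs are bit-identical (determinism contract)", {
  m <- ref_model()
  s1 <- run_scenario(m, hypoxia_scenario(o2_percent = 0, duration = 10))
  s2 <- run_scenario(m, hypoxia_scenario(o2_percent = 0, duration = 10))
  expect_identical(s1$states, s2$states)
})

test_that("severe hypoxia raises lactate monotonically after a flat phase",
{
  hyp <- ref_run(0)
  lac <- hyp$states[, "LAC"]
  expect_true(all(diff(lac) > -1e-9))
  expect_gt(lac[length(lac)], lac[1L])
  # no state goes meaningfully negative
  expect_gt(min(hyp$states), -1e-9)
})

test_that("integrated enzyme levels match the mass-action closed form", {
  hyp <- ref_run(0)
  m <- ref_model()
  hif <- hyp$hif_uM
  for (cp in m$couplings) {
    expected <- 1 + cp$sign * cp$K_Eh * hif * hyp$times
    expect_equal(unname(hyp$states[, cp$enzyme_id]), expected,
                 tolerance = 1e-7)
  }
})

test_that("active PDH stays within the conserved PDK/PDP cycle total", {
  hyp <- ref_run(0)
  total <- ref_model()$pdh_cycle$total
  a <- hyp$states[, "PDHA"]
  expect_true(all(a > 0 & a < total))
  # phospho-PDH is the derived complement; the pair sums to the total
  expect_equal(a + (total - a), rep(total, length(a)))
})

test_that("fixed-step RK4 at dt = 0.001 reproduces the adaptive solution", {
  m <- ref_model()
  scen <- hypoxia_scenario(o2_percent = 0, times = c(0, 30))
  ad <- run_scenario(m, scen)
  rk <- run_scenario(m, hypoxia_scenario(o2_percent = 0,
                                         times = seq(0, 30, by = 0.001)),
                     method = "rk4")
  final_ad <- ad$states[nrow(ad$states), ]
  final_rk <- rk$states[nrow(rk$states), ]
  expect_lt(max(abs(final_rk - final_ad) / abs(final_ad)), 1e-5)
})

test_that("halving the tolerances leaves lactate unchanged to 1e-6 mM", {
  m <- ref_model()
  scen <- hypoxia_scenario(o2_percent = 0, times = c(0, 30))
  a <- run_scenario(m, scen)
  b <- run_scenario(m, scen, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(state_at(a, "LAC", 30) - state_at(b, "LAC", 30)), 1e-6)
})

test_that("run_hif_grid produces a nondecreasing lactate family", {
  m <- ref_model()
  expect_identical(run_hif_grid(m, numeric(0)), list())
  levels <- seq(0, 1, length.out = 10)
  sims <- run_hif_grid(m, levels, duration = 30)
  lac30 <- vapply(sims, function(s) state_at(s, "LAC", 30), numeric(1))
  expect_length(sims, 10L)
  expect_true(all(diff(lac30) >= -1e-9))
  expect_error(run_hif_grid(m, c(1, 0.5)), "sorted")
})

test_that("simulation CSV writers round-trip and long format is tidy", {
  sim <- run_scenario(ref_model(),
                      hypoxia_scenario(o2_percent = 0, duration = 2))
  f <- tempfile(fileext = ".csv")
  write_simulation(sim, f)
  back <- read_simulation(f)
  expect_equal(back$times, sim$times, tolerance = 0)
  expect_equal(back$states, sim$states, tolerance = 0,
               ignore_attr = TRUE)
  expect_identical(back$species_ids, sim$species_ids)
  long <- as.data.frame(sim, long = TRUE)
  expect_identical(names(long), c("time", "species", "value"))
  expect_equal(nrow(long), length(sim$times) * ncol(sim$states))
})
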