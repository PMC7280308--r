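test_that("generation is deterministic and hits the target lactate", {
  s1 <- generate_parameters(generator_spec(seed = 42))
  s2 <- generate_parameters(generator_spec(seed = 42))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  lac0 <- as.data.frame(s1)
  lac0 <- lac0$value[lac0$scope == "species" & lac0$id == "LAC"]
  expect_equal(lac0, 5.66)
  custom <- generate_parameters(generator_spec(target_lactate = 3.2))
  tab <- as.data.frame(custom)
  expect_equal(tab$value[tab$scope == "species" & tab$id == "LAC"], 3.2)
})

test_that("generated sets build a 26-state model at an exact steady state",
{
  for (seed in c(7, 42, 99)) {
    ps <- generate_parameters(generator_spec(seed = seed, km_jitter = 1.6,
                                             conc_jitter = 1.3,
                                             randomize_keh = TRUE))
    m <- build_reference_model(ps)
    expect_length(m$state_ids, 26L)
    res <- pathway_rhs(m, m$initial[m$state_ids], hif = 0)
    expect_lt(max(abs(res)), 1e-8)
  }
})

test_that("a jittered parameterization holds its normoxic state in
           simulation", {
  ps <- generate_parameters(generator_spec(seed = 13, km_jitter = 1.5,
                                           randomize_keh = TRUE))
  m <- build_reference_model(ps)
  sim <- run_scenario(m, hypoxia_scenario(hif_uM = 0))
  y0 <- m$initial[m$state_ids]
  expect_lt(max(abs(t(sim$states) - y0) / y0), 0.001)
})

test_that("K_Eh constants are recovered from noiseless trajectories", {
  m <- ref_model()
  sim <- run_scenario(m, hypoxia_scenario(hif_uM = 0.8, duration = 30))
  est <- estimate_keh(sim)
  truth <- vapply(m$couplings, function(cp) cp$K_Eh, numeric(1))
  names(truth) <- vapply(m$couplings, function(cp) cp$enzyme_id,
                         character(1))
  expect_equal(est[names(truth)], truth, tolerance = 1e-6)
  base <- run_scenario(m, hypoxia_scenario(hif_uM = 0, duration = 5))
  expect_error(estimate_keh(base), "hif > 0")
})

test_that("calibration with no targets returns the generator set", {
  spec <- generator_spec(seed = 5)
  expect_identical(as.data.frame(calibrate_reference_fixture(spec, NULL)),
                   as.data.frame(generate_parameters(spec)))
})

test_that("contradictory targets yield a non-conforming report", {
  # a hypoxic lactate below baseline is unreachable with inducing couplings
  tg <- reference_targets(baseline_lactate = 5.66, hypoxic_lactate = 5.0)
  ps <- calibrate_reference_fixture(generator_spec(), tg)
  cal <- attr(ps, "calibration")
  expect_false(cal$conforming)
  expect_match(cal$failed, "unreachable")
})

test_that("the shipped fixture is the conforming calibration product", {
  ps <- ref_params()
  tab <- as.data.frame(ps)
  keh <- tab[tab$scope == "coupling" & tab$parameter == "K_Eh", ]
  expect_equal(nrow(keh), 12L)
  expect_true(all(keh$provenance == "calibrated"))
  expect_true(all(keh$value > 0))
})
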