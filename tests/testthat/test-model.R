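test_that("the reference assembly has 26 states and 12 HIF couplings", {
  m <- ref_model()
  expect_length(m$state_ids, 26L)
  expect_equal(sum(m$roles[m$state_ids] == "metabolite"), 13L)
  expect_equal(sum(m$roles[m$state_ids] == "enzyme"), 13L)
  expect_length(m$couplings, 12L)
  expect_setequal(vapply(m$couplings, function(c) c$enzyme_id, character(1)),
                  c("GLUT", "HK", "PGI", "PFK1", "TPI", "GAPDH", "PGK",
                    "PGM", "ENO", "PDK", "LDH", "PGCM"))
  # boundary species carry no ODE
  expect_false(any(m$boundary_ids %in% m$state_ids))
})

test_that("model consistency errors are raised for bad references", {
  sp <- list(species("A", initial_value = 1),
             species("E", role = "enzyme", initial_value = 1))
  good <- reaction("r", c(A = 1L), c(A = 1L),
                   rate_law("first_order", c(k = 1)))
  expect_error(
    pathway_model(sp, list(reaction("r", c(B = 1L), c(A = 1L),
                                    rate_law("first_order", c(k = 1))))),
    "model-consistency error.*B")
  expect_error(
    pathway_model(sp, list(good),
                  list(hif_coupling("A", 0.1))),
    "not an enzyme")
  expect_error(reaction("r", c(A = 0L), c(A = 1L),
                        rate_law("first_order", c(k = 1))),
               "positive integers")
})

test_that("rhs does stoichiometric bookkeeping on a toy A -> B chain", {
  sp <- list(species("A", initial_value = 0.4),
             species("B", initial_value = 0.1))
  rx <- reaction("conv", c(A = 1L), c(B = 1L),
                 rate_law("irreversible_mm", c(Vmax = 2, Km = 0.5)))
  m <- pathway_model(sp, list(rx))
  d <- pathway_rhs(m, c(0.4, 0.1))
  v <- mm_rate(2, 0.4, 0.5)
  expect_equal(unname(d), c(-v, v))
  expect_error(pathway_rhs(m, c(1, 2, 3)), "state-shape")
})

test_that("rhs equals the brute-force stoichiometry oracle on random models",
{
  for (seed in c(11, 23, 37, 58, 71)) {
    m <- random_small_model(seed)
    set.seed(seed + 1000)
    for (rep in 1:3) {
      st <- runif(length(m$state_ids), 0, 3)
      expect_equal(unname(pathway_rhs(m, st)),
                   unname(brute_force_rhs(m, st)),
                   tolerance = 1e-12)
    }
  }
})

test_that("enzyme-state derivatives equal their HIF drift exactly", {
  m <- ref_model()
  m$hif_level <- 0.7
  st <- m$initial[m$state_ids]
  d <- pathway_rhs(m, st, hif = 0.7)
  for (cp in m$couplings) {
    expect_identical(unname(d[cp$enzyme_id]),
                     hif_enzyme_drift(cp, 0.7))
  }
  # active PDH follows the PDK/PDP cycle, not the HIF drift
  pc <- m$pdh_cycle
  expect_equal(unname(d["PDHA"]),
               pc$k_pdp * (pc$total - 1) - pc$k_pdk * 1 * 1)
})

test_that("the calibrated normoxic point is a steady state of the rhs", {
  m <- ref_model()
  d <- pathway_rhs(m, m$initial[m$state_ids], hif = 0)
  expect_lt(max(abs(d)), 1e-8)
})

test_that("flux is conserved per reaction (production equals consumption)",
{
  # a single reaction's contributions are the same rate weighted by the
  # stoichiometric coefficients on both sides
  sp <- list(species("S", initial_value = 1),
             species("P1", initial_value = 0.2),
             species("P2", initial_value = 0.2))
  rx <- reaction("split", c(S = 2L), c(P1 = 1L, P2 = 3L),
                 rate_law("mass_action", c(k = 0.4)))
  m2 <- pathway_model(sp, list(rx))
  d <- pathway_rhs(m2, c(1, 0.2, 0.2))
  rate <- 0.4 * 1^2
  expect_equal(unname(d), c(-2, 1, 3) * rate)
})

test_that("model accessors and methods report the structure", {
  m <- ref_model()
  expect_output(print(m), "26")
  expect_output(summary(m), "K_Eh")
  cf <- coef(m)
  expect_true(all(c("HK.Vmax", "K_Eh.LDH") %in% names(cf)))
  expect_true(all(cf >= 0))
})
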