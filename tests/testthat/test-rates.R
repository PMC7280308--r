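test_that("irreversible Michaelis-Menten rate follows the closed form", {
  expect_identical(mm_rate(Vmax = 1, S = 0, Km = 0.1), 0)
  expect_equal(mm_rate(Vmax = 2, S = 0.1, Km = 0.1), 1.0)
  # linear scaling in enzyme level, against direct formula evaluation
  expect_equal(mm_rate(2, 0.1, 0.1, enzyme_level = 1.5),
               1.5 * 2 * 0.1 / (0.1 + 0.1))
  expect_error(mm_rate(1, 1, Km = 0), "parameter-domain")
  expect_error(mm_rate(1, -1, Km = 0.1), "parameter-domain")
})

test_that("mm_rate is monotone nondecreasing in substrate and enzyme level",
{
  S <- seq(0, 10, length.out = 50)
  v <- mm_rate(3, S, Km = 0.7)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 3))
  lv <- seq(0, 4, length.out = 30)
  v2 <- mm_rate(3, 0.5, 0.7, enzyme_level = lv)
  expect_true(all(diff(v2) >= 0))
})

test_that("reversible rate vanishes at equilibrium and saturates", {
  # Vf*S/Ks == Vr*P/Kp => zero net rate
  expect_equal(reversible_mm_rate(Vf = 2, Ks = 1, Vr = 1, Kp = 0.5,
                                  S = 0.3, P = 0.3), 0)
  # direct formula evaluation: (2 - 1) / (1 + 2 + 1)
  expect_equal(reversible_mm_rate(1, 1, 1, 1, S = 2, P = 1), 0.25)
  # saturation limit with no product
  big <- reversible_mm_rate(1, 1, 1, 1, S = 1e8, P = 0,
                            enzyme_level = 1.3)
  expect_equal(big, 1.3, tolerance = 1e-6)
  expect_error(reversible_mm_rate(1, 0, 1, 1, 1, 1), "parameter-domain")
})

test_that("HIF coupling drift is sign * K_Eh * hif", {
  cp <- hif_coupling("LDH", K_Eh = 0.02)
  expect_identical(hif_enzyme_drift(cp, hif = 0), 0)
  expect_equal(hif_enzyme_drift(cp, hif = 1), 0.02)
  # closed-form enzyme level after 30 min of constant forcing
  expect_equal(1 + hif_enzyme_drift(cp, 1) * 30, 1.6)
  rep_cp <- hif_coupling("LDH", K_Eh = 0.02, sign = -1)
  expect_equal(hif_enzyme_drift(rep_cp, 1), -0.02)
  expect_error(hif_enzyme_drift(cp, hif = -1), "input-domain")
  expect_error(hif_coupling("LDH", K_Eh = -0.1), "parameter-domain")
})
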