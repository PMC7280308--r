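test_that("the oxygen map hits its construction points", {
  m <- oxygen_hif_map(H_max = 1.4, H_basal = 0.1, o2_half = 2, hill_n = 2)
  expect_equal(o2_to_hif(m, 0), 1.4)
  expect_equal(o2_to_hif(m, 2), 0.1 + (1.4 - 0.1) / 2)
  expect_error(o2_to_hif(m, -1), "input-domain")
  expect_error(o2_to_hif(m, 22), "input-domain")
  expect_error(oxygen_hif_map(H_max = 1, H_basal = 2), "parameter-domain")
  expect_error(oxygen_hif_map(o2_half = 0), "parameter-domain")
})

test_that("the map is monotone nonincreasing with range [H_basal, H_max]", {
  m <- oxygen_hif_map(H_max = 1, H_basal = 0.02, o2_half = 1.2,
                      hill_n = 2.8)
  o2 <- seq(0, 21, length.out = 200)
  h <- o2_to_hif(m, o2)
  expect_true(all(diff(h) <= 0))
  expect_true(all(h >= 0.02 - 1e-12 & h <= 1 + 1e-12))
})

test_that("the calibrated map separates 1.5% from 6% oxygen", {
  map <- ref_model()$oxygen_map
  h6 <- o2_to_hif(map, 6)
  h15 <- o2_to_hif(map, 1.5)
  expect_gt(h15, 5 * h6)           # HIF-1 rises steeply below ~1.5% O2
  expect_lt(h6, 0.05 * map$H_max)  # at 6% O2, HIF-1 is near basal
})
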