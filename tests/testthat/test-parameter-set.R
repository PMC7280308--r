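test_that("parameter tables are validated on construction and load", {
  tab <- as.data.frame(ref_params())
  expect_s3_class(parameter_set(tab), "parameter_set")

  bad <- tab
  bad$value[5] <- -1
  expect_error(parameter_set(bad), "validation error.*row 5")

  bad2 <- tab
  bad2$unit[3] <- "furlongs"
  expect_error(parameter_set(bad2), "unknown unit")

  expect_error(parameter_set(tab[, -4]), "format error.*value")
})

test_that("save/load round trip is exact and saves are byte-identical", {
  ps <- ref_params()
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  save_parameters(ps, f1)
  back <- load_parameters(f1)
  t0 <- as.data.frame(ps)
  t0 <- t0[order(t0$scope, t0$id, t0$parameter), ]
  t1 <- as.data.frame(back)
  expect_equal(t1$value, t0$value, tolerance = 0)
  expect_identical(t1$unit, t0$unit)
  save_parameters(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a table missing a K_Eh entry fails model assembly by name", {
  tab <- as.data.frame(ref_params())
  tab <- tab[!(tab$scope == "coupling" & tab$id == "LDH" &
                 tab$parameter == "K_Eh"), ]
  expect_error(build_reference_model(parameter_set(tab)),
               "named-parameter error.*K_Eh.*LDH")
})

test_that("a table with a deleted Km raises a named-parameter error", {
  tab <- as.data.frame(ref_params())
  tab <- tab[!(tab$scope == "reaction" & tab$id == "HK" &
                 tab$parameter == "Km"), ]
  expect_error(build_reference_model(parameter_set(tab)),
               "named-parameter error.*Km.*HK")
})
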