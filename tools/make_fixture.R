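# Build-time script: calibrates the reference parameter fixture and writes
# it to inst/extdata/reference_parameters.csv. Run from the package root:
#   Rscript tools/make_fixture.R
suppressMessages(pkgload::load_all(".", quiet = TRUE))

ps <- calibrate_reference_fixture(generator_spec(), reference_targets(),
                                  quiet = FALSE)
cal <- attr(ps, "calibration")
if (!isTRUE(cal$conforming)) {
  stop("calibration did not conform: ", paste(cal$failed, collapse = ", "))
}
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
save_parameters(ps, "inst/extdata/reference_parameters.csv")
cat("wrote inst/extdata/reference_parameters.csv\n")
print(cal$residuals)
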