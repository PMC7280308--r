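sbml_ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")

test_that("SBML export carries 26 non-boundary species and all couplings",
{
  doc <- export_sbml(ref_model())
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", sbml_ns)
  boundary <- xml2::xml_attr(sp, "boundaryCondition")
  expect_equal(sum(boundary == "false"), 26L)
  expect_equal(sum(boundary == "true"), 6L)
  rules <- xml2::xml_find_all(doc, ".//s:rateRule", sbml_ns)
  expect_length(rules, 13L)  # 12 couplings + active PDH cycle
  rxs <- xml2::xml_find_all(doc, ".//s:reaction", sbml_ns)
  expect_length(rxs, length(ref_model()$reactions))
  # HIF-1 is a constant model parameter, not a species
  hif <- xml2::xml_find_first(doc, ".//s:parameter[@id='HIF1']", sbml_ns)
  expect_identical(xml2::xml_attr(hif, "constant"), "true")
})

test_that("SBML export is deterministic and internally consistent", {
  f1 <- tempfile(fileext = ".xml")
  f2 <- tempfile(fileext = ".xml")
  export_sbml(ref_model(), f1)
  export_sbml(ref_model(), f2)
  expect_identical(readLines(f1), readLines(f2))
  # every species referenced in reactions and rules is declared
  doc <- xml2::read_xml(f1)
  declared <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", sbml_ns), "id")
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:speciesReference", sbml_ns), "species")
  expect_true(all(refs %in% declared))
})

test_that("an empty model is rejected at export", {
  sp <- list(species("A", initial_value = 1))
  m <- pathway_model(sp, list())
  expect_error(export_sbml(m), "export error")
})
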