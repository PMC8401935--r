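roundtrip <- function(model) {
  path <- withr::local_tempfile(fileext = ".xml", .local_envir = parent.frame())
  write_sbml_model(model, path)
  read_sbml_model(path)
}

test_that("SBML round-trip preserves every field the pipeline reads", {
  m <- make_toy_gem(aa_biomass_frac = 0.1, aa_product_coeff = 1,
                    amendment_yields = c(maltose = 0.2))$model
  m2 <- roundtrip(m)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$reactions[, c("id", "name", "lower_bound", "upper_bound",
                                "subsystem")],
               m$reactions[, c("id", "name", "lower_bound", "upper_bound",
                               "subsystem")])
  expect_equal(vapply(m2$reactions$gene_association, canonical_gpr, ""),
               vapply(m$reactions$gene_association, canonical_gpr, ""),
               ignore_attr = TRUE)
  expect_equal(m2$stoichiometry, m$stoichiometry)
  expect_equal(m2$objective, m$objective)
})

test_that("generated synthesis reactions survive SBML serialisation exactly", {
  st <- make_study_toy()
  m2 <- roundtrip(st$model)
  prot <- m2$stoichiometry[["cdkl5_synthesis"]]
  expect_identical(prot[["atp[c]"]], -2288)
  expect_identical(prot[["gtp[c]"]], -2286)
  expect_identical(prot[["Pi[c]"]], 4574)
  expect_equal(m2$stoichiometry[["pB40_synthesis"]],
               st$model$stoichiometry[["pB40_synthesis"]])
  # the tiny plasmid biomass coefficient round-trips bit-exactly
  expect_identical(m2$stoichiometry[["BIOMASS"]][["pB40"]],
                   st$model$stoichiometry[["BIOMASS"]][["pB40"]])
})

test_that("SBML reader rejects malformed or incomplete files", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not xml <", path)
  expect_error(read_sbml_model(path), "cannot parse")
  expect_error(read_sbml_model("does/not/exist.xml"), "no such file")

  # a model with inverted bounds violates the bound invariant on load
  m <- chain_model()
  ok <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(m, ok)
  txt <- readLines(ok)
  swapped <- sub('fbc:lowerFluxBound="fb_1" fbc:upperFluxBound="fb_3"',
                 'fbc:lowerFluxBound="fb_3" fbc:upperFluxBound="fb_1"',
                 txt, fixed = TRUE)
  expect_false(identical(swapped, txt))  # the file really was altered
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(swapped, bad)
  expect_error(read_sbml_model(bad), "lower_bound > upper_bound")

  # strip the objective declaration: must fail naming the omission
  noobj <- grep("objective", txt, invert = TRUE, value = TRUE,
                ignore.case = TRUE)
  p3 <- withr::local_tempfile(fileext = ".xml")
  writeLines(noobj, p3)
  expect_error(read_sbml_model(p3), "objective")
})

test_that("writing an empty model is refused", {
  m <- chain_model()
  m$reactions <- m$reactions[0, ]
  m$stoichiometry <- list()
  path <- withr::local_tempfile(fileext = ".xml")
  expect_error(write_sbml_model(m, path), "at least one")
})

test_that("gene rules parse, canonicalise and round-trip", {
  expect_equal(canonical_gpr("g1"), "g1")
  expect_equal(canonical_gpr("( g1 and g2 )  or g3"), "(g1 and g2) or g3")
  expect_true(is.na(canonical_gpr(NA)))
  expect_error(canonical_gpr("g1 and (g2 or"), "parenthes|malformed")
  expect_error(canonical_gpr("and g1"), "malformed")
})

test_that("COBRApy reads our SBML and reproduces the FBA optimum", {
  # dual-route check: an established constraint-based toolchain (Python
  # COBRApy + its LP solver) must agree with our writer and solver
  m <- make_toy_gem(uptakes = c(glc = 1), yields = c(glc = 0.5))$model
  ours <- fba(m)$objective_value
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(m, path)
  out <- system2("python", c("-c", shQuote(paste0(
    "import cobra.io; m = cobra.io.read_sbml_model('", path, "'); ",
    "print(round(m.optimize().objective_value, 9))"))),
    stdout = TRUE, stderr = FALSE)
  expect_equal(as.numeric(out[length(out)]), ours, tolerance = 1e-7)
})
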