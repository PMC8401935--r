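test_that("toy generator answer sheets are validated by the solver", {
  cases <- list(
    make_toy_gem(uptakes = c(a = 1), yields = c(a = 0.5)),
    make_toy_gem(uptakes = c(a = 0.35, b = 0.66),
                 yields = c(a = 0.1, b = 0.12), product_cost = 2),
    make_toy_gem(uptakes = c(a = 1), yields = c(a = 0.5),
                 aa_biomass_frac = 0.2, aa_product_coeff = 1))
  for (toy in cases) {
    expect_equal(fba(toy$model)$objective_value, toy$answers$mu_max,
                 tolerance = 1e-9)
    prod_model <- set_objective(
      set_bounds(toy$model, "BIOMASS", lower_bound = 0, upper_bound = 0),
      "PROD")
    expect_equal(fba(prod_model)$objective_value, toy$answers$product_max,
                 tolerance = 1e-9)
  }
  expect_error(make_toy_gem(uptakes = c(a = 1), yields = c(a = -1)),
               "positive")
})

test_that("the study network's closed forms hold end to end", {
  st <- make_study_toy()
  expect_equal(fba(st$model)$objective_value, st$answers$mu_max,
               tolerance = 1e-9)
  # the construction carries the published coefficients
  expect_equal(st$construction$plasmid_biomass_coefficient,
               0.001608 * 8166 * 100 / 3850272)
  # precursor cost of one protein: residues plus phosphate equivalents
  expect_equal(st$answers$prec_per_product, 1144 + 0.05 * 4574)
})

test_that("consumption series generation is seed-deterministic", {
  a <- make_consumption_series(noise_cv = 0.05, seed = 11)
  b <- make_consumption_series(noise_cv = 0.05, seed = 11)
  c <- make_consumption_series(noise_cv = 0.05, seed = 12)
  expect_identical(a$concentrations, b$concentrations)
  expect_false(identical(a$concentrations, c$concentrations))

  # byte-identical CSV on re-run under a fixed seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_consumption_csv(a, p1)
  write_consumption_csv(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  # the generator does not disturb the global RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(make_consumption_series(noise_cv = 0.05, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("series shape follows the generating model", {
  s <- make_consumption_series(noise_cv = 0)
  truth <- attr(s, "truth")
  expect_equal(s$biomass[1], truth$x0)
  # biomass is exponential at mu
  expect_equal(diff(log(s$biomass)), rep(truth$mu * diff(s$times)[1],
                                         length(s$times) - 1))
  # concentrations never negative, non-increasing without noise
  expect_true(all(as.matrix(s$concentrations) >= 0))
  expect_true(all(sapply(s$concentrations, function(x) all(diff(x) <= 1e-12))))
})

test_that("synthetic proteins are deterministic and well-formed", {
  p1 <- make_synthetic_protein(200, seed = 4)
  p2 <- make_synthetic_protein(200, seed = 4)
  expect_identical(p1, p2)
  expect_equal(sum(p1$aa_counts), 200L)
  # molecular weight from residue masses plus one water
  expect_equal(p1$molecular_weight,
               sum(aa_residue_masses()[names(p1$aa_counts)] * p1$aa_counts) +
                 18.0153)
  single <- make_synthetic_protein(1, seed = 1)
  expect_equal(sum(single$aa_counts), 1L)
  # the reaction builder accepts any generated composition
  expect_s3_class(build_protein_synthesis_reaction(single),
                  "synthesis_reaction")
})

test_that("the bundled hCDKL5 fixtures reproduce the published inputs", {
  counts <- hcdkl5_aa_counts()
  expect_equal(sum(counts), 1144L)
  expect_equal(counts[["H"]], 49L)
  expect_equal(counts[["S"]], 140L)
  prot <- hcdkl5_protein()
  expect_equal(prot$molecular_weight, 128082.77)
  p <- pb40_plasmid()
  expect_equal(p$length_bp, 8166L)
  expect_equal(p$copy_number, 100L)
  freq <- proteome_aa_frequencies()
  expect_equal(sum(freq), 1)
  expect_length(freq, 20)
})
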