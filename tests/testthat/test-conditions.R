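study_cfg <- function(growth_fraction = 0.74) {
  condition_config(c(EX_glutamate = 0.35, EX_gluconate = 0.66),
                   growth_fraction = growth_fraction,
                   biomass_reaction = "BIOMASS",
                   product_reaction = "cdkl5_synthesis")
}

test_that("wt model predicts growth equal to the closed-form yield", {
  st <- make_study_toy()
  cfg <- study_cfg()
  wt <- build_wt_model(st$model, cfg)
  sol <- fba(wt)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, st$answers$mu_max, tolerance = 1e-9)

  # zero uptake: no growth
  zero <- condition_config(c(EX_glutamate = 0, EX_gluconate = 0),
                           biomass_reaction = "BIOMASS",
                           product_reaction = "cdkl5_synthesis")
  expect_equal(fba(build_wt_model(st$model, zero))$objective_value, 0)

  bad <- condition_config(c(EX_glutamate = 1), biomass_reaction = "nope",
                          product_reaction = "cdkl5_synthesis")
  expect_error(build_wt_model(st$model, bad), "lacks reaction")
})

test_that("recomb model maximises product under the growth floor", {
  st <- make_study_toy()
  cfg <- study_cfg(0.74)
  recomb <- build_recomb_model(st$model, cfg)
  sol <- fba(recomb)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value,
               st$answers$product_at(0.74 * st$answers$mu_max),
               tolerance = 1e-8)
  # the growth floor binds at the product optimum
  expect_equal(sol$fluxes[["BIOMASS"]], 0.74 * st$answers$mu_max,
               tolerance = 1e-8)

  # fraction 0: the unconstrained product maximum
  free <- fba(build_recomb_model(st$model, study_cfg(0)))
  expect_equal(free$objective_value, st$answers$product_at(0),
               tolerance = 1e-8)

  # strictly competing toy at fraction 1: nothing left for product
  toy <- make_toy_gem(uptakes = c(a = 1), yields = c(a = 0.5))
  tight <- condition_config(c(EX_a = 1), growth_fraction = 1,
                            biomass_reaction = "BIOMASS",
                            product_reaction = "PROD")
  expect_equal(fba(build_recomb_model(toy$model, tight))$objective_value, 0,
               tolerance = 1e-7)
})

test_that("product flux is non-increasing in the growth fraction", {
  st <- make_study_toy()
  flux_at <- vapply(c(0, 0.25, 0.5, 0.74, 1), function(f) {
    fba(build_recomb_model(st$model, study_cfg(f)))$objective_value
  }, numeric(1))
  expect_true(all(diff(flux_at) <= 1e-9))
  expect_equal(flux_at,
               st$answers$product_at(c(0, 0.25, 0.5, 0.74, 1) *
                                       st$answers$mu_max),
               tolerance = 1e-8)
})

test_that("idle production machinery only burdens growth via the plasmid term", {
  st <- make_study_toy()
  cfg <- study_cfg()
  # host without machinery, but with the same biomass composition
  host_growth <- fba(set_medium(st$host, cfg$uptake_bounds))$objective_value
  full_growth <- fba(build_wt_model(st$model, cfg))$objective_value
  # the difference is exactly the plasmid drain in the answer sheet
  no_plasmid <- sum(c(glutamate = 0.35, gluconate = 0.66) * 0.12)
  expect_equal(host_growth, no_plasmid, tolerance = 1e-9)
  expect_equal(full_growth, st$answers$mu_max, tolerance = 1e-9)
  expect_lt(full_growth, host_growth)
})

test_that("the production envelope traces the closed-form trade-off line", {
  st <- make_study_toy()
  cfg <- study_cfg()
  wt <- build_wt_model(st$model, cfg)
  env <- production_envelope(wt, "BIOMASS", "cdkl5_synthesis", n_points = 9)
  expect_equal(nrow(env), 9)
  expect_true(all(diff(env$growth) > 0))
  expect_true(all(env$product_min <= env$product_max + 1e-12))
  # monotone decreasing upper edge with closed-form endpoints
  expect_true(all(diff(env$product_max) < 0))
  expect_equal(env$product_max, st$answers$product_at(env$growth),
               tolerance = 1e-8)
  expect_equal(env$product_max[1], st$answers$product_at(0), tolerance = 1e-8)
  expect_equal(env$product_max[9], 0, tolerance = 1e-8)
  # endpoint consistency with the growth-fraction-1 condition model
  at_one <- fba(build_recomb_model(st$model, study_cfg(1)))$objective_value
  expect_equal(env$product_max[9], at_one, tolerance = 1e-8)
})
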