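test_that("FSEOF on the branched toy selects the product branch only", {
  toy <- make_toy_gem(uptakes = c(a = 1), yields = c(a = 0.5))
  scan <- fseof_scan(toy$model, "BIOMASS", "PROD",
                     fseof_config(n_steps = 10),
                     gene_encoded_only = FALSE, include_exchanges = TRUE)
  # brute-force expectation from the answer sheet: PROD itself is the
  # enforced reaction; its drain rises with it, the biomass branch falls
  expect_setequal(scan$targets$reaction_id, setdiff(toy$answers$fseof_targets,
                                                    "PROD"))
  expect_false("BIOMASS" %in% scan$targets$reaction_id)
  expect_false("CNV_a" %in% scan$targets$reaction_id)

  # with the gene filter (the default), only enzyme-catalysed steps stay
  gene_scan <- fseof_scan(toy$model, "BIOMASS", "PROD",
                          fseof_config(n_steps = 10))
  expect_setequal(gene_scan$targets$reaction_id,
                  setdiff(toy$answers$fseof_gene_targets, "PROD"))
})

test_that("FSEOF profiles rise monotonically and match step-wise brute force", {
  toy <- make_toy_gem(uptakes = c(a = 1), yields = c(a = 0.5),
                      aa_biomass_frac = 0.1, aa_product_coeff = 2)
  cfg <- fseof_config(n_steps = 8)
  scan <- fseof_scan(toy$model, "BIOMASS", "PROD", cfg,
                     gene_encoded_only = FALSE, include_exchanges = TRUE)
  for (r in scan$targets$reaction_id) {
    expect_true(all(diff(abs(scan$profiles[, r])) >= -cfg$tol))
  }
  # brute force each step with the vertex-enumeration oracle
  vmax <- fba(set_objective(toy$model, "PROD", "maximize"))$objective_value
  for (k in c(1, 4, 8)) {
    enforced <- (k / 8) * 0.9 * vmax
    mk <- set_bounds(toy$model, "PROD", lower_bound = enforced)
    ora <- fba_oracle(mk)
    expect_equal(unname(scan$profiles[k, "BIOMASS"]), ora$objective,
                 tolerance = 1e-8)
  }
  # the AA branch slope matches the closed-form selection rule
  expect_true("AA_SYN" %in% scan$targets$reaction_id)
})

test_that("FSEOF selects exactly the residues favoured by the product", {
  st <- make_study_toy()
  wt <- build_wt_model(st$model,
                       condition_config(c(EX_glutamate = 0.35,
                                          EX_gluconate = 0.66),
                                        biomass_reaction = "BIOMASS",
                                        product_reaction = "cdkl5_synthesis"))
  scan <- fseof_scan(wt, "BIOMASS", "cdkl5_synthesis",
                     fseof_config(n_steps = 12))
  slopes <- st$answers$aa_supply_slope
  aa_map <- default_aa_metabolites()
  expected_aa <- paste0("SUP_", substr(aa_map[names(slopes)[slopes > 0]], 1, 3))
  got_aa <- grep("^SUP_[A-Z][a-z]{2}$", scan$targets$reaction_id, value = TRUE)
  expect_setequal(got_aa, expected_aa)
  # measured slopes agree with the closed form
  for (aa in names(slopes)[slopes > 0]) {
    rid <- paste0("SUP_", substr(aa_map[[aa]], 1, 3))
    expect_equal(scan$targets$slope[scan$targets$reaction_id == rid],
                 unname(slopes[aa]), tolerance = 1e-6)
  }
  # ranking is by descending slope
  expect_true(all(diff(scan$targets$slope) <= 1e-12))
})

test_that("FSEOF errors are explicit", {
  toy <- make_toy_gem(uptakes = c(a = 1), yields = c(a = 0.5))
  # unproducible product: block the drain
  blocked <- set_bounds(toy$model, "DM_prod", upper_bound = 0)
  expect_error(fseof_scan(blocked, "BIOMASS", "PROD"), "not producible")
  expect_error(fseof_config(n_steps = 1), "at least 2")
  expect_error(fseof_config(max_ratio = 0), "max_ratio")
})

test_that("pathway grouping counts and filters subsystems", {
  expect_equal(nrow(group_by_pathway(data.frame())), 0)
  t3 <- data.frame(reaction_id = c("r1", "r2", "r3"),
                   subsystem = c("A", "A", "B"))
  g <- group_by_pathway(t3)
  expect_equal(g$subsystem, "A")
  expect_equal(g$n, 2L)

  st <- make_study_toy()
  wt <- build_wt_model(st$model,
                       condition_config(c(EX_glutamate = 0.35,
                                          EX_gluconate = 0.66),
                                        biomass_reaction = "BIOMASS",
                                        product_reaction = "cdkl5_synthesis"))
  scan <- fseof_scan(wt, "BIOMASS", "cdkl5_synthesis",
                     fseof_config(n_steps = 12))
  paths <- group_by_pathway(scan$targets)
  # amino-acid biosynthesis dominates the target pathways
  expect_equal(paths$subsystem[1], "Amino-acid biosynthesis")
  expect_true(all(paths$n >= 2))
})
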