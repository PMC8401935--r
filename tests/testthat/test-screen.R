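screen_fixture <- function() {
  st <- make_study_toy()
  cfg <- condition_config(c(EX_glutamate = 0.35, EX_gluconate = 0.66),
                          growth_fraction = 0.74,
                          biomass_reaction = "BIOMASS",
                          product_reaction = "cdkl5_synthesis")
  list(st = st, recomb = build_recomb_model(st$model, cfg),
       growth = 0.74 * st$answers$mu_max)
}

test_that("transported compounds are the boundary-crossing species", {
  toy <- make_toy_gem(uptakes = c(glc = 1), yields = c(glc = 0.5))$model
  expect_equal(transported_compounds(toy), "glc[e]")

  # an antiporter exposes both coupled species
  expect_setequal(transported_compounds(antiport_model()),
                  c("A[e]", "B[e]"))

  # blocklisted inorganic species are dropped
  m <- antiport_model()
  expect_equal(transported_compounds(m, blocklist = c("a", "b")),
               character(0))
  expect_error(transported_compounds(m, extracellular = "p"),
               "no compartment")
})

test_that("amendment screening matches closed forms and never hurts", {
  fx <- screen_fixture()
  res <- screen_amendments(fx$recomb, c("maltose[e]", "mannitol[e]"),
                           amendment_uptake = 0.5)
  # LP relaxation: amending can only help
  expect_true(all(res$ratio >= 1 - 1e-9))
  # closed-form amended optima from the generator answer sheet
  for (cmp in c("maltose", "mannitol")) {
    expect_equal(res$amended_flux[res$compound_id == paste0(cmp, "[e]")],
                 fx$st$answers$amended_product_at(cmp, 0.5, fx$growth),
                 tolerance = 1e-8)
  }
  # maltose (higher yield) must outrank mannitol
  expect_equal(res$compound_id, c("maltose[e]", "mannitol[e]"))
  expect_equal(res$log_fold_change, log10(res$ratio))

  # ranking is invariant to evaluation order
  rev_res <- screen_amendments(fx$recomb, c("mannitol[e]", "maltose[e]"),
                               amendment_uptake = 0.5)
  expect_equal(rev_res, res)

  # top-k selection keeps the head of the ranking
  topk <- screen_amendments(fx$recomb, c("maltose[e]", "mannitol[e]"),
                            amendment_uptake = 0.5, top_k = 1)
  expect_equal(nrow(topk), 1)
  expect_equal(topk$compound_id, "maltose[e]")
})

test_that("a dead-end compound leaves the optimum unchanged", {
  fx <- screen_fixture()
  m <- add_reaction(fx$recomb, "T_dead",
                    c("dead[e]" = -1, "dead[c]" = 1),
                    new_metabolites = data.frame(
                      id = c("dead[e]", "dead[c]"),
                      compartment = c("e", "c")))
  expect_true("dead[e]" %in% transported_compounds(m))
  res <- suppressMessages(screen_amendments(m, "dead[e]"))
  # no exchange existed: one is auto-created and flagged
  expect_true(res$exchange_created)
  expect_equal(res$ratio, 1, tolerance = 1e-9)
  expect_equal(res$log_fold_change, 0, tolerance = 1e-9)
})

test_that("amendment flux shift reuses the core filter", {
  fx <- screen_fixture()
  # amended against itself at zero uptake: nothing increases
  null_shift <- amendment_flux_shift(fx$recomb, "maltose[e]",
                                     amendment_uptake = 0)
  expect_false(any(null_shift$increased))

  shift <- amendment_flux_shift(fx$recomb, "maltose[e]",
                                amendment_uptake = 0.5)
  inc <- increased_set(shift)
  # the amendment feeds extra precursor into product synthesis: the
  # supplies of product-dominant residues must carry more flux
  expect_true("SUP_His" %in% inc$reaction_id)
  expect_true("SUP_Ser" %in% inc$reaction_id)
  expect_true(all(inc$core_a & inc$core_b))
})
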