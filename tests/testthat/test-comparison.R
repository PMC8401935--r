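fake_solution <- function(fluxes) {
  structure(list(status = "optimal", objective_value = 0, fluxes = fluxes),
            class = "flux_solution")
}

test_that("the core window accepts narrow ranges and rejects wide ones", {
  crit <- core_criterion(window = 0.3)
  sol <- fake_solution(c(r1 = 1, r2 = 1, r3 = -2, r4 = 0, r5 = -2))
  ranges <- data.frame(reaction_id = c("r1", "r2", "r3", "r4", "r5"),
                       fmin = c(0.8, 0.5, -2.5, 0, -2.7),
                       fmax = c(1.2, 1.2, -1.5, 0, -1.5))
  core <- core_reactions(sol, ranges, crit)
  expect_true("r1" %in% core)       # [0.8, 1.2] inside the 30% band around 1
  expect_false("r2" %in% core)      # lower end 0.5 breaches 0.7
  expect_true("r3" %in% core)       # mirrored band for v = -2: [-2.6, -1.4]
  expect_false("r4" %in% core)      # zero flux is never core
  expect_false("r5" %in% core)      # -2.7 breaches the mirrored band
})

test_that("shrinking the window monotonically shrinks the core set", {
  st <- make_study_toy()
  wt <- build_wt_model(st$model,
                       condition_config(c(EX_glutamate = 0.35,
                                          EX_gluconate = 0.66),
                                        biomass_reaction = "BIOMASS",
                                        product_reaction = "cdkl5_synthesis"))
  sol <- fba(wt)
  ranges <- fva(wt)
  sets <- lapply(c(0.5, 0.3, 0.1), function(w) {
    core_reactions(sol, ranges, core_criterion(window = w))
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("core calls require ranges for every flux-carrying reaction", {
  sol <- fake_solution(c(r1 = 1, r2 = 2))
  ranges <- data.frame(reaction_id = "r1", fmin = 1, fmax = 1)
  expect_error(core_reactions(sol, ranges, core_criterion()), "r2")
  # but a missing range for a zero-flux reaction is no obstacle
  sol0 <- fake_solution(c(r1 = 1, r2 = 0))
  expect_equal(core_reactions(sol0, ranges, core_criterion()), "r1")
})

test_that("identical conditions yield no increased-flux calls", {
  m <- chain_model()
  cmp <- list(solution = fba(m), ranges = fva(m))
  out <- increased_flux_reactions(cmp, cmp, core_criterion(), model = m)
  expect_false(any(out$increased))
})

test_that("production shifts flux into product-biased amino-acid supplies", {
  st <- make_study_toy()
  cfg <- condition_config(c(EX_glutamate = 0.35, EX_gluconate = 0.66),
                          growth_fraction = 0.74,
                          biomass_reaction = "BIOMASS",
                          product_reaction = "cdkl5_synthesis")
  wt <- build_wt_model(st$model, cfg)
  recomb <- build_recomb_model(st$model, cfg)
  cmp <- increased_flux_reactions(
    list(solution = fba(wt), ranges = fva(wt)),
    list(solution = fba(recomb), ranges = fva(recomb)),
    core_criterion(), model = st$model)
  inc <- increased_set(cmp)
  # histidine and serine supplies (product-enriched residues) must rise
  expect_true(all(c("SUP_His", "SUP_Ser") %in% inc$reaction_id))
  # every increased reaction is core in both conditions by construction
  expect_true(all(inc$core_a & inc$core_b))
  # annotation columns are carried through
  expect_true(all(c("subsystem", "gene_encoded") %in% names(inc)))
  expect_true(inc$gene_encoded[inc$reaction_id == "SUP_His"])

  # comparing models with different reaction sets is refused
  m2 <- chain_model()
  expect_error(increased_flux_reactions(
    list(solution = fba(m2), ranges = fva(m2)),
    list(solution = fba(recomb), ranges = fva(recomb))),
    "different reaction sets")
})
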