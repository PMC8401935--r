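test_that("the hCDKL5 synthesis reaction reproduces the published coefficients", {
  prot <- hcdkl5_protein()
  expect_equal(sum(prot$aa_counts), 1144L)
  rxn <- build_protein_synthesis_reaction(prot)
  st <- rxn$stoichiometry
  expect_equal(st[["atp[c]"]], -2288)
  expect_equal(st[["gtp[c]"]], -2286)
  expect_equal(st[["amp[c]"]], 2288)
  expect_equal(st[["gdp[c]"]], 2286)
  expect_equal(st[["Pi[c]"]], 4574)
  expect_equal(st[["cdkl5[c]"]], 1)
  # spot-check residue coefficients against the printed composition
  expect_equal(st[["Ala[c]"]], -59)
  expect_equal(st[["His[c]"]], -49)
  expect_equal(st[["Ser[c]"]], -140)
  expect_equal(st[["Trp[c]"]], -6)
  # no transporter/secretion is attached: the reaction only touches cytosol
  expect_false(any(grepl("\\[e\\]", names(st))))
})

test_that("protein energy stoichiometry follows the charging/elongation split", {
  # single residue: 2 ATP, no peptide bond, 2 Pi
  one <- build_protein_synthesis_reaction(protein_spec("p1", c(A = 1), 89.1))
  expect_equal(one$stoichiometry[["atp[c]"]], -2)
  expect_false("gtp[c]" %in% names(one$stoichiometry))  # coefficient 0 dropped
  expect_equal(one$stoichiometry[["Pi[c]"]], 2)

  # dipeptide AG: 4 ATP, 2 GTP, 6 Pi, one Ala and one Gly consumed
  dip <- build_protein_synthesis_reaction(
    protein_spec("ag", c(A = 1, G = 1), 146.1))
  st <- dip$stoichiometry
  expect_equal(st[["atp[c]"]], -4)
  expect_equal(st[["gtp[c]"]], -2)
  expect_equal(st[["Pi[c]"]], 6)
  expect_equal(st[["Ala[c]"]], -1)
  expect_equal(st[["Gly[c]"]], -1)

  expect_error(protein_spec("bad", c(Z = 3), 100), "unknown amino-acid")
  expect_error(protein_spec("none", c(A = 0), 100), "at least one residue")
})

test_that("energy identities hold for random protein compositions", {
  for (seed in 1:10) {
    prot <- make_synthetic_protein(sample(2:500, 1), seed = seed)
    st <- build_protein_synthesis_reaction(prot)$stoichiometry
    n <- sum(prot$aa_counts)
    expect_equal(st[["atp[c]"]], -2 * n)
    expect_equal(st[["gtp[c]"]], -2 * (n - 1))
    expect_equal(st[["amp[c]"]], -st[["atp[c]"]])
    expect_equal(st[["gdp[c]"]], -st[["gtp[c]"]])
    expect_equal(st[["Pi[c]"]], -(st[["atp[c]"]] + st[["gtp[c]"]]))
  }
})

test_that("the pB40 replication reaction reproduces the published coefficients", {
  rxn <- build_plasmid_synthesis_reaction(pb40_plasmid())
  st <- rxn$stoichiometry
  expect_equal(st[["atp[c]"]], -21)
  expect_equal(st[["h2o[c]"]], -21)
  expect_equal(st[["datp[c]"]], -57)
  expect_equal(st[["dgtp[c]"]], -43)
  expect_equal(st[["dctp[c]"]], -43)
  expect_equal(st[["dttp[c]"]], -57)
  expect_equal(st[["adp[c]"]], 21)
  expect_equal(st[["Pi[c]"]], 21)
  expect_equal(st[["h[c]"]], 21)
  expect_equal(st[["pB40"]], 1)
})

test_that("plasmid dNTP coefficients follow base composition and copy number", {
  sym <- build_plasmid_synthesis_reaction(
    plasmid_spec("p", 1000, gc_fraction = 0.5, copy_number = 1,
                 atp_cost_per_copy = 0))$stoichiometry
  expect_equal(unname(sym[c("datp[c]", "dgtp[c]", "dctp[c]", "dttp[c]")]),
               rep(-0.5, 4))
  expect_false("atp[c]" %in% names(sym))

  gc6 <- build_plasmid_synthesis_reaction(
    plasmid_spec("p", 1000, gc_fraction = 0.6, copy_number = 10))$stoichiometry
  expect_equal(gc6[["atp[c]"]], -2.1)
  expect_equal(gc6[["dgtp[c]"]], -6)
  expect_equal(gc6[["dctp[c]"]], -6)
  expect_equal(gc6[["datp[c]"]], -4)
  expect_equal(gc6[["dttp[c]"]], -4)

  # complementarity invariants across random parameter draws
  set.seed(7)
  for (i in 1:10) {
    gc <- runif(1)
    pcn <- sample(1:200, 1)
    st <- build_plasmid_synthesis_reaction(
      plasmid_spec("p", 5000, gc, pcn))$stoichiometry
    expect_equal(st[["datp[c]"]], st[["dttp[c]"]])
    expect_equal(st[["dgtp[c]"]], st[["dctp[c]"]])
    dn <- -sum(st[c("datp[c]", "dgtp[c]", "dctp[c]", "dttp[c]")])
    expect_equal(dn, 2 * pcn)
    expect_equal(st[["adp[c]"]], st[["Pi[c]"]])
  }
  expect_error(plasmid_spec("p", 100, 0.5, 0), "positive integer")
  expect_error(plasmid_spec("p", 100, 1.5, 10), "gc_fraction")
})

test_that("plasmid GC and length are taken from a sequence when given", {
  p <- plasmid_spec("p", 10, 0.99, 5, sequence = "ATGCATGCAT")
  expect_equal(p$length_bp, 10L)
  expect_equal(p$gc_fraction, 0.4)
})

test_that("the plasmid biomass coefficient scales total plasmid DNA", {
  expect_equal(
    signif(compute_plasmid_biomass_coefficient(3850272, 0.001608, 8166, 100), 3),
    0.000341)
  # identity case: plasmid DNA equals genome DNA
  expect_equal(compute_plasmid_biomass_coefficient(1000, 0.002, 1000, 1), 0.002)
  expect_equal(compute_plasmid_biomass_coefficient(1000, 0.002, 100, 10), 0.002)
  expect_error(compute_plasmid_biomass_coefficient(0, 1, 1, 1), "positive")
})

test_that("biomass augmentation adds one term and penalises growth monotonically", {
  toy <- make_study_toy()
  host <- toy$host
  plas <- build_plasmid_synthesis_reaction(pb40_plasmid())
  m <- add_synthesis_reaction(host, plas)
  bio0 <- m$stoichiometry[["BIOMASS"]]

  m1 <- augment_biomass(m, "pB40", 0.000341)
  bio1 <- m1$stoichiometry[["BIOMASS"]]
  expect_equal(length(bio1), length(bio0) + 1)
  expect_equal(bio1[["pB40"]], -0.000341)
  expect_equal(bio1[names(bio0)], bio0)

  # zero coefficient leaves the optimum untouched
  m0 <- augment_biomass(m, "pB40", 0)
  expect_equal(fba(m0)$objective_value, fba(m)$objective_value)

  # growing plasmid burden monotonically lowers the optimum
  mus <- vapply(c(0, 0.1, 1, 5), function(co) {
    fba(augment_biomass(m, "pB40", co))$objective_value
  }, numeric(1))
  expect_true(all(diff(mus) < 0))

  expect_error(augment_biomass(m, "pB40", 1, biomass_reaction = "nope"),
               "not found")
  expect_error(augment_biomass(host, "pB40", 1), "not in model")
})

test_that("composition deltas identify enriched residues and sum to zero", {
  prot <- hcdkl5_protein()
  delta <- composition_delta(proteome_aa_frequencies(), prot)
  expect_equal(sum(delta), 0, tolerance = 1e-12)
  # histidine and serine are enriched in the product
  expect_gt(delta[["H"]], 0)
  expect_gt(delta[["S"]], 0)

  # a protein matching the reference exactly has a null delta
  ref <- c(A = 0.5, G = 0.5)
  same <- protein_spec("same", c(A = 10, G = 10), 100)
  expect_equal(unname(composition_delta(ref, same)[c("A", "G")]), c(0, 0))

  # all-A protein against a 50/50 two-residue proteome
  allA <- protein_spec("aaa", c(A = 7), 100)
  d <- composition_delta(ref, allA)
  expect_equal(d[["A"]], 0.5)
  expect_equal(d[["G"]], -0.5)

  expect_error(composition_delta(numeric(0), prot), "empty proteome")
})
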