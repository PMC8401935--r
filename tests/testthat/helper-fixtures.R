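# Shared miniature networks, built in code.

# linear chain: substrate uptake (cap 1) -> 1:1 conversion -> biomass at
# yield 0.5 per substrate; hand-solved FBA optimum 0.5
chain_model <- function(uptake = 1, yield_ = 0.5) {
  metabolic_model(
    "chain",
    metabolites = data.frame(id = c("s[e]", "s[c]", "x[c]"),
                             compartment = c("e", "c", "c")),
    reactions = data.frame(
      id = c("EX_s", "CNV", "BIO", "DM_x"),
      lower_bound = c(-uptake, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 1000),
      gene_association = c(NA, "g1", NA, NA),
      subsystem = NA_character_),
    stoichiometry = list(
      EX_s = c("s[e]" = -1),
      CNV = c("s[e]" = -1, "s[c]" = 1),
      BIO = c("s[c]" = -1 / yield_, "x[c]" = 1),
      DM_x = c("x[c]" = -1)),
    objective = "BIO")
}

# antiporter network: A enters while B leaves through one coupled
# transporter; A is converted to B inside
antiport_model <- function() {
  metabolic_model(
    "antiport",
    metabolites = data.frame(
      id = c("A[e]", "A[c]", "B[e]", "B[c]"),
      compartment = c("e", "c", "e", "c")),
    reactions = data.frame(
      id = c("EX_A", "EX_B", "ANT", "CNV"),
      lower_bound = c(-1, 0, 0, 0),
      upper_bound = rep(1000, 4),
      gene_association = c(NA, NA, "gant", "gc"),
      subsystem = NA_character_),
    stoichiometry = list(
      EX_A = c("A[e]" = -1),
      EX_B = c("B[e]" = -1),
      ANT = c("A[e]" = -1, "B[c]" = -1, "A[c]" = 1, "B[e]" = 1),
      CNV = c("A[c]" = -1, "B[c]" = 1)),
    objective = "CNV")
}
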