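## Synthetic fixtures with analytically known answers: toy metabolic
## networks, random proteins and consumption time series. These emulate
## the study conditions (a batch culture on a two-substrate minimal
## medium producing a burdensome cytosolic protein) at a scale where
## every optimum is available in closed form.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a toy genome-scale model with a known answer sheet
#'
#' Builds a small network (exchange, transport, conversion, biomass,
#' product and drains) whose FBA optimum, FVA ranges, production
#' envelope and overexpression-target set are available in closed form.
#' Each substrate s is imported (`EX_s`, uptake capped), transported
#' (`T_s`), and converted to a common precursor with its yield
#' (`CNV_s`). Biomass drains one precursor unit per unit growth
#' (optionally partly via an amino-acid-like intermediate made by
#' `AA_SYN`); the product reaction (`PROD`) drains `product_cost`
#' precursor units (plus optionally `aa_product_coeff` amino-acid
#' units), capturing the biomass/product competition for one resource
#' pool.
#'
#' Closed forms (u = uptake bounds, y = yields): maximal growth
#' `mu_max = sum(u * y)`; maximal product
#' `mu_max / (product_cost + aa_product_coeff)`; the envelope is the
#' straight line between those endpoints.
#'
#' @param uptakes named vector: substrate -> maximum uptake
#'   (mmol/gCDW/h). Defaults emulate a glutamate/gluconate minimal
#'   medium at the measured uptake rates.
#' @param yields named vector: substrate -> precursor (biomass) yield.
#' @param product_cost precursor units consumed per product unit.
#' @param n_parallel number of equivalent parallel transporter copies
#'   for the first substrate (> 1 creates FVA degeneracy with known
#'   ranges).
#' @param aa_biomass_frac fraction of the biomass precursor demand
#'   routed through the amino-acid intermediate (0 disables the branch).
#' @param aa_product_coeff amino-acid units consumed per product unit.
#' @param amendment_yields named vector of extra transportable
#'   substrates whose exchanges start closed (uptake 0): candidates for
#'   the medium-amendment screen, each with its precursor yield.
#' @return list with `model` (a `metabolic_model`, biomass objective)
#'   and `answers` (closed-form answer sheet: `mu_max`, `product_max`,
#'   `envelope_product_at(g)`, `parallel_range`, `fseof_targets`).
#' @export
make_toy_gem <- function(uptakes = c(glutamate = 0.35, gluconate = 0.66),
                         yields = stats::setNames(rep(0.12, length(uptakes)),
                                                  names(uptakes)),
                         product_cost = 1,
                         n_parallel = 1L,
                         aa_biomass_frac = 0,
                         aa_product_coeff = 0,
                         amendment_yields = numeric(0)) {
  stopifnot(length(uptakes) >= 1, all(uptakes >= 0))
  if (any(yields <= 0)) stop("yields must be positive")
  if (product_cost <= 0) stop("product_cost must be positive")
  if (aa_biomass_frac < 0 || aa_biomass_frac >= 1) {
    stop("aa_biomass_frac must lie in [0, 1)")
  }
  if (length(amendment_yields)) {
    if (any(amendment_yields <= 0)) stop("amendment yields must be positive")
    uptakes <- c(uptakes, stats::setNames(rep(0, length(amendment_yields)),
                                          names(amendment_yields)))
    yields <- c(yields, amendment_yields)
  }
  subs <- names(uptakes)
  aa_branch <- aa_biomass_frac > 0 || aa_product_coeff > 0

  mets <- data.frame(id = c(paste0(subs, "[e]"), paste0(subs, "[c]"),
                            "prec[c]", "bio[c]", "prod[c]",
                            if (aa_branch) "aa[c]"),
                     compartment = c(rep("e", length(subs)),
                                     rep("c", length(subs) + 3 + aa_branch)),
                     stringsAsFactors = FALSE)
  mets$name <- mets$id
  mets$formula <- NA_character_

  rxns <- list()
  stoich <- list()
  addr <- function(id, st, lb = 0, ub = 1000, gene = NA, subsystem = NA, name = id) {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, name = name, lower_bound = lb, upper_bound = ub,
      gene_association = gene, subsystem = subsystem, stringsAsFactors = FALSE)
    stoich[[id]] <<- st
  }

  for (s in subs) {
    addr(paste0("EX_", s), stats::setNames(-1, paste0(s, "[e]")),
         lb = -uptakes[[s]], subsystem = "Exchange")
    np <- if (s == subs[1]) as.integer(n_parallel) else 1L
    for (k in seq_len(np)) {
      id <- if (np == 1L) paste0("T_", s) else paste0("T_", s, "_", letters[k])
      addr(id, stats::setNames(c(-1, 1), paste0(s, c("[e]", "[c]"))),
           gene = paste0("g_t_", s, if (np > 1L) paste0("_", k)),
           subsystem = "Transport")
    }
    addr(paste0("CNV_", s),
         stats::setNames(c(-1, yields[[s]]), c(paste0(s, "[c]"), "prec[c]")),
         gene = paste0("g_cnv_", s), subsystem = "Central metabolism")
  }
  if (aa_branch) {
    addr("AA_SYN", c("prec[c]" = -1, "aa[c]" = 1),
         gene = "g_aa", subsystem = "Amino-acid biosynthesis")
  }
  bio_st <- if (aa_branch) {
    c("prec[c]" = -(1 - aa_biomass_frac), "aa[c]" = -aa_biomass_frac,
      "bio[c]" = 1)
  } else c("prec[c]" = -1, "bio[c]" = 1)
  addr("BIOMASS", bio_st, subsystem = "Biomass")
  addr("DM_bio", c("bio[c]" = -1), subsystem = "Exchange")
  prod_st <- if (aa_product_coeff > 0) {
    c("prec[c]" = -product_cost, "aa[c]" = -aa_product_coeff, "prod[c]" = 1)
  } else c("prec[c]" = -product_cost, "prod[c]" = 1)
  addr("PROD", prod_st, gene = "g_prod", subsystem = "Product synthesis")
  addr("DM_prod", c("prod[c]" = -1), subsystem = "Exchange")

  model <- metabolic_model("toy_gem", mets, do.call(rbind, rxns), stoich,
                           objective = "BIOMASS")

  mu_max <- sum(uptakes * yields[subs])
  prec_per_product <- product_cost + aa_product_coeff
  aa_slope <- aa_product_coeff - aa_biomass_frac * prec_per_product
  fseof_targets <- c("PROD", "DM_prod", if (aa_branch && aa_slope > 0) "AA_SYN")
  answers <- list(
    mu_max = mu_max,
    product_max = mu_max / prec_per_product,
    prec_per_product = prec_per_product,
    envelope_product_at = function(g) pmax(0, (mu_max - g) / prec_per_product),
    amended_product_at = function(substrate, uptake, growth) {
      (mu_max - growth + uptake * yields[[substrate]]) / prec_per_product
    },
    parallel_range = c(0, unname(uptakes[1])),
    parallel_ids = grep(paste0("^T_", subs[1], "_"), names(stoich), value = TRUE),
    fseof_targets = sort(fseof_targets),
    fseof_gene_targets = sort(intersect(fseof_targets, c("PROD", "AA_SYN"))))
  list(model = model, answers = answers)
}

#' Generate the synthetic study network: toy host plus production machinery
#'
#' Builds a closed-form emulation of the full study: the toy host of
#' [make_toy_gem()] on a two-substrate minimal medium, extended with the
#' actual generated pB40 replication and protein synthesis reactions,
#' wired into the network through explicit precursor economics --
#' biomass drains one precursor unit per unit growth, split between bulk
#' precursor and proteome-proportioned free amino acids; each amino acid
#' costs `aa_cost` precursor to supply, each NTP `ntp_cost`, each dNTP
#' `dntp_cost`; translation by-products (AMP, GDP, Pi, ADP, H) are
#' drained freely and water is free. Every optimum of the resulting
#' model is therefore a ratio of linear expressions in these costs,
#' recorded in the answer sheet.
#'
#' The network reproduces, in miniature, the study's qualitative
#' behaviour: product and biomass compete for precursor; amino acids
#' enriched in the product (histidine, serine for hCDKL5) see the
#' largest relative supply-flux increase upon production; amending a
#' closed carbon source raises the product optimum by its yield.
#'
#' @param protein a `protein_spec` (default the hCDKL5 construct).
#' @param plasmid a `plasmid_spec` (default pB40).
#' @param genome genome constants for the plasmid biomass coefficient.
#' @param uptakes,yields,amendment_yields medium structure, as in
#'   [make_toy_gem()].
#' @param aa_share fraction of the biomass precursor drain routed
#'   through free amino acids (proteome-proportioned).
#' @param aa_cost,ntp_cost,dntp_cost precursor units per supplied
#'   monomer.
#' @param proteome amino-acid frequencies used in the biomass reaction.
#' @return list with `model` (the full recombinant network, biomass
#'   objective; product reaction `<protein>_synthesis`), `host` (the
#'   same network before the production machinery is attached -- the
#'   input [run_pipeline()] expects), `construction` (as returned by
#'   [build_recombinant_reconstruction()]) and `answers` (closed forms:
#'   `mu_max`, `prec_per_biomass`, `prec_per_product`,
#'   `product_at(growth)`, `amended_product_at(substrate, uptake,
#'   growth)`, `aa_supply_slope` per amino acid).
#' @export
make_study_toy <- function(protein = hcdkl5_protein(),
                           plasmid = pb40_plasmid(),
                           genome = phtac125_genome(),
                           uptakes = c(glutamate = 0.35, gluconate = 0.66),
                           yields = stats::setNames(rep(0.12, length(uptakes)),
                                                    names(uptakes)),
                           amendment_yields = c(maltose = 0.2, mannitol = 0.15),
                           aa_share = 0.5, aa_cost = 1,
                           ntp_cost = 0.05, dntp_cost = 0.05,
                           proteome = proteome_aa_frequencies()) {
  stopifnot(aa_share > 0, aa_share < 1, abs(sum(proteome) - 1) < 1e-6)
  toy <- make_toy_gem(uptakes = uptakes, yields = yields, product_cost = 1,
                      amendment_yields = amendment_yields)
  host <- toy$model
  aa_map <- default_aa_metabolites()

  ## supply reactions introduce the currency species into the host
  supply <- function(m, met, cost, gene, subsystem) {
    st <- if (cost > 0) {
      stats::setNames(c(-cost, 1), c("prec[c]", met))
    } else stats::setNames(1, met)
    add_reaction(m, paste0("SUP_", met_base_id(met, "c")), st,
                 gene_association = gene, subsystem = subsystem,
                 name = paste("Supply of", met),
                 new_metabolites = if (met %in% m$metabolites$id) NULL else
                   data.frame(id = met, compartment = "c"))
  }
  for (aa in names(aa_map)) {
    host <- supply(host, aa_map[[aa]], aa_cost, paste0("g_aa_", aa),
                   "Amino-acid biosynthesis")
  }
  for (ntp in c("atp[c]", "gtp[c]")) {
    host <- supply(host, ntp, ntp_cost, paste0("g_", met_base_id(ntp, "c")),
                   "Energy metabolism")
  }
  for (dntp in c("datp[c]", "dgtp[c]", "dctp[c]", "dttp[c]")) {
    host <- supply(host, dntp, dntp_cost,
                   paste0("g_", met_base_id(dntp, "c")),
                   "Nucleotide metabolism")
  }
  host <- supply(host, "h2o[c]", 0, NA, "Exchange")
  for (waste in c("amp[c]", "gdp[c]", "Pi[c]", "adp[c]", "h[c]")) {
    host <- add_reaction(host, paste0("DM_", met_base_id(waste, "c")),
                         stats::setNames(-1, waste),
                         subsystem = "Exchange",
                         name = paste("Drain of", waste),
                         new_metabolites = data.frame(id = waste,
                                                      compartment = "c"))
  }

  ## rewire biomass: bulk precursor + proteome-proportioned amino acids
  bio <- host$stoichiometry[["BIOMASS"]]
  bio <- bio[names(bio) != "prec[c]"]
  bio <- c(bio, stats::setNames(-(1 - aa_share), "prec[c]"),
           stats::setNames(-aa_share * unname(proteome[names(aa_map)]),
                           unname(aa_map)))
  host$stoichiometry[["BIOMASS"]] <- bio
  host <- validate_model(set_objective(host, "BIOMASS"))

  cons <- build_recombinant_reconstruction(host, protein, plasmid,
                                           genome, biomass_reaction = "BIOMASS")
  m <- cons$model

  counts <- stats::setNames(numeric(length(aa_map)), names(aa_map))
  counts[names(protein$aa_counts)] <- protein$aa_counts
  n_res <- sum(counts)
  prec_per_plasmid <- 2 * plasmid$copy_number * dntp_cost +
    plasmid$atp_cost_per_copy * plasmid$copy_number * ntp_cost
  prec_per_biomass <- (1 - aa_share) + aa_share * aa_cost +
    cons$plasmid_biomass_coefficient * prec_per_plasmid
  prec_per_product <- aa_cost * n_res + ntp_cost * (2 * n_res + 2 * (n_res - 1))
  supply_capacity <- sum(uptakes * yields[names(uptakes)])
  mu_max <- supply_capacity / prec_per_biomass
  proteome_full <- stats::setNames(numeric(length(aa_map)), names(aa_map))
  proteome_full[names(proteome)] <- proteome
  answers <- list(
    mu_max = mu_max,
    prec_per_biomass = prec_per_biomass,
    prec_per_product = prec_per_product,
    product_at = function(growth) {
      pmax(0, (supply_capacity - growth * prec_per_biomass) / prec_per_product)
    },
    amended_product_at = function(substrate, uptake, growth) {
      (supply_capacity + uptake * yields_all(substrate) -
         growth * prec_per_biomass) / prec_per_product
    },
    ## d|SUP_aa|/d(enforced product): residue demand minus the supply
    ## freed by the growth the product displaces
    aa_supply_slope = counts - aa_share * proteome_full *
      prec_per_product / prec_per_biomass)
  yields_all <- function(substrate) {
    c(yields, amendment_yields)[[substrate]]
  }
  list(model = m, host = host, construction = cons, answers = answers)
}

#' Generate a consumption time series with known uptake rates
#'
#' Biomass grows exponentially from `x0` at rate `mu`; each substrate
#' declines by its true specific uptake rate times the time-integral of
#' biomass, floored at zero once depleted; multiplicative Gaussian noise
#' of coefficient of variation `noise_cv` is applied to the
#' concentrations. Defaults emulate a 30 h batch on a
#' glutamate/gluconate minimal medium (5 g/L each, i.e. 26.7 and
#' 22.9 mM) inoculated at OD600 0.1.
#'
#' @param mu growth rate, 1/h.
#' @param true_uptakes named vector of specific uptake rates,
#'   mmol/gCDW/h.
#' @param c0 named vector of initial concentrations, mM (defaults match
#'   `true_uptakes` names).
#' @param x0 initial biomass, gCDW/L.
#' @param t_max culture duration, h.
#' @param n_points number of samples (>= 3).
#' @param noise_cv concentration noise, as a fraction.
#' @param seed RNG seed for reproducibility.
#' @return a `consumption_series`; the generating parameters are
#'   attached as `attr(x, "truth")`.
#' @export
make_consumption_series <- function(mu = 0.17,
                                    true_uptakes = c(glutamate = 0.35,
                                                     gluconate = 0.66),
                                    c0 = NULL, x0 = 0.074,
                                    t_max = 30, n_points = 16L,
                                    noise_cv = 0, seed = NULL) {
  stopifnot(n_points >= 3, mu > 0, x0 > 0, all(true_uptakes >= 0))
  if (is.null(c0)) {
    c0 <- stats::setNames(c(26.7, 22.9)[seq_along(true_uptakes)],
                          names(true_uptakes))
  }
  times <- seq(0, t_max, length.out = n_points)
  biomass <- x0 * exp(mu * times)
  integral <- x0 * (exp(mu * times) - 1) / mu
  conc <- sapply(names(true_uptakes), function(s) {
    pmax(0, c0[[s]] - true_uptakes[[s]] * integral)
  })
  conc <- as.data.frame(conc)
  if (noise_cv > 0) {
    conc[] <- with_seed(seed, {
      lapply(conc, function(x) pmax(0, x * (1 + stats::rnorm(length(x), 0, noise_cv))))
    })
  }
  out <- consumption_series(times, conc, biomass = biomass)
  attr(out, "truth") <- list(mu = mu, true_uptakes = true_uptakes,
                             c0 = c0, x0 = x0, noise_cv = noise_cv,
                             seed = seed)
  out
}

#' Write a consumption series to CSV
#'
#' Inverse of [read_consumption_csv()]: columns `time`, one per
#' substrate, and `cdw`.
#'
#' @param series a `consumption_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_consumption_csv <- function(series, path) {
  df <- cbind(data.frame(time = series$times), series$concentrations,
              data.frame(cdw = series$biomass))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate a random protein specification
#'
#' Residues drawn uniformly over the 20 amino acids; the molecular
#' weight is computed from average residue masses plus one water.
#'
#' @param length number of residues (>= 1).
#' @param seed RNG seed.
#' @return a `protein_spec`.
#' @export
make_synthetic_protein <- function(length, seed = NULL) {
  stopifnot(length >= 1)
  masses <- aa_residue_masses()
  draws <- with_seed(seed, sample(names(masses), length, replace = TRUE))
  counts <- table(factor(draws, levels = names(masses)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0]
  mw <- sum(masses[names(counts)] * counts) + 18.0153
  protein_spec(paste0("synprot", length), counts, mw)
}
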