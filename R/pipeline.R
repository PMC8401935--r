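#' Pipeline configuration
#'
#' Bundles every input of the end-to-end analysis: the base model, the
#' heterologous protein and plasmid, the culture measurements, the
#' medium, and the settings of each downstream stage.
#'
#' @param model a `metabolic_model` or a path to an SBML file.
#' @param protein a `protein_spec`.
#' @param plasmid a `plasmid_spec`.
#' @param genome list with `genome_length_bp` and
#'   `chromosomal_dna_coeff` (see [phtac125_genome()]).
#' @param measurements a `burden_measurements`.
#' @param wt_growth_rate measured wild-type growth rate, 1/h, used to
#'   derive the growth fraction from the measurements.
#' @param uptake_bounds named vector: exchange id -> uptake.
#' @param biomass_reaction biomass reaction id in the base model.
#' @param growth_fraction recombinant growth fraction; `NULL` derives
#'   it as `average_growth_rate(measurements) / wt_growth_rate`.
#' @param core window settings, a `core_criterion`.
#' @param amendment_uptake uptake granted to screened compounds.
#' @param fseof an `fseof_config`.
#' @param extracellular extracellular compartment id.
#' @param output_dir where tables are written; `NULL` disables writing.
#' @param seed RNG seed recorded with the run (the analysis itself is
#'   deterministic; the seed feeds any synthetic-input generation).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(model, protein, plasmid,
                            genome = phtac125_genome(),
                            measurements = hcdkl5_measurements(),
                            wt_growth_rate = gg_conditions()$wt_growth_rate,
                            uptake_bounds, biomass_reaction,
                            growth_fraction = NULL,
                            core = core_criterion(),
                            amendment_uptake = gg_conditions()$amendment_uptake,
                            fseof = fseof_config(),
                            extracellular = "e",
                            output_dir = NULL, seed = 1L) {
  if (is.character(model)) {
    if (!file.exists(model)) stop("model file not found: ", model)
    model <- read_sbml_model(model)
  }
  stopifnot(inherits(model, "metabolic_model"),
            inherits(protein, "protein_spec"),
            inherits(plasmid, "plasmid_spec"),
            inherits(measurements, "burden_measurements"),
            biomass_reaction %in% model$reactions$id)
  if (is.null(growth_fraction)) {
    growth_fraction <- average_growth_rate(measurements$od_initial,
                                           measurements$od_final,
                                           measurements$duration) / wt_growth_rate
  }
  structure(list(model = model, protein = protein, plasmid = plasmid,
                 genome = genome, measurements = measurements,
                 wt_growth_rate = wt_growth_rate,
                 uptake_bounds = unlist(uptake_bounds),
                 biomass_reaction = biomass_reaction,
                 growth_fraction = growth_fraction, core = core,
                 amendment_uptake = amendment_uptake, fseof = fseof,
                 extracellular = extracellular,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

#' Attach heterologous production machinery to a base model
#'
#' Adds the plasmid replication reaction, the protein synthesis
#' reaction, and the plasmid biomass term, returning the recombinant
#' reconstruction plus the generated reactions.
#'
#' @param model base `metabolic_model`.
#' @param protein a `protein_spec`.
#' @param plasmid a `plasmid_spec`.
#' @param genome genome constants (see [phtac125_genome()]).
#' @param biomass_reaction biomass reaction id.
#' @param compartment compartment for created species.
#' @param add_product_demand add a demand drain `DM_<product>` for the
#'   cytosolic protein species (default `TRUE`). The protein is not
#'   secreted -- no transporter is created -- but a steady-state model
#'   can only carry synthesis flux into a species that is drained, so
#'   accumulation is represented by a free boundary demand.
#' @return list: `model` (extended), `protein_reaction`,
#'   `plasmid_reaction`, `plasmid_biomass_coefficient`.
#' @export
build_recombinant_reconstruction <- function(model, protein, plasmid,
                                             genome = phtac125_genome(),
                                             biomass_reaction,
                                             compartment = "c",
                                             add_product_demand = TRUE) {
  prot_rxn <- build_protein_synthesis_reaction(protein, compartment = compartment)
  plas_rxn <- build_plasmid_synthesis_reaction(plasmid, compartment = compartment)
  coeff <- compute_plasmid_biomass_coefficient(
    genome$genome_length_bp, genome$chromosomal_dna_coeff,
    plasmid$length_bp, plasmid$copy_number)
  m <- add_synthesis_reaction(model, plas_rxn, compartment)
  m <- add_synthesis_reaction(m, prot_rxn, compartment)
  m <- augment_biomass(m, plas_rxn$product, coeff, biomass_reaction)
  if (add_product_demand) {
    m <- add_reaction(m, paste0("DM_", protein$name),
                      stats::setNames(-1, prot_rxn$product),
                      subsystem = "Demand",
                      name = paste("Accumulation of", protein$name))
  }
  list(model = m, protein_reaction = prot_rxn, plasmid_reaction = plas_rxn,
       plasmid_biomass_coefficient = coeff)
}

#' Run the full burden analysis pipeline
#'
#' Executes, in order: recombinant reconstruction, burden calibration,
#' wild-type/producing predictions and production envelope,
#' core/differential flux comparison, single-compound medium screen,
#' and the FSEOF overexpression-target scan. Tables are written under
#' `config$output_dir` when set; every LP status is recorded in the run
#' log.
#'
#' @param config a `pipeline_config`.
#' @return a report list with components `construction`, `calibration`,
#'   `predictions`, `envelope`, `comparison`, `screen`, `fseof`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_tsv <- function(df, file) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  note("run seed: ", config$seed, "; solver: bundled bounded-variable simplex")

  ## 1. recombinant reconstruction
  cons <- build_recombinant_reconstruction(
    config$model, config$protein, config$plasmid, config$genome,
    config$biomass_reaction)
  note("construction: plasmid biomass coefficient ",
       format(cons$plasmid_biomass_coefficient))
  if (!is.null(out_dir)) {
    write_sbml_model(cons$model, file.path(out_dir, "recombinant_model.xml"))
    write_reaction_tsv(cons$model, file.path(out_dir, "reactions.tsv"))
  }

  ## 2. calibration
  mm <- config$measurements
  calib <- list(
    production_flux = average_production_flux(mm),
    growth_rate = average_growth_rate(mm$od_initial, mm$od_final, mm$duration),
    final_cdw = cdw_from_od(mm$od_final, mm$od_to_cdw))
  calib$burden_percent <- burden_percent(calib$growth_rate,
                                         config$wt_growth_rate)
  note("calibration: production flux ", format(calib$production_flux),
       " mmol/gCDW/h, growth ", format(calib$growth_rate), " 1/h")
  save_tsv(data.frame(quantity = names(calib),
                      value = unlist(calib)), "calibration.tsv")

  ## 3. condition models and predictions
  cfg <- condition_config(config$uptake_bounds,
                          growth_fraction = config$growth_fraction,
                          biomass_reaction = config$biomass_reaction,
                          product_reaction = cons$protein_reaction$id)
  wt <- build_wt_model(cons$model, cfg)
  wt_sol <- fba(wt)
  note("wt FBA: ", wt_sol$status, ", growth ", format(wt_sol$objective_value))
  recomb <- build_recomb_model(cons$model, cfg, wt_growth = wt_sol$objective_value)
  rec_sol <- fba(recomb)
  note("recomb FBA: ", rec_sol$status, ", product flux ",
       format(rec_sol$objective_value))
  env <- production_envelope(wt, cfg$biomass_reaction, cfg$product_reaction)
  predictions <- list(wt_growth = wt_sol$objective_value,
                      recomb_product_flux = rec_sol$objective_value,
                      growth_fraction = cfg$growth_fraction)
  if (!is.null(out_dir)) {
    utils::write.csv(env, file.path(out_dir, "production_envelope.csv"),
                     row.names = FALSE)
  }
  save_tsv(data.frame(quantity = names(predictions),
                      value = unlist(predictions)), "predictions.tsv")

  ## 4. differential flux comparison
  cmp <- increased_flux_reactions(
    list(solution = wt_sol, ranges = fva(wt)),
    list(solution = rec_sol, ranges = fva(recomb)),
    config$core, model = cons$model)
  note("core wt: ", sum(cmp$core_a), "; core recomb: ", sum(cmp$core_b),
       "; increased: ", sum(cmp$increased))
  save_tsv(cmp, "flux_comparison.tsv")

  ## 5. medium screen
  compounds <- transported_compounds(cons$model, config$extracellular)
  base_mets <- unlist(lapply(names(config$uptake_bounds),
                             function(rid) names(cons$model$stoichiometry[[rid]])))
  compounds <- setdiff(compounds, base_mets)
  screen <- screen_amendments(recomb, compounds,
                              amendment_uptake = config$amendment_uptake)
  note("screen: ", nrow(screen), " compounds; best ",
       if (nrow(screen)) screen$compound_id[1] else "none")
  save_tsv(screen, "amendment_screen.tsv")

  ## 6. FSEOF
  scan <- fseof_scan(wt, cfg$biomass_reaction, cfg$product_reaction,
                     config$fseof)
  pathways <- group_by_pathway(scan$targets)
  note("fseof: ", nrow(scan$targets), " gene-encoded targets")
  save_tsv(scan$targets, "fseof_targets.tsv")
  save_tsv(pathways, "fseof_pathways.tsv")
  if (!is.null(out_dir)) {
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }

  list(construction = cons, calibration = calib, predictions = predictions,
       envelope = env, comparison = cmp, screen = screen,
       fseof = list(targets = scan$targets, pathways = pathways),
       log = log)
}
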