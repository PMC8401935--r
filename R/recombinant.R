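#' Heterologous protein specification
#'
#' @param name protein/species name (used for the product metabolite).
#' @param aa_counts named non-negative integer vector of residue counts,
#'   keyed by one-letter amino-acid code; must sum to at least 1.
#' @param molecular_weight protein molecular weight, mg/mmol.
#' @return object of class `protein_spec`.
#' @export
protein_spec <- function(name, aa_counts, molecular_weight) {
  aa_counts <- aa_counts[aa_counts > 0]
  unknown <- setdiff(names(aa_counts), names(aa_residue_masses()))
  if (length(unknown)) {
    stop("unknown amino-acid letter(s): ", paste(unknown, collapse = ", "))
  }
  if (length(aa_counts) == 0 || sum(aa_counts) < 1) {
    stop("protein must contain at least one residue")
  }
  if (any(aa_counts != round(aa_counts)) || any(aa_counts < 0)) {
    stop("aa_counts must be non-negative integers")
  }
  if (!is.numeric(molecular_weight) || molecular_weight <= 0) {
    stop("molecular_weight must be positive")
  }
  structure(list(name = name,
                 aa_counts = stats::setNames(as.integer(aa_counts), names(aa_counts)),
                 molecular_weight = molecular_weight),
            class = "protein_spec")
}

#' Read a protein specification from FASTA or a counts table
#'
#' FASTA input must hold a single record; a TSV must have columns `aa`
#' (one-letter code) and `count`. The molecular weight is computed from
#' average residue masses plus one water unless supplied.
#'
#' @param path FASTA (`.fa`, `.fasta`) or TSV file.
#' @param name protein name; defaults to the FASTA header or file name.
#' @param molecular_weight optional override, mg/mmol.
#' @return a `protein_spec`.
#' @export
read_protein_spec <- function(path, name = NULL, molecular_weight = NULL) {
  lines <- readLines(path)
  if (any(startsWith(lines, ">"))) {
    heads <- which(startsWith(lines, ">"))
    if (length(heads) != 1) stop("protein FASTA must contain exactly one record")
    seq <- toupper(gsub("[^A-Za-z*]", "", paste(lines[-heads], collapse = "")))
    seq <- gsub("\\*$", "", seq)
    counts <- table(strsplit(seq, "")[[1]])
    aa <- stats::setNames(as.integer(counts), names(counts))
    if (is.null(name)) name <- sub("^>\\s*(\\S+).*", "\\1", lines[heads])
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    aa <- stats::setNames(as.integer(df$count), df$aa)
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(molecular_weight)) {
    molecular_weight <- sum(aa_residue_masses()[names(aa)] * aa) + 18.0153
  }
  protein_spec(name, aa, molecular_weight)
}

#' Expression plasmid specification
#'
#' @param name plasmid/species name.
#' @param length_bp plasmid length in base pairs.
#' @param gc_fraction GC content in `[0, 1]`; recomputed from `sequence`
#'   when one is given.
#' @param copy_number average plasmid copies per cell (Pcn).
#' @param atp_cost_per_copy ATP per plasmid copy unit for replication
#'   (0.21 for pB40, scaled from the chromosomal DNA synthesis cost).
#' @param sequence optional plasmid nucleotide sequence; overrides
#'   `length_bp` and `gc_fraction`.
#' @return object of class `plasmid_spec`.
#' @export
plasmid_spec <- function(name, length_bp, gc_fraction, copy_number,
                         atp_cost_per_copy = 0.21, sequence = NULL) {
  if (!is.null(sequence)) {
    sequence <- toupper(gsub("[^A-Za-z]", "", sequence))
    length_bp <- nchar(sequence)
    gc_fraction <- mean(strsplit(sequence, "")[[1]] %in% c("G", "C"))
  }
  if (length_bp <= 0 || length_bp != round(length_bp)) {
    stop("length_bp must be a positive integer")
  }
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must lie in [0, 1]")
  if (copy_number <= 0 || copy_number != round(copy_number)) {
    stop("copy_number must be a positive integer")
  }
  structure(list(name = name, length_bp = as.integer(length_bp),
                 gc_fraction = gc_fraction,
                 copy_number = as.integer(copy_number),
                 atp_cost_per_copy = atp_cost_per_copy),
            class = "plasmid_spec")
}

#' Generate the heterologous protein synthesis reaction
#'
#' Consumes the free amino acids per the protein composition and the
#' translation energy budget of four high-energy phosphate equivalents
#' per residue, split mechanistically: 2 ATP -> AMP per residue for
#' tRNA charging and 2 GTP -> GDP per peptide bond for elongation, so a
#' chain of N residues costs 2N ATP and 2(N-1) GTP and releases
#' 2N AMP, 2(N-1) GDP and 4N-2 Pi. The product is a cytosolic protein
#' species with no exporter (the protein is not secreted).
#'
#' @param protein a `protein_spec`.
#' @param aa_map named character vector mapping one-letter codes to model
#'   metabolite ids; every composition letter must be mapped.
#' @param compartment compartment tag for the currency metabolites and
#'   product.
#' @param currency named list overriding the currency metabolite ids
#'   (`atp`, `gtp`, `amp`, `gdp`, `pi`).
#' @return a `synthesis_reaction`: list with `id`, `name`,
#'   `stoichiometry` (named numeric, negative = consumed), bounds, and
#'   `provenance` tagging the derivation rule of every coefficient.
#' @export
build_protein_synthesis_reaction <- function(protein,
                                             aa_map = default_aa_metabolites(compartment),
                                             compartment = "c",
                                             currency = NULL) {
  stopifnot(inherits(protein, "protein_spec"))
  cur <- list(atp = paste0("atp[", compartment, "]"),
              gtp = paste0("gtp[", compartment, "]"),
              amp = paste0("amp[", compartment, "]"),
              gdp = paste0("gdp[", compartment, "]"),
              pi = paste0("Pi[", compartment, "]"))
  cur[names(currency)] <- currency
  counts <- protein$aa_counts
  unmapped <- setdiff(names(counts), names(aa_map))
  if (length(unmapped)) {
    stop("no metabolite mapping for amino acid(s): ",
         paste(unmapped, collapse = ", "))
  }
  n <- sum(counts)
  atp <- 2 * n
  gtp <- 2 * (n - 1)
  product <- paste0(protein$name, "[", compartment, "]")
  st <- c(stats::setNames(-as.numeric(counts), aa_map[names(counts)]),
          stats::setNames(c(-atp, -gtp, 1, atp, gtp, atp + gtp),
                          c(cur$atp, cur$gtp, product,
                            cur$amp, cur$gdp, cur$pi)))
  prov <- c(stats::setNames(rep("residue count", length(counts)),
                            aa_map[names(counts)]),
            stats::setNames(c("2 ATP per residue (charging)",
                              "2 GTP per peptide bond (elongation)",
                              "product",
                              "AMP = ATP consumed",
                              "GDP = GTP consumed",
                              "Pi = ATP + GTP consumed"),
                            c(cur$atp, cur$gtp, product,
                              cur$amp, cur$gdp, cur$pi)))
  prov <- prov[names(st)[st != 0]]
  st <- st[st != 0]
  structure(list(id = paste0(protein$name, "_synthesis"),
                 name = paste("Synthesis of", protein$name),
                 stoichiometry = st, lower_bound = 0, upper_bound = 1000,
                 product = product, provenance = prov),
            class = "synthesis_reaction")
}

#' Generate the plasmid replication reaction
#'
#' dNTP demand follows double-stranded base composition at one plasmid
#' copy unit per strand pair: `dATP = dTTP = Pcn * (1 - GC)` and
#' `dGTP = dCTP = Pcn * GC`, so the four coefficients sum to
#' `2 * Pcn`. Replication energy is `atp_cost_per_copy * Pcn` ATP
#' hydrolysed to ADP, with matching H2O, Pi and H.
#'
#' @param plasmid a `plasmid_spec`.
#' @param compartment compartment tag.
#' @return a `synthesis_reaction` producing one plasmid species.
#' @export
build_plasmid_synthesis_reaction <- function(plasmid, compartment = "c") {
  stopifnot(inherits(plasmid, "plasmid_spec"))
  pcn <- plasmid$copy_number
  gc <- plasmid$gc_fraction
  atp <- plasmid$atp_cost_per_copy * pcn
  at <- pcn * (1 - gc)
  gcx <- pcn * gc
  tag <- function(x) paste0(x, "[", compartment, "]")
  st <- stats::setNames(
    c(-atp, -atp, -at, -gcx, -gcx, -at, 1, atp, atp, atp),
    c(tag("h2o"), tag("atp"), tag("datp"), tag("dgtp"), tag("dctp"),
      tag("dttp"), plasmid$name, tag("adp"), tag("Pi"), tag("h")))
  prov <- stats::setNames(
    c("ATP cost per copy x Pcn (water)", "ATP cost per copy x Pcn",
      "Pcn x (1 - GC)", "Pcn x GC", "Pcn x GC", "Pcn x (1 - GC)",
      "product", "ADP = ATP", "Pi = ATP", "H = ATP"),
    names(st))
  prov <- prov[names(st)[st != 0]]
  st <- st[st != 0]
  structure(list(id = paste0(plasmid$name, "_synthesis"),
                 name = paste("Replication of", plasmid$name),
                 stoichiometry = st, lower_bound = 0, upper_bound = 1000,
                 product = plasmid$name, provenance = prov),
            class = "synthesis_reaction")
}

#' @exportS3Method base::print
print.synthesis_reaction <- function(x, ...) {
  st <- x$stoichiometry
  fmt <- function(v) paste(
    vapply(seq_along(v), function(k) {
      co <- abs(v[k])
      if (co == 1) names(v)[k] else paste(format(co), names(v)[k])
    }, character(1)), collapse = " + ")
  cat("<synthesis_reaction>", x$id, "\n ",
      fmt(st[st < 0]), "->", fmt(st[st > 0]), "\n")
  invisible(x)
}

#' Plasmid stoichiometric coefficient for the biomass reaction
#'
#' Scales the chromosomal-DNA biomass coefficient by the total plasmid
#' DNA content (plasmid length times copy number) relative to genome
#' length:
#' `coeff = chromosomal_dna_coeff * plasmid_length_bp * copy_number / genome_length_bp`.
#' This total-plasmid-DNA scaling reproduces the published pB40
#' coefficient of 0.000341 for 100 copies of the 8166 bp plasmid against
#' the 3,850,272 bp genome (DNA coefficient 0.001608).
#'
#' @param genome_length_bp genome size, bp.
#' @param chromosomal_dna_coeff DNA coefficient in the biomass reaction.
#' @param plasmid_length_bp plasmid size, bp.
#' @param copy_number plasmid copies per cell.
#' @return the plasmid biomass coefficient.
#' @export
compute_plasmid_biomass_coefficient <- function(genome_length_bp,
                                                chromosomal_dna_coeff,
                                                plasmid_length_bp,
                                                copy_number) {
  if (any(c(genome_length_bp, chromosomal_dna_coeff,
            plasmid_length_bp, copy_number) <= 0)) {
    stop("all inputs must be positive")
  }
  chromosomal_dna_coeff * (plasmid_length_bp * copy_number) / genome_length_bp
}

#' Add a generated synthesis reaction to a model
#'
#' Creates any metabolites the reaction references that the model lacks
#' (in the given compartment) and appends the reaction.
#'
#' @param model a `metabolic_model`.
#' @param reaction a `synthesis_reaction`.
#' @param compartment compartment assigned to newly created species.
#' @return the extended model.
#' @export
add_synthesis_reaction <- function(model, reaction, compartment = "c") {
  stopifnot(inherits(reaction, "synthesis_reaction"))
  st <- reaction$stoichiometry
  new_ids <- setdiff(names(st), model$metabolites$id)
  new_mets <- if (length(new_ids)) {
    data.frame(id = new_ids, name = new_ids,
               compartment = compartment, formula = NA_character_,
               stringsAsFactors = FALSE)
  } else NULL
  add_reaction(model, reaction$id, st,
               lower_bound = reaction$lower_bound,
               upper_bound = reaction$upper_bound,
               name = reaction$name, new_metabolites = new_mets)
}

#' Include the plasmid species in the biomass reaction
#'
#' Adds the plasmid as a biomass precursor at the given stoichiometric
#' coefficient, so plasmid replication draws resources in proportion to
#' growth; all other biomass coefficients are untouched.
#'
#' @param model a `metabolic_model`.
#' @param plasmid_species plasmid metabolite id (must exist in the
#'   model, i.e. its synthesis reaction was added first).
#' @param coefficient plasmid per unit biomass (positive; consumed).
#' @param biomass_reaction biomass reaction id; defaults to the model
#'   objective.
#' @return the modified model.
#' @export
augment_biomass <- function(model, plasmid_species, coefficient,
                            biomass_reaction = model$objective$reaction) {
  if (!biomass_reaction %in% model$reactions$id) {
    stop("biomass reaction not found: ", biomass_reaction)
  }
  if (!plasmid_species %in% model$metabolites$id) {
    stop("plasmid species not in model: ", plasmid_species,
         " (add its synthesis reaction first)")
  }
  st <- model$stoichiometry[[biomass_reaction]]
  st[plasmid_species] <- (if (plasmid_species %in% names(st)) st[[plasmid_species]] else 0) -
    coefficient
  if (st[[plasmid_species]] == 0) st <- st[names(st) != plasmid_species]
  model$stoichiometry[[biomass_reaction]] <- st
  validate_model(model)
}

#' Amino-acid composition difference against a reference proteome
#'
#' Compares the relative amino-acid frequencies of a protein with those
#' of a host proteome: positive entries mark residues enriched in the
#' protein (the drivers of pathway-level flux shifts upon production).
#' The differences sum to zero.
#'
#' @param proteome_counts named numeric vector of proteome amino-acid
#'   frequencies or counts (one-letter codes); normalised internally.
#' @param protein a `protein_spec`.
#' @return named numeric vector over the union of amino acids.
#' @export
composition_delta <- function(proteome_counts, protein) {
  stopifnot(inherits(protein, "protein_spec"))
  if (length(proteome_counts) == 0 || sum(proteome_counts) <= 0) {
    stop("empty proteome composition")
  }
  aas <- union(names(proteome_counts), names(protein$aa_counts))
  ref <- stats::setNames(numeric(length(aas)), aas)
  ref[names(proteome_counts)] <- proteome_counts / sum(proteome_counts)
  prot <- stats::setNames(numeric(length(aas)), aas)
  prot[names(protein$aa_counts)] <- protein$aa_counts / sum(protein$aa_counts)
  prot - ref
}
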