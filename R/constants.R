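## Bundled study constants: the hCDKL5 construct composition, the pB40
## expression plasmid, and the PhTAC125 GG-medium culture measurements.
## These let every construction and calibration step be regenerated
## offline from first inputs.

#' Amino-acid composition of the hCDKL5 construct
#'
#' Residue counts of the 1144-aa engineered hCDKL5 variant (His-Sumo and
#' Tatk N-terminal tags, C-terminal 3xflag) expressed in
#' *P. haloplanktis* TAC125, keyed by one-letter code.
#'
#' @return named integer vector over the 20 amino acids (sums to 1144).
#' @export
hcdkl5_aa_counts <- function() {
  c(A = 59L, C = 6L, D = 63L, E = 76L, F = 32L, G = 72L, H = 49L,
    I = 39L, K = 84L, L = 101L, M = 20L, N = 59L, P = 80L, Q = 53L,
    R = 76L, S = 140L, T = 56L, V = 41L, W = 6L, Y = 32L)
}

#' The hCDKL5 protein specification
#'
#' Composition from [hcdkl5_aa_counts()] and the construct molecular
#' weight of 128,082.77 mg/mmol.
#'
#' @return a `protein_spec`.
#' @export
hcdkl5_protein <- function() {
  protein_spec("cdkl5", hcdkl5_aa_counts(), molecular_weight = 128082.77)
}

#' The pB40 expression plasmid specification
#'
#' 8166 bp, GC fraction 0.43, average copy number 100, ATP cost of 0.21
#' per plasmid copy unit (scaled from the chromosomal DNA synthesis
#' cost).
#'
#' @return a `plasmid_spec`.
#' @export
pb40_plasmid <- function() {
  plasmid_spec("pB40", length_bp = 8166L, gc_fraction = 0.43,
               copy_number = 100L, atp_cost_per_copy = 0.21)
}

#' PhTAC125 genome constants used for the plasmid biomass coefficient
#'
#' @return list with `genome_length_bp` (3,850,272) and
#'   `chromosomal_dna_coeff` (0.001608, the DNA coefficient in the
#'   biomass assembly reaction).
#' @export
phtac125_genome <- function() {
  list(genome_length_bp = 3850272, chromosomal_dna_coeff = 0.001608)
}

#' hCDKL5 production-run measurements
#'
#' The GG-medium culture scalars behind the burden calibration: 5.2 mg/L
#' titer over the 8 h induction, OD600 0.94 -> 2.55, OD-to-CDW factor
#' 0.74 g/L per OD, and the construct molecular weight.
#'
#' @return a `burden_measurements` object.
#' @export
hcdkl5_measurements <- function() {
  burden_measurements(titer = 5.2, duration = 8,
                      od_initial = 0.94, od_final = 2.55,
                      od_to_cdw = 0.74, protein_mw = 128082.77)
}

#' GG-medium study conditions
#'
#' The experimentally determined substrate uptake rates (glutamate 0.35,
#' gluconate 0.66 mmol/gCDW/h), the wild-type average growth rate
#' (0.169 1/h), the recombinant growth fraction used when optimising
#' production, and the amendment-screen uptake (0.5 mmol/gCDW/h).
#'
#' @return named list of study constants.
#' @export
gg_conditions <- function() {
  list(uptake_bounds = c(glutamate = 0.35, gluconate = 0.66),
       wt_growth_rate = 0.169,
       growth_fraction = 0.74,
       amendment_uptake = 0.5)
}

#' Host proteome amino-acid frequencies (synthetic stand-in)
#'
#' Relative amino-acid frequencies of a typical bacterial proteome,
#' shipped as a stand-in for the PhTAC125 proteome composition (whose
#' exact frequencies are not published as a table). Used as the
#' reference in [composition_delta()] and to set the amino-acid share of
#' the synthetic study network's biomass reaction. Against this
#' reference, hCDKL5 is roughly two-fold enriched in histidine and
#' serine.
#'
#' @return named numeric vector over the 20 amino acids, summing to 1.
#' @export
proteome_aa_frequencies <- function() {
  path <- system.file("extdata", "proteome_aa_freq_synthetic.tsv",
                      package = "fluxburden")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$frequency, df$aa)
}

#' Average residue masses of the 20 amino acids
#'
#' Monomer-in-chain (water-subtracted) average masses in mg/mmol, used to
#' compute synthetic-protein molecular weights (plus one water per
#' chain).
#'
#' @return named numeric vector keyed by one-letter code.
#' @export
aa_residue_masses <- function() {
  c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
}

#' Default mapping from one-letter amino acids to model metabolite ids
#'
#' Cytosolic free amino-acid species in the `Xxx[c]` namespace used by
#' the PhTAC125 reconstruction.
#'
#' @param compartment compartment tag (default "c").
#' @return named character vector, one-letter code -> metabolite id.
#' @export
default_aa_metabolites <- function(compartment = "c") {
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             E = "Glu", Q = "Gln", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")
  stats::setNames(paste0(three, "[", compartment, "]"), names(three))
}
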