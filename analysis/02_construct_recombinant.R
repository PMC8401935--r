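# Stage 2 -- recombinant model construction.
# Generates the pB40 replication reaction, the hCDKL5 synthesis
# reaction and the plasmid biomass term from sequence-level inputs,
# and attaches them to the host network.

source("analysis/00_setup.R")

protein <- hcdkl5_protein()
plasmid <- pb40_plasmid()

cat("Generated production reactions:\n")
print(build_plasmid_synthesis_reaction(plasmid))
print(build_protein_synthesis_reaction(protein))

cons <- study$construction
cat(sprintf("\npB40 biomass coefficient: %.3g (chromosomal DNA coefficient\n",
            cons$plasmid_biomass_coefficient))
cat("scaled by total plasmid DNA over genome length)\n")

write_sbml_model(cons$model,
                 file.path(results_dir, "recombinant_model.xml"))
cat("  wrote", file.path(results_dir, "recombinant_model.xml"), "\n")
write_reaction_tsv(cons$model, file.path(results_dir, "reactions.tsv"))
cat("  wrote", file.path(results_dir, "reactions.tsv"), "\n")

# amino-acid composition of the product vs the host proteome: the
# positive deltas mark residues whose biosynthesis the product strains
delta <- composition_delta(proteome_aa_frequencies(), protein)
dtab <- data.frame(aa = names(delta), delta = unname(delta))
dtab <- dtab[order(-dtab$delta), ]
cat("\nMost product-enriched residues (relative frequency delta):\n")
print(head(dtab, 5), row.names = FALSE)
save_tsv(dtab, "composition_delta.tsv")
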