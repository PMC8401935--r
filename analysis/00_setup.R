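# Shared objects for the analysis scripts: the study constants and the
# synthetic study network (a closed-form host emulating growth on
# glutamate + gluconate, carrying the generated pB40 and hCDKL5
# machinery). To rerun the model-based stages on the published
# iMF721_v2 reconstruction instead, load it with read_sbml_model() and
# swap it in as `study$host` with the matching reaction ids.

library(fluxburden)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

seed <- 1L

study <- make_study_toy()
medium <- c(EX_glutamate = 0.35, EX_gluconate = 0.66)   # mmol/gCDW/h
cond <- condition_config(medium,
                         growth_fraction = 0.74,
                         biomass_reaction = "BIOMASS",
                         product_reaction = "cdkl5_synthesis")

save_tsv <- function(df, file) {
  write.table(df, file.path(results_dir, file), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("  wrote", file.path(results_dir, file), "\n")
}
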