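# Stage 5 -- carbon-source amendment screen.
# Enumerates transportable compounds, grants each one 0.5 mmol/gCDW/h
# of uptake on top of the glutamate/gluconate medium, and ranks the
# product-flux fold change; then inspects which reactions carry more
# flux under the best amendment.

source("analysis/00_setup.R")

recomb <- build_recomb_model(study$model, cond)
compounds <- transported_compounds(study$model)
baseline <- unlist(lapply(names(medium),
                          function(r) names(study$model$stoichiometry[[r]])))
candidates <- setdiff(compounds, baseline)
cat("Transportable non-medium compounds:", paste(candidates, collapse = ", "),
    "\n")

screen <- screen_amendments(recomb, candidates,
                            amendment_uptake = gg_conditions()$amendment_uptake)
cat("\nAmendment ranking (log10 fold change of product flux):\n")
print(screen[, c("compound_id", "ratio", "log_fold_change")],
      row.names = FALSE)
save_tsv(screen, "amendment_screen.tsv")

best <- screen$compound_id[1]
shift <- amendment_flux_shift(recomb, best,
                              amendment_uptake = gg_conditions()$amendment_uptake)
inc <- increased_set(shift)
cat(sprintf("\nReactions with increased flux under %s amendment: %d\n",
            best, nrow(inc)))
print(head(inc[, c("reaction_id", "flux_a", "flux_b", "subsystem")], 8),
      row.names = FALSE)
save_tsv(inc, "amendment_flux_shift.tsv")
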