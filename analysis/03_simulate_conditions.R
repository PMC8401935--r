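# Stage 3 -- condition models and predictions.
# Builds the paired wild-type and producing models on the
# glutamate/gluconate medium, predicts growth and product flux, and
# traces the production envelope.

source("analysis/00_setup.R")

wt <- build_wt_model(study$model, cond)
wt_sol <- fba(wt)
recomb <- build_recomb_model(study$model, cond, wt_growth = wt_sol$objective_value)
rec_sol <- fba(recomb)

pred <- data.frame(
  quantity = c("wt_growth_per_h", "growth_fraction",
               "recomb_product_flux_mmol_per_gCDW_h"),
  value = c(wt_sol$objective_value, cond$growth_fraction,
            rec_sol$objective_value))
cat("Model predictions on the synthetic study network:\n")
print(pred, row.names = FALSE)
cat(sprintf("(closed-form check: product at %.0f%% growth = %.6g)\n",
            100 * cond$growth_fraction,
            study$answers$product_at(cond$growth_fraction *
                                       study$answers$mu_max)))
save_tsv(pred, "predictions.tsv")

env <- production_envelope(wt, cond$biomass_reaction, cond$product_reaction,
                           n_points = 20)
write.csv(env, file.path(results_dir, "production_envelope.csv"),
          row.names = FALSE)
cat("  wrote", file.path(results_dir, "production_envelope.csv"), "\n")
cat(sprintf("Envelope: product %.4g at zero growth, 0 at mu_max %.4g;\n",
            env$product_max[1], max(env$growth)))
cat("biomass and product compete linearly for the precursor pool.\n")
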