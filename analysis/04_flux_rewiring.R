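# Stage 4 -- metabolic rewiring upon induction.
# FVA-filtered differential flux comparison between the wild-type and
# producing conditions: reactions whose flux is robust to optimum
# degeneracy (core, 30% window) in both conditions, and among them
# those carrying more flux when the product is made.

source("analysis/00_setup.R")

wt <- build_wt_model(study$model, cond)
recomb <- build_recomb_model(study$model, cond)

cmp <- increased_flux_reactions(
  list(solution = fba(wt), ranges = fva(wt)),
  list(solution = fba(recomb), ranges = fva(recomb)),
  core_criterion(window = 0.3), model = study$model)
save_tsv(cmp, "flux_comparison.tsv")

inc <- increased_set(cmp)
cat(sprintf("Core reactions: %d (wt), %d (recomb); increased in recomb: %d\n",
            sum(cmp$core_a), sum(cmp$core_b), nrow(inc)))
cat("Top increased reactions (product-enriched residue supplies lead):\n")
print(head(inc[, c("reaction_id", "flux_a", "flux_b", "subsystem")], 8),
      row.names = FALSE)
save_tsv(inc, "increased_reactions.tsv")
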