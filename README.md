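# fluxburden

Constraint-based analysis of the metabolic burden of heterologous
protein production, built around the recombinant hCDKL5 production
system in the Antarctic bacterium *Pseudoalteromonas haloplanktis*
TAC125 (PhTAC125). The package turns sequence-level inputs (a protein
composition, a plasmid description) and culture measurements (titer,
optical densities, substrate consumption) into a recombinant
genome-scale metabolic model and a set of in silico analyses that
explain where the burden falls and how production could be improved.

hCDKL5 — human cyclin-dependent kinase-like 5 — is a
difficult-to-produce therapeutic enzyme for which PhTAC125 is the only
prokaryotic host demonstrated to make the full-length protein. Who this
package is for: modellers who want to rebuild or extend that analysis,
and anyone constructing recombinant-production variants of a
genome-scale model from first inputs.

## What it computes

**Construction.** From a protein of composition `n_a` (N = Σ n_a
residues) the synthesis reaction

    Σ n_a AA_a + 2N ATP + 2(N−1) GTP → protein + 2N AMP + 2(N−1) GDP + (4N−2) Pi

i.e. four high-energy phosphate equivalents per residue, split as 2 ATP
for amino-acid charging and 2 GTP per elongation step. For the
1144-residue hCDKL5 construct this gives 2288 ATP, 2286 GTP and 4574 Pi.
From a plasmid of length L, GC fraction g and copy number Pcn, the
replication reaction consumes `Pcn·(1−g)` dATP = dTTP, `Pcn·g` dGTP =
dCTP and `0.21·Pcn` ATP (for pB40: 57/43/43/57 dNTPs and 21 ATP), and
the plasmid enters the biomass reaction with coefficient
`c_DNA · L · Pcn / L_genome` (0.000341 for pB40).

**Calibration.** Average production flux
`(titer/Δt) / MW / (OD_final · 0.74)` = 2.7·10⁻⁶ mmol/gCDW/h for the
measured 5.2 mg/L over 8 h; growth rate `ln(OD_f/OD_i)/Δt` = 0.125 1/h,
a 26% burden against the wild-type 0.169 1/h. Specific uptake rates are
the slope of substrate consumed regressed on the time-integral of
biomass.

**Simulation.** Paired condition models — wild type (biomass objective)
and producer (growth floored at 74% of the wild-type optimum, product
objective) — solved by flux balance analysis (FBA) on a bundled
bounded-variable simplex; flux variability analysis (FVA) with a 30%
core window filters degeneracy-robust fluxes for the differential
comparison; a production envelope traces the growth/product trade-off;
a single-compound amendment screen ranks extra carbon sources by
product-flux fold change; and FSEOF (flux scanning based on enforced
objective flux, 100 steps up to 90% of the product maximum) ranks
overexpression targets.

## Worked example

```r
library(fluxburden)

# a synthetic study network with closed-form optima, carrying the real
# generated pB40 and hCDKL5 reactions
st <- make_study_toy()
print(build_protein_synthesis_reaction(hcdkl5_protein()))
#> <synthesis_reaction> cdkl5_synthesis
#>   59 Ala[c] + 6 Cys[c] + ... + 2288 atp[c] + 2286 gtp[c] ->
#>   cdkl5[c] + 2288 amp[c] + 2286 gdp[c] + 4574 Pi[c]

cond <- condition_config(c(EX_glutamate = 0.35, EX_gluconate = 0.66),
                         growth_fraction = 0.74,
                         biomass_reaction = "BIOMASS",
                         product_reaction = "cdkl5_synthesis")
fba(build_wt_model(st$model, cond))$objective_value
#> [1] 0.120745          # wild-type growth, 1/h
fba(build_recomb_model(st$model, cond))$objective_value
#> [1] 2.295622e-05      # product flux at the 74% growth floor, mmol/gCDW/h
```

The first number is the growth supported by the glutamate/gluconate
medium on this network; the second is the product flux left over once
74% of that growth is guaranteed — the same trade-off the production
envelope traces between (0, 8.8·10⁻⁵) and (0.12, 0).

The full workflow lives in `analysis/01_calibrate_burden.R` …
`analysis/06_fseof_targets.R`; each script prints what it found and
writes its tables under `results/`. Run them from the repository root,
e.g. `Rscript analysis/03_simulate_conditions.R`. They use the
synthetic study network; to run on the published PhTAC125
reconstruction, load it with `read_sbml_model()` and swap it in as
described in `analysis/00_setup.R`.

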