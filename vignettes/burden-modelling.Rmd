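---
title: "Modelling recombinant protein burden in a genome-scale metabolic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling recombinant protein burden in a genome-scale metabolic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxburden)
```

## The model and its assumptions

A genome-scale metabolic model (GEM) is a stoichiometric matrix $S$
(metabolites $\times$ reactions) with flux bounds $l \le v \le u$ in
mmol/gCDW/h. Flux balance analysis (FBA) assumes a metabolic steady
state, $S v = 0$, and predicts the flux distribution maximising a
designated objective reaction, here either the biomass assembly
reaction (whose flux approximates the growth rate) or the heterologous
product synthesis reaction. Exchange reactions carry mass across the
model boundary with the uptake-negative sign convention.

The package models the burden of producing the 1144-residue hCDKL5
construct in *P. haloplanktis* TAC125 as three stoichiometric drains
on the host:

1. **Plasmid replication.** A reaction consuming dNTPs in
   double-stranded base proportion — $\mathrm{dATP} = \mathrm{dTTP} =
   P_{cn}(1-g)$, $\mathrm{dGTP} = \mathrm{dCTP} = P_{cn}\,g$ for GC
   fraction $g$ and copy number $P_{cn}$ — plus replication energy of
   $0.21\,P_{cn}$ ATP hydrolysed to ADP + Pi. The dNTP coefficients
   follow the base composition at one copy unit per strand pair (they
   are not normalised by plasmid length; that is what reproduces the
   published pB40 reaction, whose four dNTP coefficients sum to
   $2 P_{cn} = 200$).
2. **Plasmid maintenance in biomass.** The plasmid species enters the
   biomass reaction with coefficient
   $c_{\mathrm{DNA}} \cdot L_{\mathrm{plasmid}} P_{cn} /
   L_{\mathrm{genome}}$ — the chromosomal DNA coefficient scaled by
   total plasmid DNA content. The alternative reading of the published
   proportion (per single plasmid copy, dividing by $P_{cn}$ again)
   yields a value 100-fold smaller than the published 0.000341; the
   total-DNA interpretation reproduces the published coefficient and is
   the one implemented.
3. **Protein synthesis.** Four high-energy phosphate equivalents per
   residue, realised mechanistically as 2 ATP → AMP per residue
   (amino-acid charging) and 2 GTP → GDP per peptide bond
   (elongation): for $N$ residues, $2N$ ATP, $2(N-1)$ GTP and $4N-2$
   Pi. This split, rather than a flat 4 ATP per residue, is what the
   published hCDKL5 reaction prints (2288/2286/4574 for $N = 1144$).
   The product is a cytosolic species with no transporter — the
   protein is not secreted. Because a steady-state model can only
   carry flux into a species that is drained, the reconstruction step
   adds a free demand reaction representing intracellular
   accumulation; this demand carries no energy cost and is not a
   secretion reaction.

mRNA synthesis for the heterologous gene is not modelled as a separate
reaction: no such reaction is part of the recombinant reconstruction
being reproduced, and its cost is far below the translation cost at
100 plasmid copies.

## Calibration from culture measurements

The producer strain's measured quantities fix the constraints:
specific production flux $(\mathrm{titer}/\Delta t)/M_W/(OD_f \cdot
0.74)$, average growth rate $\ln(OD_f/OD_i)/\Delta t$, and the burden
as the relative growth reduction against the wild type. The OD-to-CDW
factor 0.74 g/L per OD600 is a configurable constant. The wild-type
growth rate (0.169 1/h) is used as a measured constant; its own OD
inputs are not re-derived.

Substrate uptake rates are estimated from a consumption time series.
Under balanced growth at constant specific uptake $q$, consumption
obeys $C_0 - C(t) = q \int_0^t X\,dt$, so $q$ is the slope of consumed
substrate regressed on the time-integral of biomass (trapezoidal). No
estimator is prescribed by the study being reproduced (only the
resulting rates, 0.35 and 0.66 mmol/gCDW/h for glutamate and
gluconate); the integrated-biomass regression is chosen because it is
exact under the balanced-growth model and degrades gracefully under
sampling noise. The regression window runs from the first sample to
depletion (concentration below 5% of its initial value, configurable):
after depletion the concentration is flat and carries no rate
information. A flat series returns rate 0; a rising series is an
error, not a rate.

## The paired condition models

The wild-type model applies the medium (named uptake bounds; all other
organic-carbon uptake closed, inorganic exchanges left open) and
maximises biomass. The producer model floors the biomass flux at a
fraction of the wild-type optimum — 0.74, the measured
recombinant/wild-type growth ratio 0.125/0.169 rounded to two digits;
`pipeline_config()` re-derives it from the measurements rather than
hard-coding — and maximises product synthesis. The floor is a lower
bound, not an equality: it binds at the product optimum (so the results
coincide) but avoids spurious infeasibility on networks where growth
above the floor is cheap. Whether the fraction should apply to the
optimum of the plasmid-augmented or the bare model differs only through
the tiny plasmid biomass term; the augmented model's optimum is used,
and `build_recomb_model()` accepts an explicit `wt_growth` to override.

## Solver

No linear-programming package is part of this package's dependency
footprint; FBA and FVA run on a self-contained two-phase primal
simplex with bounded variables and Bland's anti-cycling rule
(`solve_lp()`). Numerical choices: feasibility tolerance $10^{-9}$
(below the smallest meaningful flux here, $2.7\cdot10^{-6}$); flux
comparisons at $10^{-6}$; basis systems re-factorised every iteration
(cheap at the network sizes used); degenerate ties broken by smallest
variable index, which also makes every solution deterministic.
Variables with two infinite bounds are rejected rather than silently
clamped — flux variables always carry at least one finite capacity.
FBA optima need not be unique; no canonicalisation (such as pFBA) is
applied, and the analyses that would be sensitive to vertex choice are
filtered through FVA instead (below). The solver is validated in the
test suite against a brute-force vertex-enumeration oracle, against a
second simplex implementation, and against an established external
constraint-based toolchain reading this package's SBML output.

At genome scale (thousands of reactions) this dense simplex is not
competitive with sparse LP solvers; the package's analyses of the full
published reconstruction are therefore practical only where that
trade-off is acceptable, and the bundled studies run on small networks
whose optima are known in closed form.

## FVA, core reactions and differential flux

Because alternate optima make single FBA vertices unreliable, the
differential analysis first runs FVA with the objective pinned at its
optimum (the constraint set of the preceding FBA, re-imposed as an
equality within tolerance; `fraction_of_optimum` is configurable). A
flux-carrying reaction is *core* when its FVA range stays within a
±30% window of its FBA flux — for $v > 0$, $f_{min} > 0.7v$ and
$f_{max} < 1.3v$; for $v < 0$ the mirrored window. The published
negative-flux branch repeats $f_{max}$ in both inequalities, which is
unsatisfiable as printed; the symmetric mirror is implemented.
Reactions core in both conditions whose flux magnitude rises in the
producer are reported as the rewiring set. Magnitudes (not signed
values) are compared so reversible reactions are handled consistently;
a signed comparison remains available. Shrinking the window provably
shrinks the core set, and the tests assert this monotonicity.

## Medium amendment screen

Candidate compounds are the extracellular species moved across the
boundary by at least one transport reaction (same chemical species in
two compartments — antiporters and symporters contribute every
translocated species), minus a blocklist of water, protons and
inorganic ions. Each candidate's exchange is opened to at least
0.5 mmol/gCDW/h of uptake on top of the unchanged baseline medium and
growth constraint, and the product is re-maximised. Opening a bound
can only relax the LP, so an amendment never lowers the optimum — the
tests assert this for every screened compound; a bound already wider
than the amendment is left untouched for the same reason. Results are
ranked by fold change (reported raw and as log10), ties broken
lexicographically for determinism. Reactions responding to the best
amendment are found by re-using the FVA-filtered differential
comparison between the amended and unamended producer models.

## FSEOF

Flux scanning based on enforced objective flux: the maximal product
flux $v^*$ under the medium constraints is computed, then for $k =
1\ldots100$ the product flux is forced to at least
$(k/100)\,0.9\,v^*$ while biomass is re-maximised. Reactions whose
flux magnitude rises from first to last step, never falls between
consecutive steps beyond tolerance ($10^{-6}$), and never changes
sign are overexpression candidates, ranked by the least-squares slope
of $|v|$ against the enforced flux (final-step flux is the obvious
alternative ranking; the slope uses the whole profile and is the one
implemented). Enforcement is a lower bound, the recorded fluxes are
the FBA optima at each step, and exchange plus non-gene-encoded
reactions are dropped from the reported list, since only
enzyme-catalysed steps can be overexpressed.

## The synthetic study network

`make_toy_gem()` builds miniature hosts — substrate exchanges,
transporters, conversions to a common precursor, a biomass drain and a
competing product — whose FBA optimum, FVA ranges, envelope and FSEOF
answer are closed-form. `make_study_toy()` extends this into an
emulation of the full study: the real generated pB40 and hCDKL5
reactions are wired to the precursor pool through supply reactions (1
precursor per amino acid, 0.05 per NTP/dNTP — values chosen so that
monomer cost, not energy, dominates, as in real biosynthesis), biomass
drains amino acids in host-proteome proportion (share 0.5 of its
precursor demand), and translation by-products drain freely. Defaults
are the study conditions: glutamate/gluconate uptakes 0.35/0.66,
yields 0.12 gCDW per mmol (a typical bacterial biomass yield on amino
acids/sugar acids, giving a wild-type growth near the measured range),
and two closed amendable sugars (yields 0.2 and 0.15, higher than the
medium substrates, as sugars yield more precursor per mmol).

On this network every pipeline quantity has a closed form — e.g.
product at growth $g$ is $(\sum u_i y_i - g\,c_X)/c_P$ with $c_X$,
$c_P$ the precursor costs of biomass and product — and the end-to-end
tests compare the computed tables against these forms exactly. The
emulation reproduces the study's qualitative structure: a linear
growth/product trade-off, supply fluxes of product-enriched residues
(histidine, serine — roughly two-fold enriched in hCDKL5 over the host
proteome) rising upon production, amino-acid biosynthesis dominating
the FSEOF pathway grouping, and sugar amendments boosting the product
optimum.

What the toy does **not** emulate: the published reconstruction's
topology (alternative pathways, cofactor coupling, maintenance ATP),
so core-set sizes, exact target counts (84 shared core, 70 FSEOF
targets, 12 increased reactions) and compound identities
(amylotriose, maltose, mannitol) are not reproduced here — those
quantities also depend on solver vertex selection and are soft
targets even on the published model. Passing tests show the methods
are implemented correctly, not that the toy predicts PhTAC125
physiology.

The consumption-series generator grows biomass exponentially from
OD600 0.1 (0.074 gCDW/L) for 30 h at $\mu = 0.17$/h with initial
substrate concentrations matching the 5 g/L GG-medium recipe (26.7 mM
glutamate, 22.9 mM gluconate), consumes substrate by the true rates
times integrated biomass with a floor at zero, and applies
multiplicative Gaussian noise to concentrations. Sixteen samples over
30 h emulate a realistically sampled batch. All generators are
deterministic under a seed and restore the global RNG state.

## Host proteome reference

The amino-acid frequencies of the PhTAC125 proteome are not available
as a published table; the package ships a synthetic stand-in
(`inst/extdata/proteome_aa_freq_synthetic.tsv`, canonical bacterial
averages) used for the composition-delta analysis and the study-toy
biomass. Sign-level conclusions (histidine and serine enriched in
hCDKL5) are robust to this substitution; exact delta magnitudes are
not.

## Known limitations

* The dense simplex limits routine use to networks of a few hundred
  reactions.
* SBML support covers Level 3 + FBC v2 with the fields this pipeline
  reads (species, bounds, objective, gene associations, subsystem
  notes); groups, annotations and units round-trip is out of scope.
* Degeneracy-sensitive counts from the published study are not
  acceptance-gated anywhere, for the reasons above.
* Amendment screening is single-compound; combinatorial media and
  uptake-rate sweeps are out of scope, as are knockout-design
  algorithms and dynamic (time-course) FBA.
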