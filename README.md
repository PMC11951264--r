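# hfadecomp

Home-field advantage (HFA) analysis for reciprocal litter-transplant
microcosm experiments, with a full synthetic-data generator so the pipeline
can be exercised and validated end to end.

## The scientific problem

Leaf litter often decomposes faster in the soil beneath the plant it came
from ("home") than in foreign soil ("away") — the home-field advantage,
attributed to decomposer communities specialised on their local litter. In a
reciprocal transplant design, each of two litter species (here labelled `P`
and `C`, two conifers) is decomposed in the soil of both species across a
series of destructive harvests, with a labile-carbon (glucose) amendment in
the late decomposition stage to probe whether root-exudate-like carbon
inputs strengthen the HFA (a rhizosphere-priming analogue).

`hfadecomp` implements the quantitative core of this analysis:

- **Mass loss** per microcosm: `ML = (M_t0 − M_ti)/M_t0 × 100`.
- **Relative mass loss** of litter A at site a: `A_RMLa = A_a/(A_a + B_a) × 100`.
- **Net HFA index** for the species pair:
  `HFA = [(A_RMLa + B_RMLb)/2] / [(A_RMLb + B_RMLa)/2] × 100 − 100`,
  positive when litter decays faster at its native site.
- **Mean HFA** per species: `(ML_home − ML_away)/ML_away × 100`.
- **Community dissimilarity** between paired home and away samples:
  OTU-level Bray–Curtis, and the per-taxon *dissimilarity abundance*
  `|log2(X_home / X_away)|` on class-rank relative abundances (with a
  half-minimum pseudocount for zeros).
- **Inference layer**: principal coordinate analysis, a hand-implemented
  sequential-SS PERMANOVA with free label permutation, one-way ANOVA with
  Bonferroni post-hoc compact letters, Welch/Student t-tests,
  Shapiro–Wilk/Levene assumption gating, and single + multiple OLS
  regressions of mean HFA on dissimilarity predictors.
- **Community preparation**: sliding-window read quality filtering,
  rarefaction (default 57,742 reads/sample), taxonomic aggregation,
  FUNGuild-style trophic-guild assignment with saprotroph precedence, and
  dominant-class selection (>95% cumulative share).

The synthetic generator reproduces the reference design — 2 litter species
× 2 soil sources × 5 harvest events × 4 replicates = 80 microcosms, with
the 6-month harvest split into control (CK) and glucose batches — using
single-pool exponential decay with a multiplicative home-affinity term and
a calibrated late-stage glucose boost, plus Dirichlet-multinomial fungal
communities with soil-source separation, Ascomycota-to-Basidiomycota
succession, and a glucose-driven composition shift.

## Worked example

```r
library(hfadecomp)

sim  <- simulate_experiment(seed = 11)          # mass records + OTU table
plan <- phase_plan(n_perm = 199, seed = 5)

p1 <- run_phase1(sim$mass, sim$units, sim$otu, plan)
p1$community$permanova
#> PERMANOVA (sequential SS, 199 permutations)
#>            term df  sum_sq r_squared pseudo_f p_value
#>     soil_source  1 2.57345  0.502973  67.0845   0.005
#>  litter_species  1 0.03296  0.006442   0.8592   0.435
#>           month  3 0.28511  0.055724   2.4774   0.005
#>        Residual 58 2.22496  0.434861       NA      NA
#>           Total 63 5.11648  1.000000       NA      NA

p2 <- run_phase2(sim$mass, sim$units, sim$otu, plan)
p2$hfa_difference        # glucose minus CK net HFA, percentage points
#> [1] 16.69763
p2$hfa_t_test$p_value
#> [1] 3.093468e-05
```

Soil source dominates fungal composition (R² ≈ 0.50 here), harvest time is
significant, and the glucose amendment raises the month-6 net HFA by ~16.7
points in this run (the generator's noise-free calibration is a
15.19-point contrast), with a strongly significant t-test — the structure
the generator builds in, recovered by the analysis layer.

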