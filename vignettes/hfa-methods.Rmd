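---
title: "Quantifying home-field advantage in reciprocal litter transplants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying home-field advantage in reciprocal litter transplants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfadecomp)
```

## The experiment and its statistics

`hfadecomp` analyses reciprocal litter-transplant microcosms: two litter
species decomposed in both species' soils across destructive harvests, with
a glucose amendment added late in decomposition to one batch of the final
harvest. The design type keys harvests jointly by `(month, treatment)`, so
a final month split into control and glucose batches counts as two harvest
events; the reference layout (2 species × 2 soils × 5 events × 4
replicates) expands to 80 microcosms.

Four statistics carry the mass-loss side of the analysis. Mass loss is
`(M_t0 − M_ti)/M_t0 × 100` (percent, grams in and out). Relative mass loss
apportions a site's total decomposition between the two litters,
`A_RMLa = A_a/(A_a + B_a) × 100`. The net HFA index for the pair is the
percent excess of the mean home-side relative mass loss over the mean
away-side one; it is scale-invariant in the four mass losses, zero when
home and away RML sums balance, and obeys the role-swap identity
`(H + 100)(H' + 100) = 100²` — all of which the test suite checks over
random quartets. The per-species mean HFA, `(ML_home − ML_away)/ML_away ×
100`, is the response variable of the linkage regressions. Percentages are
on the 0–100 scale end to end; the indices consume percent mass losses,
not fractions.

**Replicate pairing.** Per-harvest HFA error bars require replicate-level
index values, but nothing in the quartet structure dictates how replicates
of the four (litter × soil) cells combine. The default pairs replicate *k*
of all four cells into quartet *k* (n = 4 per harvest, matching mean ± SE
reporting); an `all_pairs` option enumerates every 4-way combination as a
sensitivity check. Mean HFA likewise pairs each home replicate with the
same-index away replicate, which also defines the home/away sample pairs
used for community dissimilarity — one pair per (species, harvest,
replicate), litter fixed and soil varying. A `site_fixed` alternative
(soil fixed, litter varying) is provided because the subscript convention
of the dissimilarity statistic admits both readings.

## Community dissimilarity

Whole-community dissimilarity between paired home and away samples is
Bray–Curtis on rarefied OTU counts; per-taxon dissimilarity is the
*dissimilarity abundance* `|log2(X_home/X_away)|` on class-rank relative
abundances. Zeros are handled with a table-wide pseudocount, by default
half the smallest non-zero class relative abundance — standard log-ratio
practice; the statistic stays finite, symmetric, and non-negative. The
saprotroph version applies the same log-ratio to the summed relative
abundance of OTUs assigned a saprotrophic guild.

Guild assignment accepts lookup entries at "highly probable" or "probable"
confidence only, and any taxon whose trophic mode contains a saprotrophic
component counts as a saprotroph (precedence switchable). Dominant classes
are the smallest prefix of classes, sorted by mean relative abundance with
alphabetical tie-breaks, whose cumulative share exceeds 0.95.

## Inference layer

PCoA is classical scaling: double-centre the squared distance matrix,
eigendecompose, scale eigenvectors by the square root of positive
eigenvalues. Negative eigenvalues (expected under Bray–Curtis) are
reported unmodified; on Euclidean inputs the embedding reproduces the
input distances to 1e-8, which is the correctness test.

PERMANOVA is implemented directly (not delegated): sequential (Type I)
sums of squares on the Gower-centred inner-product matrix, pseudo-F per
term, and p-values from free permutation of sample labels,
`p = (1 + #[F* ≥ F]) / (1 + n_perm)` with 999 permutations by default and a
mandatory seed. An `exact = TRUE` mode enumerates all `n!` permutations
(n ≤ 8) for oracle comparisons. The main-effects model (soil source +
litter species + time or treatment) is the default because per-factor R²
is the quantity of interest; `vegan::adonis2` serves as an independent
cross-check in the tests, never as the implementation.

The ANOVA path gates on Shapiro–Wilk (residuals) and Levene tests at 0.05;
on failure it applies `log(x + 1)` — appropriate for positive-skew
abundance and diversity data — and re-tests. HFA values can drop below −1,
so the pipeline gates HFA with a min-shifted log instead; if a transform
produces non-finite values the raw data are retained with a warning.
Post-hoc structure is all-pairwise pooled-SD t-tests with Bonferroni
adjustment, summarised as compact letters (insert-and-absorb). The
phase-2 treatment contrast uses Welch's t-test by default, with the
Student variant available; at n = 4 replicates Welch's Satterthwaite
approximation is slightly conservative (true size ≈ 0.042 in our
simulations), which is why the suite's exactness calibration uses the
Student variant while the pipeline keeps the robust Welch default.

Linkage regressions are ordinary least squares: mean HFA on community
Bray–Curtis, on each dominant class's dissimilarity abundance, and on the
saprotroph dissimilarity; plus the two-step multiple regression on all
eight dominant-class predictors in which taxa significant at 0.05 are
flagged and refit singly. No correction is applied across the eight refits
by default (a Holm flag exists); collinear predictor sets warn on
condition numbers above 1e8.

## What the synthetic generator emulates

**Decay.** Single-pool exponential decay with a multiplicative
home-affinity gain: `k_eff = k_base(species) · (1 + δ_home·is_home)`, with
glucose multiplying the rate by `(1 + δ_gluc_home)` at home and
`(1 + δ_gluc_away)` away over the post-addition interval. The base rates
are solved from the observed 4-month away-soil mass losses of the two
species — 31.59% and 42.26%, giving `k_P = 0.0949` and `k_C = 0.1373`
month⁻¹. The default affinity `δ_home = 0.30` produces a positive net HFA
that declines over harvests (≈26.9% at month 1 to ≈18.5% at month 6)
without any time-varying schedule, because relative mass losses compress
as decomposition proceeds; a month-keyed `δ_home` schedule is available
for scenarios with explicitly fading affinity. The glucose boosts
(`δ_gluc_home = 0.936`, `δ_gluc_away = 0.15`) are calibrated so the
noise-free month-6 HFA contrast equals 15.19 percentage points — the
generator's headline study condition. Noise is mean-one lognormal on the
remaining-mass fraction (`sd = 0.03`, clamped to ≤ 1), which keeps mass
records physically valid by construction; no within-treatment variance was
reported for the reference system, so the noise level is a plausibility
choice, not a fit.

One subtlety worth recording: a glucose boost applied *equally* at home
and away is pure time dilation of the decay curves, so the glucose−CK HFA
contrast under an equal boost is not exactly zero — it is the small drift
of the HFA-vs-time curve over the dilated interval (≈ −1.1 points at the
defaults), an order of magnitude below the calibrated home-biased
contrast. The tests assert the simulated contrast centres on this exact
construction value.

**Communities.** Composition is modelled at class level: eight dominant
classes (Sordariomycetes, Eurotiomycetes, Tremellomycetes,
Mortierellomycotina, Agaricomycetes, Orbiliomycetes, Leotiomycetes, and a
pooled unclassified fraction) with baseline shares summing to 0.96, and
four real minor classes holding the remainder. Per sample, class
log-shares are shifted by a soil-source term (alternating sign pattern,
±`source_effect`/2), a succession trend (−slope·month for Ascomycota
classes, +slope·month for Basidiomycota — the r- to K-strategist shift),
and a glucose boost on Basidiomycota; shares are renormalised, spread over
within-class OTUs with fixed base proportions, Dirichlet-jittered
(concentration 300) and drawn multinomially at a library size uniform on
60,000–100,000 so rarefaction at 57,742 is always feasible. A synthetic
genus-level guild lookup assigns saprotrophy with class-dependent
probabilities and mixed confidence levels so the guild filter is
exercised.

What the generator does *not* emulate: OTU-level ecological structure
(effects are class-level with neutral within-class jitter), sequence-level
artefacts (chimeras, primers), spatial soil heterogeneity, litter
chemistry, or any coupling between the realised community and the decay
noise — mass loss and community composition are conditionally independent
given the design factors. Passing tests therefore demonstrate that the
statistics recover structure *of the kinds built in*, at the built-in
effect sizes; they cannot certify behaviour on real data with, e.g.,
OTU-level idiosyncrasy or community-driven decay feedbacks.

**Reads.** The read simulator emits fixed-length reads with Gaussian
per-base Phred jitter and an optional low-quality tail, for exercising the
quality filter: windows of 50 bp advancing 1 bp, truncation at the first
base of the first window whose mean quality is below 20, discard below
50 bp after truncation, and discard of ambiguous-base reads. Step size and
truncation anchor follow common trimmer conventions since only the window
length, threshold, and minimum length are fixed by the protocol; reads
shorter than one window are judged as a single whole-read window. The
minimum pair-overlap parameter is recorded but applies only to paired-end
merging, which is upstream of this package.

## Numerical and degenerate-input choices

Rarefaction is a multivariate hypergeometric draw (without replacement),
one draw per sample under a single run seed; samples below depth are
dropped with a warning. Undefined ratios raise typed conditions rather
than returning NaN: both-zero relative mass loss, zero away-side RML sum,
zero away mass loss, both-zero log-ratio with zero pseudocount, all-zero
Bray–Curtis vectors, and zero-total samples each have a named error class.
Two constant equal samples give t = 0, p = 1 by convention with a message.
All simulation functions take a `seed` argument and restore the session
RNG state on exit, so identical inputs give byte-identical outputs without
side effects.

## Problem sizes

The shipped tests and the acceptance script run the generator at the
reference design size (80 microcosms, ~136 OTUs): 100 community
simulations for the dominant-class share, 200 phase-2 simulations for the
glucose contrast, 1,000 replicate microcosms for the mass-loss noise
check, 500-simulation null calibrations for PERMANOVA, the regression
slope test and the t-test, 10,000 reads against the brute-force filter
oracle, and exact 720-permutation enumeration for the PERMANOVA oracle at
n = 6. The whole suite completes in about a minute on one core.

## Known limitations

The HFA index is a two-species net index; multi-species regression-based
HFA decompositions are out of scope. Distances are non-phylogenetic
(no UniFrac). PERMANOVA permutes labels freely — no restricted permutation
within blocks — and fits main effects by default. The regression layer
pools species and harvests into one sample by default (per-species
stratification is a matter of subsetting the pair table). OTU clustering,
chimera removal and taxonomy assignment are consumed as inputs, not
performed.
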