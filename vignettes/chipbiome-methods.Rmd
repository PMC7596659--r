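---
title: "chipbiome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipbiome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedures chipbiome implements,
the assumptions behind them, and the design decisions taken where the
methodology left genuine choices open. It is the package's reference for
*why* things are computed the way they are; the README shows *how* to run
them.

## The measurement model

A two-channel 16S phylogenetic array hybridises a Cy5-labelled test sample
against a Cy3-labelled common reference pool. The reference pool lights up
every spot, so the Cy3 channel acts as a per-spot loading control; the Cy5
channel carries the sample signal. Each species is represented by an oligo
probe printed in triplicate. Quantification is entirely within-array: every
hybridisation carries its own reference mix, so background and baseline are
estimated per array, never pooled across a cohort.

The per-array chain in `quantifyCohort()` is:

1. *Aggregation* (`aggregateSpots`): arithmetic triplicate means per channel,
   then the species ratio `R = mean(Cy5) / mean(Cy3)`. A species whose mean
   Cy3 is zero has an undefined ratio; it is excluded from ratio rankings
   and can never be called positive, but still participates in the
   intensity ranking.
2. *Background* (`estimateBackground`): species are ranked ascending by
   mean Cy5 and the background is the mean over the lowest
   `floor(0.30 * S)` species (minimum 1). On a catalogue array most panel
   species are absent from any one gut community, so the dim tail measures
   non-specific hybridisation plus scanner floor.
3. *First pass*: `mean(Cy5) > fold * background`, strict, `fold = 5` by
   default.
4. *Baseline ratio* (`estimateBaselineRatio`): mean of the lowest
   `floor(S / 2)` defined ratios. This second filter removes species that
   are bright in absolute terms (e.g. large or sticky spots) but no brighter
   than the reference pool predicts.
5. *Second pass*: `R > fold * baseline`, strict. A species is *positive*
   iff it passes both.
6. *Normalisation* (`normalizeAbundance`): positive species' ratios are
   normalised to sum 1; non-positive species are exactly 0.

Decisions this leaves open, and what the package does:

- **"Mean signal intensity" channel.** The intensity ranking and background
  use the Cy5 (test) channel: background is a property of the sample
  signal, while Cy3 is a constant-design reference. A median-based spot
  summary is available (`aggregate = "median"`) but off by default — no
  outlier rejection is applied unless asked for.
- **Rounding of the 30% / 50% set sizes.** `floor`, with a minimum of one
  species, deterministically; ties in either ranking are broken by species
  label so results are reproducible on permuted input.
- **Number of passes.** The calling rule has exactly two filters; the
  positive set is the intersection of both. Abundance normalisation runs
  over that set.
- **Strictness.** Both thresholds are strict inequalities: a species at
  exactly `fold *` background or baseline is negative.

Scale invariance holds by construction: multiplying both channels of every
spot by a constant changes neither calls nor abundances.

## Downstream analyses

**Alpha diversity** (`alphaDiversity`): Shannon (natural log; `log2`
optional) and Simpson (`1 - sum p^2`) are computed on relative abundances.
Chao1 and ACE need integer singleton/doubleton counts, which a
ratio-normalised profile does not have, so abundances are rescaled to
pseudo-counts totalling 10,000 (configurable) and rounded. Chao1 uses the
classic estimator `S_obs + F1^2 / (2 F2)`, falling back to
`S_obs + F1 (F1 - 1) / 2` when there are no doubletons; ACE is the standard
abundance-based coverage estimator with rare cutoff 10 (via vegan). Group
comparisons are two-sided Wilcoxon rank-sum tests, exact where sample sizes
and ties allow, otherwise the tie-corrected normal approximation.

**Beta diversity**: Bray-Curtis dissimilarity; a pair of all-zero samples
(possible when no species is called on either array) is defined as distance
0 and flagged. PCoA is classical metric scaling; negative eigenvalues are
reported as-is (no Cailliez/Lingoes correction) and excluded from the
explained-variance denominator. NMDS minimises Kruskal stress-1 from up to
20 random starts under a fixed seed; the best solution is returned. PERMANOVA
partitions the distance matrix by group with freely permuted labels (999 by
default); it is run once, on the distance matrix — an ordination-specific
test would be testing the same quantity twice.

**Differential abundance** (`lefse`): a Kruskal-Wallis screen at
`alpha = 0.05` (for two groups this is the rank-sum test), then bootstrapped
two-class LDA on the survivors: profiles rescaled to a per-sample total of
1e6, 30 rounds of 2/3-per-class subsampling, per-taxon effect = mean over
rounds of (|raw class-mean difference| + |unit-norm LD coefficient times LD
class separation|)/2, reported as `sign * log10(1 + effect)` with a 2.0
cutoff. These are the conventional defaults of the cascade; the study design
is two-group, so the subclass Wilcoxon step degenerates to the screen and is
implemented as a pass-through. No multiple-testing correction is applied by
default (the cascade's convention); a Benjamini-Hochberg column is always
computable (`adjust = TRUE`). Within-class zero variance is handled by a
tiny flagged jitter before the LDA; compositional collinearity is tolerated.
`buildCladogramTable()` re-tests abundances aggregated to genus, family and
order rather than propagating species results, so each rank's report is a
genuine test at that rank.

**Classification** (`loocvScores`, `rocAuc`, `compareRanks`): random
forests, 500 trees, `sqrt(p)` feature subsampling, leave-one-out
cross-validation; the out-of-fold score is the fraction of trees voting for
the case class. Each tree draws a *class-balanced stratified bootstrap*
(both classes at the minority-class size): with a 58:23 imbalance the
vanilla bootstrap lets the training prior shift depending on which class
the held-out sample came from, which systematically depresses null AUC
below 0.5; balanced sampling removes that artefact and is common practice
for imbalanced microbiome classifiers. AUC uses the rank (Mann-Whitney)
formulation with ties counted 1/2 — it equals the all-pairs concordance
probability exactly — and the 95% CI is DeLong's. Feature importance is
mean decrease in Gini impurity from a single balanced forest on all
samples.

**Validation** (`qpcrRelativeAbundance`, `comparePlatforms`,
`spearmanMatrix`): the delta-Ct quantity `2^(Ct_universal - Ct_specific) *
10^4` references each species-specific reaction to a universal 16S
amplification of the same sample; it reads 10,000 at equal threshold
cycles, halves per extra specific cycle, and censored (no-amplification)
reactions report 0 and are excluded from platform correlations rather than
imputed. Species-cytokine association is Spearman rank correlation with
average-rank ties and a two-sided t-approximation p, computed within the
case group by default (`group = "all"` widens it); raw p-values carry
star tiers and a BH-adjusted column is emitted for transparency without
being used as the filter.

## The synthetic-data generator

`simulateCohort()` renders a complete study from one seed: a latent
community, spot-level arrays, metadata with a coupled cytokine panel, and a
qPCR plate. What it emulates, and the defaults (all surfaced in
`simulationConfig()`, none hard-coded):

- **Cohort shape**: 58 cases (ALL) vs 23 controls (NC) — the two-group
  imbalanced design the downstream stages must cope with.
- **Community**: a 150-species panel of which 60% are present
  (`prop_present`), with log-normal base abundances (`sigma_log = 1`);
  absent panel species hybridise at background. Between-subject variation
  is multiplicative log-normal (`sample_sigma = 0.5`), and compositions are
  re-normalised per sample.
- **Group effect**: 15 differential species with fold-changes drawn from
  [2, 8] (fixable, e.g. `c(4, 4)`), applied before re-normalisation so the
  compositional echo — unaffected species shrinking in relative terms — is
  preserved. Differential species are drawn from above the lower quartile
  of the present community so a planted effect is in principle detectable
  rather than buried below the calling floor.
- **Signal model**: per spot,
  `Cy5 = background_mean * e1 + signal_scale * abundance * e2` and
  `Cy3 = reference_channel_mean * e3`, with independent unit-mean
  log-normal noises of CV `triplicate_cv` (0.15 default — a typical
  fluorescence-scanner replicate CV). Defaults `background_mean = 500`,
  `signal_scale = 2e6`, `reference_channel_mean = 1000` put a
  median-abundance present species comfortably above the 5x floor while
  the dim tail stays at background, mirroring how catalogue arrays behave.
- **Cytokines**: the six-analyte serum panel (IL-1B, IL-2R, IL-6, IL-8,
  IL-10, TNF-a); IL-10 is linearly coupled to the first differential
  species (`value = 5 + 1000 * abundance + N(0, 2)`), the rest are
  intercept plus noise.
- **qPCR**: for each target, `Ct_specific = Ct_universal - log2(abundance)`
  plus per-well noise (0.15 cycles), duplicate wells averaged — constructed
  so the delta-Ct formula recovers `10^4 *` the planted abundance exactly at
  zero noise. Absent targets are censored at the 45-cycle ceiling.

One integer seed is threaded to every sub-generator through fixed offsets,
so a cohort is byte-reproducible. What the generator does **not** emulate:
cross-hybridisation between probes, scanner saturation, spatial artefacts,
batch effects between arrays, and any taxonomic correlation structure
beyond the nested synthetic lineage. Passing recovery tests on this
generator therefore demonstrates that the pipeline's inference machinery is
correct and calibrated — not that a real cohort of this size would yield
the same power.

## Numerical choices and degenerate inputs

- Ratio undefined (zero mean Cy3): excluded from ratio ranking, never
  positive, flagged.
- No positive species on an array: all-zero abundance row plus a warning;
  Bray-Curtis between two such rows is 0, flagged.
- Constant taxa: Kruskal-Wallis p fixed at 1 and flagged rather than NaN.
- Degenerate within-class variance in the LDA: flagged jitter of relative
  size 1e-5.
- PERMANOVA on constant distances: an error, not a silent NaN.
- Censored Ct: recorded at the 45-cycle ceiling, excluded from platform
  correlation.
- File round-trips write doubles at 17 significant digits.

## Calibration and recovery checks

The acceptance-style tests exercise the package at these problem sizes,
chosen to make Monte-Carlo error small while keeping a full run of the
suite in minutes on one core: oracle equivalence of the calling chain on
200 random 4-12-species arrays against an independently coded brute-force
transcription (exact to 1e-12); null calibration from 200 simulated
30-species cohorts (Kruskal-Wallis), 1,000 label redraws on an 81-sample
cohort (PERMANOVA at 199 permutations), and 50 label-shuffle seeds (LOOCV
AUC at 100 trees); and signal recovery over 50 seeds of the planted design
(150 species, 15 differential at fold-change 4, triplicate CV 0.15,
58 vs 23), requiring PERMANOVA detection in >= 95% of seeds, >= 80% of
planted species reported with the correct direction, and species-level
AUC >= 0.8 in >= 90% of seeds, plus the genus-cancellation construction in
which species-level classification must not lose to genus-level.

## Known limitations

- The detection threshold interacts with the abundance distribution: on
  communities with little dynamic range the lower-half baseline rises
  toward the bulk and sensitivity drops. The `fold` parameter is exposed
  precisely because 5x is a convention, not an optimum.
- Chao1/ACE on pseudo-counts inherit the arbitrariness of the rescaling
  total; they are comparable within a study, not across platforms.
- LEfSe effect sizes depend on the 1e6 rescaling convention; scores are
  comparable to published LDA-score thresholds but are not effect sizes in
  natural units.
- Relative abundances are compositional; differential results include the
  re-normalisation echo of true changes, and no compositional correction
  (e.g. log-ratio transforms) is applied because the quantification chain
  is defined on relative values.
- qPCR concordance assumes perfect primer efficiency (a cycle = a doubling);
  no standard-curve calibration is modelled.
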