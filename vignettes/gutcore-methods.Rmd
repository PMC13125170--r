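---
title: "Methods: core microbiota and functional stability screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core microbiota and functional stability screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcore)
```

`gutcore` re-implements, as a tested and reusable pipeline, the secondary-analysis
computations used to characterize a baseline intestinal microbiota across many
independent 16S rRNA gene sequencing studies of healthy chickens. The unit of
aggregation throughout is the *dataset* — the combination of one BioProject and
one intestinal segment (duodenum, jejunum, ileum, ceca, feces) — because a study
that sampled several segments contributes systematically different communities
for each. This vignette documents the statistical procedures, the defaults and
why they were chosen, the synthetic corpus the tests run on, and the known
limitations.

## Preprocessing rules

Three filters are applied before any analysis, in this order:

1. **Taxonomic retention.** Only features whose domain is `Bacteria` are kept,
   and any feature whose lineage contains `Mitochondria` or `Chloroplast` at any
   rank (case-insensitive substring) is removed. Silva-style taxonomies place
   mitochondria at family rank and chloroplasts at order rank, so the match is
   deliberately rank-agnostic. Features without a taxonomy record are dropped
   with a warning.
2. **Depth pruning.** Samples with fewer than 10,000 reads are removed; the
   inequality is strict, so a sample with exactly 10,000 reads is retained.
   Because the taxonomic filter runs first, depth is measured on bacterial
   reads only — the read count that actually informs the community estimates.
3. **Zero pruning.** Features with zero total count across retained samples are
   removed. All three filters are idempotent.

For beta diversity and the core screen, ASV-level tables are collapsed to genus
by summing counts over identical genus labels. Features lacking a genus label
are pooled into a synthetic `unclassified:<lowest non-empty parent label>`
feature rather than discarded, so collapsing conserves per-sample read totals
exactly — a requirement for Bray-Curtis values to be unaffected by the
collapse bookkeeping. Corpus-level taxon counts exclude these placeholders by
default, since summaries conventionally count named taxa.

## Dataset-averaged relative abundance

Counts are first normalized to proportions within each sample; proportions are
then averaged with equal weight per sample within each dataset, and finally with
equal weight per dataset across the corpus. The two-stage average means a
100-sample dataset counts no more than a 10-sample one: corpus summaries target
the population of *studies*, not the population of samples, and the grand mean
is provably invariant to duplicating every sample within a dataset (this is a
property test in the suite). Taxa absent from a dataset enter that dataset's
profile as 0, which keeps the unweighted mean well defined and makes grand
means sum to one.

## The dual-threshold core screen

A genus is *core* for a scope (usually one segment) when its prevalence —
the fraction of a dataset's samples where the genus is detected with count
> 0 — exceeds threshold 1 in more than threshold 2 percent of the scope's
datasets. Both inequalities are strict, following the "more than" definition.
Presence means detection, not a relative-abundance floor: prevalence-based core
definitions conventionally use detection, and the count tables have already
passed depth filtering. The screen is evaluated on a 5×5 grid (50, 60, 70, 80,
90 percent on both axes; 25 cells), with (80, 50) the presentation pair.
For each cell the screen reports the core set size, the cumulative percentage
of all detected genera, and the summed grand-mean relative abundance of the
core set. Core sets are nested along both grid axes (monotonicity is tested
exhaustively), and the whole screen is invariant to genus and dataset order.

## Alpha diversity and the mixed model

Shannon diversity is computed in natural log, $H = -\sum_i p_i \ln p_i$, and
Simpson diversity in the Gini–Simpson form $D = 1 - \sum_i p_i^2$ — the
conventions of the phyloseq ecosystem, since the indices are conventionally
named without formulas. Both are permutation- and scale-invariant.

Simpson values are heavily left-skewed in practice, so they are rank
normalized before modelling: average ranks are mapped through
$\Phi^{-1}\!\big((r - 0.5)/n\big)$, ties sharing one output value. The analysis
of the transformed variable reflects relative ordering rather than absolute
differences.

Each diversity response is modelled with a random-intercept linear mixed model
(REML, via `lme4`): intestinal segment, continent, days of age (`doa`,
continuous), bird type, housing and hypervariable region as fixed effects and
BioProject as the random intercept, since samples within a study share
technical and husbandry context. Factor baselines follow a canonical order
(segments anatomically, duodenum first) so coefficients are reproducible.
Model reduction drops every fixed term whose coefficients all have
$|t| < 2$ — a factor survives if any level reaches the threshold — and refits.
AIC comparisons between fixed-effect structures use maximum-likelihood refits,
because REML criteria are not comparable across different fixed effects.
Collinearity is screened with adjusted generalized variance inflation factors,
$\mathrm{GVIF}^{1/(2\,\mathrm{df})}$, with a warning threshold of 1.2. With few
datasets the design factors can be mutually confounded;
`select_estimable_predictors()` greedily removes aliased terms until the fixed
design is full rank rather than failing.

## Beta diversity

Bray-Curtis dissimilarity,
$BC_{jk} = \sum_i |x_{ij} - x_{ik}| \big/ \sum_i (x_{ij} + x_{ik})$, is
computed on raw genus counts by default — no rarefaction or proportion
transform is applied, matching the upstream convention — with a
`proportions = TRUE` option for the compositional variant. Principal
coordinates use Gower double-centering of $-d^2/2$ and an eigendecomposition;
axes are returned for positive eigenvalues and negative eigenvalues are
reported but contribute no axis.

The dispersion-homogeneity test embeds the samples by PCoA (axes of negative
eigenvalues retained with their sign, so semi-metric dissimilarities are
handled the standard way), measures each sample's distance to its group
center, and tests equality of mean distances by one-way ANOVA plus a
permutation test of the same F. The group center defaults to the centroid,
which has a closed form and is exactly testable against hand-computed
configurations; the coordinate-wise median is available as an option.

PERMANOVA partitions squared dissimilarities among groups:
$F = \frac{SS_B/(a-1)}{SS_W/(N-a)}$ with
$SS_W = \sum_g \sum_{j<k \in g} d^2_{jk}/n_g$, tested by unrestricted random
relabeling with 999 permutations. The p-value convention includes the observed
statistic, $p = (1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$, so $p \ge 1/(n_{perm}+1)$
always. Degenerate input (all samples identical) is defined to give $F = 0$,
$p = 1$. Because the permutations ignore the BioProject nesting — as the
upstream convention does — the pipeline annotates each factor's PERMANOVA as
*descriptive* whenever the dispersion test rejects homogeneity, and
*inferential* otherwise.

Days of age are categorized for PERMANOVA as <5, 5–9, 10–19, 20–49, and ≥50
days; age exactly 50 belongs to the oldest bin, following the published table
header ("50 or older") where the prose leaves 50 unassigned.

## Functional stability (nDFO screening)

Predicted functional ortholog (FO) counts are tested for differential
abundance between two groups with a negative-binomial Wald test built from
three transparent stages:

1. **Size factors** by median-of-ratios: per-feature geometric means over
   samples (features containing any zero are excluded from the reference), and
   each sample's factor is the median ratio of its counts to those means. When
   no feature is positive everywhere, ratios fall back to each sample's
   positive entries with a warning.
2. **Dispersion** by method of moments on normalized counts, pooled within the
   two condition levels, $\hat\alpha = \max\!\big(0, (s^2-\mu)/\mu^2\big)$,
   then shrunk on the log scale toward a fitted mean-dispersion trend
   $\alpha_{tr}(\mu) = a_0 + a_1/\mu$ with weight $n/(n+20)$. Moment estimates
   at zero (at- or under-dispersed features) are floored at $10^{-8}$ rather
   than shrunk. This deliberately replaces empirical-Bayes shrinkage,
   independent filtering and outlier refitting with a simpler estimator whose
   behaviour is fully testable; marginal disagreement with heavier machinery
   is expected and accepted.
3. **Wald test** per FO: a negative-binomial GLM with log link, log-size-factor
   offset, the two-level condition as single covariate and the dispersion held
   fixed; the Wald statistic is the condition coefficient over its standard
   error with a two-sided normal p-value, adjusted across tested FOs by
   Benjamini–Hochberg. Non-convergent fits yield missing p-values and leave
   the testing universe entirely — "not testable" is never conflated with
   "not significant".

An FO is a *non-differential FO* (nDFO) when its adjusted p-value is present
and at least 0.05 (configurable). For each unordered pair of groups the tested
universe is the set of FOs detected (nonzero total) in both groups — this
reconciles pairwise percentages with differing per-group FO totals; a union
universe is available as an option. Pairs where a group has fewer than two
samples are reported as not available. The pairwise matrix is presented with
percentages above and absolute counts below the diagonal. Intersections across
comparisons use upset semantics (exclusive membership combinations), and the
*conserved* set is the intersection of all nDFO sets, which provably shrinks
as comparisons are added.

Pathway enrichment of a query set (typically the conserved nDFOs) uses the
upper-tail hypergeometric probability $P(X \ge k)$ with universe size $N$,
pathway membership $K$ (intersected with the universe), query size $n$ and
overlap $k$; gene ratio is $k/n$; BH adjustment across pathways. Membership is
always supplied as a file — nothing is fetched from a live service — for
reproducibility.

## The synthetic corpus

Every stage is tested against `generate_corpus()`, which emulates the
post-denoising state of a multi-study corpus with known planted structure:

- **Taxon counts**: a global log-normal genus composition, perturbed per
  dataset by a log-normal effect (`dataset_effect_sd`, default 1.0 on the log
  scale) — a Dirichlet-multinomial-like hierarchy that reproduces the
  dataset-level clustering real PCoA plots show — then multinomial sampling at
  a depth drawn uniformly from `depth_range` (default 5,000–60,000, spanning
  the 10,000-read filter).
- **Planted core genera** (default 10 of 300) are detected per sample with
  probability 0.95 inside every dataset and forced present (count ≥ 1) where
  detected; background genera use detection 0.2. The detection probabilities
  are deliberately well separated so the 80/50 screen should recover the
  planted set exactly.
- **Contaminants**: a configurable fraction of extra features carrying
  mitochondrial or chloroplast lineages, with small Poisson counts.
- **FO counts**: independent negative binomials per FO (default dispersion
  0.2). Planted differential FOs (default half the universe, mirroring the
  observed ~40–60% stability) carry a log2 fold change (default 2) across the
  levels of a design factor, graded linearly between the extreme levels and
  centred on the FO's base mean, with signs alternating between FOs. The
  centring and sign balance keep the corpus free of a net compositional shift:
  median-of-ratios normalization assumes most features do not change, and an
  all-one-direction corpus would violate that assumption by construction (it
  also would in real data).
- **Pathway map**: random memberships, except one planted pathway composed
  predominantly (default 90%) of stable FOs — the enrichment stage's known
  answer.

A single master seed drives everything; sub-generators (the pathway map, the
acceptance script's replicates) derive child seeds deterministically, so
corpora are byte-reproducible.

What the generator does *not* emulate: phylogenetic signal, chimeras and
primer artifacts (out of scope upstream of the count tables), correlated FO
blocks, zero-inflation beyond what the multinomial/NB hierarchy produces, and
planted effects on alpha diversity — the mixed-model recovery studies
simulate from the model directly instead. Passing tests therefore demonstrate
correctness of the computations and calibration under this generating model,
not robustness to every pathology of real amplicon data.

## Numerical choices and problem sizes

- Strict inequalities wherever the definitions say "more than" or "less
  than" (depth filter, both core thresholds, the nDFO cut at `padj < 0.05`
  for differential calls).
- F statistics define 0/0 as 0 with a relative tolerance of $10^{-12}$ on the
  sums of squares, so exactly degenerate configurations are reported as null
  rather than numerically unstable.
- PCoA treats eigenvalues within $10^{-9}$ (relative) of zero as zero.
- Permutation p-values always include the observed statistic.
- Dispersion floor $10^{-8}$; a floored dispersion corresponds to an
  effectively Poisson GLM.
- The test suite and the acceptance script use desk-scale problem sizes
  chosen to keep the full run in minutes while leaving comfortable
  statistical margins: corpora of 12–15 datasets × 20 samples, FO universes
  of 300–2,000, 199–999 permutations, and 60–500 replicate simulations per
  calibration claim.

## Limitations

- The NB Wald stage is a transparent simplification; studies needing
  empirical-Bayes moderation should treat its calls as conservative
  approximations at the margin.
- PERMANOVA permutations are unrestricted; with strong dataset-level
  structure the test is best read descriptively (the pipeline annotates
  this automatically), and a stratified option is the statistically
  defensible alternative.
- The corpus-level reference numbers printed by a full-scale study (thousands
  of samples, thousands of genera) are not reproducible at desk scale; the
  pipeline's claims are about the correctness and calibration of the
  computations, which is what the acceptance suite measures.
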