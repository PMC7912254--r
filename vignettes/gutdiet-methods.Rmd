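---
title: "Methods: diet-microbiome patterns, enterotypes, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-microbiome patterns, enterotypes, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gutdiet` implements a complete cross-sectional analysis linking habitual diet
to the gut microbiome: from an OTU count table, a rooted phylogeny and a
food-frequency intake table to (i) partial-correlation screens between diet
and clr-transformed taxon abundances, (ii) a reduced-rank-regression dietary
pattern that best explains within-sample (α-) diversity, and (iii) discrete
community types ("enterotypes") found in β-diversity space and contrasted
against diet. This vignette explains the models, the defaults and their
units, the numerical choices, and what the synthetic-data generator does and
does not emulate.

## The analysis graph

1. **Rarefaction.** Counts are subsampled without replacement to a common
   depth (one seeded draw, not an average over draws), the standard guard
   against sequencing-depth confounding of diversity comparisons. The default
   depth is the cohort minimum; a 222-subject 16S cohort of the design this
   package targets had a minimum of 5887 reads, which `pipeline_config()`
   accepts via `depth`. Samples below the depth are dropped and logged.
2. **Aggregation and compositional transforms.** Counts are summed to phylum
   and genus rank (taxa unassigned at a rank pool into `"unclassified"`),
   converted to proportions, zeros are imputed by geometric
   Bayesian-multiplicative replacement, and the result is centred log-ratio
   (clr) transformed. All correlation screens operate on clr values, because
   proportions live on a simplex where ordinary covariance is distorted.
3. **Diversity.** α-diversity per sample: Chao1 (bias-corrected), Shannon
   (natural log by default, `shannon_base` flag otherwise) and Faith
   phylogenetic diversity. β-diversity between samples: Bray-Curtis,
   unweighted UniFrac and weighted UniFrac (raw by default, `normalized`
   flag).
4. **Diet adjustment.** Each food group (g/day) is log-transformed and
   energy-adjusted by the residual method: residuals of log intake on log
   total energy, re-located at the sample-mean log energy. Adjusted columns
   are exactly orthogonal to log energy.
5. **Dietary pattern.** A single-response reduced rank regression of the
   log α-diversity index (Shannon by default) on the standardised food
   groups.
6. **Enterotypes.** Principal coordinates of a β-diversity matrix, k-means
   on the first two axes, k-selection diagnostics (elbow, silhouette, gap
   statistic), dominant-genus labelling, and covariate-adjusted diet
   contrasts across the clusters.

## Key formulas and conventions

**Bayesian-multiplicative zero replacement.** For sample $i$ with original
count total $N_i$ and per-part prior strengths $s_j$ (Jeffreys $s_j = 0.5$ by
default, `prior_strength`), each zero part receives
$\delta_{ij} = s_j / (N_i + \sum_j s_j)$ and the non-zero parts are rescaled
by $1 - \sum_{j \in \text{zeros}(i)} \delta_{ij}$, preserving all ratios
among observed parts exactly. This is the simplest closed-form member of the
Bayesian-multiplicative family; the prior is exposed rather than fixed
silently. Note the imputed value shrinks with sequencing depth — the
transform is deliberately *not* scale-invariant for samples containing zeros.

**clr.** $\mathrm{clr}(x)_{ij} = \ln x_{ij} - \tfrac1D \sum_j \ln x_{ij}$;
rows sum to zero. The difference of two clr coordinates equals the log ratio
of the parts, so the Firmicutes-to-Bacteroidetes balance is
`clr_log_ratio(cm, "Firmicutes", "Bacteroidetes")`.

**UniFrac.** Both variants are computed from a leaves-by-edges incidence
matrix built once per tree (`tree_branches()`), making each distance matrix a
couple of matrix products: unweighted UniFrac is (branch length unique to one
sample's observed leaf set) / (branch length in either); weighted UniFrac is
$\sum_b \ell_b |P_A(b) - P_B(b)|$ with $P_X(b)$ the fraction of sample $X$
descending through branch $b$ (divided by $\sum_b \ell_b (P_A + P_B)$ in the
normalised form). Faith PD uses the rooted convention: all branches on the
union of root-to-leaf paths of observed taxa count. Tests verify both
variants against an explicit per-branch enumeration oracle on all small
trees, and against `phyloseq::UniFrac`.

**Single-response RRR.** With one response the first RRR factor is exact and
equals the fitted direction of OLS on the column-standardised foods: weights
$\propto$ OLS coefficients, score $= $ standardised $X w$, loadings $=$
food-score Pearson correlations, `response_r2` $=$ squared score-response
correlation. The score is oriented so that it correlates non-negatively with
the response ("high diversity" points up). Loadings are reported as
correlations (the convention of the dietary-pattern literature) and the raw
weights are emitted alongside, so the choice is transparent. Main
contributors use the conventional $|$loading$| > 0.3$ cutoff.

**Partial Spearman.** Rank-transform everything (midranks on ties),
residualise the ranked variables on the ranked covariates by OLS, correlate
the residuals; $t$-test on $n - 2 - c$ degrees of freedom with $c$ the
indicator-expanded covariate count. With no covariates this is textbook
Spearman (verified to 1e-12 in tests).

**PERMANOVA.** Single-factor pseudo-F from the Gower-centred matrix
$G = -\tfrac12 J D^2 J$ and the factor's projection $H$:
$F = \mathrm{tr}(HGH)/\mathrm{df}_m \,/\, (\mathrm{tr}(G) - \mathrm{tr}(HGH))/\mathrm{df}_r$,
which covers categorical groupings and single numeric regressors through the
same code path (cross-checked against `vegan::adonis2`). The permutation p is
$(1 + \#\{F^* \ge F\})/(1 + n_\text{perm})$, never zero; samples are put in
canonical sorted-id order before permuting so the result cannot depend on
input row order.

**PCoA and k-means.** Classical scaling via `cmdscale`; negative eigenvalues
(expected for Bray-Curtis) are excluded and their absolute mass reported — no
Cailliez/Lingoes correction, keeping the decision auditable. Clustering uses
the first two principal coordinates (configurable), Lloyd iterations from 50
k-means++ seedings, keeping the lowest within-cluster sum of squares; an
empty cluster is re-seeded with the point farthest from its assigned centre.
The gap statistic draws its reference sets uniformly over the bounding box of
the two coordinates (the original simple reference), `B = 50` by default;
suggestions are elbow $=$ largest second difference of WSS, silhouette $=$
argmax, gap $=$ smallest $k$ with $\text{gap}(k) \ge \text{gap}(k+1) -
\text{se}(k+1)$. The final $k$ is deliberately a user decision (default 3,
the canonical enterotype count); the diagnostics inform but never override
it.

**Dominant-genus labels.** Each cluster is named by the genus maximising
(mean proportion within cluster − mean proportion elsewhere), with
within-mean and lexicographic tie-breaks and an injectivity rule (a genus can
name only one cluster; the lower-scoring cluster takes its next best). The
differential-mean rule is used rather than raw dominance because a uniformly
abundant genus would otherwise label every cluster. This rule is this
package's definition; other implementations may name clusters differently.

**FDR scope.** BH correction is applied within an explicit scope
(`fdr_scope`), defaulting to one global family; the genus screen of the
pipeline corrects genera within their phylum. The scope is always explicit
config, never implicit.

## The synthetic cohort

`simulate_study()` generates the complete input set (tree, counts, diet,
covariates) with known ground truth, under independent seed sub-streams per
component so adding one component never perturbs another's draws. It emulates
a 222-adult cohort:

* **Tree and taxonomy** — four phylum subtrees (random binary, exponential
  branch lengths) joined at the root; nested clade partitions define
  class/order/family/genus, so every rank is monophyletic; the largest genera
  get recognisable names (*Bacteroides*, *Prevotella*, *Ruminococcus*,
  *Lactobacillus*, ...).
* **Communities** — per-taxon base abundances are log-normal within phylum,
  scaled by phylum masses (0.42/0.51/0.055/0.015 before boosts) chosen once
  so that realized sample medians reproduce the dominant-phyla ordering of a
  Korean adult cohort (Bacteroidetes ≈ 54%, Firmicutes ≈ 38%, Proteobacteria
  ≈ 4%, Actinobacteria ≈ 1%). These are shape calibrations, not estimates of
  any cohort. Each sample draws an enterotype (proportions 0.40/0.33/0.27), whose
  dominant genus clade is boosted 12-fold in the Dirichlet mean — strong
  enough that the three planted communities separate cleanly in ordination
  space, which is the regime the enterotype machinery is specified to
  recover.
* **Latent diversity** — each sample's Dirichlet precision is
  `concentration * exp(latent_sd * z)` with `z ~ N(0,1)`. Low precision gives
  spiky, uneven draws, so `z` drives *true community evenness* rather than
  any diversity statistic directly; recovering the diet signal therefore
  genuinely exercises rarefaction, Shannon estimation and RRR end to end.
* **Diet** — total energy log-normal (median ≈ 2100 kcal/day, sd 0.2 on the
  log scale); every food log-normal with a planted slope on log energy (so
  the residual method has real structure to remove) and noise sd 0.45; the
  planted pattern (positive weights on fermented legumes, vegetables,
  potatoes, seaweeds, nuts/seeds, tea; negative on non-alcoholic beverages)
  enters as `diet_effect * weight * 0.35 * z` on the log scale. A planted
  sex→alcohol effect provides the confounding fixture for partial-correlation
  tests. Covariates are otherwise independent of diet and community.

What the generator does **not** emulate: read-level error, chimeras and
taxonomy mis-assignment; item-level (106-food) FFQ structure; genus-level
abundance distributions of any real cohort; any enterotype→diet association
(enterotype labels are independent of the latent diversity and of intake, so
diet contrasts across synthetic enterotypes are null). Passing tests
demonstrate the machinery recovers what was planted at the stated effect
sizes — they do not certify effect sizes in real data.

## Numerical choices and degenerate inputs

* Zero dietary intakes are offset by half the smallest positive value in the
  column before logging (the instrument's effective detection limit), and the
  offset rule is deterministic.
* All-zero samples are hard errors at `to_proportions()` naming the sample;
  constant energy is a degenerate design; collinear or constant food columns
  abort the RRR fit naming the columns.
* Rarefaction keeps a sample whose total equals the depth unchanged; the
  subsample is hypergeometric (verified against its moments).
* The Mann-Whitney test is exact (enumeration) for combined n ≤ 12 without
  ties, otherwise normal with tie and continuity corrections.
* Determinism: every stochastic step (rarefaction draw, k-means restarts, gap
  references, permutations) derives a named sub-stream from one root seed;
  two runs of `run_pipeline()` with the same config and seed produce
  byte-identical outputs, and the test suite checks this.

## Problem sizes used in the tests

The suite exercises cohort scale (n = 222, 200 taxa, depth 5887) for the
recovery checks — 25 seeds for enterotype recovery and silhouette selection,
50 seeds for loading-sign recovery — and smaller configurations (n = 36–80)
for the orchestration and determinism checks; oracle-equivalence tests
enumerate all tree shapes up to 6 leaves. These sizes were chosen so that
each planted effect is comfortably inside the power of the corresponding
test at its stated acceptance rate.

## Known limitations

* Enterotype discreteness is itself debated; the package reports silhouette,
  elbow and gap diagnostics and a cross-metric agreement check rather than
  asserting that k = 3 is "true".
* The single-response RRR reduction does not generalise to multi-response
  designs (a non-goal here).
* PERMANOVA is single-factor only; no strata or marginal multi-factor tests.
* Unweighted-UniFrac enterotyping tends to produce fewer, coarser clusters;
  the same code path supports it without special-casing.
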