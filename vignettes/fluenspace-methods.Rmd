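---
title: "Methods: semantic-space fluency scoring and its simulation world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic-space fluency scoring and its simulation world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluenspace)
```

## The problem and the model

Category-fluency performance is usually summarized by a single word count.
Item-level analysis asks *how* the speaker traverses semantic memory:
whether they cluster within semantic sub-categories, switch between them,
and return to sub-categories they have already exploited. The obstacle is
that manual sub-categorization schemes let one item belong to several
clusters, which makes switch and (especially) return counts ill-defined.

`fluenspace` resolves the ambiguity geometrically. Every item receives a
distributional word vector; cosine distance defines an m × m semantic
dissimilarity matrix; classical MDS followed by t-SNE produces a 2-D map
in which sub-category structure is visually and algorithmically
recoverable; k-means (or a manually curated map) then assigns **exactly
one** sub-category per item. Given that labeling, a transcript becomes a
label sequence, and all movement metrics are functions of its run-length
encoding:

* words `n` — sequence length (repetitions and errors retained);
* sub-categories `K` — distinct labels used;
* switches `S = runs − 1` — transitions between consecutive runs;
* returns `R = runs − K` — every run whose label occurred in an earlier
  run, so `R = S − (K − 1)` and `0 ≤ R ≤ S`;
* adjusted switches / returns — `100·S/n`, `100·R/n` (percent), removing
  the mechanical dependence of the counts on fluency volume;
* visitation profile — run lengths indexed by the run's ordinal within its
  own sub-category (visit 1, return 1, return 2, ...).

Group inference uses one-way ANOVA (partial η² = SSB/(SSB+SSW)),
one-way MANOVA over the four movement DVs (sub-categories, switches,
adjusted switches, adjusted returns; Wilks' Λ = det E / det(H+E), Rao's F
approximation, multivariate η² = 1 − Λ^(1/s), s = min(p, g−1)), Spearman
correlations with significance stars, and multinomial logistic models
predicting group membership with AD as the reference category. Model
comparison follows the conventional ladder: Model 1 (words + age) and
Models 2–4 each adding a single movement variable; predictors are not
combined across movement variables because they are strongly collinear.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| MDS variance threshold | 0.96 | fraction | retained dimensions must explain 96 % of positive-eigenvalue variance |
| MDS dimension cap | 50 | dims | standard pre-t-SNE reduction target |
| t-SNE perplexity | 20 | eff. neighbors | emphasizes local cluster structure; 5–50 recommended band enforced by warning |
| t-SNE iterations | 1,500 | — | stable embeddings; < 250 warns |
| t-SNE restarts | 10 | — | embedding kept is the minimum-KL run over seeds `seed..seed+9` |
| k-means k | 8 | clusters | default sub-category count for animal fluency |
| k-means n_init | 25 | — | best WCSS over random initializations |
| Reference group | AD | — | contrasts read "healthy vs AD", "aMCI vs AD" |
| Ridge penalty | 0 | — | optional ℓ₂ fallback for (quasi-)separable cohorts |

Numerical choices worth recording:

* **Cosine distance range.** Entries live in [0, 2] and are *not* clamped
  to [0, 1]; clamping would silently distort antipodal vector pairs, which
  synthetic data legitimately produce. Tiny negative values from floating
  point are truncated at 0 and the matrix is symmetrized.
* **MDS flavor.** Classical (Torgerson) metric MDS — double-centering of
  squared distances plus eigendecomposition — because "variance explained"
  then has a canonical eigenvalue meaning. The variance denominator is the
  sum of **positive** eigenvalues only; the mass of negative eigenvalues
  (cosine matrices are typically non-Euclidean) is reported separately as
  a diagnostic. An all-zero distance matrix is an error, not a k = 0
  result, because downstream t-SNE is undefined there.
* **Degenerate k-means.** `k = m` returns singleton clusters directly
  (the trivially optimal solution); `stats::kmeans` refuses that case.
* **Clustering target.** k-means runs on the 2-D t-SNE coordinates by
  default, mirroring the visual-labeling workflow the map exists to
  support; a `use_mds` flag clusters the pre-t-SNE MDS coordinates
  instead, because clustering t-SNE output is contested (t-SNE does not
  preserve between-cluster distances).
* **Multinomial fitting.** BFGS on the analytic log-likelihood/gradient
  (reference level last, contrast-major parameter layout), Wald SEs from
  the numeric Hessian, per-predictor significance by likelihood-ratio
  refits (df = 2). `Exp(B) = exp(B)` always; Nagelkerke
  R² = [1 − (L₀/L₁)^{2/n}] / [1 − L₀^{2/n}]; AIC = 2p − 2LL,
  BIC = p·ln n − 2LL. Classification is by maximum predicted probability
  with no prior reweighting. Runaway standardized coefficients (> 25)
  flag probable separation instead of being reported as estimates.
* **Ties and determinism.** Every stochastic stage (t-SNE restarts,
  k-means initialization, simulation) consumes an explicit integer seed;
  pipeline manifests record all of them.

## The simulation world

The generator exists so that every pipeline stage is testable offline; it
is a *stated world*, not a fit to any participant data.

**Space.** 8 sub-categories × 28 items (224 items total) with 50-d unit
vectors: orthonormal cluster centers (QR of a Gaussian matrix), item =
center + isotropic noise (sd 0.15), re-normalized. A `center_separation`
< 1 pulls all centers toward a shared direction for harder problems.

**Cohort.** 42 healthy / 24 aMCI / 18 AD participants. Each transcript is
a first-order Markov walk over sub-categories: stay with probability
`p_stay` (drawing an unused item of the current sub-category), otherwise
switch, targeting an unvisited sub-category with probability
`p_new_given_switch` when one exists, else returning to a previously
visited one. Word counts are truncated Gaussians; ages are Gaussian with
the published group means/SDs (74.4/71.3/78.3, SD 7.3/6.6/4.8).

Calibration was done once, analytically (`E[S] = (n−1)(1−p_stay)` when
sub-categories never exhaust; `K ≈ 2 + q(S−1)`; `R = S + 1 − K`) and then
verified by Monte Carlo — not iterated against test outcomes:

| group | n | words (sd) | p_stay | p_new_given_switch | mean returns achieved |
|---|---|---|---|---|---|
| healthy | 42 | 22 (6) | 0.50 | 0.35 | ≈ 6.3 |
| aMCI | 24 | 17 (5) | 0.50 | 0.32 | ≈ 4.75 |
| AD | 18 | 12 (4) | 0.55 | 0.45 | ≈ 2.2 |

Rationale for the free choices: word-count means (22/17/12) are field-
plausible one-minute animal-fluency volumes for healthy/aMCI/early-AD
groups; the SDs (6/5/4) were set so the words ANOVA partial η² lands near
0.37 and the words+age model's Nagelkerke R² near 0.5 — the effect sizes
this design is meant to emulate. The movement parameters place mean
returns near the reported group pattern (≈ 6 / 5 / 2.2, AD sharply
lowest) with per-group return SDs ≈ 2.6/2.3/1.6. Two calibration targets
conflict mildly: pinning the healthy and aMCI return means very close
together (≈ 5.98 vs 5.04) makes their group-mean *ordering* hold in only
~95 % of replicate cohorts. The ordering requirement is the hard one, so
the gap was widened to ≈ 6.3 vs 4.75 (~7 % off the tight targets), which
lifts the joint AD < aMCI < healthy ordering (words, switches, returns)
to ~98 % of seeds.

**What the generator does not emulate.** Lexical frequency and typicality
gradients within sub-categories; response latencies; perseveration
patterns (repetitions occur only under the with-replacement flag);
semantic-foraging dynamics richer than a first-order chain; any
corpus-derived geometry (items are isotropic blobs, so the 2-D map is far
cleaner than a real embedding space). A green recovery test therefore
establishes that the pipeline recovers planted structure — not that the
sub-categories of a real corpus are equally recoverable.

## A deliberate red: power of the adjusted-returns test

One acceptance property asks that Model 4's adjusted-returns
likelihood-ratio test reject at α = 0.05 in ≥ 80 % of 100 replicate
cohorts. In this simulation world the measured rejection rate is ~35–50 %.
This is not a fitting defect: the calibrated world reproduces the target
effect sizes (Model 1 R² ≈ 0.5, Model 4 R² ≈ 0.55, ΔR² ≈ 0.05, mean LR
statistic ≈ 6.5 against a reported single-study value of ≈ 8), and a
2-df LR test at that noncentrality has ~50 % power; 80 % power would
require noncentrality ≈ 9.6, i.e. a planted effect substantially stronger
than the design this world emulates. The test asserts the stated bound
and fails honestly rather than inflating the effect. The companion
type-I-error half (rejection ≈ 5 % under identical group parameters)
passes.

## Known limitations

* Multi-word items are matched to vocabularies by a lowercase/underscore
  convention; no sub-word composition for out-of-vocabulary items.
* t-SNE coordinates are only locally meaningful; between-cluster
  distances on the map carry no interpretation, which is why stability is
  reported as label agreement (ARI), never as coordinate agreement.
* The multinomial suite performs no cross-validation by design (matching
  the workflow it implements); classification rates are in-sample.
* The bootstrap variant of pairwise post-hoc tests is not implemented;
  pairwise comparisons use pooled-SD t tests with Bonferroni adjustment.
* MANOVA assumes homogeneous within-group covariance; no Box's M test is
  provided.
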