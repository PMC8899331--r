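# fluenspace

Semantic-space scoring of category ("semantic") fluency transcripts, for
researchers and clinicians studying early Alzheimer's disease and related
conditions.

In the semantic fluency task a participant names as many members of a
category (classically *animals*) as possible in one minute. Beyond the raw
word count, diagnostic information hides in *how* the speaker moves through
semantic space: clustering inside a sub-category (pets, birds, farm
animals, ...), switching between sub-categories, and — the variable this
package emphasizes — **returning** to sub-categories visited earlier.
Manual sub-categorization schemes are ambiguous (one word may belong to
several clusters); `fluenspace` instead derives an *unambiguous* item →
sub-category map from word-embedding geometry.

## The method

1. **Semantic space.** Each produced item gets a word2vec-style vector
   (text or binary format); dissimilarity is the cosine distance
   `D(i, j) = 1 − vᵢ·vⱼ / (‖vᵢ‖‖vⱼ‖)`.
2. **2-D map.** Classical (Torgerson) MDS reduces the m×m distance matrix
   to the smallest number of dimensions explaining ≥ 96 % of the
   positive-eigenvalue variance (capped at 50), then t-SNE (perplexity 20,
   1,500 iterations) embeds those coordinates in 2-D; the embedding is
   restarted (default 10×) and the run with the lowest Kullback–Leibler
   divergence kept.
3. **Sub-categories.** k-means (default k = 8) on the map — or an imported
   manual label map — assigns every item to exactly one sub-category.
   Stability across perplexities and seeds is quantified with the adjusted
   Rand index.
4. **Movement metrics.** With `runs` the maximal blocks of consecutive
   same-label items: switches `S = runs − 1`, distinct sub-categories `K`,
   returns `R = runs − K`, adjusted variants `100·S/n` and `100·R/n`
   (percent of the word count `n`), plus per-visit run-length
   ("visitation") profiles.
5. **Group statistics.** One-way ANOVA with partial η², MANOVA (Wilks' Λ),
   Spearman correlations, and a suite of multinomial logistic models
   predicting diagnostic group (healthy / aMCI / AD, reference AD):
   Model 1 = words + age; Models 2–4 add adjusted switches,
   sub-categories, and adjusted returns respectively, compared by
   likelihood-ratio χ², Nagelkerke pseudo-R², AIC/BIC and confusion
   matrices.

A synthetic-data module generates clustered embedding spaces and
group-structured cohorts (a first-order Markov walk over sub-categories),
so the entire pipeline runs and is tested without any external corpus or
participant data.

## Worked example

```r
library(fluenspace)

scen <- default_paper_like_scenario(seed = 2)   # 224 items, 8 sub-categories,
                                                # 42 healthy / 24 aMCI / 18 AD
labs <- label_sequence(scen$records[[1]], scen$labeling)
compute_metrics(labs)
#> <fluency_metrics: n = 16, K = 5, switches = 9, returns = 5,
#>                   adj. S = 56.2%, adj. R = 31.2%>

m <- cohort_metrics_table(scen$records, scen$labeling)
oneway_anova(m$n_words, m$group)
#> <group_test (ANOVA): F(2, 81) = 24.42, p = 5.03e-09, partial eta^2 = 0.376>
group_difference_report(m)$manova
#> <group_test (MANOVA): F(8, 156) = 7.60, p = 1.485e-08,
#>                       Wilks' lambda = 0.518, partial eta^2 = 0.280>

suite <- model_suite(m)        # Models 1-4, reference group AD
suite
#>    model chisq df nagelkerke_r2   bic   aic         p
#> 1 model1 50.83  4        0.5196 149.6 135.0 2.419e-10
#> 2 model2 55.13  6        0.5508 154.1 134.7 4.355e-10
#> 3 model3 53.71  6        0.5407 155.5 136.1 8.423e-10
#> 4 model4 60.36  6        0.5866 148.9 129.5 3.801e-11
suite$confusions$model4
#>         healthy aMCI AD correct (%)
#> healthy      34    6  2        81.0
#> aMCI         12    8  4        33.3
#> AD            1    2 15        83.3
#> overall correct: 67.9%
```

Reading the numbers: the groups differ strongly in words produced
(F(2,81) = 24.4, η² = 0.38) and in multivariate movement behavior
(Λ = 0.52). Adding adjusted returns to the words+age model (Model 4)
raises the pseudo-R² from 0.52 to 0.59 and lowers both AIC and BIC —
returning to previously visited sub-categories carries diagnostic signal
beyond the word count. In this cohort the mean return counts are 7.3
(healthy), 5.9 (aMCI) and 1.7 (AD); per one percentage point of adjusted
returns, the odds of being healthy rather than AD rise by the factor
Exp(B) = 1.12 (95 % CI 1.02–1.22).

## Command line

```sh
fluenspace simulate --scenario paper-like --seed 0 --out data/
fluenspace build-space --vectors data/vectors.txt --format text --out distances.csv
fluenspace map --distances distances.csv --perplexity 20 --iters 1500 --restarts 10 --seed 0
fluenspace label --map map.csv --k 8
fluenspace metrics --transcripts data/transcripts.csv --labels labels.tsv --out metrics.csv
fluenspace analyze --metrics metrics.csv --reference AD --out report/
fluenspace run --simulate --seed 0 --out fluenspace-out/   # everything above
```

`fluenspace run` writes a `manifest.json` recording versions, seeds, stage
parameters and the per-restart KL table, sufficient to reproduce every
seeded stage bit-identically.

## Vignette

`vignettes/fluenspace-methods.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and known limitations
— including one acceptance property (statistical power of the
adjusted-returns test) that the calibrated simulation world deliberately
fails.
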