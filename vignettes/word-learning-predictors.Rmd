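---
title: "Modelling cross-linguistic predictors of early word learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cross-linguistic predictors of early word learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexacq)
```

## The scientific question

Children learn some words months or years before others. One productive way
to study the mechanisms behind this is to treat the *order of acquisition* as
the outcome of a regression problem: for each word on a parent-report
vocabulary checklist (CDI-style instruments, on which parents indicate
whether their child "understands" or "understands and says" each of several
hundred words), estimate how strongly word-level properties — how often the
word is heard, in what kinds of utterances, how long it is, what it means —
predict the proportion of children reported to know it at each age. Doing
this separately in many languages then lets one ask a second-order question:
are the *profiles* of predictor effects consistent across languages, or does
each language pose its own learning problem?

`lexacq` implements that full analysis as a tested pipeline:

1. **Predictor extraction** (`build_predictor_table()` and friends): derive
   word frequency, solo frequency, utterance-final frequency, and MLU-w
   (mean length in words of the utterances containing the word) from a
   corpus of child-directed speech, count phonemes from supplied
   transcriptions, and join adult rating norms (concreteness, valence,
   arousal, babiness).
2. **Imputation** (`impute_predictors()`): fill missing predictor cells by
   iterative regression imputation within each language.
3. **Acquisition models** (`build_design()`, `fit_glmm()`): per language and
   measure (comprehension vs. production), a mixed-effects logistic
   regression predicting each child x word response from standardized age,
   the nine standardized word properties, property x age interactions,
   property x lexical-category interactions, with a by-word random intercept
   and random age slope.
4. **Consistency analysis** (`pairwise_correlations()`,
   `shuffled_baseline()`, `cluster_languages()`, `category_consistency()`):
   correlate the per-language coefficient profiles, compare them against a
   permutation null, and cluster languages by effect similarity.
5. **Synthetic studies** (`generate_study()` and the other generators): a
   first-class generative model of all the input families, with a known
   coefficient vector per language, used throughout the test suite for
   parameter recovery, calibration, and end-to-end checks.

Real studies of this kind draw on external archives (checklist repositories,
child-language corpora, published rating norms). This package deliberately
takes those as *inputs* in simple interchange formats and focuses on the
analysis; the synthetic generator stands in for the archives so every stage
can be validated against ground truth.

## The model

For child $c$ with standardized age $a_c$ and word $w$ with standardized
property vector $x_w$ and lexical category $k(w)$, the probability of a
positive checklist response is

$$
\Pr(y_{cw} = 1) = \mathrm{logit}^{-1}\!\Big(
\alpha + u_w + (\beta_{\mathrm{age}} + s_w)\,a_c
 + x_w^\top\beta
 + (x_w^\top\beta_{\mathrm{age}\times})\,a_c
 + \gamma_{k(w)} + x_w^\top\delta_{\cdot k(w)}
\Big),
$$

with $(u_w, s_w)$ bivariate normal across words. There are no child-level
terms: each child contributes one administration, and the target estimands
are word-level. Category terms are contrast coded (deviation / sum-to-zero
by default, with `Other` as the dropped level), so "main" property effects
are across-category averages and the per-category cell effect of a property
is *main effect + category main effect + interaction*, composed by
`compose_category_effects()`.

Models are fit per language x measure by maximum likelihood under the
Laplace approximation. The default engine is glmmTMB; `engine = "glmer"`
(lme4, also Laplace) is available and the two are cross-checked against each
other in the test suite, with plain `glm()` as the oracle in the degenerate
zero-variance case. Inference on fixed effects uses Wald standard errors.

**A likelihood identity worth knowing about:** because every covariate in
the model is a function of (word, age) only, the Bernoulli child x word
rows can be collapsed to word x age binomial counts with an *identical*
likelihood. `fit_glmm()` always does this. It changes no estimate and no
standard error, but makes fits roughly 30x faster, which is what allows the
simulation-based test suite to run at full study sizes (e.g. 1,000 children
x 100 words per replicate).

## Predictor construction choices

* **Counting.** Tokens are case-folded and resolved in a fixed order:
  inflected/synonym variants collapse to their canonical form first, then
  polysemous forms split their unit mass uniformly over their $k$ senses
  ($1/k$ each), then remaining forms match the item table; anything else is
  tallied as unmapped. Mass is conserved: item counts + unmapped = total
  adult tokens (a tested invariant).
* **Normalization.** Counts are Laplace smoothed (exact zeros replaced by
  one — fractional polysemy mass below one is left as is), normalized per
  million tokens, and natural-log transformed. The base is recorded in the
  output metadata so corpora of different sizes remain comparable.
* **Solo/final frequencies** count a word as *solo* when it is an
  utterance's only token and as *final* when it ends an utterance of length
  at least two; both are smoothed and normalized like frequency and then
  residualized on log frequency (OLS), *before* within-language scaling, so
  they measure variance beyond plain frequency.
* **MLU-w** is the occurrence-mass-weighted mean utterance length; words
  with fewer than 10 (possibly fractional) occurrences get a missing value
  rather than a noisy estimate.
* **Scaling.** Every numeric predictor is z-scored within language using the
  mean and sample SD of its non-missing cells; the scaling metadata is kept
  for back-transformation.

## Imputation

Missing cells are first filled by resampling the column's observed values
(seeded), then sweeps run in declared predictor order: each predictor with
missing data is regressed (OLS) on all the others using the rows where it
was observed, and its missing cells are replaced by the regression
predictions. Sweeps stop when the largest absolute change of any imputed
cell falls below `tolerance` (default 1e-6) or after `max_iterations`
(default 20); both the rule and the defaults are package choices, exposed as
configuration, and the convergence report records iterations and the final
maximum change. Observed cells are never modified — a tested invariant.
Point prediction (no residual noise) makes the procedure deterministic after
initialization; monotone convergence is *not* guaranteed by the procedure
and is therefore checked empirically, not asserted.

Two consequences of this design are worth flagging. First, MLU-w missingness
is frequency-driven (rare words lack stable estimates), i.e. not at random,
so imputed MLU-w cells are systematically pulled toward the regression
surface and the column mean can drift away from zero after imputation; the
model layer's "is this table standardized?" guard is deliberately loose for
this reason. Second, when a large fraction of a column is imputed, imputed
cells are near-linear combinations of the other predictors, which inflates
variance inflation factors; the collinearity diagnostics
(`collinearity_diagnostics()`: pairwise Pearson correlations and
$\mathrm{VIF}_p = 1/(1 - R_p^2)$) are computed post-imputation precisely so
that this shows up rather than being hidden.

## Consistency and the shuffled baseline

Per-language main-effect vectors (nine values each) are compared by Pearson
correlation (Spearman available by flag); each language's consistency is its
mean correlation with all other languages. The null reference is a
*shuffled baseline*: in each of `n_bootstrap` (default 1,000) replicates,
every language's coefficient vector is independently permuted and the
per-language mean correlations recomputed; the 2.5-97.5 percentile band of
those replicates is the chance interval. Because the baseline is a
permutation construction it is distribution-free, and under independent
vectors the observed value falls inside the band ~95% of the time — a
calibration property the acceptance suite verifies directly.

Language similarity structure is summarized by complete-linkage (default)
agglomerative clustering on the distance $1 - r$, serialized as Newick.
Per-category consistency applies the same correlation machinery to the
composed per-category cell effects; only main effects enter the headline
consistency comparison (whether interaction terms belong there is genuinely
open; the choice is exposed as configuration).

## The synthetic generator: what it does and does not emulate

`generate_study()` produces, from one master seed: a shared item set
(playing the role of cross-language translation equivalents) with latent
standardized properties drawn from a multivariate normal whose default
correlation matrix includes a -0.35 frequency-concreteness, -0.33
frequency-length, and -0.44 MLU-solo correlation, mimicking the structure
seen in real corpus-derived predictors; per-language word forms with
inflected variants and a few shared polysemous forms; per-language corpora
whose empirical log frequencies and per-word mean utterance lengths track
the latent targets (a tested round-trip, Spearman rho >= 0.9 at 20,000
utterances); rating norms as affine maps of the latent properties with
MCAR missingness at configurable per-column rates (word length always
complete, since it is computable from any transcription); and checklist
administrations drawn from the logistic model above.

Defaults were chosen once to represent a plausible study of this kind:
standardized main effects equal to the across-language means reported in
large-scale checklist studies (frequency 0.23, concreteness 0.18, solo
frequency 0.17, final frequency 0.13, MLU-w -0.14, word length -0.19,
babiness 0.13, valence 0.06, arousal 0.003); random intercept/age-slope SDs
0.5/0.2 with correlation 0.25; ages uniform over 8-18 months for
comprehension and 8-30 for production; norm missingness rates inside the
ranges seen in real resources (babiness 20%, valence/arousal 10%,
concreteness 0.5%). Age is standardized by mapping the instrument range's
endpoints to -1/+1 ("midpoint" scaling) — how age was scaled is not
something the analysis literature pins down, so the method (`"midpoint"` or
`"zscore"`) is explicit configuration rather than a hidden constant.

What the generator does *not* emulate: longitudinal (repeated-child)
sampling, parent reporting biases, real CHAT morphology tiers, resource-
driven (non-MCAR) norm missingness, or cross-language differences in
instrument construction. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated under the stated generative model,
not that real archives would yield any particular substantive result.

## Numerical and design choices

* **Aggregation** (above) is exact, not an approximation.
* **Separation** is detected, not assumed: before each GLMM fit a plain
  logistic fit is run and the fit aborts if its fitted linear predictor
  diverges (|eta| > 30, i.e. fitted probabilities within ~1e-13 of 0/1).
  Divergence of *coefficients* alone is not used as the criterion, because
  near-collinear designs (e.g. few items in a category) produce large,
  mutually compensating coefficients without separation.
* **Rank deficiency**: when a category has fewer items than predictors, the
  category-interaction block is aliased; engines drop those columns, the
  coefficient table reports them as `NA` with the names recorded, and the
  pipeline excludes affected predictors from the consistency stage with a
  recorded warning instead of failing.
* **Age standardization** uses the instrument range, not the sample, by
  default, so coefficients are comparable across samples with different age
  compositions.
* **Deviation coding** drops `Other`; fixed-effect fits are invariant to the
  coding (tested), and all four levels enter the coding even though reports
  typically focus on nouns, predicates and function words.
* **Convergence policy**: glmmTMB runs with raised iteration limits; a fit
  only errors when the Hessian is not positive definite or standard errors
  are non-finite. Boundary fits (zero variance estimates) are legitimate
  outcomes, not errors.
* **Seeds**: every stochastic step takes an explicit seed; the pipeline
  derives per-stage seeds deterministically from one master seed, and
  rerunning a configuration reproduces byte-identical outputs (tested via
  manifest checksums).

## Problem sizes used in the test suite

The simulation tests run at the sizes stated in their descriptions: type-I
error and parameter recovery use 1,000 children x 50 or 100 words with 50
response replicates (the recovery/coverage study holds the item design fixed
across replicates, since Wald intervals promise conditional-on-design
coverage); imputation comparisons use n = 400 rows, 20% missingness, 100
replicates; the end-to-end category-consistency study uses five languages,
100 items, 150 children and 4,000-utterance corpora over 20 seeded runs; the
acceptance script's demonstration study uses five languages, 150 items, 500
children per measure and 20,000-utterance corpora. Thin corpora (a few
thousand utterances for a hundred items) are deliberately exercised in the
pipeline tests as well, because they are the regime where MLU-w missingness
and post-imputation collinearity bite.

## Known limitations

* Single imputation: no uncertainty propagation from imputed cells into the
  model standard errors (multiple imputation is out of scope).
* Wald inference: with on the order of a hundred words, Wald intervals on
  word-level properties are mildly anticonservative (empirical coverage
  ~0.92 at a nominal 0.95 in the recovery study); profile or bootstrap
  intervals are not implemented.
* The shuffled baseline permutes within language only; it does not resample
  languages, so it tests exchangeability of predictors within a profile,
  not sampling variability across languages.
* Sense disambiguation is uniform splitting only, and morphology is limited
  to the supplied variant map — faithful CHAT parsing is a non-goal.
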