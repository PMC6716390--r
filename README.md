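# lexacq

Cross-linguistic predictors of early word learning.

`lexacq` is for researchers who study *why children learn some words before
others*. Given parent-report vocabulary-checklist data (CDI-style: for each
word, does the child understand it / say it?), a corpus of child-directed
speech, and adult rating norms, it estimates — separately per language and
per measure — how strongly nine word properties predict a word's acquisition
trajectory, and then asks whether those effect profiles are consistent
across languages.

The nine predictors are: log word frequency in adult child-directed speech,
solo frequency (the word as a complete utterance) and utterance-final
frequency (both residualized on frequency), MLU-w (mean length in words of
the utterances containing the word), number of phonemes, and adult-rated
concreteness, valence, arousal, and babiness (association with babies).

## The model

For child $c$ (standardized age $a_c$) and word $w$ (standardized property
vector $x_w$, lexical category $k(w)$):

$$\Pr(y_{cw}=1) = \mathrm{logit}^{-1}\big(\alpha + u_w + (\beta_{age} + s_w)a_c
 + x_w^\top\beta + (x_w^\top\beta_{age\times})a_c
 + \gamma_{k(w)} + x_w^\top\delta_{\cdot k(w)}\big)$$

a mixed-effects logistic regression with a random intercept $u_w$ and random
age slope $s_w$ per word, fit per language × measure by Laplace-approximated
maximum likelihood (glmmTMB by default, lme4 as an alternative engine).
Category terms are deviation (sum-to-zero) coded. Cross-language consistency
is the mean pairwise Pearson correlation of per-language coefficient
vectors, judged against a shuffled bootstrap baseline (each language's
coefficients independently permuted, 1,000 replicates, 95% percentile band),
with complete-linkage clustering on $1-r$ for similarity structure and the
same correlation machinery applied within lexical categories.

Because no external archive can be assumed, the package includes a
first-class synthetic-study generator (`generate_study()`) with a known
per-language coefficient vector, by-word random effects, corpora that
realize target frequency and utterance-length profiles, rating norms with
controllable missingness, and inflection/polysemy/translation-equivalent
mapping tables — so the entire pipeline is testable against ground truth.

## Worked example

Simulate a five-"language" study and run the full pipeline (predictor
extraction → imputation → models → consistency):

```r
library(lexacq)

cfg <- run_config(
  languages = c("croatian", "danish", "english", "norwegian", "russian"),
  n_items = 120, n_children = 300, n_utterances = 10000,
  measures = "production",
  category_proportions = c(0.45, 0.25, 0.15, 0.15),
  seed = 42)
man <- run_pipeline(cfg, "demo_out")

coefs <- readr::read_csv("demo_out/coefficients.csv")
summarize_coefficients(unname(split(coefs, coefs$language)))
```

```
            term type       predictor mean_estimate n_models n_significant n_sign_consistent
       frequency main       frequency         0.276        5             3                 4
           mlu_w main           mlu_w        -0.244        5             1                 3
    concreteness main    concreteness         0.229        5             4                 5
      n_phonemes main      n_phonemes        -0.158        5             3                 5
        babiness main        babiness         0.152        5             2                 5
 final_frequency main final_frequency        -0.087        5             3                 4
         valence main         valence        -0.053        5             0                 4
         arousal main         arousal         0.043        5             0                 3
  solo_frequency main  solo_frequency        -0.016        5             1                 3
```

The generator's true main effects (frequency 0.23, concreteness 0.18,
MLU-w −0.14, …) are recovered with the expected ordering: frequency is the
strongest positive predictor, utterance length and word length act
negatively, valence and arousal are near zero. Each language's mean
correlation with the other languages' profiles, against its shuffled
baseline band:

```
  language observed_mean_r ci_low ci_high
  croatian            0.40  -0.33    0.36
    danish            0.58  -0.33    0.35
   english            0.14  -0.36    0.36
 norwegian            0.42  -0.36    0.33
   russian            0.24  -0.34    0.37
```

Three of five languages exceed chance consistency at these (deliberately
modest) simulation sizes. Per-category consistency and the language
dendrogram come from the same run:

```
       category mean_r n_languages
          Nouns  0.751           5
     Predicates  0.869           5
 Function Words  0.075           5
          Other  0.187           5

((danish:0.086,(croatian:0.017,norwegian:0.017):0.070):0.493,(english:0.189,russian:0.189):0.390);
```

Content-word effect profiles correlate strongly across languages; function
words — few items, noisier cell effects — do not.

A thin command-line front end over the same functions is installed at
`inst/cli/lexacq.R` (subcommands `simulate`, `predictors`, `impute`, `fit`,
`consistency`, `run-all`).

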