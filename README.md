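# carefair

Counterfactual gender-bias auditing for automatic summarisation of
long-term-care records.

## What problem this addresses

Social workers write free-text "pen portraits" describing a person's care
needs. When a language model summarises these records, it may treat
comparable men and women differently — more negative sentiment for one
gender, health topics omitted for the other, the same needs described in
softer words. Such differences can propagate into decisions about care.

`carefair` audits a summariser under a **counterfactual fairness** design.
For each document it builds a validated pair of texts — a female and a male
version identical except for gendered tokens — runs both through
byte-identical summarisation and scoring over a factorial design of
gender × model × output-length cap, and quantifies differences four ways.
It is aimed at researchers and analytics teams who need to evaluate a
summarisation model *before* deployment on health or care text, without
access to each other's restricted records: everything runs on plug-in
summarisers and metrics, with a seeded synthetic corpus generator so the
whole pipeline is testable against planted ground truth.

## The statistical core

**Sentiment.** Per-summary sentiment (mean of per-sentence scores) is
modelled with a linear mixed model,

```
sentiment_ij = b0 + b1'model_j + b2 male_j + b3'(model_j x male_j)
             + b4'max_tokens_j + u_0i + u_1i'model_j + e_ij
```

with per-document random intercepts varying by model, reference levels
BART and max-tokens 50. Per-model gender contrasts (female − male) are
estimated marginal means, algebraically `-(b2)` for the reference model and
`-(b2 + b3m)` otherwise, with delta-method standard errors, likelihood
ratio tests for nested comparisons and a cluster bootstrap over documents.
Metrics are screened first on the original pair texts: a metric that scores
identical texts differently by gender alone is excluded.

**Inclusion bias.** Theme-lexicon term counts per (model, theme, gender),
tested by a 1-df chi-squared against equal expected counts (the exact null
under the counterfactual design), Benjamini–Hochberg adjusted across the
whole family.

**Linguistic bias.** A lemma-level document-term matrix (stop words,
punctuation and out-of-dictionary tokens removed) feeds a per-word **dual
criterion**: a word counts as used differently by gender only if (a) the
gender coefficient of a Firth-penalised Poisson regression
(`log E[count] = b0 + b1 male + b2'max_tokens + b3'doc`) is significant —
the Jeffreys penalty keeps estimates finite under perfect separation, with
a negative-binomial refit when the Pearson dispersion ratio exceeds 1.25 —
and (b) the BH-adjusted chi-squared/Fisher count test (Fisher whenever
either gender's count is below 5) is significant.

**Hallucination.** Lemma-level scan of a medical-term list in summaries vs
sources; a term present in a summary but absent from its source is a
hallucination, tallied by gender and model against the full opportunity
space (documents × versions × parameter sets × terms).

## Worked example

Generate a 100-document synthetic corpus, plant two biases in a mock
summariser — physical-health sentences dropped from female summaries with
probability 0.5, and "unable" replaced by "requires assistance" in female
summaries with probability 0.8 — and audit it:

```r
library(carefair)
cfg <- synthetic_config(
  n_docs = 100, seed = 2024,
  inclusion_drop_prob = list(female = c(physical_health = 0.5)),
  substitution_map = data.frame(source = "unable",
                                replacement = "requires assistance",
                                gender = "female", prob = 0.8))
pairs  <- generate_pairs(cfg)
report <- run_audit(pairs, biased_mock_summarizer(cfg, name = "biased"),
                    models = "biased", levels = c("100", "None"),
                    random = "intercept")
report
#> Counterfactual gender-bias audit
#>   100 validated pairs (0 dropped), 400 grid cells, metric 'lexicon'
#>   metric screen: passed
#>   gender EMM contrasts (female - male):
#>     biased     +0.0213 (p = 0.0126)
#>   themes with adjusted p < 0.05: 1 of 4
#>   dual-significant words: 22 of 156 tested
#>   hallucinations: 0 in 21600 opportunities
```

Every planted effect is recovered and nothing else fires:

```r
report$themes[, c("theme", "count_female", "count_male", "p_adjusted")]
#>                 theme count_female count_male   p_adjusted
#> 1       mental_health          544        538 8.621486e-01
#> 2 physical_appearance          778        761 8.621486e-01
#> 3     physical_health          302        603 5.761889e-23
#> 4 subjective_language          600        594 8.621486e-01

w <- report$words
w[w$lemma %in% c("unable", "assistance"),
  c("lemma", "count_female", "count_male", "direction", "coefficient",
    "regression_p", "p_adjusted")]
#>         lemma count_female count_male direction coefficient regression_p   p_adjusted
#> 1  assistance           15          0    female   -3.433987 4.594967e-03 5.445504e-04
#> 90     unable            1         43      male    3.367296 2.348142e-06 3.618130e-09
```

Reading the output: female summaries carry roughly half the
physical-health terms of male summaries (302 vs 603, the planted drop), the
substitution makes "unable" male-leaning and "assistance" female-leaning
under the dual criterion, the sentiment contrast turns positive for women
(dropping health problems removes negative-sentiment words), and the
extractive mock produces zero hallucinations. The remaining
dual-significant words are other physical-health lemmas — the footprint of
the dropped sentences, not false positives.

To audit a real summariser, wrap it in `summarizer_spec()` (and a real
sentiment model in `sentiment_metric()`) and run the same pipeline on pairs
built from your corpus with `make_pairs()` + `validate_pairs()`.

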