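---
title: "Auditing gender bias in care-record summarisation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing gender bias in care-record summarisation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the design

Social-care free-text records ("pen portraits") describe a person's needs at
assessment. When a language model summarises such a record, subtle
differences in tone, emphasis or included content between otherwise
comparable men and women can propagate into care decisions. `carefair`
audits a summariser for such differences under a *counterfactual fairness*
design: a summariser is fair towards an individual if its output
distribution is unchanged when only the person's gender markers are altered
and everything else is held fixed.

The unit of analysis is therefore a **counterfactual pair**: a female and a
male version of the same document, identical except for gendered tokens
(titles, pronouns, kinship and person nouns). Both versions are pushed
through byte-identical processing — same summariser, same parameters, same
scoring — so any measured difference is attributable to how the summariser
treats gender, not to the inputs.

The audit quantifies differences four ways:

1. **Sentiment** — a linear mixed model on per-summary sentiment scores with
   per-model gender contrasts;
2. **Inclusion bias** — theme-lexicon term counts by gender with
   chi-squared tests and false-discovery-rate correction;
3. **Linguistic bias** — per-word dual-criterion tests combining a
   Firth-penalised Poisson regression and BH-adjusted chi-squared / Fisher
   count tests;
4. **Hallucination** — medical terms present in a summary but absent from
   its source.

## Pair construction and validation

`filter_eligible()` keeps documents of 200–500 words (whitespace tokens
after unicode/whitespace normalisation; the counter is part of the package
contract since different tokenisers disagree on boundaries) and screens a
configurable exclusion-term list for content that would not describe a
comparable situation after a gender swap (sex-specific anatomy, domestic
violence). `dedupe_near()` removes near-duplicates by word 5-shingle
Jaccard similarity at threshold 0.9, keeping the earlier document; the
paper-level goal (drop near-duplicates) does not pin down a method, so the
shingle/Jaccard rule is the package's choice, chosen because it is
deterministic, order-stable and transparent.

`swap_gender()` is deterministic and rule-based: a shipped two-column
lexicon of female/male form pairs, case-preserving replacement, and a
context rule for the ambiguous token "her" (possessive before a noun-like
token, objective before a verb or function word, e.g. *"saw her leave her
coat"* becomes *"saw him leave his coat"*). An LLM-based swapper can be
plugged in through the same `(text) -> text` contract, but the default is
downloads-free and bit-reproducible. The title mapping collapses Mrs/Ms to
Mr in one direction and restores Mrs by default in the other; this is lossy
and intentional — title distinctions carry marital-status information that
has no male counterpart.

`validate_pair()` accepts a pair only when both versions have the same
number of sentences and, sentence by sentence, the same count of tokens
that are neither stop words nor gender-lexicon entries. The sentence
splitter and stop-word list are shipped as versioned code/data so
validation outcomes cannot drift across environments. Validation failure is
a data state (with the first mismatch recorded), not an error: real
swapped corpora legitimately contain non-equivalent pairs, and the pipeline
drops them.

## The generation design

The summariser's output-length cap (`max_tokens`) is a six-level factor
`50, 75, 100, 150, 300, None` with 50 as the reference level; `None` (no
cap) is deliberately a first-class level rather than a missing value.
`build_grid()` forms the full cross of documents × 2 genders × models ×
levels — with 617 documents and 4 models that is the 29,616-cell design,
48 cells per document. Summarisers are plug-ins
(`summarizer_spec`): the shipped mocks are extractive (first *k* sentences
per level), deterministic, and need no model downloads; adapters for real
checkpoints satisfy the same contract.

## Sentiment model

Metrics score one sentence at a time (`sentiment_metric`); a summary's
score is the mean over its sentences — for a binary classifier, the
proportion of positive sentences. The one-score-per-grid-cell convention is
what makes the 29,616-row model table line up with the design. Before any
metric is used it is screened on the *original* pair texts
(`screen_metric_bias`): a metric that assigns different sentiment to
identical texts that differ only in gender markers measures its own bias,
not the summariser's, and is excluded.

Per-summary sentiment for document $i$ in cell $j$ is modelled as

$$
\text{sentiment}_{ij} = \beta_0
 + \boldsymbol\beta_1^\top \mathbf{model}_j
 + \beta_2\,\text{male}_j
 + \boldsymbol\beta_3^\top(\mathbf{model}_j \times \text{male}_j)
 + \boldsymbol\beta_4^\top \mathbf{maxtokens}_j
 + u_{0i} + \mathbf{u}_{1i}^\top\mathbf{model}_j
 + \varepsilon_{ij},
$$

with reference levels BART (or the first model present) and max-tokens 50,
per-document random intercepts varying by model with unstructured
covariance ($u_{0i}$ plus per-model offsets $\mathbf u_{1i}$), and
$\varepsilon_{ij}\sim N(0,\sigma^2)$. Fitting is by maximum likelihood
(lme4) so nested fits are comparable with `likelihood_ratio_test()`.
Fixed-effect inference uses Wald $z$; with hundreds of documents this is
indistinguishable from the $t$-based output of mixed-model software, and
the difference is documented rather than hidden. Demographic covariates
(age, ethnicity) are supported but off by default. When only one model is
present the random structure collapses to a plain document intercept, and
`random = "intercept"` forces that structure for large simulation studies.

Per-model gender contrasts (`estimate_gender_emm`) are estimated marginal
means over a balanced max-tokens grid. Because max-tokens enters
additively, the female−male contrast is algebraically $-\beta_2$ for the
reference model and $-(\beta_2+\beta_{3m})$ for model $m$; standard errors
follow by the delta method. This identity is exact for any converged fit
and is cross-checked against the emmeans package in the test suite.
`cluster_bootstrap()` resamples documents (the clustering unit) with
replacement and returns seeded percentile intervals.

## Inclusion bias

`count_theme_terms()` counts theme-lexicon terms (lemma-level,
word-boundary, multi-word terms as contiguous lemma sequences) per
(model, theme, gender). The default test (`theme_chisq`) is a 1-df
goodness-of-fit of the (female, male) count pair against equal expectation:
the counterfactual design guarantees the *sources* use each term equally
often per gender, so equal expected counts is the exact null. An
exposure-adjusted 2×2 variant (term count vs all-other-token count) is
available for unbalanced corpora. The BH family is all (theme × model)
tests jointly. The shipped starter lexicons (physical health, mental
health, physical appearance, subjective language) are editable plain-text
files and make no claim to clinical completeness.

## Linguistic bias and the dual criterion

`build_doc_term_matrix()` lemmatises summaries, removes stop words,
punctuation and out-of-dictionary tokens, and returns sparse lemma counts
with design annotations. Lemmas of gender-lexicon entries are excluded by
default: on counterfactual pairs they differ by construction and would be
flagged trivially. The lemmatiser is a deterministic rule engine
(exceptions table, -ies/-es/-s, -ing/-ed with e-restoration and consonant
un-doubling, all validated against the shipped dictionary snapshot); it is
cruder than a tagger-based lemmatiser but bit-stable, which matters more
here — the dictionary and rules are versioned data, so vocabularies are
identical across machines.

Aggregate counts per lemma and gender are tested with a chi-squared test on
the exposure 2×2 table, except when either gender's count is below 5, where
Fisher's exact test is used. Document-level behaviour is modelled per lemma
by Poisson regression with log link:

$$
\log \mathbb E[\text{count}_{ij}]
 = \beta_0 + \beta_1\,\text{male}_j
 + \boldsymbol\beta_2^\top \mathbf{maxtokens}_j
 + \boldsymbol\beta_3^\top \mathbf{doc}_i ,
$$

where the rows are all summaries of documents in which the lemma appears at
least once — structural zeros inside those documents are retained because
the gender contrast lives exactly in within-document zero/nonzero
variation — and document fixed effects absorb baseline rate differences
(they are estimated but never reported). No length offset is used: the
max-tokens factor absorbs summary-length variation within the design.

Words never used for one gender make the unpenalised likelihood
unbounded (perfect separation), so the package maximises the
Jeffreys-penalised log-likelihood
$\ell(\beta) + \tfrac12 \log\det I(\beta)$. For the canonical log link the
penalised score is $X^\top(y - \mu + h/2)$ with $h$ the hat diagonal, and
`carefair` implements a damped Newton iteration on this modified score
(tolerance $10^{-8}$ on the score norm, at most 100 iterations). The
implementation is checked in the tests against brute-force numerical
maximisation of the penalised likelihood. When the Pearson dispersion ratio
$\sum r_i^2/\text{df}$ exceeds 1.25, a maximum-likelihood negative binomial
with the same design replaces the Poisson inference (falling back, flagged,
if it does not converge).

A lemma is reported as used differently by gender only under the **dual
criterion**: regression $p < \alpha$ *and* BH-adjusted count-test
$p < \alpha$ (family = all testable lemmas within one model). Lemmas with
total count below 2 are untestable and skipped. Requiring both tests
guards against each test's failure mode: the aggregate test ignores
document clustering, the regression can be driven by a few unusual
documents.

## Hallucination audit

`scan_terms()` does lemma-level, word-boundary membership for a shipped,
editable list of long-term-care diagnoses; `audit_hallucinations()` marks a
term hallucinated when it appears in a summary but not in the matching
gender's source text, and reports counts by gender and model alongside the
opportunity space (`opportunity_count`, the product of documents ×
versions × parameter sets × terms). Negation is deliberately not parsed:
the audit mirrors a plain search, and "no history of dementia" counts as
present in both source and summary, which cancels in the hallucination
definition. An extractive summariser can never hallucinate under this
definition — a property the tests assert exactly.

## The synthetic test bed

`generate_pairs()` builds counterfactual pairs from a seeded template
grammar: an intro sentence plus 10–16 sentences drawn from per-theme pools
(each carrying terms from the shipped theme lexicons) and neutral filler,
instantiated once per gender through slot substitution. Realism is
secondary to controlled statistical structure: every generated pair passes
validation by construction, and the default corpus size of 400 pairs
matches the scale of a small synthetic evaluation corpus. What the
generator does *not* emulate: real lexical diversity (the template
vocabulary is a few hundred lemmas), discourse structure, typographical
noise, or clinically coherent case histories. Passing tests therefore
demonstrate that the statistical machinery detects what it is supposed to
detect under known truth — not that any particular real summariser is
biased or unbiased.

Bias is injected at summarisation time, never in the sources, mirroring the
causal claim under audit (sources are gender-equivalent; differences arise
in summaries). `biased_mock_summarizer()` drops theme sentences for a
target gender with a configured probability, substitutes phrases
(e.g. "unable" → "requires assistance" for female summaries with
probability 0.8), shifts sentiment by appending a negative-tone sentence,
or appends a medical term absent from the source. Gender is inferred from
the text itself, so both genders pass through identical code. Randomness is
seeded per (text, level) hash, making whole runs byte-reproducible.

## Numerical choices and test scales

- Firth Newton iteration: score-norm tolerance 1e-8, max 100 iterations,
  step halving against the penalised likelihood; standard errors from the
  inverse Fisher information at the penalised optimum.
- Degenerate inputs: an all-constant sentiment table returns the exact
  degenerate fit (intercept = the constant, zero variances) rather than
  calling the optimiser; a both-zero count pair is "undefined", not 0/0.
- Tie-breaks: deduplication keeps the earlier document; theme
  classification of a sentence takes the first matching theme in
  alphabetical order.
- Simulation sizes in the test suite and acceptance script are chosen to
  estimate the quantities they check with adequate precision at desk
  scale: 200 documents with 2 models × 2 max-token levels for
  mixed-model coverage (150–200 replicates), 200 documents for word-count
  recovery (60–100 replicates), 300–500 replicates for the LRT null, and
  10–20 seeds of 200-document corpora for power against planted bias.
  These are the package's own choices of problem size.

## Known limitations

- The rule-based "her" disambiguation is a heuristic; unusual syntax can
  mis-resolve possessive vs objective. Validation catches the cases where
  this would distort counts, because both resolutions are gendered tokens.
- The lemmatiser has no part-of-speech awareness; rare derivations may
  lemmatise unexpectedly. The dictionary filter bounds the damage by
  construction.
- The goodness-of-fit theme test assumes the balanced counterfactual
  design; use the exposure-adjusted variant on anything else.
- Wald inference for fixed effects is asymptotic; at very small document
  counts prefer the cluster bootstrap.
- The hallucination audit is a presence test, blind to negation,
  uncertainty and paraphrase.
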