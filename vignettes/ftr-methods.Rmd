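---
title: "Measuring future time reference and temporal cognition with ftrclassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring future time reference and temporal cognition with ftrclassify}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftrclassify)
```

## The problem

English marks future time reference (FTR) loosely: *The train gets in at 7
tonight* is present tense but future-referring, while *That will be the
postman* uses *will* for a present inference. Measuring how people talk
about the future in naturalistic text therefore needs two separate
judgements: **whether** a sentence refers to the future or past at all,
and, for future-referring sentences, **how** the future is construed —
with bare tense, with hedged (low-certainty) modality, with obligation
(deontic), desire (bouletic), or counterfactual (irrealis) framing. Both
judgements, together with how far into the future people talk (their
*time horizon*) and behavioural measures of time perspective (delay
discounting, subjective temporal distance, mood-symptom scores), form a
single analysis pipeline in this package.

## Stage 1: the time-reference classifier

`train_time_reference()` fits a linear model on unigram + bigram presence
features with a three-way softmax over {FTR, PTR, OTHER}. OTHER is a
residual class — anything that is neither future nor past reference
(statements of fact, ability, present states) — not a "present tense"
class. The fit is ridge-penalised multinomial regression (glmnet, alpha =
0) at a fixed small penalty (`lambda = 0.01` by default): the problem is
convex, so training is deterministic given the data; the seed only
controls the 80/20 train/held-out split. We deliberately avoid
architectures that need tuned stochastic optimisation: the classifier
contract is scalar class probabilities, and a regularised linear model
delivers that reproducibly at desk scale.

Probabilities binarise at 0.5 with an inclusive threshold (`p >= 0.5` is
a positive call), and per-label metrics follow the four standard
confusion-matrix formulas, with undefined ratios (zero denominators)
reported as absent rather than zero.

Annotation semantics: examples marked `ignore` are dropped; `reject`
means "this sentence is *not* the candidate label" and is folded into
OTHER. Merging the future and past annotation pools into one 3-class
problem gives a single coherent model with the same downstream contract
as separate binary detectors.

## Stage 2: the FTR-type lexicon classifier

`classify_ftr_type()` is deliberately *not* statistical: it is a
closed-vocabulary keyword classifier so that every labelling decision is
auditable. The shipped lexicon (`default_lexicon()`, version 1.0) extends
the canonical exemplars of each category conservatively (e.g. *perhaps,
maybe, likely, I guess* in other-low-certainty; *surely, for sure,
undoubtedly* in other-high-certainty) and is fully overridable from a
JSON config (`read_lexicon()`). Three design rules matter:

* **Dominance.** Modal categories dominate tense categories: *It will
  possibly rain tomorrow* is other-low-certainty only, because *will
  possibly* and bare *will* express different semantics.
* **Concord.** A modal verb and a modal modifier of the same strength may
  co-occur (*It could probably rain tomorrow*); both low-certainty flags
  are set. This is the only intended multi-flag combination within the
  low-certainty subdivision, but since each category is a dichotomous
  flag, sentences mixing distinct modal bases (e.g. *I wish it would
  rain*) legitimately set each matched flag (here bouletic and irrealis).
* **Exclusions.** Negation reverses modal polarity (*Rain tomorrow is not
  possible* reads as high certainty despite the low-certainty keyword
  *possible*), and "mixed-modal" sentences combine high- and
  low-certainty keywords (*There is definitely a possibility of rain
  tomorrow*); in both cases a keyword method cannot know the intended
  polarity, so such sentences are excluded wholesale — scope is not
  resolved. Negation detection is token-based after contraction expansion
  (*won't* → *will not*), not parser-based; sentence-level presence is
  sufficient for the wholesale-exclusion policy.

`verbal_high_certainty` exists as a category slot with an empty default
vocabulary: a verbal high-certainty trigger set is not well defined for
English (the high-certainty domain is typically adverbial/adjectival), so
the flag never fires unless a user configures it. We prefer an explicit
empty category over invented semantics.

Tokenisation is whitespace/punctuation splitting with a
contraction-expansion table, so keyword matching sees the underlying
modal or negator. The periphrastic future is matched as
*am/is/are/was/were + going to*, and *have to/need to* cover their
inflections. Known limitation: matching is surface-level, so e.g. the
month *May* triggers the modal *may*; this is inherent to
closed-vocabulary methods and is documented rather than patched with
heuristics.

`proportions_by_type()` reports per-category means of the flags
renormalised to sum to 1, i.e. the proportional breakdown of FTR types in
a corpus or condition.

## Temporal horizons

`extract_temporal_expressions()` is a from-scratch deterministic rule
tagger (keyword deictics, *in N units*, *N units ago*,
*next/last/this* + unit, weekday names, month-name/numeric/ISO dates)
rather than a wrapper around a Java tagging stack: the rule inventory is
small, documented, unit-tested per pattern, and needs no model downloads.
Conventions, each chosen once:

* Numeric dates are parsed **day-first** by default (10-06-2020 is 10
  June), with a `dayfirst = FALSE` switch.
* Day-deltas are computed on **calendar dates** (posting time truncated),
  so *tomorrow* is always exactly +1 day and time-of-day noise never
  enters H(s).
* *this Friday* resolves to the nearest forward occurrence (0–6 days
  ahead), *next Friday* to 1–7 days ahead, *last Friday* to the nearest
  backward occurrence.
* *next year* resolves to the same month/day one year on (a
  representative date), and similarly for months.
* Sub-day expressions (*tonight*, *in two hours*) resolve to the anchor
  date itself (delta 0) and are flagged `sub_day`.

The horizon statistic is H(s) = Σ_r D(r)/n, the mean signed day-delta;
`t_ref` codes future (0) vs past (1). `filter_horizons()` drops sentences
with no expressions and the *same-day past* false positives: a sub-day
future expression resolved to midnight of the posting day looks like a
negative delta of up to a day (posting *I'm seeing her tonight* at 16:00
yields a raw delta of −16 h). The record keeps both the calendar
`H_days` and the fractional `raw_delta_days` so this case is detected
without reintroducing time-of-day noise elsewhere. Analysis uses
log|H|; a retained record with |H| = 0 cannot be log-transformed and is
an error by default (`on_zero = "drop"` removes the surviving sub-day
zeros with a message).

## Delay discounting

The choice battery fully crosses 10 smaller-sooner amounts (£50–£95 by
£5) with 11 delays against a fixed £100 larger-later reward: 110 items.
The delay labels map to days by the standard convention (later today = 0,
tomorrow = 1, one week = 7, one month = 30, two months = 61, three months
= 91, six months = 182, one year = 365, two years = 730, five years =
1825, ten years = 3650); the map is configurable since the labels, not
the day counts, are what participants see.

`estimate_k()` scores every indifference-point candidate
k = (LLR/SSR − 1)/D against the participant's empirical choices under a
single shared comparator: the delayed reward is predicted iff
A/(1 + kD) **strictly** exceeds the immediate amount; exact equality
predicts the immediate choice (a deterministic tie rule on a
measure-zero boundary). Zero-delay items yield no finite indifference
point and are excluded from the candidate grid, but are included in
match counting, where every candidate predicts the delayed (strictly
larger) reward. Ties on match count resolve to the geometric mean of the
*full* tied set. `stochasticity = 1 − match_prop` is the fraction of
choices disagreeing with the best candidate's predictions — a cheap
randomness check on responding.

## DASS-21, sliders, and mediation

`score_dass()` doubles each 7-item dimension sum (range 0–42), using the
standard item-to-dimension map; `mean_subjective_distance()` averages a
participant's 0–100 slider ratings across the 11 delays.

`fit_mediation()` estimates the two-equation system by least squares and
quantifies uncertainty with a nonparametric case-resampling bootstrap
(default 4000 draws, mirroring the scale of a typical 4-chain × 1000
kept-iteration posterior). With flat-prior Bayesian estimation the
posterior at n ≈ 200 is likelihood-dominated, so the bootstrap and an
MCMC backend agree at this scale while keeping the package free of a
sampler toolchain. Both equations are refitted on the *same* resampled
rows, so the decomposition identity total = αβ + τ′ holds exactly within
every draw and the summary of the total is the summary of sums, never
the sum of summaries. One-tailed probabilities (`pp`) are the fraction of
draws whose sign matches the predicted direction — a per-effect input
(default positive), not hard-coded. Intervals are reported at 90% and
95% because directional decisions conventionally use the 90% band while
two-tailed ones use 95%. R² per equation per draw is explained variance
over explained-plus-residual, with draw-wise *empirical* residual
variance (the alternative, model-based residual variance, differs only
by a degrees-of-freedom correction at this n). Predictors enter raw by
default; `standardize = TRUE` gives standardised effects.

A genuinely degenerate case is worth naming: with a literally noiseless
mediator equation, M is an exact linear combination of the predictors and
the outcome equation is rank deficient — β and τ′ are not separately
identified. `fit_mediation()` raises an explicit error rather than
silently dropping a column.

## The synthetic-data generators

Every generator is a pure function of its arguments and seed.

* `generate_labeled_sentences()` renders template sentences with sampled
  slot fillers (subjects, verbs, places — all absent from the lexicon) for
  each tense/modal category, the concord case, both exclusion cases, plus
  PTR and OTHER sentences. Because the templates are built from the
  shipped lexicon, perfect agreement between `classify_ftr_type()` and
  the planted flags is the classifier's closure test, and the distractor
  fillers keep the trainable stage from simply memorising category
  keywords.
* `generate_timed_posts()` plants temporal expressions at known day
  offsets with midnight UTC anchors, so the horizon pipeline must recover
  the planted mean exactly (date arithmetic, no float error).
* `simulate_choices()` applies the shared comparator under a true k and
  flips each choice independently with probability ε.
* `simulate_study2()` draws latent bivariate-normal symptom scores
  (defaults: anxiety mean 4.4, SD 7.07; depression mean 6.86, SD 9.66;
  latent correlation ρ = 0.6 — a realistic comorbidity level),
  discretises them to even scores clamped to the 0–42 DASS range, and
  generates M and Y from the planted two-equation structure with Gaussian
  noise. Discretisation to a bounded score necessarily *attenuates* the
  realised correlation (≈ 0.565 at the defaults); ρ is the latent
  correlation, and tests check the attenuated value. Default planted
  paths (α1 = 0.9, β = 0.045, τ′1 = 0.04, α2 = 0.15, τ′2 = −0.01, sd_m =
  14, sd_y = 2.1) produce an anxiety-driven mediation with indirect ≈
  0.04 and total ≈ 0.08 on the raw DASS scale, equation R²s around
  0.12–0.15, and a negligible depression effect.

What the generators do *not* emulate: real social-media text (lexical
diversity, sarcasm, typos, code-switching), annotation noise, missing
questionnaire responses, or participant heterogeneity in choice noise. A
classifier that is perfect on templates will not be perfect on Reddit;
the closure tests establish that the *pipeline machinery* is correct, not
that the shipped lexicon is complete for naturalistic English.

## Problem sizes and numerical choices

The test suite and the acceptance script run the estimator-closure check
on 200 simulated choosers, the flip-noise check at ε = 0.1 on 200
choosers, and mediation calibration on 150–200 replicates of n = 202
participants at 250 bootstrap draws — sizes chosen so the full suite
completes in about a minute while binomial noise on coverage stays near
±1.5 percentage points. Coverage assertions accept ≥ 0.89 for a nominal
0.95 interval, i.e. roughly four binomial standard errors of slack plus
the usual mild undercoverage of percentile bootstrap intervals.
Degenerate bootstrap resamples (rank-deficient by chance) are discarded
with a message rather than imputed. The glmnet penalty (0.01) is small
enough not to bias the softmax probabilities visibly at template scale
while keeping the optimisation well-conditioned on sparse
document-term matrices.

## Known limitations

* The lexicon is a documented superset of canonical exemplars, not a
  recovered copy of any particular research lexicon; category membership
  (e.g. whether *should* is low-certainty or deontic) follows the
  standard listing and is overridable.
* The temporal tagger handles dates, not durations or recurrences
  (*every Monday*), and resolves season/decade-scale expressions only via
  the representative-date convention for years and months.
* The time-reference model is a linear n-gram classifier: adequate for
  the package's contract (probabilities + reproducibility) and for
  template-scale corpora, but weaker than neural ensembles on
  naturalistic text.
* Negation triggers exclusion regardless of scope; sentences like *It is
  not that I doubt it* are lost along with true polarity reversals.
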