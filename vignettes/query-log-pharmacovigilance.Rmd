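---
title: "Detecting adverse-reaction signals in search query logs"
author: "querysignal"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Spontaneous-report pharmacovigilance works only for substances the
reporting systems track. For substances used outside medical supervision,
query logs are one of the few population-scale observational sources:
someone experiencing a reaction will often describe the symptom to a search
engine, in lay language, from the same account that earlier queried for the
substance itself. `querysignal` turns that intuition into a concrete
estimator in four stages: match, anchor, count, compare.

**Match.** A lexicon maps query phrases to concepts — one target-substance
concept with its synonyms and slang, and one concept per symptom with
layperson synonyms. Matching is whole-token phrase containment after
lowercasing and punctuation stripping. Token matching (rather than
substring) is a deliberate choice: slang target terms are short, and a
substring matcher would drown in false positives ("pot" inside "potato").
Multi-word synonyms must appear as contiguous token runs. The cost is
missing inflections ("marijuanas" does not match "marijuana"); with no
stemmer in scope we prefer the conservative error.

**Anchor.** Day 0 is the date of a user's first target-concept query, at
date (not time) granularity, matching the day-indexed temporal analysis.
Non-exposed users still need an anchor so the before/after table has a
comparison column; each receives a pseudo-day-0 sampled with replacement
from the exposed users' empirical day-0 distribution. Calendar matching is
our design choice where no anchoring rule is forced by the problem: it
controls for secular and seasonal query-volume trends, and it is isolated
behind `assign_reference_day0()` so an alternative (e.g. uniform dates)
can be swapped in one place.

**Count.** Both contingency tables count *people*, not queries. In the
before/after table a user with ADR queries on both sides of day 0
contributes to both rows — the rows are two conditions on the same
population, not a partition. An ADR query on day 0 itself counts as
post-exposure: immediate reactions are queried on the day of the first
substance query, and classifying them as "before" would erase exactly the
signal of interest. Undefined scores (zero denominators) are reported as
`NA` with a reason, never clamped to 0 or 1: downstream ranking must be
able to distinguish "no signal" from "no data", and AUC/correlation
routines exclude (and count) them rather than impute.

**Compare.** QLRS is the Pearson chi-squared statistic without continuity
correction — the intended regime is populations of thousands, where the
correction is negligible; a zero margin yields 0 by convention (a
degenerate table carries no association evidence). QR and QPRR are ratio
measures on the two tables; PQR is the *before*-share proportionality
ratio, which by construction ranks genuinely reactive symptoms (whose
queries concentrate after day 0) *low* — in validation output it behaves
close to an inverted detector, which is worth knowing before averaging
measures.

## News filtering

Media events produce query texts with high total volume concentrated in a
few days. A text is excluded when its total count reaches 10,000 over the
log period and its count exceeds 1,000/day on between 1 and 10 days (all
four thresholds configurable via `news_filter_config()`). Two decisions
needed making. First, "same text" means equality after the same
normalization used for matching — otherwise a text could be filtered in one
form and matched in another. Second, the spike clause is counted in
calendar days (day boundaries at midnight); an episode-based reading
("spikes lasting 1–10 days") is grammatically possible but needs an episode
segmentation the day-count semantics avoids. The filter runs before every
downstream stage.

## Geographic prevalence

Features are, per geographic unit and term, the fraction of the unit's
distinct users with at least one matching query — user-level counting, so
one enthusiastic user cannot move a unit's feature. The regression is
forward–backward stepwise OLS on partial-F p-values with the conventional
thresholds `p_enter = 0.05`, `p_remove = 0.10`, deterministic tie-breaks by
term name, and a stop once the fit is numerically exact (on a noise-free
response the residual is machine epsilon and partial-F p-values are
meaningless). Units are unweighted observations — no population weighting
is applied by default since none is implied by the design. The model keeps
an intercept, and predictions are reported both raw and clipped to [0, 1];
cross-resolution transfer (fit coarse, predict fine, or vice versa) is a
plain application of the linear model to another feature table containing
the selected terms.

## Temporal profiles and onset

For exposed users only — the lag axis exists only for them — the profile at
lag t is the share of that day's ADR queries matching the concept, with
queries (not users) as the counting unit, following the "fraction of
queries" definition. Normalizing within ADR queries (rather than all
queries) makes profiles comparable across concepts and removes overall
activity drift; a switch (`exposed_only = FALSE`) includes pseudo-anchored
users in the denominator. Smoothing is a centered 7-day moving average,
truncated at the series edges, with undefined lags excluded from numerator
and divisor alike. "Top activity" days are the lags at or above the m-th
largest smoothed value, m = ceiling(quantile × defined lags), ties
included.

Onset estimation needed one genuine design iteration. A first detector —
baseline mean + 3 sd of the *smoothed* series — is mis-calibrated, because
the per-lag denominator varies by an order of magnitude across lags (few
users contribute at extreme lags), so the smoothed values are
heteroscedastic: the rule both missed true onsets and fired on noisy tails.
The shipped detector therefore works on the windowed counts underlying the
smoothing: a pooled baseline share p0 over lags ≤ −4, a one-sided Fisher
exact comparison of each centered 7-day window against the pooled baseline
counts (which also propagates the sampling noise of p0 itself), detection
at the first lag opening `min_run = 2` consecutive windows with tail
probability below `alpha = 1e-4`, and a leading-edge backtrack (at most
half a window, while the raw share exceeds twice baseline) to undo the
dilution bias a centered window imposes on a step onset. On the default
study conditions this recovers planted onsets of 0, 5 and 40 days within
±2 days in ≥ 9 of 10 replicates; individual replicates can still miss by a
few days when the planted elevation is noise-masked near its true start.

## What the generator emulates — and what it does not

`generate_query_log()` produces the data regime the analysis assumes: a
six-month window (2016-11-01 to 2017-04-30), users assigned to 20 counties
nested in 10 regions and 5 states, county exposure prevalence spanning
0.06–0.20 (the range of annual-use prevalence across US states), exposure
drawn per user at the county's prevalence, one guaranteed target query at a
uniform random day 0 plus repeat target queries (p = 0.02/day), background
queries at 0.05/user-day over a vocabulary disjoint from all lexicon
synonyms, and 20 symptom concepts at 0.001 queries/user-day, five of them
elevated ×5 in a post-exposure window (three immediate, one 5-day onset,
one 40-day onset — the qualitative temporal patterns such analyses aim to
recover). The background rate is deliberately the *health-relevant slice*
of a query stream, not total search volume. Reference report counts are
negative binomial (spontaneous-report counts are overdispersed) with mean
0.5 + 12500 × (multiplier − 1) × baseline rate, so planted reactions
dominate the reference set the way true reactions dominate real report
databases.

Two generator choices are load-bearing for testing. Exposed users always
issue the day-0 target query, so exposure-set recovery is an exact test of
the matcher, not a statistical one; and the background vocabulary is
disjoint from the lexicon by construction for the same reason. What the
generator does *not* emulate: realistic query language (queries are terms,
sometimes wrapped in short templates), user demographics, left-censoring
(first in-window query vs first-ever use), seasonality beyond injected
news spikes, and any correlation between symptoms. Passing recovery tests
therefore show the *estimators* are correct and well-calibrated under the
stated statistical structure — they do not show that real logs satisfy
that structure.

## Problem sizes and numerical choices

The recovery studies run at 10,000 users × 181 days × 20 concepts (about
140,000 records per replicate): 20 replicates for signal ranking (mean
QLRS AUC against the planted set ≥ 0.9; observed 1.0), 10 for onset
recovery, 20 prevalence scenarios of 100 units × 13 terms (3 informative,
noise sd = 10% of signal range). Oracle-equivalence checks run exact
comparisons on 200 random small logs (≤ 50 users), 1,000 random 2×2
tables against the chi-squared closed form (tolerance 1e−9), 100 random
AUC problems against pairwise counting (1e−12), and 50 greedy-outlier
problems against exhaustive stepwise search. Determinism is end-to-end:
one seed drives generation, pseudo-anchoring and reporting through derived
substreams, and a rerun reproduces output files byte for byte.

## Known limitations

Log-presence bias: users with no queries are invisible, so any denominator
built from "users in the log" over-represents active queriers (the
generator's ground truth therefore records the full simulated population).
The lexicon is static; street vocabulary drifts faster than any fixed
synonym list. The stepwise model inherits the instability of stepwise
selection at small n (fitting 13 candidate terms on 20 coarse units can
select noise terms; the cross-resolution experiment shows this as
occasional transfer correlations below the typical ~0.95). PQR is reported
for completeness but is anti-oriented for reactions whose queries follow
exposure. And all before/after inference assumes the pseudo-day-0 makes
the comparison population exchangeable with the exposed one up to calendar
time — unmeasured confounding between querying the substance and querying
symptoms is outside what this design can address.
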