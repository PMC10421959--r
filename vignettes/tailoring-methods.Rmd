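---
title: "Tailoring a PRO-CTCAE core survey: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tailoring a PRO-CTCAE core survey: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proctailor)
```

## The instrument and the data model

The adult PRO-CTCAE item library probes 78 symptomatic adverse events
through 80 *terms* (two term pairs share a display stem: the depression and
irregular-menstruation items) and 124 attribute questions. Each term asks
up to three of five *attributes*: presence (binary, 0–1), or severity,
interference, frequency and amount (5-level ordinal, 0–4). The shipped
80-term fixture (`proctcae_library()`) is a reconstruction of the public
instrument description; term ids are lowercase snake-case of the display
names, domains are opaque strings, and the code never interprets either
beyond identity and grouping.

Responses are long-format records `(patient, timepoint, term, attribute,
level)`. One completed survey at one timepoint is an *administration*; the
three study-like timepoints are baseline and the two mid-cycle visits, but
any number of timepoints ≥ 1 is accepted. All analyses run over the
*pooled* administrations: every score's unit is a survey administration
(or an item response within one), not a unique patient. The reporting for
the source cohort mixes "responses" and "patients" in prose; we follow the
operational definition — "number of responses" — throughout, which is also
the only one consistent with pooling repeated timepoints.

Attrition is handled by denominator bookkeeping, never imputation: a
patient who missed a timepoint simply contributes no administration there,
and an unanswered item within an administered survey is excluded from both
numerator and denominator of any score that uses it. The stricter
complete-case reading (keep only patients observed at every timepoint) is
available as `pool_timepoints(..., complete_case = TRUE)` but is not the
default, since it discards most of the information attrition leaves behind.

## Scores

For term $t$ over pooled administrations:

* **prevalence** $= \frac{\#\{\text{administrations with any attribute level} > 0\}}{\#\{\text{administrations in which the term was presented}\}}$.
  For presence-only terms the numerator is the "yes" count.
* **attribute proportion score** (severity, interference, frequency,
  amount) $= \frac{\#\{\text{responses at/above the cut}\}}{\#\{\text{responses above level } 0\}}$.
  All four cuts sit at level 2 of the 0–4 scale ("moderate", "somewhat",
  "occasionally", "somewhat"). The denominator is the *symptomatic* subset,
  so the score reads "among those who had the symptom, how often was it at
  least moderate".
* **high-end proportion**: same denominator, numerator cut at a
  caller-chosen level (e.g. ≥ "severe" = level 3), used to inspect the top
  of the distribution of eliminated-but-borderline terms.
* **physician impact proportion score** $= \frac{\#\{\text{ratings} \ge \text{moderate}\}}{\#\{\text{all ratings of the term}\}}$ —
  note the denominator is the whole panel, not a symptomatic subset; with
  a 9-member panel every defined score is a multiple of $1/9$.

Undefined scores (denominator 0) are explicit markers, never silently 0,
and attributes a term does not ask carry a distinct "not asked" marker.
Stored values are full precision; thresholds always compare full-precision
values, and only display formatting rounds, half-up, to one decimal percent
(so $1/9$ prints as 11.1 and $2/9$ as 22.2).

## The elimination pipeline

Steps run in a fixed order — prevalence (threshold 0.05), severity,
interference, frequency, amount (threshold 0.25 each), reliability,
physician impact (threshold 0.25) — with three structural rules:

* **strictness**: eliminate only when a score is defined and strictly
  below the threshold; a term exactly at the threshold is retained;
* **carry-forward**: a term lacking the step's attribute question (or
  holding an undefined 0/0 score on an asked attribute) is retained and
  flagged, so presence-only terms can only be eliminated by prevalence,
  reliability or the physician panel;
* **score-once**: all threshold scores are computed once from the pooled
  data; only the reliability step is evaluated on the then-current working
  set, because leave-one-out alpha depends on which terms remain.

A term with undefined *prevalence* was never presented and is eliminated
with reason `not_administered`; under the "any attribute" prevalence
definition, a term that passes prevalence necessarily has positive
denominators for its asked attributes, so undefined attribute scores only
arise for unasked attributes.

The ledger records, per step, the metric, threshold, eliminated terms with
their scores, carried-forward flags and the surviving count, and the
conservation identity
$|\text{library}| - \sum |\text{eliminated}| + |\text{reintroduced}| = |\text{final}|$
is checked before a report or survey object is produced.

### Reliability pruning

Domain reliability is Cronbach's alpha,
$\alpha = \frac{k}{k-1}\bigl(1 - \frac{\sum_i s_i^2}{s_{\text{total}}^2}\bigr)$,
with sample variances ($n-1$) over complete rows (listwise deletion within
the domain; pairwise covariance estimation was rejected for reproducibility
— alpha on complete item vectors is the textbook estimator and the listwise
set is unambiguous). The item entering alpha is a per-term *composite*
score, which the source procedure leaves unspecified; the default is the
maximum level across the term's answered attributes — consistent with the
"any attribute" prevalence logic and defined for every attribute
composition — with `severity`-only and `mean` composites available as
configuration.

For each term, $\alpha_2$ is alpha without that term,
$\Delta\alpha = \alpha_2 - \alpha_1$, and the percent change is
$100\,\Delta\alpha/\alpha_1$. One term with the *lowest* percent change is
removed per domain with more than 2 remaining terms. "Lowest" is read as
smallest **absolute** percent change by default — the stated rationale is
minimal effect on the domain's reliability, and a large positive change
(alpha improves a lot when the term is dropped) is not a minimal effect —
with the signed minimum available as the `reliability_policy = "signed"`
alternative. Ties break lexicographically by term id; a domain whose
$|\alpha_1| < 10^{-8}$ is skipped with a warning since the percent change
is undefined there.

## The synthetic generator

The generator emulates the design of the source cohort: three timepoints
with independent Bernoulli retention per timepoint (study-like defaults
$1$, $191/219$, $118/219$ over 219 patients, matching expected
administration counts 219/191/118), ordinal item responses, and
within-domain correlation.

Per administration, each domain draws a standard-normal factor $z$; term
$t$ with loading $\lambda_t \in [0,1)$ is symptomatic iff
$\lambda_t z + \sqrt{1-\lambda_t^2}\,\varepsilon < \Phi^{-1}(\pi_t)$, so
the marginal symptomatic probability is exactly the configured $\pi_t$
while loadings control co-occurrence. Given a symptomatic draw, attribute
levels 1–4 come from per-term conditional distributions; attributes of one
term are comonotone by default (one uniform mapped through each
attribute's quantile function — symptom facets of a single AE move
together), with an independent-coupling option. Level draws are
independent of the thresholding noise, so the composite score is
$X_t = s_t \cdot M_t$ with $s_t$ the indicator and $M_t$ the conditional
composite; `analytic_marginals()` returns the exact expected score table,
and `analytic_alpha()` the exact population alpha from bivariate-normal
orthant probabilities. Latent-threshold generation was chosen over direct
multinomial sampling precisely to make the reliability step meaningful
while keeping marginals exact by construction.

All randomness flows from a single integer seed via an isolated stream
(the caller's RNG state is untouched).

What the generator does **not** emulate: symptom onset/resolution dynamics
across timepoints (draws are independent across administrations),
informative dropout (retention is independent of symptom burden),
item-level missingness within an administered survey, and respondent-level
heterogeneity in the physician panel. Passing tests therefore demonstrate
correctness of the pipeline's arithmetic and bookkeeping under a
structurally faithful data model — not robustness to those real-data
features.

## Study replay fixtures

Because the source cohort's raw responses are not deposited, the package
ships two replay surfaces built from the printed results:

* `replay_study_tailoring()` drives the pipeline bookkeeping from a score
  table carrying the printed per-term values exactly (as numerator/1000;
  unlisted scores take clearly-passing fill-ins of 35% prevalence / 55%
  proportion), the printed seven reliability removals, and a deterministic
  9-member panel whose ratings reproduce the printed impact scores. The
  replay yields survivor counts 62, 50, 45, 45, 44, 37 and a final survey
  of 30 terms, 58 items, 11 domains.
* `study_like_fixture()` packages a generator configuration whose analytic
  marginals put every printed eliminated term on the correct side of its
  threshold with wide margins (prevalence 0.02 vs 0.35 around the 5%
  threshold; conditional mass 0.10 vs 0.55 around the 25% cuts), and
  per-domain loadings of 0.85 except the seven published reliability
  removals, whose loadings are calibrated by solving for a near-zero
  population leave-one-out percent change (`calibrate_weak_loading()`).
  At the default 1200 patients (~2900 pooled administrations) binomial
  noise is an order of magnitude inside every margin and the smallest
  reliability gap is several percent against sub-percent noise, so an
  end-to-end run reproduces the published ledger with failure probability
  well below 1%.

The margins, not the printed values themselves, drive the stochastic
fixture: several printed scores (e.g. severity 23.2% or 23.3% against a
25% threshold) sit within Monte-Carlo noise of their cut at any practical
cohort size, so a generator parameterized at the printed values could not
reproduce the printed decisions reliably — the deterministic replay
surface is where the printed values are honoured exactly.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `prevalence_threshold` | 0.05 | eliminate terms reported in < 5% of administrations |
| `proportion_score_threshold` | 0.25 | eliminate terms whose symptomatic share at/above the cut is < 25% |
| `impact_threshold` | 0.25 | eliminate terms < 25% of panel ratings at/above moderate |
| `reintroduction_terms` | none | terms restored (full attribute set) after the physician step; must have been eliminated earlier |
| `reliability_policy` | `absolute` | argmin of \|percent change\| (vs `signed`) |
| `composite` | `max` | per-term item score entering alpha (vs `severity`, `mean`) |
| `complete_case` | `FALSE` | administered-surveys denominators (vs complete-case pooling) |
| `n_patients` | 219 | generator cohort size |
| `retention` | 1, 191/219, 118/219 | per-timepoint completion probabilities |
| `loading` | 0.45 | domain-factor loading (0.85 in the study-like fixture) |
| `seed` | 1 | single RNG stream for all simulation |

## Problem sizes and numerical choices

The test suite runs the deterministic replay (instant), property tests on
random small matrices (alpha and leave-one-out against an independent
covariance-matrix oracle at $10^{-12}$), and simulation checks at roughly
1 000–1 500 patients (2 400–3 600 pooled administrations), where empirical
scores are required to sit within 3 Monte-Carlo standard errors of the
closed-form marginals and the end-to-end fixture must reproduce the full
published ledger; the whole suite completes in well under a minute. The
bivariate-normal CDF uses one-dimensional quadrature of the conditional
normal CDF (`integrate`, relative tolerance $10^{-10}$), and the loading
calibration a `uniroot` bracket with tolerance $10^{-4}$ — both far inside
the margins they serve.

## Known limitations

* The 80-term fixture is a reconstruction of the public item library; it
  satisfies every structural constraint the tailoring run implies
  (80 terms, 124 items, the per-step attribute compositions, the final
  30-term/58-item/11-domain survey) but is not the official instrument
  file, and the instrument version administered to the source cohort is
  not pinned.
* Per-term scores of the source cohort can only be reproduced where
  printed; the raw-data path is validated against the generator instead.
* The pipeline scores once from pooled data; if a deployment rescored
  survivors between steps the frequency/amount steps could in principle
  differ (it is moot for the published run, where both sub-threshold
  frequency terms were already gone).
* No composite grading of the tailored survey's responses is provided —
  translating responses into a tolerability grade is downstream work, as
  is any IRT/factor-analytic item reduction.
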