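# proctailor

Condensing the PRO-CTCAE symptomatic adverse-event library into a tailored
core survey for phase I oncology trials.

## The problem

Phase I oncology trials need patient-reported outcomes (PROs) to describe
*tolerability* — how acceptable a drug's adverse effects are from the
patient's perspective — but the NCI's PRO-CTCAE item library (124 survey
items covering 78 symptomatic adverse events in 80 terms) is too long for
routine use in this setting. `proctailor` implements a reproducible
item-reduction pipeline that condenses the full library into a core list,
and a synthetic response generator so the pipeline can be exercised and
validated without access to raw trial data.

Each PRO-CTCAE *term* (e.g. fatigue) belongs to an organ-system *domain*
and carries up to three *attribute* questions: presence (yes/no, scored
0–1) or severity / interference / frequency / amount (5-level ordinal,
scored 0–4).

## The method

Over the pooled survey administrations (one administration = one completed
survey at one timepoint; attrition is handled by counting only administered
surveys in denominators), terms pass through seven ordered steps:

1. **Prevalence filter (5%).** For term *t*,
   `prev(t) = #{administrations with any attribute level > 0} / #{administrations presented}`;
   terms with `prev(t) < 0.05` are eliminated.
2. – 5. **Attribute proportion-score filters (25%).** For each of severity,
   interference, frequency, amount:
   `score_a(t) = #{responses with level ≥ 2} / #{responses with level > 0}`,
   i.e. the share of *symptomatic* responses at or above
   moderate/somewhat/occasionally. Terms with a defined score `< 0.25` are
   eliminated; terms lacking the attribute question are retained and
   flagged *carried forward*. A term exactly at a threshold is retained.
6. **Reliability pruning.** Per domain, Cronbach's alpha
   `α = k/(k−1) · (1 − Σ var(itemᵢ) / var(row sums))` is computed on
   per-term composite scores (default: max level across a term's answered
   attributes), then recomputed leaving each term out (α₂). The term with
   the smallest |Δα/α₁| (Δα = α₂ − α₁) is removed from every domain with
   more than 2 remaining terms.
7. **Physician refinement (25%).** A panel rates each remaining term's
   impact on tolerability; `impact(t) = #{ratings ≥ moderate} / #{all ratings}`.
   Terms below 0.25 are eliminated, and a configured list of terms the
   panel flagged as essential is reintroduced.

Every step is recorded in an elimination ledger whose conservation identity
`|library| − eliminated + reintroduced = |final|` is enforced before any
report is rendered.

The synthetic generator draws symptomatic indicators from a Gaussian
latent-threshold model — term *t* is symptomatic when
`λ_t z_domain + √(1−λ_t²) ε < Φ⁻¹(π_t)` — so marginal prevalences equal the
configured `π_t` exactly while domain-factor loadings `λ_t` control the
within-domain co-occurrence that the reliability step measures. Population
alpha and leave-one-out percent changes are available in closed form
(`analytic_alpha()`, `analytic_loo_percent_change()`).

## Worked example

Replaying the published tailoring run from the printed per-term scores and
removal lists:

```r
library(proctailor)
r <- replay_study_tailoring()
print(r$ledger)
#> elimination ledger: 80 library terms, 7 steps, 30 surviving
#>   prevalence   - 18 -> 62
#>   severity     - 12 -> 50
#>   interference -  5 -> 45
#>   frequency    -  0 -> 45
#>   amount       -  1 -> 44
#>   reliability  -  7 -> 37
#>   physician    - 13 +6 -> 30
print(r$survey)
#> tailored survey: 30 terms, 11 domains, up to 58 items
```

Reading the ledger: the 5% prevalence filter removes 18 of the 80 terms
(62 survive), the severity/interference/frequency/amount filters remove
12, 5, 0 and 1 more, reliability pruning removes one term from each of the
7 eligible domains, and the physician step removes 13 and reintroduces 6 —
a final core survey of 30 terms from 11 organ-system domains, at most 58
items when conditional branching is off. The same ledger is reproduced
end-to-end from simulated raw responses by `study_like_fixture()` +
`tailor_survey()`.

Scoring primitives work standalone:

```r
lib <- proctcae_library()            # 80 terms, 124 items
summ <- cohort_summary(study_patient_table())
summ$orr_percent
#> [1] 9.6                            # (3 CR + 18 PR) / 219
```

## Analysis workflow

Numbered drivers under `analysis/` run the package over generated data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # study-scale cohort + physician panel
Rscript analysis/02_score.R      # score table + marginal-recovery check
Rscript analysis/03_tailor.R     # end-to-end pipeline on a large cohort
Rscript analysis/04_replay_study.R  # deterministic replay of the published run
```

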