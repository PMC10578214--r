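---
title: "Milestone-based composite progression endpoints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Milestone-based composite progression endpoints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmilestones)
```

## The problem

Quantifying Parkinson's disease (PD) progression with rating-scale change
scores is fragile: the MDS-UPDRS motor exam is highly sensitive to
symptomatic therapy, and single-scale outcomes miss the disorder's
heterogeneous motor and non-motor course. An alternative is a composite
time-to-event endpoint built from *progression milestones*: predefined,
clinically meaningful severity thresholds on individual assessment items,
chosen to mark unequivocal disability. `pdmilestones` implements such a
framework end to end: a declarative registry of 25 milestones across six
clinical domains (walking and balance; motor complications; cognition;
autonomic dysfunction; functional dependence; activities of daily living),
derivation of the time-to-first-milestone endpoint on a five-year
per-protocol visit grid, the associated survival modelling and
trial-design machinery, and a ground-truth cohort simulator so the whole
pipeline is testable without access-controlled patient data.

## The milestone engine

Each milestone is a small boolean tree over criterion atoms
(`item >= / == / < threshold`), built once by `build_registry()` and
exportable as auditable JSON. Three structural features matter:

* **Conservative missing-data rule.** An atom whose required score is
  absent evaluates to `FALSE`. Missing data can therefore never *create* a
  milestone, and removing any score from a visit can only remove hits
  (monotonicity — enforced as a property-style test).
* **ON-or-OFF motor items.** Motor-exam atoms are satisfied if *either*
  medication state's score meets the threshold, so a milestone remains
  evaluable when only one state was recorded.
* **Schedule classes.** Most milestones are assessed quarterly in year one
  and semiannually thereafter; the three SCOPA-AUT-based autonomic
  milestones only at six months and then annually; the three
  cognitive-battery/MoCA/investigator milestones only annually. With
  `restrict_to_schedule = TRUE` a milestone is only evaluated where its
  class says it was assessed. Baseline is always evaluated in full,
  because the baseline-exclusion rule considers every milestone.

Two definitions are genuinely underdetermined by the published criteria
table and are therefore explicit parameters:

* the cognitive-test "impairment" entering the dementia (composite)
  milestone defaults to *z ≤ −1.5 on at least one test within a domain, on
  at least two of the four assessed domains*, the conventional level-II
  cutoff for this battery (`build_registry(cognitive_cutoff = )`);
* orthostatic hypotension uses the sitting→standing positional drop
  (systolic ≥ 20 mm Hg *and* diastolic ≥ 10 mm Hg, plus SCOPA-AUT item 15
  ≥ 2), as printed, even though the baseline covariate uses
  supine→standing; both position pairs are representable.

Schwab & England scores are multiples of 5, so the `< 80` criterion is
equivalent to `≤ 75`; the engine evaluates the printed `< 80` form.
Milestones are evaluated per visit with no carry-forward.

The engine's correctness is established against an independently coded
brute-force evaluator (a literal scalar re-read of the criteria table kept
in the test helpers) on 10,000 random synthetic visits spanning full
instrument ranges and missingness.

## The composite endpoint

`derive_endpoint()` computes, per participant, time from enrollment to the
first scanned visit meeting any milestone. Two source modes mirror the two
analysis data sets: `"annual_visits"` scans months 12–60 only;
`"all_visits"` adds the seven interim visits (3, 6, 9, 18, 30, 42, 54),
schedule-restricted. Participants meeting any milestone at baseline, or
with no follow-up of the scanned kind, are excluded. Event times use the
right-endpoint convention (the visit at which criteria are first
recorded); event-free participants censor at their last completed annual
visit in *both* modes. A participant observed only at interim visits would
otherwise contribute no person-time, so they censor at the last interim
visit and carry a `deviation_interim_censor` flag — the source publication
is silent on this case, and the flag lets analysts drop or keep those
records explicitly. A visit counts as completed when at least one score
was recorded. Missing baseline visits are reported as an explicit
exclusion (`missing_baseline`), escalatable to a hard error.

Three invariants hold by construction and are asserted on every simulated
cohort: conservation (excluded + events + censored = enrolled), mode
dominance (an annual-mode event implies an all-visits event at a time no
later), and missingness monotonicity (deleting scores never creates or
hastens an event).

## Survival modelling

`km_curve()` is the product-limit estimator with optional per-protocol
rounding (times snapped to the nearest 3 months before estimation; deaths
precede censorings at ties). The Cox workflow follows the published
analysis plan:

* **Transforms** (`transform_covariates()`): reporting scales such as age
  per 5 years, MDS-UPDRS total per 5 units, SBR per 0.1 units; CSF
  biomarkers as mid-rank decile scores 1–10 (skewed distributions);
  "decrease"-direction covariates are negated so HR > 1 always reads
  "faster progression". The CSF hemoglobin sensitivity filter (> 200
  ng/mL) is available via `hb_filter = TRUE`.
* **Screening** (`screen_predictors()`): one Cox model per candidate at
  α = 0.10 with 90% CIs. Screening models are univariable — the published
  table reports one HR per predictor, consistent with per-candidate fits —
  and medication is screened in its own time-dependent model.
  Multicollinearity priority rules then exclude a passing candidate whose
  designated superseder also passed (MDS-UPDRS total over Hoehn & Yahr and
  PIGD; striatum over putamen SBR; t-tau/Aβ ratio over Aβ alone).
* **Selection** (`backward_select()`): from forced covariates (sex,
  medication) plus all screened candidates, repeatedly remove the
  non-forced covariate with the largest p > 0.05, ties broken by smaller
  |β| (the source is silent on the removal order), refitting each step;
  the full removal trace is returned. No multiplicity adjustment anywhere,
  by design.
* **Fitting** (`fit_cox_td()`): partial likelihood with Efron's tie
  approximation on counting-process data; the medication indicator is 0
  before initiation of symptomatic therapy and 1 after (episode split at
  the initiation month). Convergence is delegated to
  `survival::coxph` (Newton–Raphson, `iter.max = 100`); the returned fit
  object supports Schoenfeld-residual diagnostics via
  `survival::cox.zph`.

## Stability (reverter) analysis

Among participants whose first event occurred at an annual visit,
`classify_reverters()` scans any-milestone status at subsequent annual
visits: *persistent* (hit at the next annual visit), *temporary reverter*
(clean at the next, hit later; the reversion gap in years is reported),
*permanent reverter* (never hit again), with participants lacking any
subsequent annual visit set aside. The scan uses annual visits only,
matching how the stability analysis is framed; `domain_persistence()`
reports same-domain-next, any-domain-next and any-domain-ever proportions
per first-event domain. `pearson_chi2_2x2()` defaults to *no* continuity
correction — the uncorrected statistic is what reproduces the reference
comparison of permanent vs temporary reverters on short follow-up
(χ²(1) = 15.6); Yates' correction is available behind a flag.

## Trial design

The sample-size module targets a two-arm log-rank design. Required events
come from the Schoenfeld identity
`d = ceil((z[1-a/2] + z[1-b])^2 (1+r)^2 / (r (log Δ)^2))`. The control
arm's survival is
a piecewise-linear curve with knots on the 3-month grid (typically
`piecewise_from_km()` of a per-protocol Kaplan-Meier estimate), flat
beyond the last knot; the experimental arm is `S_c(t)^Δ` (proportional
hazards). `lakatos_sample_size()` evaluates a Markov recursion on monthly
intervals — at-risk proportions depleted by events, dropout, and
staggered-entry censoring — accumulating the expected log-rank numerator
and variance, and solves for the total N at the target power (rounded up
to an even total under 1:1 allocation). Halving the time step changes N by
under 1% (tested). Accrual is instantaneous and dropout zero by default —
the published design table states neither — and both are exposed in
`design_spec()`. The simpler `events / mean event probability` N is
reported alongside as a cross-check, and `simulate_power()` estimates
empirical power by inverting the piecewise curve, for self-consistency
checks (the calculator's N yields ≈81% empirical power for a 3-year
HR 0.5 design from the observed annual progression rates — Lakatos is
known to be slightly conservative for large effects).

## The synthetic cohort generator

`simulate_cohort()` is *truth-first*: the milestone trajectory is decided
before any item score exists, and scores are back-filled so the engine
reproduces the intended states exactly (`engine_roundtrip_check()` asserts
bitwise agreement). The stated world:

| quantity | default | rationale |
|---|---|---|
| age | N(61.5, 9), ≥ 30 years | cohort mean; eligibility floor |
| sex | 65% male | typical de novo PD cohort |
| MDS-UPDRS total | N(32, 13), ≥ 3 | early-disease totals |
| GDS-15 | NegBin(μ = 2.3, size = 2) | overdispersed low counts |
| striatum SBR | N(1.40, 0.40), ≥ 0.3 | deficit-range binding |
| CSF α-syn | logN(log 1500, 0.45) pg/mL-scale | right-skewed |
| true HRs | 1.25/5 y, 1.18/5 u, 1.07/pt, 1.07/0.1 SBR ↓, 1.09/decile ↓ | the reference multivariable estimates |
| sex, medication HR | 1.0 | non-significant in the reference model |
| baseline hazard | 0.01/month, constant | ≈45% reach a milestone by year 5 |
| dropout | 4%/year (≈18% by year 5) | observed retention |
| baseline-positive | 7.6% | observed exclusions |
| never return | 1.5% | observed |
| persistence | 0.55 per subsequent assessable visit | observed next-visit persistence |
| baseline flag missingness | 74.9% | late introduction of the investigator assessment |

Latent event times are exponential given the linear predictor (covariates
centred at their configured means; CSF enters as within-cohort decile),
then snapped to the next visit at which the assigned milestone — drawn
from domain/milestone mixture weights shaped like the observed first-event
distribution — is assessable. Item back-filling sets only the assigned
milestone's items above threshold; all other scores are drawn strictly
below every threshold, and the milestones' item sets are pairwise
disjoint, so no accidental hits occur. Missingness deletes only
non-milestone rows, which under the conservative rule cannot change the
truth. A medication hazard ratio other than 1 switches the event hazard at
the (independently drawn) initiation time.

What the generator does *not* emulate: correlations among baseline
covariates, item-level measurement noise dynamics (scores jump from
"normal" to "severe"), visit-date jitter (`actual_month` equals the
scheduled month), within-participant correlation of missingness, and
multi-milestone first events. A green test therefore establishes the
*pipeline's logic and statistical calibration*, not distributional realism
of any real cohort.

`simulate_endpoints()` is an endpoint-level fast path with the identical
covariate/latent-time model, used for replicate-heavy calibration studies
(type-I error of screening; parameter recovery: over 500 cohorts of 400,
the workflow recovers every true log-HR with |bias| ≤ 2.5% and 93–96%
CI coverage). Since the engine round-trip invariant pins the item-level
path to the same truth, the fast path is statistically equivalent for
those purposes.

## Numerical choices and degenerate inputs

* Cox convergence: `survival::coxph` defaults with `iter.max = 100`;
  non-convergence raises an error.
* Mid-rank deciles: `floor(10(r − 0.5)/n) + 1`, clipped to 1–10; ties get
  the average rank.
* Per-protocol rounding: `3·round(t/3)` (banker's rounding at exact
  halves, immaterial on grid times).
* Constant or all-missing covariates are dropped from screening with a
  warning; zero-margin 2×2 tables, curves with no events over the study
  window, HR = 1 designs, and empty included sets raise errors rather
  than returning NaN.
* Piecewise inversion uses the earliest time on flat segments (probability
  zero under continuous draws).

## Known limitations

Interval-censored estimators and recurrent-event models are out of scope
(the right-endpoint convention is used throughout, as in the reference
analysis). The engine does not re-score instruments from sub-items.
Reproducing the access-controlled cohort's numeric tables is explicitly
not a goal; the package's claims are carried by its property-based and
self-consistency tests.
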