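---
title: "A needs-based workforce model for nurse-led hypertension care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A needs-based workforce model for nurse-led hypertension care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htnworkforce)
```

## The model

`htnworkforce` estimates how many full-time equivalents (FTEs) of each
health-worker cadre a hypertension program needs, month by month, when
management is task-shifted from physicians to nurses and clinical officers.
Three equations define the model:

* **Need**: expected clinical encounters per month for provider $j$,
  $v_j = \sum_i f_{ij} \, n_{ij}$, where $n_{ij}$ counts patients in group
  $i$ and $f_{ij}$ is the monthly encounter frequency that group needs with
  provider $j$.
* **Capacity**: encounters one FTE can deliver per month,
  $E_j = t_j / m_j$, from monthly patient-contact minutes $t_j$ and minutes
  per encounter $m_j$.
* **Requirement**: $F_j = v_j / E_j$.

The substance of the model is in how $v_j(t)$ evolves. Patients are managed
under *clinician-frequency combinations* — a lead provider paired with a
visit interval $q$: nurse-led every 1, 2 or 6 months (`Nq1`, `Nq2`, `Nq6`),
clinical-officer-led every 1 or 2 months (`Cq1`, `Cq2`), physician-led
monthly (`Pq1`). On every trip the patient sees each provider on the
combo's schedule (lead clinician, pharmacist for the refill, triage for
intake). Every $R = 6$ months the patient is re-assessed and improves,
stays, or worsens, moving along the transition rules. The deterministic
engine propagates *expected* occupancy mass (continuous, not integer
patients) through these rules; a stochastic microsimulation over the same
protocol realizes integer patients and serves as the engine's validation
oracle.

## The clinical protocol as data

The protocol layer is configuration, not code: provider types with an
escalation hierarchy (nurse < clinical officer < physician), combos, trip
schedules, and one transition rule per combo. The full patient-category
layer of the underlying clinical algorithm (26 states pairing a
blood-pressure band with a management plan) maps many-to-one onto the
combos; the package treats it as optional metadata because the demand
arithmetic only needs combos. An illustrative subset ships with the default
protocol (`combo_for_category(default_protocol(), 7)` returns `"Nq1"`).

Outcome probabilities default to equal thirds wherever improvement,
no-change and worsening all exist. Two boundary states have only two
outcomes: the least intensive combo (`Nq6`) cannot improve further and the
most intensive (`Pq1`) cannot worsen further, so the unavailable outcome's
third is reassigned to "unchanged" (giving 2/3), preserving the probability
simplex without inventing states.

The default destinations encode a clinical reading of escalation:

| from | improve | worsen |
|------|---------|--------|
| Nq1  | Nq2     | Cq1    |
| Nq2  | Nq6     | Cq1    |
| Nq6  | —       | Nq1    |
| Cq1  | Cq2     | Pq1    |
| Cq2  | Nq1     | Cq1    |
| Pq1  | Cq1     | —      |

Improvement relaxes care one step (longer interval, then a lower-rank lead
at the interval extreme). Worsening under intensive nurse care (`Nq1`,
`Nq2`) is a referral to the clinical officer; a stable 6-monthly patient
who worsens resumes monthly nurse visits rather than skipping cadres; and
clinical-officer patients escalate toward the physician. The composition of
the six default combos and these destinations are the model's declared
defaults: the interval range (1–6 months) and the provider hierarchy are
fixed by the care model, but the exact destination set is configurable per
program, and the packaged defaults were fixed so that the shipped scenarios
reproduce the published planning figures for the reference nurse-led
hypertension program (see the acceptance script). The one destination the
care model pins directly — worsening under monthly nurse care refers to the
clinical officer — is not subject to that calibration.

## Demand projection

A unit cohort enrolled in month $s$ is projected as follows: occupancy
starts at the initial distribution $\pi$ (default 60% `Nq1`, 32% `Nq2`, 8%
`Nq6`, reflecting the measured shares of patients needing 1-, 2- and
6-monthly follow-up), mixes through the transition matrix at months
$s + kR$, and is discounted by geometric survival $(1-\rho)^{t-s}$ under
monthly attrition $\rho$ (default 0: the shipped scenarios assume no loss
to follow-up). Aggregate demand is the enrollment-weighted superposition of
unit cohorts — the engine is exactly linear in the enrollment stream.

Trips can be counted two ways:

* **phase** (default): a combo with interval $q$ generates a trip at
  block-relative months $0, q, 2q, \dots$ within each $R$-month block. The
  first trip falls in the enrollment month (enrollment is a visit) and the
  re-assessment itself is a visit, so each block starts with a trip.
* **smoothed**: each member generates $1/q$ expected trips every month.

The two modes give identical totals over every complete re-assessment block
of every cohort; they differ within partially elapsed blocks (phase
front-loads the trip at the block start). Consequently calendar-year totals
coincide exactly when enrollment is block-aligned, and differ by a few
percent for cohorts enrolled mid-year. Phase mode is the default because
enrollment and re-assessment visits are real encounters that a planner must
staff in the month they occur.

Two enrollment scenarios are built in: *steady state* (constant monthly
rate) and *ramp-up* (cumulative year-end targets, spread uniformly within
each year so the cumulative count hits each target exactly at months 12,
24, 36).

## Capacity and FTE defaults

The nurse parameters are measured values for the reference setting: 2
clinic days per month × 6 h per day = 720 contact minutes, and 8.9 minutes
per encounter (observed range 3.5–20.2), giving $E =$
`r round(720 / 8.9, 2)` encounters per month per FTE. "FTE" therefore means
one provider's hypertension-clinic allocation, not a 40-hour week; to
interpret it as a full-time post, override `contact_minutes_per_month`.
Non-nurse encounter times (clinical officer 15, physician 20, pharmacist 3,
triage 3 minutes) are package assumptions flagged as such in the shipped
configurations and should be replaced with program measurements.

Yearly figures default to the **year average** (mean of the 12 monthly
FTEs, identically equal to total yearly encounters over $12 E_j$), which
is the aggregation under which the model's yearly outputs track the
published planning figures; `year_end` (the December value) is available
and reports the staffing level needed at the year's close rather than on
average. Continuous FTEs are the primary output; a `fte_ceiling` column
gives the whole-staff cover alongside, never instead.

## The microsimulation oracle

`simulate_patients()` draws individual patients: a categorical combo
assignment at enrollment, trips on the phase schedule, geometric survival
(a patient who leaves generates no further encounters, with no re-entry —
loss to follow-up and death are one pooled process), and a categorical
outcome at each re-assessment. A master seed expands to per-replicate
substreams, so raising the replicate count never alters earlier replicates.
`check_agreement()` compares every provider-month cell of the deterministic
grid against the replicate mean at a 4-standard-error tolerance; cells with
zero replicate spread (counts that are deterministic under the protocol)
must match to 1e-9. The test suite runs this comparison on both packaged
scenarios with 200 replicates over 36 months (3600 and 7000 patients
respectively), plus exact-equality checks in the degenerate cases
(probability-1 transitions; $\rho \in \{0, 1\}$) where no randomness
remains.

Because the microsimulation needs whole patients, fractional streams (e.g.
1000/12 per month) are integerized by largest-remainder rounding on the
cumulative curve: cumulative counts never drift more than half a patient
and whole-number year-end targets are preserved exactly. The oracle
comparison runs the deterministic engine on the same integerized stream.

What the generator emulates — protocol-driven visit schedules, 6-month
outcome mixing, geometric attrition, Poisson-like enrollment-cohort
variability — bounds what agreement demonstrates: it validates the
expected-value bookkeeping, not the realism of the protocol parameters.
Real programs have seasonality, missed and rescheduled appointments,
within-month congestion, covariate-dependent transitions and re-entry after
loss to follow-up, none of which either engine models.

## Numerical choices

* Transition probabilities must sum to 1 within 1e-9; the unchanged
  destination must equal the source.
* Attrition multiplies survival *before* encounter counting; $\rho = 1$
  leaves exactly the enrollment-month trip.
* Visit intervals are validated against $R$ (an interval longer than the
  re-assessment cadence would silently never recur within a block).
* `fte_ceiling` uses `ceiling(fte - 1e-9)` so values that are whole up to
  float error do not round up.
* Sensitivity sweeps run a full factorial grid (guarded at 10 000 runs) and
  probe every dotted parameter path before the first run, so typos fail
  fast.

## Limitations

* The six-combo composition, non-nurse encounter times and the yearly
  aggregation rule are declared defaults, not measured facts; conclusions
  about cadres other than nurses inherit the capacity assumptions.
* The deterministic engine reports expected demand; it says nothing about
  queueing, peak loads within a month, or the variance a small clinic
  experiences (the microsimulation's replicate spread gives a first
  impression of the latter).
* No costing, leave/absence modeling, or multi-facility pooling.
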