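---
title: "Methods: a decision-analytic model of population AF screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-analytic model of population AF screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afscreen)
```

## The question the model answers

Atrial fibrillation (AF) raises stroke risk about five-fold and is often
asymptomatic, so many patients are first diagnosed when they present with a
stroke. In settings with limited routine ECG surveillance, a one-time
population screening session with a single-lead ECG device can surface
these undiagnosed cases and start them on oral anticoagulation. `afscreen`
evaluates whether doing so in the Nigerian population aged 55 and over is
good value for money: it compares a **screening** strategy (newly detected
AF patients start a NOAC or dose-adjusted warfarin immediately) against
**no screening** (AF goes undetected and anticoagulation starts only after
a first stroke), and reports lifetime discounted costs, QALYs, the
incremental cost-effectiveness ratio (ICER) and net monetary benefit (NMB)
at a willingness-to-pay (WTP) threshold of \$2,000/QALY, roughly Nigeria's
2018 GDP per capita.

The pipeline has three stages:

1. **Screening decision tree** (`run_cascade()`): from the 9,053,294
   people aged 55+, through 50% attendance, 1% AF prevalence and a 70%
   previously-undiagnosed fraction, to the cohort of newly detected AF
   patients (31,687 in the base case) and the one-time screening cost.
2. **Markov cohort model** (`run_cohort()`): both arms of that cohort are
   propagated in 6-month cycles from age 55 until extinction over eight
   health states, with age-specific background mortality.
3. **Economic aggregation** (`run_cea()`): per-cycle utilities and costs
   are summed with 4% annual discounting, scaled to the cohort, and turned
   into increments, ICERs and NMB.

Uncertainty is handled by a probabilistic sensitivity analysis
(`run_psa()`), one-way/scenario analyses (`scenario_table()`) and a NOAC
price-threshold search (`noac_price_threshold()`).

## State space and transitions

The Markov model uses eight states: stable **AF**, an
**acute stroke** tunnel occupied for exactly one cycle, chronic **post
stroke**, an **acute major bleed** tunnel, and four absorbing death states
(acutely fatal stroke, post-stroke death, fatal bleeding, age-related
death). Per-cycle event probabilities in untreated AF are 0.0108 for
stroke (ischemic plus intracranial haemorrhage), 0.0023 for an immediately
fatal stroke, 0.0013 for major extracranial bleeding and 0.0001 for fatal
bleeding; stroke survivors face a 0.1751 per-cycle post-stroke death risk,
lifelong. Background (age-related) mortality is taken from the life table
at the cohort's current integer age and converted to the cycle length by
constant-hazard rescaling, `1 - (1 - q)^(1/2)`.

Competing risks within a cycle are applied jointly: the event
probabilities are laid out first and background mortality multiplies the
event-free residual. If sampled or user-supplied probabilities
over-subscribe a row the engine raises a model-consistency error naming
the state rather than silently renormalising. Every occupancy row
therefore sums to one to machine precision, which the test suite asserts,
and which an explicit transition-matrix route (`build_transition_matrix()`)
and an individual-level microsimulation (`microsimulate()`) independently
confirm.

Several conventions are deliberate choices where the published description
is silent, each switchable:

* **No half-cycle correction** by default
  (`options$half_cycle_correction`); state membership is counted at cycle
  start.
* **`p_stroke_acute_death` is an absolute per-cycle probability** of an
  immediately fatal stroke (implying roughly 21% acute case fatality),
  not a fatality fraction conditional on stroke; the conditional reading
  is available via `options$conditional_acute_death`.
* **Bleeds occupy a one-cycle tunnel** carrying the bleed utility
  (0.8140 = AF utility 0.8430 minus the six-month disutility 0.029,
  which fixes the subtractive reading) and the bleed cost, after which
  survivors return to AF. With `options$bleed_tunnel = FALSE` bleeds are
  instantaneous cost/disutility hits inside AF; the two conventions agree
  to within a fraction of a percent.
* The 67%/33% mild/severe stroke split is carried as metadata only: the
  published utility table prints a single acute-stroke and a single
  post-stroke utility, so severity does not branch.

## Treatment, persistence and the relative-risk table

In the screening arm every detected patient starts oral anticoagulation;
persistence is 70% during the first 6-month cycle and 60% from the second
cycle on, held constant lifelong. The cohort is blended: a fraction `f` of
AF-state occupants carries the treated probabilities and `1 - f` the
untreated ones. Both arms treat stroke survivors, with the persistence
clock restarted at stroke onset — the acute-stroke tunnel carries 0.70 and
the post-stroke state 0.60. In the no-screening arm AF-state occupants are
never treated (their AF is undiagnosed). Treated occupants accrue drug
costs each cycle (\$448 per 6 months for a NOAC; \$17 plus \$30 INR
monitoring for warfarin); the two drugs are otherwise identical in the
base case, so the treatment mix only reprices the same traces.

The published relative-risk table is the model's most awkward input: it
prints stroke 0.38, bleeding 0.74, mortality 2.40 under the header
"Relative Risk Reduction". Read literally, anticoagulation would reduce
bleeding by 26% and raise all-cause mortality 2.4-fold — the opposite of
the meta-analytic evidence the table cites (stroke RR ≈ 0.38, all-cause
mortality RR ≈ 0.74, major bleeding increased). The package implements
both readings behind `effect$mapping_mode`:

* `clinically_coherent` (default): stroke ×0.38 (applied to both the
  stroke probability and its acutely fatal component, keeping case
  fatality constant), bleeding ×2.40, and background mortality ×0.74 for
  the treated fraction;
* `literal_table`: the printed order (bleeding ×0.74, mortality ×2.40),
  under which screening is dominated — retained for transparency, not for
  use.

The mortality multiplier acts on background mortality only;
event-specific deaths keep their own probabilities, since the published
description models them separately.

### What this choice does to the headline numbers

This is the model's main known limitation. The published evaluation
reports a 10-year median survival without screening and 10.5 years with
it, and a gain of 0.41 QALYs per detected patient. Calibrating the life
table so the untreated arm's median survival is 10 years (see below)
forces mean background mortality of roughly 5–6% per year over the first
decade. Applying ×0.74 to that hazard for the ~60–70% treated fraction
yields a ~1.7-year median-survival gain and ~0.80 QALYs per patient —
about twice the published gain — which halves the ICERs (≈\$6,400 vs
\$12,587 per QALY for 100% NOAC). Neutralising the mortality benefit
instead undershoots the QALY gain, overshoots the ICERs by 20–60% and
flips the published conclusion that warfarin-based screening is
cost-effective at \$2,000/QALY. No reading of the printed table reproduces
the published numbers exactly; they are internally consistent only with an
effective mortality reduction about half as strong as 0.74 at 60%
persistence. The default keeps the clinically coherent mapping because it
preserves every published ordering and sign (warfarin cost-effective, NOAC
and the 50:50 mix not; ICER(warfarin) < ICER(mix) < ICER(NOAC);
undiscounted ICER below discounted; the PSA acceptability pattern), while
the incremental cost per patient (≈\$5,150 vs \$5,205) is essentially
unaffected because treatment costs dominate it.

## Background mortality: the synthetic life table

The national age-specific mortality table behind the published analysis is
not in the public record, so the default background-mortality input is a
**Gompertz–Makeham life table**, `q(x) = 1 - exp(-(c + a e^{bx}))`, with
senescence rate `b = 0.085` and Makeham constant `c = 0.005` fixed at
typical adult-mortality values and the baseline hazard `a` calibrated by
deterministic (log-scale) bisection so that the untreated no-screening
cohort — run through the full Markov model, events included — reaches 50%
cumulative mortality 10 years after entry at age 55, matching the
published median survival. The calibration is idempotent and reproducible;
`load_life_table()` accepts a real `age,q_annual` CSV whenever one is
available, and exact reproduction of the published ICERs would require the
original national table. The mortality-vs-age lookup uses `floor(age)`
with no interpolation, and mortality is not decremented for event-specific
deaths, following the published description.

## Costs, currencies and the screening session

Event costs (2018 US\$/int\$ per 6 months): acute stroke \$938, fatal
stroke \$1,126 (20% above non-fatal), post-stroke upkeep \$6 per cycle,
major bleeding \$195, fatal bleeding \$778 (4× non-fatal). Event costs are
booked at the cycle in which the event state is entered; post-stroke
upkeep per cycle of occupancy; drug and INR costs per cycle on the treated
occupancy. The screening session prices one device-year per clinic
(1,000 × \$275), a screening contact at one third of an int\$5.20
health-centre visit per attendee, and cardiologist confirmation of
detected cases (one full visit each). Device specificity is deliberately
not priced in the base case, following the published costing; false-
positive confirmations can be switched on. International-dollar components
pass through a single configurable conversion factor with default 1.0
(literal table values). Under these defaults the session costs ≈\$8.3M
(\$1.83 per screened person) against the published \$7.3M/\$1.60 — the
exact conversions live in the unpublished supplement, so the difference is
documented rather than tuned away.

## Discounting and outcome accounting

Both costs and effects are discounted at 4% per year,
`(1.04)^{-t}` with `t` in years from model entry; the first cycle is
undiscounted and the one-time screening cost enters at `t = 0`. QALYs
weight each state's occupancy by its annual utility (AF 0.8430, acute
stroke 0.3280, post stroke 0.5490, bleed 0.8140) times the half-year cycle
length. Per-patient results divide cohort totals by the detected count —
the convention the published per-patient figures follow. Rounding happens
only at presentation; the single computational rounding in the pipeline is
the final detected count (round-half-up, 31,686.5 → 31,687, matching the
published figure).

## Probabilistic sensitivity analysis

Each PSA iteration redraws, independently: the five event probabilities,
utilities (AF, acute stroke, post stroke and the bleed disutility, with
the bleed utility re-derived as `u_af - d_bleed`), the five event costs,
the three treatment-effect multipliers and both persistence fractions.
Distributions are method-of-moments betas whose ±20% range is read as a
95% interval (`sd = range / (2 × 1.96)`); probabilities and utilities live
on `[0, 1]`, costs and multipliers on `[0, 2 × mean]` so the symmetric
range fits a bounded support (a gamma alternative for costs is available
via `options$cost_distribution`). Treatment costs and total screening
costs are fixed, as stated in the published analysis, and the cascade
inputs are held fixed so the cohort and screening cost per patient are
constant across draws. Draws that over-subscribe a transition row are
excluded (not resampled) and counted. Because arm dynamics do not depend
on the drug mix, each draw propagates two traces and reprices them under
all three mixes, which keeps 10,000 iterations near a minute of CPU.

With the base-case inputs the acceptability results reproduce the
published pattern: ~99.7% of iterations cost-effective at \$2,000/QALY
with 100% warfarin, ~0% with 100% NOAC and the 50:50 mix. These are
computed by `run_psa()` in the test suite; the vignette states no number
the tests do not recompute.

## Scenario analyses and the price threshold

`table6_scenarios()` mirrors the published sensitivity analyses under 100%
NOAC use: stroke probability ×0.5/×1.5 (probability and fatal component
together), starting age 45–65 (same life table, cohort entering younger or
older), stroke utilities ×0.5/×1.5 (acute and post-stroke together, capped
at 1), stroke costs ×0.5/×1.5 (acute, post-event and fatal together), AF
prevalence 0.5–4% (the printed table range; the text's 1–7% is available
by overriding `values`), screening costs ×0.5/×1.5, a NOAC efficacy
advantage (stroke multiplier ×0.81, mortality ×0.90, bleeding ×1.25), and
pulse palpation. The pulse-palpation scenario keeps every new AF case in
the modelled cohort but scales both persistence fractions by the 0.92
sensitivity (the missed 8% never start therapy, entering at `t = 0`
untreated), prices a full health-centre visit per attendee, and adds
confirmation work-up for false positives at 0.82 specificity. How the
published analysis combined those components into its \$21.0M screening
cost is not decomposed in the text; the decomposition here is
parameterised and lands lower under literal int\$ values.

The NOAC price threshold sweeps 1%–150% of the \$448 list price, verifies
the incremental cost (hence ICER) is monotone non-decreasing in price,
then bisects to \$0.5 for the highest price that is cost-effective at the
WTP, or cost-saving. Traces are propagated once and repriced. Under the
default mapping the cost-effectiveness threshold lands near \$126 per six
months (published: \$72 — the difference follows directly from the doubled
QALY gain discussed above), and no in-range price is cost-saving because
even a free NOAC leaves the increment marginally positive under the
package's literal screening-cost defaults (published: ≤\$1, effectively
the same boundary statement).

## What the synthetic data does and does not show

The Gompertz–Makeham table emulates the *level* of background mortality
consistent with the published survival behaviour, not Nigerian mortality
statistics: its shape is parametric, it ignores cohort-vs-period effects,
HIV/violence-related age patterns, and sex. Tests passing against it show
the machinery is correct and the published orderings robust; they do not
certify the absolute ICERs for Nigeria. Likewise the PSA's independent
draws ignore correlations (e.g. between stroke probability and stroke
mortality) because none are published.

## Problem sizes and numerical settings

Deterministic runs propagate ~115 half-year cycles (age 55 to the 110-year
cap, plus drain-out cycles for the tunnels) in under a millisecond; the
cohort is declared extinct below a living mass of 1e-8. Calibration
bisects ~60 model runs to a 0.05-year tolerance. The test suite uses
10,000 PSA iterations and a 100,000-individual microsimulation (compared
to the cohort trace at 3 Monte-Carlo standard errors), all seeded. The
price search uses a 31-point monotonicity sweep plus ~10 bisection steps.
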