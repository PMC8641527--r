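# afscreen

Cost-effectiveness modelling of one-time population screening for
non-valvular atrial fibrillation (AF), set in Nigeria.

AF raises stroke risk about five-fold and is frequently asymptomatic, so
in settings without routine ECG surveillance many patients are diagnosed
only when they present with a stroke. `afscreen` asks whether a single
nationwide screening session with a single-lead ECG device, followed by
lifelong oral anticoagulation in the newly detected patients, is good
value for money. It is written for health economists and epidemiologists
who want a tested, configurable implementation of this evaluation rather
than a spreadsheet.

## Model

Three stages, each exposed as package functions:

1. **Screening decision tree** — from the 9,053,294 Nigerians aged 55+,
   through 50% attendance, 1% AF prevalence, a 70% previously-undiagnosed
   fraction and device sensitivity, to the cohort of newly detected AF
   patients and the one-time screening cost.
2. **Markov cohort model** — both strategies (screen-and-treat vs
   anticoagulation only after a first stroke) are followed in 6-month
   cycles lifelong over eight states: stable AF, one-cycle acute-stroke
   and acute-bleed tunnels, chronic post-stroke, and four absorbing death
   states. Background mortality is age-specific; anticoagulation
   multiplies stroke risk by 0.38, major bleeding by 2.40 and background
   mortality by 0.74 for the on-treatment fraction (70% in the first
   cycle, 60% thereafter).
3. **Economics** — per-cycle QALYs and costs, discounted at 4%/year, are
   aggregated into the incremental cost-effectiveness ratio
   ICER = ΔCost/ΔQALY and net monetary benefit
   NMB = WTP × ΔQALY − ΔCost at a willingness-to-pay threshold of
   $2,000/QALY.

Around the deterministic core: a probabilistic sensitivity analysis
(cost-effectiveness plane and acceptability curves), the standard one-way
and scenario analyses, a NOAC price-threshold search, and a
Gompertz–Makeham life-table generator calibrated so the untreated cohort
has the evaluation's 10-year median survival (the original national
mortality table is not publicly available). An individual-level
microsimulation cross-checks the cohort engine.

## Worked example

```r
library(afscreen)

p  <- af_parameters()            # published base case
cs <- run_cascade(p)             # decision tree
cs
#> AF screening cascade
#>   attended:                 4,526,647
#>   prevalent AF attending:      45,266
#>   known AF:                    13,580
#>   new AF (true):             31,686.5
#>   new AF detected:             31,687
#>   false positives:            183,737
#>   screening cost total:  $8,285,961 (devices $275,000, contacts $7,846,188, confirmations $164,772)
#>   cost per screened:     $1.83

lt  <- calibrated_life_table(p)  # synthetic mortality, 10-year median survival
res <- run_cea(p, lt, mix = 1)   # 100% NOAC vs no screening
summary(res)
#> AF screening cost-effectiveness analysis (100% NOAC)
#>   newly detected AF patients: 31,687
#>   median survival: 11.72 years (screening) vs 9.98 years (no screening)
#> Incremental cost-effectiveness (discounted)
#>   dQALY 25,435  dLY 28,949  dCost $163,320,885  (cohort N = 31,687)
#>   per patient: 0.803 QALY, $5154
#>   ICER: $6,421/QALY (undiscounted $4,996/QALY)
#>   NMB at WTP $2,000/QALY: $-3549 per patient (not cost-effective)
#>
#> Cohort totals (discounted):
#>   screening    QALYs    249,858  LYs    299,241  costs $   174,541,489  (treatment 93%)
#>   no_screening QALYs    224,422  LYs    270,292  costs $    11,220,604  (treatment 50%)
```

Reading this: one screening session detects 31,687 new AF patients for
$8.3M. Treating them all with a NOAC buys 0.80 QALYs per patient at
$5,154 per patient — an ICER of $6,421/QALY, far above the $2,000/QALY
threshold, driven almost entirely (93%) by drug cost. Switching the same
cohort to warfarin changes only the pricing:

```r
run_cea(p, lt, mix = 0)$ce
#> Incremental cost-effectiveness (discounted)
#>   dQALY 25,435  dLY 28,949  dCost $23,235,060  (cohort N = 31,687)
#>   per patient: 0.803 QALY, $733
#>   ICER: $913/QALY (undiscounted $658/QALY)
#>   NMB at WTP $2,000/QALY: $872 per patient (cost-effective)
```

so screening is cost-effective when stroke prevention uses warfarin, and
not when it uses a NOAC at its $448/6-month list price — the evaluation's
central finding. `run_psa(p, lt, n = 10000, seed = 1)` quantifies the
uncertainty (≈99.7% of draws cost-effective with warfarin, ≈0% with
NOAC), `scenario_table(p, lt)` reruns the one-way analyses, and
`noac_price_threshold(p, lt)` finds the NOAC price at which the
conclusion flips. The ICER magnitudes sit below the original evaluation's
(see the methods vignette for why the printed relative-risk table forces
an interpretation choice); every qualitative conclusion and ordering is
preserved.

A thin command-line wrapper over the same functions lives at
`inst/cli/afscreen.R`:

```sh
Rscript inst/cli/afscreen.R dump-defaults --out config.yaml
Rscript inst/cli/afscreen.R run --mix warfarin --out report.csv
Rscript inst/cli/afscreen.R psa --n 10000 --seed 1 --out points.csv --ceac ceac.csv
```

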