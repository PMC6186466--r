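---
title: "Methods: prevalence-based cost-of-illness estimation for stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prevalence-based cost-of-illness estimation for stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecoi)
```

## The estimation framework

strokecoi implements a prevalence-based cost-of-illness (COI) model: it
prices everything stroke cost a society in one calendar year, for all
cases treated that year, rather than the lifetime cost of incident cases.
Costs split into:

* **direct medical** — covered inpatient and outpatient treatment
  (insurer share plus the legal copay, read straight off claim lines),
  the non-covered out-of-pocket allotment, medication plus pharmacy
  dispensing, and assistive devices;
* **direct non-medical** — transportation for outpatient visits and paid
  caregivers during hospitalization;
* **indirect** — productivity lost to care episodes (morbidity) and to
  premature death (mortality), both valued with the human-capital
  approach: lost time is worth the earnings it would have produced.

Everything is computed per stroke subtype — cerebral infarction
(ICD-10-CM I63, "ischemic") and intracerebral hemorrhage (I61,
"hemorrhagic") — and the all-stroke column is always the elementwise sum
of the subtype columns, never an independent aggregation.

The data model is claim-line granularity: one row per outpatient visit or
inpatient admission episode. This matters because the standard cohort
table mixes units — gender, age and subtype count distinct patients,
while disposition and facility count visits (one patient can contribute
several). `summarize_cohort()` reproduces exactly that convention,
deduplicating on `patient_id` for the patient-level strata only.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `round_trip_fare` | 21,000 | KRW/visit | published average round-trip fare for an outpatient visit |
| `assistive_device_annual_base` | 241,512 (2010) | KRW/patient-year | published annual cost of keeping an assistive device, in 2010 prices |
| `caregiver_daily_rate_base` | none — required | KRW/day | the underlying 2010 ministry figure is not published; the shipped default fixture assumes 60,000 KRW/day, a typical 2010 Korean informal caregiving day rate. This is a synthetic stand-in and is the main reason absolute caregiver totals from the default fixture should not be over-read |
| `noncovered_ratio_*` | 0.17614 (fixture) | ratio | the survey behind the non-covered allotment is unpublished; the fixture ships the stroke-level ratio implied by inverting the published rows: 354,489 / (1,898,241 + 114,285) = 0.17614, applied to both dispositions |
| `outpatient_day_fraction` | 1/3 | work-day/visit | one outpatient visit is assumed to consume one-third of a work day, so three visits equal one day of hospitalization |
| `daily_wage_divisor` | 365 | days/year | calendar-day convention for converting annual income to daily earnings; set 250 for a working-day convention (the source convention is not stated) |
| `working_age_min`, `retirement_age` | 20, 70 | years | earnings are zero below 20 and at/after 70. The source phrase "between 1 and 19" is implemented as *all* ages below 20, since leaving age 0 with income would be absurd |
| `discount_rate` | 0 | /year | keeps the product and present-value mortality modes consistent by default |
| `krw_per_usd` | 1090.14 | KRW/USD | the rate implied by the published KRW/USD headline pair |

CPI adjustment uses the index-ratio convention
(`amount * cpi[to] / cpi[from]`) rather than chaining annual inflation
rates — equivalent for a consistent index and much easier to validate.
The shipped index is the Korean CPI with 2010 = 100.

Income and employment rates by age band in `default_parameters()` are
stylized 2015 Korean figures (peak annual income 40M KRW at 40–49,
employment 0.58–0.79 across working ages). They only shape synthetic
results; real analyses should supply official statistics via
`read_parameters()`.

## The mortality loss: two modes

The default `product` mode is the literal multiplication
`deaths x lost_years x annual_income x employment_rate` per age band,
with bands entirely outside the working ages contributing zero. It is
simple and matches the stated estimation formula, but it freezes income
at the band of death and does not truncate lost years at retirement.

`present_value` mode is the textbook human-capital alternative: from the
band's midpoint age at death (85 for the open 80+ band, otherwise lower
bound + 5 — bands are ten years wide and no finer resolution exists),
walk each lost year forward, credit it the income and employment of the
band that year falls in (zero outside the working window), and discount
at `discount_rate`. The final partial year is fraction-weighted, which
makes the two modes agree exactly at discount rate zero whenever the
lost years stay inside one earning band — a property the test suite
asserts. The modes deliberately differ for deaths below working age:
`product` assigns zero (the band earns nothing), while `present_value`
credits the adult years the person would have reached. Neither is
asserted to be the published study's exact procedure (its supplementary
calculation is unavailable); both are expressible, and `product` is the
default because it follows the stated formula.

## Rounding policy

Internal arithmetic is in unrounded KRW end to end; conversion to
million KRW, 2-decimal shares and 1-decimal per-case costs is half-up
rounding at render time only. The published tables themselves show the
signature of rounding *before* summing: e.g. 57,387 + 8,924 = 66,311 vs
a printed 66,312, and subtype cells that sum one below the all-stroke
cell. `check_reference_costs()` therefore compares a subtotal
reconstructed from k printed components with tolerance k/2 million KRW —
the exact propagation bound for independently rounded inputs — and two
subtotals that are exactly attainable (the all-stroke medical and
indirect totals) are checked exactly. Three published figures cannot be
reconciled with their own inputs and are recorded rather than
reproduced: the cohort table's gender percentages are transposed (the
counts support male 53.82%), the hemorrhagic per-case cost prints 18.5
where its own components give (3,485,390 − 2,521,126) / 52,701 = 18.3
million KRW, and the mortality-to-morbidity ratio described as 4.5 is
4.24 from the printed rows.

## What the synthetic generator does and does not emulate

`generate_cohort()` exists so every downstream stage is testable without
the restricted national claims database. With `default_reference_config()`
it reproduces, in expectation, the published *structure* of the 2015
cohort:

* category probabilities are the published shares exactly (ischemic
  0.8978, male 0.5382, age 70–79 0.3460, general hospital 0.3954, ...);
* the admission probability 129,513 / 515,848 and a pre-truncation
  outpatient Poisson rate of 0.26 reproduce the published visit-to-patient
  ratios (zero-truncation guarantees non-admitted patients at least one
  claim; admitted patients may have no outpatient visits);
* inpatient days per admission are zero-truncated negative binomial with
  mean 37 — the value implied by inverting the published caregiver row at
  the assumed 60,000 KRW/day 2010 rate — with dispersion 1.5 for the
  heavy right tail typical of stroke stays;
* claim costs are gamma (shape 2) with means from published totals over
  published counts: 14.66M KRW per admission, 242K per outpatient visit,
  632K medication per claim;
* deaths are drawn per (subtype, age band) from binomial rates per 1,000
  patients, independent of the claim stream, because mortality comes
  from a separate cause-of-death source. How that source's I60–I69
  deaths were apportioned to I61/I63 is not published, so the rates are
  explicit inputs; the defaults are stylized, age-increasing, with
  hemorrhagic case fatality well above ischemic. Lost years are remaining
  life expectancy at band midpoints from 2015 Korean life tables.

It does **not** emulate: subtype- or age-specific cost and length-of-stay
differences (all patients share the cost families, so synthetic
hemorrhagic direct costs are *not* proportionally higher as they are in
reality); correlation between visit counts, stay length and cost within
a patient; readmission clustering; year-boundary-spanning episodes
(never generated, so the open question of splitting them never arises);
or mixed-subtype patients. Consequently, passing tests on synthetic data
demonstrate the *arithmetic contracts* of the pipeline — conservation,
linearity in unit costs, oracle equivalence, boundary behavior,
calibration of category frequencies — not the epidemiological realism of
any particular synthetic total.

Reproducibility contract: one seed feeds one RNG stream, and the
sampling order (subtype, gender, age, admission flag, outpatient counts,
stay lengths, facilities, costs, deaths) is fixed; identical
configuration and seed give byte-identical CSV output.

## Numerical and design choices

* **Half-up rounding** everywhere a display value is produced
  (`round_half_up()`), because banker's rounding disagrees with the
  published per-case figures.
* **Degenerate inputs**: empty claim sets produce zero-valued components
  and a zero-count summary with omitted percentages; a zero grand total
  yields undefined (NA) shares; `per_case_cost()` refuses zero patients
  and a mortality loss exceeding the grand total.
* **Validation reports all violations**, not the first: a claims file
  with several bad rows names every row number, which is what you want
  when auditing an extract.
* **Patients with both subtypes** are representable (the subtype
  stratifier counts them once per subtype); the generator never creates
  them, and the published subtype counts sum exactly to N.
* **Non-covered ratios are parameters**, not estimates: estimating them
  from microdata is out of scope, and the fixture value is an inversion
  of the published rows, shipped so the forward computation reproduces
  the published non-covered total.
* The facility stratifier's published counts use a different visit
  denominator (a patient can appear once per facility type), so facility
  shares are only comparable within claim-line data, not against the
  published table's facility percentages.

## Problem sizes in the test suite

Tests run the generator at 200–10,000 patients: calibration checks use
n = 10,000 (3-standard-error bands on realized frequencies), the oracle
equivalence property runs 1,000 random five-band tables against
brute-force loop oracles, and the published-table reconstruction is
exact arithmetic on nine rows. The full suite completes in well under a
minute on a single core.

## Known limitations

Long-term-care insurance costs, intangible costs (recreation,
psychological pain), disability-adjusted life expectancy, secondary and
tertiary diagnoses, and incidence-based (lifetime) costing are all out
of scope, as they were for the framework this package implements. The
employment rates are population rates, not stroke-survivor rates, which
biases the morbidity loss upward; the lost-years multiplication ignores
disability-shortened life expectancy, which biases the mortality loss
relative to a disability-adjusted computation.
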