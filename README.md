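# strokecoi

Prevalence-based cost-of-illness (COI) estimation for stroke from
health-insurance claims data, packaged as a tested, reusable R pipeline.

COI studies monetize a disease's societal impact in one calendar year as
the sum of **direct costs** (resources consumed by care) and **indirect
costs** (productivity lost to illness and premature death). This package
implements the estimation framework used for the 2015 South Korean stroke
cohort — ischemic stroke (ICD-10-CM I63) and hemorrhagic stroke (I61)
claims from a single-payer national insurance system, combined with
cause-of-death statistics — for analysts who need to reproduce, audit, or
re-run that framework on their own claim extracts. Because the national
claims database is not public, the package ships a seeded synthetic claims
generator calibrated to the published cohort structure, so the entire
pipeline is testable end to end without any restricted data.

## The model

For each stroke subtype *s*, with claims aggregated over the reference
year:

**Direct medical costs** — covered inpatient and outpatient treatment
(insurer payment plus legal copay, summed from claim lines), the
non-covered out-of-pocket allotment (a survey-derived ratio applied to
covered totals per disposition), medication/pharmacy costs, and assistive
devices (a CPI-adjusted annual cost per patient times the patient count):

    C_noncovered = r_in * C_in + r_out * C_out
    C_assistive  = base_2010 * CPI_2015 / CPI_2010 * N_patients

**Direct non-medical costs** — transportation (outpatient visit-claims
times a 21,000 KRW average round-trip fare) and caregivers (a CPI-adjusted
daily rate times total inpatient days).

**Indirect costs** use the human-capital approach. Productivity lost to
care episodes, with one outpatient visit costing one-third of a work day
(so three visits equal one day's hospitalization):

    C_morbidity = sum_a ( D_a + (1/3) V_a ) * (I_a / 365) * E_a

and productivity lost to premature death:

    C_mortality = sum_a  N_a * L_a * I_a * E_a

where, per age band *a*: `D` = inpatient days, `V` = outpatient visits,
`N` = deaths, `L` = expected remaining life-years at death ("lost
years"), `I` = annual expected income and `E` = the employment rate.
Income is zero below age 20 and at/after age 70. A `present_value` mode
is also provided that walks the lost years forward from the band midpoint
with age-specific income and an optional discount rate.

The **cost per stroke case** excludes the premature-death loss:

    per_case = (C_total - C_mortality) / N_patients    [million KRW]

All internal arithmetic is in unrounded KRW; rounding (half-up) to
million KRW, two-decimal shares and one-decimal per-case costs happens
only at render time.

## Worked example

Simulate a 1,000-patient cohort with the published 2015 cohort structure,
then run the full estimation with the default parameter set:

```r
library(strokecoi)

cohort <- generate_cohort(default_reference_config(n_patients = 1000, seed = 7))
dir <- file.path(tempdir(), "coi"); dir.create(dir)
write_cohort(cohort, file.path(dir, "claims.csv"), file.path(dir, "deaths.csv"))
write_parameters(default_parameters(), file.path(dir, "params.yaml"))

res <- run_pipeline(file.path(dir, "claims.csv"), file.path(dir, "deaths.csv"),
                    file.path(dir, "params.yaml"), file.path(dir, "report"))
print(res$breakdown)
#> Cost breakdown (million KRW, shares % of column grand total)
#>              label ischemic hemorrhagic stroke
#>          inpatient     3200         329   3529
#>         outpatient      192          22    214
#>         noncovered      598          62    659
#>         medication      675          75    750
#>          assistive      239          26    265
#>     transportation       17           2     19
#>          caregiver      545          54    600
#>     mortality_loss     1038        2219   3258
#>     morbidity_loss      229          25    254
#>     direct_medical     4904         513   5417
#>  direct_nonmedical      563          56    619
#>       direct_total     5467         569   6036
#>     indirect_total     1267        2245   3512
#>        grand_total     6734        2814   9548
res$per_case
#>    ischemic hemorrhagic      stroke
#>         6.3         6.0         6.3
```

Reading the output: covered inpatient treatment dominates the direct side
(3.5 of 9.5 billion KRW here), and the premature-death loss dominates the
indirect side, concentrated in hemorrhagic stroke — whose higher case
fatality makes its mortality loss (2.2 billion KRW) dwarf its treatment
costs despite a tenth of the caseload. `report/` now holds
`table1_cohort.csv`, `table2_costs.csv`, `table3_per_case.csv`,
`report.md` and a machine-readable `results.json`. The per-case costs are
in million KRW per patient.

The published 2015 tables are packaged as fixtures
(`reference_cohort_2015()`, `reference_costs_2015()`), and

```r
check_reference_costs()
```

re-derives every subtotal, share, per-case cost and USD total from the
nine published component rows and compares them with the published
figures (tolerances reflect that the published cells were rounded to the
nearest million independently; one published cell, the hemorrhagic
per-case cost, is inconsistent with its own components and is flagged
rather than reproduced).

A thin command-line front end with `simulate`, `estimate` and `check`
subcommands is installed at
`system.file("scripts", "strokecoi-cli.R", package = "strokecoi")`.

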