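# Builders for small in-code fixtures.

make_claims <- function(n = 1, patient_id = sprintf("P%03d", seq_len(n)),
                        subtype = "ischemic", gender = "male",
                        age_band = "60-69", disposition = "outpatient",
                        facility = "general", inpatient_days = 0,
                        covered_cost = 100000, medication_cost = 10000,
                        year = 2015) {
  tibble::tibble(
    patient_id = patient_id, subtype = subtype, gender = gender,
    age_band = age_band, disposition = disposition, facility = facility,
    inpatient_days = inpatient_days, covered_cost = covered_cost,
    medication_cost = medication_cost, year = year
  )
}

# A 20-claim mixed cohort used by several descriptive/cost tests.
mixed_cohort_claims <- function() {
  dplyr::bind_rows(
    make_claims(6, patient_id = sprintf("A%02d", 1:6),
                subtype = "ischemic", gender = "male",
                age_band = "70-79", disposition = "outpatient",
                facility = "tertiary", covered_cost = 120000,
                medication_cost = 30000),
    make_claims(4, patient_id = sprintf("A%02d", 3:6),  # repeat visits
                subtype = "ischemic", gender = "male",
                age_band = "70-79", disposition = "outpatient",
                facility = "clinic", covered_cost = 80000,
                medication_cost = 15000),
    make_claims(5, patient_id = sprintf("B%02d", 1:5),
                subtype = "ischemic", gender = "female",
                age_band = "50-59", disposition = "inpatient",
                facility = "general", inpatient_days = c(3, 7, 14, 2, 30),
                covered_cost = 4e6, medication_cost = 2e5),
    make_claims(3, patient_id = sprintf("C%02d", 1:3),
                subtype = "hemorrhagic", gender = "female",
                age_band = "40-49", disposition = "inpatient",
                facility = "tertiary", inpatient_days = c(10, 21, 5),
                covered_cost = 9e6, medication_cost = 3e5),
    make_claims(2, patient_id = sprintf("C%02d", 4:5),
                subtype = "hemorrhagic", gender = "male",
                age_band = "80+", disposition = "outpatient",
                facility = "public_health", covered_cost = 50000,
                medication_cost = 5000)
  )
}

# Minimal valid parameter set with flat CPI, used when the test should not
# depend on inflation adjustment.
flat_params <- function(...) {
  economic_parameters(
    cpi_index = c("2010" = 100, "2015" = 100),
    annual_income = stats::setNames(
      c(0, 0, 20e6, 30e6, 35e6, 33e6, 25e6, 0, 0), coi_age_bands()),
    employment_rate = stats::setNames(
      c(0, 0, 0.6, 0.8, 0.8, 0.7, 0.5, 0.2, 0), coi_age_bands()),
    noncovered_ratio_inpatient = 0.2,
    noncovered_ratio_outpatient = 0.1,
    caregiver_daily_rate_base = 60000,
    caregiver_base_year = 2010,
    ...
  )
}
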