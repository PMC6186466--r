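#' Cost components
#'
#' A cost component is one labelled row of the cost breakdown, carried as a
#' tidy tibble `(label, subtype, amount_krw)` with one row per subtype
#' column. Amounts are always unrounded KRW internally; rounding to million
#' KRW happens only at render time.
#'
#' @param label One of the nine breakdown labels: `inpatient`, `outpatient`,
#'   `noncovered`, `medication`, `assistive`, `transportation`,
#'   `caregiver`, `mortality_loss`, `morbidity_loss`.
#' @param amounts Named numeric vector of nonnegative KRW amounts, one per
#'   subtype column.
#' @return A tibble with columns `label`, `subtype`, `amount_krw`.
#' @export
cost_component <- function(label, amounts) {
  if (!label %in% cost_component_labels()) {
    coi_error(paste0("unknown cost component label: ", label),
              "coi_domain_error")
  }
  if (any(amounts < 0)) {
    coi_error(paste0("cost component ", label, " has negative amount"),
              "coi_domain_error")
  }
  tibble(label = label, subtype = names(amounts),
         amount_krw = unname(amounts))
}

#' @rdname cost_component
#' @export
cost_component_labels <- function() {
  c("inpatient", "outpatient", "noncovered", "medication", "assistive",
    "transportation", "caregiver", "mortality_loss", "morbidity_loss")
}

# Sum a claim field by subtype, always reporting both canonical subtypes.
sum_by_subtype <- function(claims, value) {
  vapply(coi_subtypes(),
         function(s) sum(value[claims$subtype == s]), numeric(1))
}

#' Covered treatment costs
#'
#' Total covered cost (insurer-paid plus legal copay) summed over claim
#' lines, split by disposition and subtype — the inpatient and outpatient
#' treatment rows of the breakdown.
#'
#' @param claims A validated claim table.
#' @return A two-component tibble (`inpatient` and `outpatient` labels).
#' @export
covered_treatment_costs <- function(claims) {
  claims <- as_tibble(claims)
  comp <- function(disp, lab) {
    sel <- claims$disposition == disp
    cost_component(lab, sum_by_subtype(claims[sel, ],
                                       claims$covered_cost[sel]))
  }
  bind_rows(comp("inpatient", "inpatient"), comp("outpatient", "outpatient"))
}

#' Non-covered care costs
#'
#' The fully out-of-pocket allotment is not present in covered claim
#' amounts; it is estimated as a ratio applied to covered totals, per
#' disposition: `ratio_in * covered_inpatient + ratio_out *
#' covered_outpatient`, per subtype. The ratios come from external surveys
#' of actual treatment spending and are parameters.
#'
#' @param covered The output of [covered_treatment_costs()].
#' @param params A `coi_parameters` object.
#' @return A `noncovered` cost component.
#' @export
noncovered_costs <- function(covered, params) {
  if (params$noncovered_ratio_inpatient < 0 ||
      params$noncovered_ratio_outpatient < 0) {
    coi_error("non-covered ratios must be >= 0", "coi_parameter_error")
  }
  wide <- tidyr::pivot_wider(covered, names_from = "label",
                             values_from = "amount_krw")
  amt <- params$noncovered_ratio_inpatient * wide$inpatient +
    params$noncovered_ratio_outpatient * wide$outpatient
  cost_component("noncovered", stats::setNames(amt, wide$subtype))
}

#' Medication and pharmacy costs
#'
#' Sum of the medication amount (drug cost plus pharmacy dispensing cost,
#' one combined field) over claim lines, by subtype.
#'
#' @param claims A validated claim table.
#' @return A `medication` cost component.
#' @export
medication_costs <- function(claims) {
  claims <- as_tibble(claims)
  cost_component("medication",
                 sum_by_subtype(claims, claims$medication_cost))
}

#' CPI adjustment of a base-year amount
#'
#' Inflates (or deflates) an amount between years with the index-ratio
#' convention: `amount * cpi[to_year] / cpi[from_year]`.
#'
#' @param amount Amount in `from_year` prices (KRW).
#' @param from_year,to_year Calendar years; both must be present in the
#'   index.
#' @param cpi_index Named numeric vector, year -> index value.
#' @return The amount in `to_year` prices.
#' @export
cpi_adjust <- function(amount, from_year, to_year, cpi_index) {
  for (y in c(from_year, to_year)) {
    if (!as.character(y) %in% names(cpi_index)) {
      coi_error(paste0("CPI index has no entry for year ", y),
                "coi_parameter_error")
    }
  }
  amount * cpi_index[[as.character(to_year)]] /
    cpi_index[[as.character(from_year)]]
}

#' Assistive device costs
#'
#' The annual cost for a patient to keep an assistive device (a base-year
#' figure, default 241,512 KRW in 2010 prices) is CPI-adjusted to the
#' reference year and multiplied by the number of patients, per subtype.
#'
#' @param n_patients_by_subtype Named count vector (patients per subtype).
#' @param params A `coi_parameters` object.
#' @return An `assistive` cost component.
#' @export
assistive_device_cost <- function(n_patients_by_subtype, params) {
  annual <- cpi_adjust(params$assistive_device_annual_base,
                       params$assistive_base_year, params$reference_year,
                       params$cpi_index)
  cost_component("assistive", annual * n_patients_by_subtype)
}

#' Transportation costs
#'
#' Outpatient visit-claims multiplied by the average round-trip fare
#' (default 21,000 KRW per visit). Applied to outpatient visits only;
#' admission trips are not costed.
#'
#' @param n_outpatient_visits_by_subtype Named count vector of outpatient
#'   visit-claims per subtype.
#' @param params A `coi_parameters` object.
#' @return A `transportation` cost component.
#' @export
transportation_cost <- function(n_outpatient_visits_by_subtype, params) {
  cost_component("transportation",
                 params$round_trip_fare * n_outpatient_visits_by_subtype)
}

#' Caregiver costs
#'
#' The caregiver daily rate (a base-year figure, CPI-adjusted to the
#' reference year) multiplied by total inpatient days, per subtype.
#'
#' @param inpatient_days_by_subtype Named vector of total inpatient days
#'   per subtype.
#' @param params A `coi_parameters` object.
#' @return A `caregiver` cost component.
#' @export
caregiver_cost <- function(inpatient_days_by_subtype, params) {
  daily <- cpi_adjust(params$caregiver_daily_rate_base,
                      params$caregiver_base_year, params$reference_year,
                      params$cpi_index)
  cost_component("caregiver", daily * inpatient_days_by_subtype)
}

#' Claim-stream aggregates used by the cost components
#'
#' Convenience extractors: distinct patients, outpatient visit-claims and
#' inpatient days per subtype, and person-time (inpatient days and
#' outpatient visits) per subtype and age band for the morbidity loss.
#'
#' @param claims A validated claim table.
#' @return Named vectors by subtype, or a tibble for
#'   [care_time_by_age()].
#' @export
patients_by_subtype <- function(claims) {
  claims <- as_tibble(claims)
  dedup <- dplyr::distinct(claims, .data$patient_id, .data$subtype)
  vapply(coi_subtypes(),
         function(s) sum(dedup$subtype == s), numeric(1))
}

#' @rdname patients_by_subtype
#' @export
outpatient_visits_by_subtype <- function(claims) {
  claims <- as_tibble(claims)
  sel <- claims$disposition == "outpatient"
  sum_by_subtype(claims[sel, ], rep(1, sum(sel)))
}

#' @rdname patients_by_subtype
#' @export
inpatient_days_by_subtype <- function(claims) {
  claims <- as_tibble(claims)
  sum_by_subtype(claims, claims$inpatient_days)
}

#' @rdname patients_by_subtype
#' @export
care_time_by_age <- function(claims) {
  claims <- as_tibble(claims)
  tidyr::expand_grid(subtype = coi_subtypes(),
                     age_band = coi_age_bands()) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      inpatient_days = sum(claims$inpatient_days[
        claims$subtype == .data$subtype &
          claims$age_band == .data$age_band]),
      outpatient_visits = sum(claims$subtype == .data$subtype &
                                claims$age_band == .data$age_band &
                                claims$disposition == "outpatient")
    ) |>
    dplyr::ungroup()
}
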