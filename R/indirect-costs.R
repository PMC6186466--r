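#' Productivity loss from care episodes (morbidity)
#'
#' Human-capital valuation of work time lost to treatment: each inpatient
#' day costs one day of earnings and each outpatient visit costs
#' `outpatient_day_fraction` of a day (default 1/3, so three outpatient
#' visits equal one day's hospitalization). Daily earnings are
#' `annual_income / daily_wage_divisor` weighted by the employment rate of
#' the age band, and are zero for bands outside the working-age window
#' (below `working_age_min` or at/above `retirement_age`).
#'
#' @param care_time A tibble with columns `subtype`, `age_band`,
#'   `inpatient_days`, `outpatient_visits` (see [care_time_by_age()]).
#' @param params A `coi_parameters` object.
#' @return A `morbidity_loss` cost component.
#' @export
morbidity_loss <- function(care_time, params) {
  care_time <- as_tibble(care_time)
  check_bands_covered(care_time$age_band, params)
  lost_days <- care_time$inpatient_days +
    params$outpatient_day_fraction * care_time$outpatient_visits
  daily <- band_daily_earnings(care_time$age_band, params)
  care_time$loss <- lost_days * daily
  amt <- vapply(unique(care_time$subtype), function(s) {
    sum(care_time$loss[care_time$subtype == s])
  }, numeric(1))
  cost_component("morbidity_loss", amt)
}

# Earnings are attributed to a band only when it lies wholly inside
# [working_age_min, retirement_age); bands straddling a bound earn zero.
band_earns <- function(band, params) {
  b <- age_band_bounds(band)
  b$lower >= params$working_age_min & b$upper <= params$retirement_age
}

band_daily_earnings <- function(band, params) {
  ifelse(band_earns(band, params),
         params$annual_income[band] / params$daily_wage_divisor *
           params$employment_rate[band],
         0)
}

check_bands_covered <- function(bands, params) {
  missing <- setdiff(unique(bands),
                     intersect(names(params$annual_income),
                               names(params$employment_rate)))
  if (length(missing) > 0) {
    coi_error(paste0("income/employment map missing age band(s): ",
                     oxford(missing)),
              "coi_parameter_error")
  }
}

#' Productivity loss from premature death (mortality)
#'
#' Human-capital valuation of future earnings lost to stroke deaths, per
#' subtype. Two modes:
#'
#' * `"product"` (default): the direct multiplication
#'   `deaths x lost_years x annual_income x employment_rate` summed over
#'   age bands, with income zero for bands entirely below
#'   `working_age_min` or at/above `retirement_age`.
#' * `"present_value"`: walks the lost years forward from the band's
#'   midpoint age (85 for the open 80+ band), year by year, crediting each
#'   future year the income and employment rate of the band that year
#'   falls in (zero outside the working-age window), discounted at
#'   `discount_rate`. A fractional final year is weighted by its fraction,
#'   so at discount rate 0 with lost years that stay inside one earning
#'   band the two modes agree exactly.
#'
#' @param mortality A [mortality_table()].
#' @param params A `coi_parameters` object.
#' @param mode `"product"` or `"present_value"`.
#' @return A `mortality_loss` cost component.
#' @export
mortality_loss <- function(mortality, params,
                           mode = c("product", "present_value")) {
  mode <- match.arg(mode)
  mortality <- mortality_table(mortality)
  check_bands_covered(mortality$age_band, params)

  per_row <- if (mode == "product") {
    annual <- ifelse(band_earns(mortality$age_band, params),
                     params$annual_income[mortality$age_band] *
                       params$employment_rate[mortality$age_band],
                     0)
    mortality$deaths * mortality$lost_years * annual
  } else {
    vapply(seq_len(nrow(mortality)), function(i) {
      mortality$deaths[i] * present_value_earnings(
        age_band_midpoint(mortality$age_band[i]),
        mortality$lost_years[i], params
      )
    }, numeric(1))
  }

  amt <- vapply(unique(mortality$subtype), function(s) {
    sum(per_row[mortality$subtype == s])
  }, numeric(1))
  cost_component("mortality_loss", amt)
}

# Discounted earnings over `horizon` years starting at `age`, crediting
# each year the (income x employment) of the band it falls in; zero below
# working_age_min and at/after retirement_age. Partial final year is
# fraction-weighted so the zero-discount case integrates exactly
# `horizon` years.
present_value_earnings <- function(age, horizon, params) {
  if (horizon <= 0) return(0)
  total <- 0
  j <- 0
  while (j < horizon) {
    y <- age + j
    weight <- min(1, horizon - j)
    annual <- if (y < params$working_age_min || y >= params$retirement_age) {
      0
    } else {
      band <- age_to_band(y)
      params$annual_income[[band]] * params$employment_rate[[band]]
    }
    total <- total + weight * annual / (1 + params$discount_rate)^j
    j <- j + 1
  }
  total
}

#' Total indirect cost
#'
#' Elementwise sum of the morbidity (care-episode) and mortality
#' (premature-death) productivity losses per subtype.
#'
#' @param morbidity,mortality The two indirect cost components.
#' @return A tibble with `label = "indirect_total"` and one row per
#'   subtype.
#' @export
total_indirect <- function(morbidity, mortality) {
  both <- bind_rows(morbidity, mortality)
  if (!setequal(both$label, c("morbidity_loss", "mortality_loss"))) {
    coi_error("total_indirect needs morbidity_loss and mortality_loss",
              "coi_domain_error")
  }
  both |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(amount_krw = sum(.data$amount_krw),
                     .groups = "drop") |>
    dplyr::mutate(label = "indirect_total") |>
    dplyr::select("label", "subtype", "amount_krw")
}
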