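#' Summarize a stroke cohort
#'
#' Stratified counts with percentage shares, in the layout of the standard
#' cohort characteristics table: gender, age band and subtype are tallied
#' over distinct patients (a patient with claims of both subtypes counts
#' once in each subtype row), while disposition and facility are tallied
#' over claim lines, since one patient can contribute several visits. All
#' categories are reported, including empty ones; percents are rounded
#' half-up to 2 decimals and omitted (NA) when a stratifier total is zero.
#'
#' @param claims A validated claim table.
#' @return A `coi_cohort_summary`: list with `patients` and `visits`
#'   tibbles (`stratifier, category, n, pct`), `n_patients` and `n_claims`.
#' @export
summarize_cohort <- function(claims) {
  claims <- as_tibble(claims)
  validate_claims(claims)

  tally_level <- function(data, var, levels) {
    n <- vapply(levels, function(l) sum(data[[var]] == l), numeric(1))
    total <- sum(n)
    tibble(
      stratifier = var, category = levels, n = unname(n),
      pct = if (total > 0) round_half_up(100 * unname(n) / total, 2)
            else rep(NA_real_, length(levels))
    )
  }

  patient_strat <- function(var, levels) {
    dedup <- dplyr::distinct(claims, .data$patient_id, .data[[var]])
    tally_level(dedup, var, levels)
  }

  patients <- bind_rows(
    patient_strat("gender", coi_genders()),
    patient_strat("age_band", coi_age_bands()),
    patient_strat("subtype", coi_subtypes())
  )
  visits <- bind_rows(
    tally_level(claims, "disposition", coi_dispositions()),
    tally_level(claims, "facility", coi_facilities())
  )

  structure(list(
    patients = patients,
    visits = visits,
    n_patients = dplyr::n_distinct(claims$patient_id),
    n_claims = nrow(claims)
  ), class = "coi_cohort_summary")
}

#' @export
print.coi_cohort_summary <- function(x, ...) {
  cat("Stroke cohort summary: ", x$n_patients, " patients, ",
      x$n_claims, " claim lines\n", sep = "")
  cat("Patient-level strata:\n")
  print(as.data.frame(x$patients), row.names = FALSE)
  cat("Visit-level strata:\n")
  print(as.data.frame(x$visits), row.names = FALSE)
  invisible(x)
}

#' Ratio between two category counts
#'
#' Headline ratios such as outpatient-to-inpatient visits or
#' ischemic-to-hemorrhagic patients, rounded half-up.
#'
#' @param count_a,count_b Nonnegative counts; `count_b` must be positive.
#' @param decimals Decimal places (default 1, the usual display precision).
#' @return `count_a / count_b`, rounded.
#' @export
category_ratio <- function(count_a, count_b, decimals = 1) {
  if (count_b <= 0) {
    coi_error("category_ratio: denominator count must be > 0",
              "coi_domain_error")
  }
  round_half_up(count_a / count_b, decimals)
}
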