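#' Configure the synthetic claims generator
#'
#' Builds a validated simulation configuration. Category probabilities
#' (subtype, gender, age band, facility) default to the 2015 Korean stroke
#' cohort shares derived from [reference_cohort_2015()]; per-patient visit
#' counts, lengths of stay and claim costs are modelled with simple
#' parametric families (zero-truncated Poisson outpatient visits,
#' zero-truncated negative-binomial inpatient days, gamma claim costs)
#' because only cohort totals, not per-patient distributions, are
#' published. Deaths are generated independently of the claim stream, as
#' mortality comes from a separate cause-of-death source.
#'
#' @param n_patients Number of distinct patients to simulate.
#' @param p_ischemic Probability a patient's stroke is ischemic (I63)
#'   rather than hemorrhagic (I61).
#' @param p_male Probability a patient is male.
#' @param age_band_probs Probability vector over the nine age bands of
#'   [coi_age_bands()]; must sum to 1.
#' @param p_patient_hospitalized Probability a patient has an inpatient
#'   admission (one admission episode is generated when so).
#' @param mean_outpatient_visits Poisson rate for outpatient visit counts,
#'   before zero-truncation. Patients without an admission are guaranteed
#'   at least one outpatient visit (zero-truncated draw); admitted patients
#'   may have none.
#' @param mean_inpatient_days Negative-binomial mean for inpatient days per
#'   admission, before zero-truncation.
#' @param inpatient_days_dispersion Negative-binomial size parameter.
#' @param facility_probs Probability vector over [coi_facilities()].
#' @param cost_distributions Per-component gamma parameters: a list with
#'   elements `covered_inpatient`, `covered_outpatient`, `medication`,
#'   each `list(mean = , shape = )` in KRW per claim.
#' @param deaths_per_1000_patients Named list `ischemic`/`hemorrhagic`,
#'   each a vector of death rates per 1000 patients by age band.
#' @param lost_years Expected remaining life-years at death, by age band.
#' @param year Calendar year stamped on every claim.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return An object of class `coi_sim_config`.
#' @export
simulation_config <- function(n_patients,
                              p_ischemic = 0.8978,
                              p_male = 0.5382,
                              age_band_probs = NULL,
                              p_patient_hospitalized = 0.2511,
                              mean_outpatient_visits = 0.26,
                              mean_inpatient_days = 37,
                              inpatient_days_dispersion = 1.5,
                              facility_probs = NULL,
                              cost_distributions = NULL,
                              deaths_per_1000_patients = NULL,
                              lost_years = NULL,
                              year = 2015,
                              seed = 1L) {
  ref <- reference_cohort_2015()
  ref_probs <- function(strat, levels) {
    x <- ref[ref$stratifier == strat, ]
    p <- x$count[match(levels, x$category)]
    p / sum(p)
  }
  bands <- coi_age_bands()
  age_band_probs <- age_band_probs %||% ref_probs("age", bands)
  facility_probs <- facility_probs %||% ref_probs("facility", coi_facilities())
  cost_distributions <- cost_distributions %||% list(
    covered_inpatient = list(mean = 14656700, shape = 2),
    covered_outpatient = list(mean = 241900, shape = 2),
    medication = list(mean = 632500, shape = 2)
  )
  # Stylized age-increasing case-fatality, hemorrhagic well above ischemic.
  deaths_per_1000_patients <- deaths_per_1000_patients %||% list(
    ischemic = stats::setNames(c(1, 1, 1, 2, 3, 5, 10, 25, 70), bands),
    hemorrhagic = stats::setNames(c(20, 20, 25, 30, 40, 60, 90, 150, 250),
                                  bands)
  )
  # Remaining life expectancy at band midpoints (2015 Korean life tables,
  # rounded to 0.1 years).
  lost_years <- lost_years %||% stats::setNames(
    c(77.5, 67.6, 57.8, 48.1, 38.5, 29.3, 20.6, 12.9, 6.7), bands
  )

  config <- structure(list(
    n_patients = as.integer(n_patients),
    p_ischemic = p_ischemic,
    p_male = p_male,
    age_band_probs = stats::setNames(age_band_probs, bands),
    p_patient_hospitalized = p_patient_hospitalized,
    mean_outpatient_visits = mean_outpatient_visits,
    mean_inpatient_days = mean_inpatient_days,
    inpatient_days_dispersion = inpatient_days_dispersion,
    facility_probs = stats::setNames(facility_probs, coi_facilities()),
    cost_distributions = cost_distributions,
    deaths_per_1000_patients = deaths_per_1000_patients,
    lost_years = lost_years,
    year = as.integer(year),
    seed = as.integer(seed)
  ), class = "coi_sim_config")
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  bad <- character(0)
  if (config$n_patients < 1) bad <- c(bad, "n_patients must be >= 1")
  for (p in c("p_ischemic", "p_male", "p_patient_hospitalized")) {
    if (config[[p]] < 0 || config[[p]] > 1) {
      bad <- c(bad, paste0(p, " must lie in [0, 1]"))
    }
  }
  for (v in c("age_band_probs", "facility_probs")) {
    if (any(config[[v]] < 0) || abs(sum(config[[v]]) - 1) > 1e-9) {
      bad <- c(bad, paste0(v, " must be nonnegative and sum to 1"))
    }
  }
  for (m in c("mean_outpatient_visits", "mean_inpatient_days",
              "inpatient_days_dispersion")) {
    if (config[[m]] <= 0) bad <- c(bad, paste0(m, " must be > 0"))
  }
  for (d in names(config$cost_distributions)) {
    cd <- config$cost_distributions[[d]]
    if (cd$mean <= 0 || cd$shape <= 0) {
      bad <- c(bad, paste0("cost distribution ", d,
                           " needs positive mean and shape"))
    }
  }
  if (length(bad) > 0) {
    coi_error(paste0("invalid simulation config:\n",
                     paste(bad, collapse = "\n")),
              "coi_config_error")
  }
  invisible(config)
}

#' Default configuration matching the 2015 reference cohort
#'
#' Category probabilities are exactly the published 2015 cohort shares
#' (each count divided by its stratifier total): ischemic 0.8978, male
#' 0.5382, age 70-79 0.3460, general hospital 0.3954, and so on. The
#' hospitalization probability and visit rate reproduce the published
#' visit-to-patient ratios (129,513 admissions and 472,371 outpatient
#' visit-claims over 515,848 patients).
#'
#' @param n_patients Number of patients to simulate (the real cohort had
#'   515,848; simulations default to a much smaller cohort).
#' @param seed Integer seed.
#' @return A `coi_sim_config`.
#' @export
default_reference_config <- function(n_patients = 10000, seed = 1L) {
  ref <- reference_cohort_2015()
  cnt <- function(strat, cat) {
    ref$count[ref$stratifier == strat & ref$category == cat]
  }
  n_total <- sum(ref$count[ref$stratifier == "subtype"])
  n_visits <- sum(ref$count[ref$stratifier == "disposition"])
  p_hosp <- cnt("disposition", "inpatient") / n_total
  simulation_config(
    n_patients = n_patients,
    p_ischemic = cnt("subtype", "ischemic") / n_total,
    p_male = cnt("gender", "male") / n_total,
    p_patient_hospitalized = p_hosp,
    seed = seed
  )
}

# Inverse-CDF zero-truncated samplers; draws consume exactly n uniforms.
rztpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}
rztnbinom <- function(n, size, mu) {
  stats::qnbinom(stats::runif(n, stats::pnbinom(0, size, mu = mu), 1),
                 size, mu = mu)
}

#' Generate a synthetic stroke cohort
#'
#' Draws `n_patients` distinct patients with subtype, gender and age band
#' from the configured probabilities, gives each patient outpatient
#' visit-claims and (with probability `p_patient_hospitalized`) one
#' inpatient admission with a zero-truncated negative-binomial length of
#' stay, attaches gamma-distributed covered and medication costs and a
#' facility to every claim line, and draws deaths per (subtype, age band)
#' from binomial rates per 1000 patients. The single seed feeds one RNG
#' stream; the sampling order (subtype, gender, age, admission flag,
#' outpatient counts, lengths of stay, facilities, costs, deaths) is part
#' of the reproducibility contract.
#'
#' @param config A [simulation_config()].
#' @return A list with `claims` (validated claim tibble, one row per visit
#'   or admission) and `mortality` (a [mortality_table()]).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  bands <- coi_age_bands()

  patients <- tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    subtype = ifelse(stats::runif(n) < config$p_ischemic,
                     "ischemic", "hemorrhagic"),
    gender = ifelse(stats::runif(n) < config$p_male, "male", "female"),
    age_band = sample(bands, n, replace = TRUE,
                      prob = config$age_band_probs),
    hospitalized = stats::runif(n) < config$p_patient_hospitalized
  )

  # Outpatient visit counts: admitted patients may have none (plain
  # Poisson); others are zero-truncated so every patient has >= 1 claim.
  lam <- config$mean_outpatient_visits
  n_visits <- integer(n)
  n_visits[patients$hospitalized] <-
    stats::rpois(sum(patients$hospitalized), lam)
  n_visits[!patients$hospitalized] <-
    rztpois(sum(!patients$hospitalized), lam)

  los <- integer(n)
  los[patients$hospitalized] <- rztnbinom(
    sum(patients$hospitalized),
    size = config$inpatient_days_dispersion,
    mu = config$mean_inpatient_days
  )

  inpat <- patients[patients$hospitalized, ]
  inpat_claims <- tibble(
    patient_id = inpat$patient_id, subtype = inpat$subtype,
    gender = inpat$gender, age_band = inpat$age_band,
    disposition = "inpatient",
    inpatient_days = los[patients$hospitalized]
  )
  outpat <- patients[rep(seq_len(n), n_visits), ]
  outpat_claims <- tibble(
    patient_id = outpat$patient_id, subtype = outpat$subtype,
    gender = outpat$gender, age_band = outpat$age_band,
    disposition = "outpatient",
    inpatient_days = 0L
  )
  claims <- bind_rows(inpat_claims, outpat_claims)
  claims <- claims[order(claims$patient_id, claims$disposition), ]

  m <- nrow(claims)
  claims$facility <- sample(coi_facilities(), m, replace = TRUE,
                            prob = config$facility_probs)
  rg <- function(k, d) stats::rgamma(k, shape = d$shape,
                                     rate = d$shape / d$mean)
  cd <- config$cost_distributions
  claims$covered_cost <- numeric(m)
  is_in <- claims$disposition == "inpatient"
  claims$covered_cost[is_in] <- rg(sum(is_in), cd$covered_inpatient)
  claims$covered_cost[!is_in] <- rg(sum(!is_in), cd$covered_outpatient)
  claims$medication_cost <- rg(m, cd$medication)
  claims$year <- config$year
  claims <- claims[claim_columns]

  cells <- tidyr::expand_grid(subtype = coi_subtypes(), age_band = bands)
  cells$n_patients <- purrr::map2_int(cells$subtype, cells$age_band,
    ~ sum(patients$subtype == .x & patients$age_band == .y))
  cells$rate <- purrr::map2_dbl(cells$subtype, cells$age_band,
    ~ config$deaths_per_1000_patients[[.x]][[.y]])
  cells$deaths <- stats::rbinom(nrow(cells), cells$n_patients,
                                pmin(cells$rate / 1000, 1))
  mortality <- mortality_table(tibble(
    subtype = cells$subtype,
    age_band = cells$age_band,
    deaths = cells$deaths,
    lost_years = unname(config$lost_years[cells$age_band])
  ))

  validate_claims(claims)
  list(claims = claims, mortality = mortality)
}

#' Write a generated cohort to CSV files
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param claims_path,mortality_path Output CSV paths.
#' @return The claims path, invisibly.
#' @export
write_cohort <- function(cohort, claims_path, mortality_path) {
  write_claims(cohort$claims, claims_path)
  write_mortality(cohort$mortality, mortality_path)
  invisible(claims_path)
}
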