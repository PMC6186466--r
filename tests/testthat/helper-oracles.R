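# Brute-force oracles for the human-capital losses, written independently
# of the package implementation (explicit loops, band bounds re-derived
# from the band label).

# A band earns only when fully inside [working_age_min, retirement_age).
oracle_earns <- function(band, p) {
  lower <- if (band == "80+") 80 else
    as.numeric(strsplit(band, "-")[[1]][1])
  upper <- if (band == "80+") Inf else
    as.numeric(strsplit(band, "-")[[1]][2]) + 1
  lower >= p$working_age_min && upper <= p$retirement_age
}

# Double loop over (row, component) for the care-episode loss.
oracle_morbidity <- function(care_time, p) {
  out <- c(ischemic = 0, hemorrhagic = 0)
  for (i in seq_len(nrow(care_time))) {
    band <- care_time$age_band[i]
    daily <- if (oracle_earns(band, p)) {
      p$annual_income[[band]] / p$daily_wage_divisor *
        p$employment_rate[[band]]
    } else 0
    days <- care_time$inpatient_days[i] +
      p$outpatient_day_fraction * care_time$outpatient_visits[i]
    out[[care_time$subtype[i]]] <- out[[care_time$subtype[i]]] +
      days * daily
  }
  out
}

# Loop oracle for the product-mode premature-death loss.
oracle_mortality <- function(mort, p) {
  out <- c(ischemic = 0, hemorrhagic = 0)
  for (i in seq_len(nrow(mort))) {
    band <- mort$age_band[i]
    annual <- if (oracle_earns(band, p)) {
      p$annual_income[[band]] * p$employment_rate[[band]]
    } else 0
    out[[mort$subtype[i]]] <- out[[mort$subtype[i]]] +
      mort$deaths[i] * mort$lost_years[i] * annual
  }
  out
}
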