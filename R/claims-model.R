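#' Claims data model: enumerations
#'
#' Canonical category levels for stroke claim records. Age is carried as a
#' 10-year band; no exact ages are modelled. Facilities follow the Korean
#' provider tiers (tertiary hospital, general hospital, hospital, clinic,
#' public health center).
#'
#' @return A character vector of levels, in display order.
#' @export
coi_age_bands <- function() {
  c("0-9", "10-19", "20-29", "30-39", "40-49",
    "50-59", "60-69", "70-79", "80+")
}

#' @rdname coi_age_bands
#' @export
coi_subtypes <- function() c("ischemic", "hemorrhagic")

#' @rdname coi_age_bands
#' @export
coi_genders <- function() c("male", "female")

#' @rdname coi_age_bands
#' @export
coi_dispositions <- function() c("inpatient", "outpatient")

#' @rdname coi_age_bands
#' @export
coi_facilities <- function() {
  c("tertiary", "general", "hospital", "clinic", "public_health")
}

# Numeric [lower, upper) bounds of an age band; "80+" is [80, Inf).
age_band_bounds <- function(band) {
  b <- sub("\\+$", "-Inf", band)
  list(
    lower = as.numeric(sub("-.*", "", b)),
    upper = as.numeric(sub(".*-", "", b)) + 1  # Inf + 1 stays Inf
  )
}

# Midpoint age used as age-at-death within a band; open-ended 80+ uses 85.
age_band_midpoint <- function(band) {
  age_band_bounds(band)$lower + 5
}

# Band containing an exact age (ages >= 80 map to "80+").
age_to_band <- function(age) {
  ifelse(age >= 80, "80+",
         paste0(floor(age / 10) * 10, "-", floor(age / 10) * 10 + 9))
}

claim_columns <- c(
  "patient_id", "subtype", "gender", "age_band", "disposition",
  "facility", "inpatient_days", "covered_cost", "medication_cost", "year"
)

#' Validate a collection of claim records
#'
#' Checks every row of a claim table against the data-model invariants:
#' categorical fields drawn from the canonical enumerations
#' ([coi_subtypes()], [coi_genders()], [coi_age_bands()],
#' [coi_dispositions()], [coi_facilities()]); monetary amounts nonnegative;
#' outpatient claims have zero inpatient days and inpatient claims at least
#' one. All violating rows are reported, not only the first.
#'
#' @param claims A data frame with one row per claim line (one visit or one
#'   admission episode).
#' @return The claims as a tibble, invisibly, if valid. Otherwise an error of
#'   class `"coi_validation_error"` listing every offending row.
#' @export
validate_claims <- function(claims) {
  claims <- as_tibble(claims)
  missing <- setdiff(claim_columns, names(claims))
  if (length(missing) > 0) {
    coi_error(
      paste0("claims are missing required column(s): ", oxford(missing)),
      "coi_schema_error"
    )
  }
  if (nrow(claims) == 0) return(invisible(claims))

  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad)) {
      rows <- which(bad)
      problems <<- c(problems, paste0(
        "row ", oxford(as.character(rows)), ": ", what
      ))
    }
  }

  note(!claims$subtype %in% coi_subtypes(), "invalid subtype")
  note(!claims$gender %in% coi_genders(), "invalid gender")
  note(!claims$age_band %in% coi_age_bands(), "invalid age_band")
  note(!claims$disposition %in% coi_dispositions(), "invalid disposition")
  note(!claims$facility %in% coi_facilities(), "invalid facility")
  note(is.na(claims$inpatient_days) | claims$inpatient_days < 0 |
         claims$inpatient_days != floor(claims$inpatient_days),
       "inpatient_days must be a nonnegative integer")
  note(claims$disposition == "outpatient" & claims$inpatient_days != 0,
       "outpatient claim with nonzero inpatient_days")
  note(claims$disposition == "inpatient" & claims$inpatient_days < 1,
       "inpatient claim with inpatient_days < 1")
  note(is.na(claims$covered_cost) | claims$covered_cost < 0,
       "covered_cost must be >= 0")
  note(is.na(claims$medication_cost) | claims$medication_cost < 0,
       "medication_cost must be >= 0")

  if (length(problems) > 0) {
    coi_error(
      paste0("invalid claim record(s):\n", paste(problems, collapse = "\n")),
      "coi_validation_error"
    )
  }
  invisible(claims)
}

#' Read and write claim records as CSV
#'
#' Claims are exchanged as UTF-8 CSV with a header, `.` decimal separator,
#' and monetary amounts in KRW (not million KRW, to avoid rounding at
#' ingest). Columns: `patient_id, subtype, gender, age_band, disposition,
#' facility, inpatient_days, covered_cost, medication_cost, year`. Row order
#' is preserved and every row is validated on read.
#'
#' @param path Path to a CSV file.
#' @return `read_claims()` returns a validated tibble of claim records.
#' @export
read_claims <- function(path) {
  header <- names(readr::read_csv(
    path, n_max = 0,
    col_types = readr::cols(.default = readr::col_character())))
  missing <- setdiff(claim_columns, header)
  if (length(missing) > 0) {
    coi_error(
      paste0("claims file is missing column(s): ", oxford(missing)),
      "coi_schema_error"
    )
  }
  claims <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      subtype = readr::col_character(),
      gender = readr::col_character(),
      age_band = readr::col_character(),
      disposition = readr::col_character(),
      facility = readr::col_character(),
      inpatient_days = readr::col_double(),
      covered_cost = readr::col_double(),
      medication_cost = readr::col_double(),
      year = readr::col_integer()
    )
  )
  validate_claims(claims)
  claims[claim_columns]
}

#' @rdname read_claims
#' @param claims A validated claim table.
#' @export
write_claims <- function(claims, path) {
  validate_claims(claims)
  readr::write_csv(as_tibble(claims)[claim_columns], path)
  invisible(path)
}

#' Construct and validate a mortality table
#'
#' Deaths and expected remaining life-years at death (lost years), per
#' stroke subtype and 10-year age band. This is the input to the
#' premature-mortality arm of the human-capital computation; it comes from
#' cause-of-death statistics, a source separate from the claim stream.
#'
#' @param mortality A data frame with columns `subtype`, `age_band`,
#'   `deaths` (nonnegative integer) and `lost_years` (nonnegative real).
#' @return A validated tibble.
#' @export
mortality_table <- function(mortality) {
  mortality <- as_tibble(mortality)
  required <- c("subtype", "age_band", "deaths", "lost_years")
  missing <- setdiff(required, names(mortality))
  if (length(missing) > 0) {
    coi_error(
      paste0("mortality table is missing column(s): ", oxford(missing)),
      "coi_schema_error"
    )
  }
  bad <- !mortality$subtype %in% coi_subtypes() |
    !mortality$age_band %in% coi_age_bands() |
    mortality$deaths < 0 | mortality$deaths != floor(mortality$deaths) |
    mortality$lost_years < 0
  if (any(bad)) {
    coi_error(
      paste0("invalid mortality row(s): ", oxford(as.character(which(bad)))),
      "coi_validation_error"
    )
  }
  mortality[required]
}

#' @rdname mortality_table
#' @param path Path to a CSV file with columns
#'   `subtype, age_band, deaths, lost_years`.
#' @export
read_mortality <- function(path) {
  mortality_table(readr::read_csv(
    path,
    col_types = readr::cols(
      subtype = readr::col_character(),
      age_band = readr::col_character(),
      deaths = readr::col_double(),
      lost_years = readr::col_double()
    )
  ))
}

#' @rdname mortality_table
#' @export
write_mortality <- function(mortality, path) {
  readr::write_csv(mortality_table(mortality), path)
  invisible(path)
}
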