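#' Published 2015 Korean stroke reference tables
#'
#' The package ships the published summary tables of the 2015 nationwide
#' Korean stroke cost analysis as plain-text fixtures, since the underlying
#' claims database is not public. `reference_cohort_2015()` returns the
#' stratified cohort counts (N = 515,848 patients; disposition and facility
#' rows count visits, the footnoted duplication). `reference_costs_2015()`
#' returns the nine published cost-component rows in million KRW, per
#' subtype and for all stroke; note the all-stroke cells were rounded
#' independently of the subtype cells, so subtype cells can sum one below
#' the printed all-stroke cell.
#'
#' @return A tibble (`stratifier, category, count` for the cohort;
#'   `label, ischemic, hemorrhagic, stroke` in million KRW for the costs).
#' @export
reference_cohort_2015 <- function() {
  readr::read_csv(
    system.file("extdata", "cohort_2015_counts.csv", package = "strokecoi",
                mustWork = TRUE),
    col_types = "ccd"
  )
}

#' @rdname reference_cohort_2015
#' @export
reference_costs_2015 <- function() {
  readr::read_csv(
    system.file("extdata", "stroke_costs_2015_mkrw.csv",
                package = "strokecoi", mustWork = TRUE),
    col_types = "cddd"
  )
}

# Published subtotals and headline figures used by check_reference_costs().
reference_published_2015 <- function() {
  list(
    subtotals_mkrw = tibble(
      row = c("direct_medical", "direct_nonmedical", "direct_total",
              "indirect_total", "grand_total"),
      ischemic = c(2198827, 299961, 2498788, 1488646, 3987434),
      hemorrhagic = c(685058, 84644, 769702, 2715689, 3485391),
      stroke = c(2883887, 384606, 3268493, 4204334, 7472828)
    ),
    n_patients = c(ischemic = 463147, hemorrhagic = 52701, stroke = 515848),
    per_case_mkrw = c(ischemic = 6.7, hemorrhagic = 18.5, stroke = 7.9),
    usd_billion = c(ischemic = 3.658, hemorrhagic = 3.197, stroke = 6.855),
    shares_pct = c(
      mortality_loss = 45.53, treatment = 26.93,
      morbidity_loss = 10.73, medication = 5.09,
      direct_total = 43.73, indirect_total = 56.26
    )
  )
}
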