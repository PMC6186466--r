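#' Estimate the full cost of illness from claim and mortality files
#'
#' End-to-end orchestration: read and validate the claims, mortality table
#' and economic parameters; compute every direct component (covered
#' inpatient/outpatient treatment, non-covered care, medication,
#' CPI-adjusted assistive devices, transportation, caregiver) and both
#' indirect components (morbidity and premature-mortality productivity
#' loss); assemble the breakdown with subtotals and shares; compute
#' per-case costs; and write the report tables plus a machine-readable
#' `results.json` of every subtotal. Any stage failure aborts with a
#' stage-named error.
#'
#' @param claims_path CSV of claim records (see [read_claims()]).
#' @param mortality_path CSV mortality table (see [read_mortality()]).
#' @param params_path YAML/JSON economic parameters
#'   (see [read_parameters()]).
#' @param out_dir Output directory for tables, `report.md` and
#'   `results.json`.
#' @param mortality_mode `"product"` or `"present_value"`, passed to
#'   [mortality_loss()].
#' @param verbose Log row counts and parameter provenance to stderr.
#' @return Invisibly, a list with `summary`, `components`, `breakdown`,
#'   `per_case` (million KRW by column) and `results` (the JSON payload).
#' @export
run_pipeline <- function(claims_path, mortality_path, params_path, out_dir,
                         mortality_mode = "product", verbose = FALSE) {
  log_msg <- function(...) if (verbose) message("[strokecoi] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      coi_error(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                "coi_stage_error")
    })
  }

  claims <- stage("read_claims", read_claims(claims_path))
  mortality <- stage("read_mortality", read_mortality(mortality_path))
  params <- stage("read_parameters", read_parameters(params_path))
  log_msg(nrow(claims), " claim lines from ", claims_path)
  log_msg(nrow(mortality), " mortality cells from ", mortality_path)
  log_msg("parameters from ", params_path,
          " (reference year ", params$reference_year, ")")

  summary <- stage("cohort_descriptives", summarize_cohort(claims))

  components <- stage("direct_costs", {
    covered <- covered_treatment_costs(claims)
    bind_rows(
      covered,
      noncovered_costs(covered, params),
      medication_costs(claims),
      assistive_device_cost(patients_by_subtype(claims), params),
      transportation_cost(outpatient_visits_by_subtype(claims), params),
      caregiver_cost(inpatient_days_by_subtype(claims), params)
    )
  })
  components <- stage("indirect_costs", bind_rows(
    components,
    mortality_loss(mortality, params, mode = mortality_mode),
    morbidity_loss(care_time_by_age(claims), params)
  ))

  breakdown <- stage("reporting", build_cost_breakdown(components))

  n_by_col <- patients_by_subtype(claims)
  if ("stroke" %in% breakdown$columns) {
    n_by_col <- c(n_by_col, stroke = summary$n_patients)
  }
  per_case <- vapply(breakdown$columns, function(col) {
    if (n_by_col[[col]] == 0) return(NA_real_)
    per_case_cost(breakdown_amount(breakdown, "grand_total", col),
                  breakdown_amount(breakdown, "mortality_loss", col),
                  n_by_col[[col]])
  }, numeric(1))

  results <- list(
    schema_version = "1.0",
    n_patients = summary$n_patients,
    n_claims = summary$n_claims,
    mortality_mode = mortality_mode,
    columns = as.list(stats::setNames(
      purrr::map(breakdown$columns, function(col) {
        amt <- stats::setNames(as.list(breakdown$amounts[[col]]),
                               breakdown$amounts$label)
        c(amt, list(
          per_case_mkrw = per_case[[col]],
          grand_total_usd = krw_to_usd(
            breakdown_amount(breakdown, "grand_total", col), params)
        ))
      }),
      breakdown$columns
    ))
  )

  stage("render", {
    paths <- render_tables(summary, breakdown, per_case, out_dir)
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg("wrote ", length(paths) + 1, " files to ", out_dir)
  })

  invisible(list(summary = summary, components = components,
                 breakdown = breakdown, per_case = per_case,
                 results = results))
}
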