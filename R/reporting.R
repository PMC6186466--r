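direct_medical_labels <- c("inpatient", "outpatient", "noncovered",
                           "medication", "assistive")
direct_nonmedical_labels <- c("transportation", "caregiver")
indirect_labels <- c("mortality_loss", "morbidity_loss")

#' Assemble the full cost breakdown
#'
#' Takes the nine cost components (rows `(label, subtype, amount_krw)`,
#' every label exactly once per column) and produces the standard
#' breakdown: direct medical, direct non-medical, direct, indirect and
#' grand totals per column, plus each row's percentage share of its
#' column's grand total. When more than one subtype column is supplied an
#' all-stroke column is added as their elementwise sum — it is never
#' aggregated independently. All arithmetic is in unrounded KRW; shares
#' are rounded half-up to 2 decimals.
#'
#' @param components A tibble of cost components (rows from
#'   [cost_component()] and friends, bound together).
#' @return A `coi_cost_breakdown`: list with `amounts` (wide tibble, rows
#'   = 9 components + 5 subtotal rows, one column per subtype plus
#'   `stroke`), `shares` (same shape, percent of column grand total),
#'   `columns`, and `row_type` (component/subtotal).
#' @export
build_cost_breakdown <- function(components) {
  components <- as_tibble(components)
  labels <- cost_component_labels()
  cols <- unique(components$subtype)
  canonical <- intersect(coi_subtypes(), cols)
  cols <- c(canonical, setdiff(cols, canonical))

  for (col in cols) {
    have <- components$label[components$subtype == col]
    missing <- setdiff(labels, have)
    dup <- unique(have[duplicated(have)])
    if (length(missing) > 0) {
      coi_error(paste0("column ", col, " is missing component(s): ",
                       oxford(missing)), "coi_domain_error")
    }
    if (length(dup) > 0) {
      coi_error(paste0("column ", col, " has duplicate component(s): ",
                       oxford(dup)), "coi_domain_error")
    }
  }

  wide <- tidyr::pivot_wider(components, names_from = "subtype",
                             values_from = "amount_krw")
  wide <- wide[match(labels, wide$label), c("label", cols)]
  combined <- length(cols) > 1
  if (combined) {
    wide$stroke <- rowSums(as.matrix(wide[cols]))
    cols <- c(cols, "stroke")
  }

  subtotal <- function(row_labels, name) {
    sums <- colSums(as.matrix(wide[wide$label %in% row_labels, cols]))
    tibble(label = name, !!!as.list(sums))
  }
  subtotals <- bind_rows(
    subtotal(direct_medical_labels, "direct_medical"),
    subtotal(direct_nonmedical_labels, "direct_nonmedical"),
    subtotal(c(direct_medical_labels, direct_nonmedical_labels),
             "direct_total"),
    subtotal(indirect_labels, "indirect_total"),
    subtotal(labels, "grand_total")
  )
  amounts <- bind_rows(wide, subtotals)

  shares <- amounts
  for (col in cols) {
    grand <- subtotals[[col]][subtotals$label == "grand_total"]
    shares[[col]] <- if (grand > 0) {
      round_half_up(100 * amounts[[col]] / grand, 2)
    } else {
      NA_real_
    }
  }

  structure(list(
    amounts = amounts,
    shares = shares,
    columns = cols,
    row_type = c(rep("component", length(labels)),
                 rep("subtotal", nrow(subtotals)))
  ), class = "coi_cost_breakdown")
}

#' @export
print.coi_cost_breakdown <- function(x, ...) {
  cat("Cost breakdown (million KRW, shares % of column grand total)\n")
  disp <- x$amounts
  for (col in x$columns) {
    disp[[col]] <- round_half_up(disp[[col]] / 1e6)
  }
  print(as.data.frame(disp), row.names = FALSE)
  invisible(x)
}

# Pull one cell out of a breakdown, in KRW.
breakdown_amount <- function(breakdown, label, column) {
  breakdown$amounts[[column]][breakdown$amounts$label == label]
}

#' Average cost per stroke case
#'
#' Total cost excluding the premature-death loss, divided by the number of
#' patients: the standard per-case figure of a prevalence-based COI study
#' (death costs are excluded because they do not accrue to treated,
#' surviving case management).
#'
#' @param grand_total Grand total cost, KRW.
#' @param mortality_loss Premature-death productivity loss, KRW; must not
#'   exceed `grand_total`.
#' @param n_patients Number of distinct patients (> 0).
#' @param decimals Decimal places of the reported figure (default 1).
#' @return Cost per case in million KRW, rounded half-up.
#' @export
per_case_cost <- function(grand_total, mortality_loss, n_patients,
                          decimals = 1) {
  if (n_patients <= 0) {
    coi_error("per_case_cost: n_patients must be > 0", "coi_domain_error")
  }
  if (mortality_loss > grand_total) {
    coi_error("per_case_cost: mortality_loss exceeds grand_total",
              "coi_domain_error")
  }
  round_half_up((grand_total - mortality_loss) / n_patients / 1e6, decimals)
}

#' Currency conversion
#'
#' @param amount Amount in KRW (or USD for the inverse).
#' @param params A `coi_parameters` object with a positive `krw_per_usd`.
#' @return The converted amount.
#' @export
krw_to_usd <- function(amount, params) {
  if (params$krw_per_usd <= 0) {
    coi_error("krw_per_usd must be > 0", "coi_parameter_error")
  }
  amount / params$krw_per_usd
}

#' @rdname krw_to_usd
#' @export
usd_to_krw <- function(amount, params) {
  if (params$krw_per_usd <= 0) {
    coi_error("krw_per_usd must be > 0", "coi_parameter_error")
  }
  amount * params$krw_per_usd
}

#' Render report tables to files
#'
#' Writes CSV and Markdown analogues of the three standard report tables:
#' the stratified cohort summary, the cost breakdown (million KRW,
#' rounded half-up at render time only, with shares), and per-case costs.
#' Rendering is a pure function of its inputs: identical inputs give
#' byte-identical files.
#'
#' @param summary A [summarize_cohort()] result.
#' @param breakdown A [build_cost_breakdown()] result.
#' @param per_case Named numeric vector of per-case costs (million KRW)
#'   by breakdown column.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
render_tables <- function(summary, breakdown, per_case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table1 = file.path(dir, "table1_cohort.csv"),
    table2 = file.path(dir, "table2_costs.csv"),
    table3 = file.path(dir, "table3_per_case.csv"),
    report = file.path(dir, "report.md")
  )

  t1 <- bind_rows(
    dplyr::mutate(summary$patients, level = "patient"),
    dplyr::mutate(summary$visits, level = "visit")
  )[c("level", "stratifier", "category", "n", "pct")]
  readr::write_csv(t1, paths[["table1"]])

  t2 <- breakdown$amounts["label"]
  t2$row_type <- breakdown$row_type
  for (col in breakdown$columns) {
    t2[[paste0(col, "_mkrw")]] <-
      round_half_up(breakdown$amounts[[col]] / 1e6)
    t2[[paste0(col, "_pct")]] <- breakdown$shares[[col]]
  }
  readr::write_csv(t2, paths[["table2"]])

  t3 <- tibble(column = names(per_case),
               per_case_mkrw = round_half_up(unname(per_case), 1))
  readr::write_csv(t3, paths[["table3"]])

  md_table <- function(df) {
    fmt <- function(x) {
      if (is.numeric(x)) ifelse(is.na(x), "", format(x, scientific = FALSE,
                                                     trim = TRUE))
      else as.character(x)
    }
    cells <- vapply(df, fmt, character(nrow(df)))
    cells <- matrix(cells, nrow = nrow(df))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    rule <- paste0("|", paste(rep(" --- |", ncol(df)), collapse = ""))
    body <- apply(cells, 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    c(header, rule, body)
  }
  lines <- c(
    "# Stroke cost-of-illness report", "",
    paste0("Cohort: ", summary$n_patients, " patients, ",
           summary$n_claims, " claim lines."), "",
    "## Cohort characteristics", "", md_table(t1), "",
    "## Cost breakdown (million KRW)", "", md_table(t2), "",
    "## Cost per stroke case (million KRW)", "", md_table(t3), ""
  )
  writeLines(lines, paths[["report"]])
  invisible(paths)
}

#' Check the breakdown arithmetic against the published 2015 tables
#'
#' Feeds each published column of [reference_costs_2015()] (its nine
#' component rows, million KRW) through [build_cost_breakdown()] and
#' [per_case_cost()] and compares the recomputed subtotals, shares and
#' per-case costs with the published figures. Each published component was
#' rounded to the nearest million independently, so a subtotal of k
#' components is only determined to within k/2 million KRW; that
#' propagation bound is the tolerance for subtotals, and 0.011 percentage
#' points for shares. One published figure (the hemorrhagic per-case cost)
#' is inconsistent with the published components it should derive from;
#' it is flagged `known_discrepancy` rather than reproduced.
#'
#' @return A tibble with `quantity`, `column`, `computed`, `published`,
#'   `tolerance`, `ok`, `known_discrepancy`.
#' @export
check_reference_costs <- function() {
  ref <- reference_costs_2015()
  pub <- reference_published_2015()
  rows <- list()

  n_comp <- c(direct_medical = 5, direct_nonmedical = 2, direct_total = 7,
              indirect_total = 2, grand_total = 9)

  for (col in c("ischemic", "hemorrhagic", "stroke")) {
    comps <- cost_component_labels() |>
      purrr::map(~ cost_component(.x, stats::setNames(
        1e6 * ref[[col]][ref$label == .x], col))) |>
      bind_rows()
    bd <- build_cost_breakdown(comps)
    grand <- breakdown_amount(bd, "grand_total", col)

    for (s in names(n_comp)) {
      rows[[length(rows) + 1]] <- tibble(
        quantity = paste0(s, "_mkrw"), column = col,
        computed = breakdown_amount(bd, s, col) / 1e6,
        published = pub$subtotals_mkrw[[col]][
          pub$subtotals_mkrw$row == s],
        tolerance = n_comp[[s]] / 2,
        known_discrepancy = FALSE
      )
    }
    share_rows <- c(mortality_loss = "mortality_loss",
                    morbidity_loss = "morbidity_loss",
                    medication = "medication",
                    direct_total = "direct_total",
                    indirect_total = "indirect_total")
    if (col == "stroke") {
      for (q in names(share_rows)) {
        rows[[length(rows) + 1]] <- tibble(
          quantity = paste0(q, "_share_pct"), column = col,
          computed = 100 * breakdown_amount(bd, share_rows[[q]], col) /
            grand,
          published = pub$shares_pct[[q]],
          tolerance = 0.011,
          known_discrepancy = FALSE
        )
      }
      rows[[length(rows) + 1]] <- tibble(
        quantity = "treatment_share_pct", column = col,
        computed = 100 * (breakdown_amount(bd, "inpatient", col) +
                            breakdown_amount(bd, "outpatient", col)) /
          grand,
        published = pub$shares_pct[["treatment"]],
        tolerance = 0.011, known_discrepancy = FALSE
      )
    }
    rows[[length(rows) + 1]] <- tibble(
      quantity = "per_case_mkrw", column = col,
      computed = per_case_cost(grand,
                               breakdown_amount(bd, "mortality_loss", col),
                               pub$n_patients[[col]]),
      published = pub$per_case_mkrw[[col]],
      tolerance = 0.05,
      known_discrepancy = col == "hemorrhagic"
    )
    rows[[length(rows) + 1]] <- tibble(
      quantity = "total_usd_billion", column = col,
      computed = krw_to_usd(grand, default_parameters()) / 1e9,
      published = pub$usd_billion[[col]],
      tolerance = 0.0035,
      known_discrepancy = FALSE
    )
  }

  out <- bind_rows(rows)
  out$ok <- abs(out$computed - out$published) <= out$tolerance
  out[c("quantity", "column", "computed", "published", "tolerance",
        "ok", "known_discrepancy")]
}
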