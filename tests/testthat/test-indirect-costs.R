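test_that("three outpatient visits cost one inpatient day of earnings", {
  p <- flat_params()
  ct_visits <- tibble::tibble(subtype = "ischemic", age_band = "40-49",
                              inpatient_days = 0, outpatient_visits = 3)
  ct_day <- tibble::tibble(subtype = "ischemic", age_band = "40-49",
                           inpatient_days = 1, outpatient_visits = 0)
  expect_equal(morbidity_loss(ct_visits, p)$amount_krw,
               morbidity_loss(ct_day, p)$amount_krw)
  # with daily earnings 90000 and full employment the value is forced
  p$annual_income["40-49"] <- 90000 * p$daily_wage_divisor
  p$employment_rate["40-49"] <- 1
  expect_equal(morbidity_loss(ct_visits, p)$amount_krw, 90000)
})

test_that("person-time outside the working ages earns nothing", {
  p <- flat_params()
  ct <- tibble::tibble(subtype = "hemorrhagic", age_band = "80+",
                       inpatient_days = 500, outpatient_visits = 900)
  expect_equal(morbidity_loss(ct, p)$amount_krw, 0)
  mort_old <- tibble::tibble(subtype = c("ischemic", "ischemic"),
                             age_band = c("70-79", "80+"),
                             deaths = c(100, 40), lost_years = c(12, 7))
  expect_equal(mortality_loss(mort_old, p)$amount_krw, 0)
  expect_equal(mortality_loss(mort_old, p, "present_value")$amount_krw, 0)
  # a death in childhood earns nothing under the product formula, but the
  # present-value walk does credit the adult years the person would reach
  mort_young <- tibble::tibble(subtype = "ischemic", age_band = "10-19",
                               deaths = 10, lost_years = 60)
  expect_equal(mortality_loss(mort_young, p)$amount_krw, 0)
  expect_gt(mortality_loss(mort_young, p, "present_value")$amount_krw, 0)
})

test_that("losses match brute-force loop oracles on random tables", {
  p <- flat_params()
  set.seed(314)
  for (rep in 1:25) {
    bands <- sample(coi_age_bands(), 5)
    ct <- tibble::tibble(
      subtype = sample(coi_subtypes(), 5, replace = TRUE),
      age_band = bands,
      inpatient_days = rpois(5, 200),
      outpatient_visits = rpois(5, 400)
    )
    got <- morbidity_loss(ct, p)
    want <- oracle_morbidity(ct, p)
    for (s in unique(ct$subtype)) {
      expect_equal(got$amount_krw[got$subtype == s], unname(want[[s]]))
    }
    mort <- tibble::tibble(
      subtype = sample(coi_subtypes(), 5, replace = TRUE),
      age_band = bands,
      deaths = rpois(5, 30),
      lost_years = round(runif(5, 0, 60), 1)
    )
    gotm <- mortality_loss(mort, p)
    wantm <- oracle_mortality(mort, p)
    for (s in unique(mort$subtype)) {
      expect_equal(gotm$amount_krw[gotm$subtype == s], unname(wantm[[s]]))
    }
  }
})

test_that("the product formula multiplies deaths, years, income, employment", {
  p <- flat_params()
  p$annual_income["60-69"] <- 30e6
  p$employment_rate["60-69"] <- 0.6
  mort <- tibble::tibble(subtype = "ischemic", age_band = "60-69",
                         deaths = 10, lost_years = 5)
  expect_equal(mortality_loss(mort, p)$amount_krw, 10 * 5 * 30e6 * 0.6)
})

test_that("present value equals the product at zero discount within a band", {
  p <- flat_params()  # discount_rate 0
  set.seed(27)
  for (band in c("20-29", "40-49", "60-69")) {
    mort <- tibble::tibble(subtype = "hemorrhagic", age_band = band,
                           deaths = sample(1:50, 1),
                           lost_years = runif(1, 0, 5))
    expect_equal(mortality_loss(mort, p, "present_value")$amount_krw,
                 mortality_loss(mort, p, "product")$amount_krw,
                 tolerance = 1e-10)
  }
})

test_that("discounting never increases the present value", {
  p0 <- flat_params()
  p3 <- flat_params(discount_rate = 0.03)
  mort <- tibble::tibble(
    subtype = c("ischemic", "ischemic", "hemorrhagic"),
    age_band = c("30-39", "50-59", "40-49"),
    deaths = c(5, 10, 3), lost_years = c(40, 25, 35)
  )
  pv0 <- mortality_loss(mort, p0, "present_value")
  pv3 <- mortality_loss(mort, p3, "present_value")
  expect_true(all(pv3$amount_krw <= pv0$amount_krw))
})

test_that("mortality loss is monotone in each factor (product mode)", {
  p <- flat_params()
  base <- tibble::tibble(subtype = "ischemic", age_band = "50-59",
                         deaths = 10, lost_years = 10)
  v0 <- mortality_loss(base, p)$amount_krw
  more_deaths <- base; more_deaths$deaths <- 20
  more_years <- base; more_years$lost_years <- 20
  p_up <- p; p_up$annual_income["50-59"] <- p$annual_income[["50-59"]] * 2
  expect_gte(mortality_loss(more_deaths, p)$amount_krw, v0)
  expect_gte(mortality_loss(more_years, p)$amount_krw, v0)
  expect_gte(mortality_loss(base, p_up)$amount_krw, v0)
})

test_that("zero employment silences both losses", {
  p <- flat_params()
  p$employment_rate[] <- 0
  ct <- tibble::tibble(subtype = "ischemic", age_band = "40-49",
                       inpatient_days = 100, outpatient_visits = 300)
  mort <- tibble::tibble(subtype = "ischemic", age_band = "40-49",
                         deaths = 50, lost_years = 30)
  expect_equal(morbidity_loss(ct, p)$amount_krw, 0)
  expect_equal(mortality_loss(mort, p)$amount_krw, 0)
  expect_equal(mortality_loss(mort, p, "present_value")$amount_krw, 0)
})

test_that("total indirect cost sums the published component pair", {
  ref <- reference_costs_2015()
  morb <- cost_component("morbidity_loss", c(
    ischemic = 1e6 * ref$ischemic[ref$label == "morbidity_loss"],
    hemorrhagic = 1e6 * ref$hemorrhagic[ref$label == "morbidity_loss"]))
  mort <- cost_component("mortality_loss", c(
    ischemic = 1e6 * ref$ischemic[ref$label == "mortality_loss"],
    hemorrhagic = 1e6 * ref$hemorrhagic[ref$label == "mortality_loss"]))
  tot <- total_indirect(morb, mort)
  # published subtotals were rounded from unrounded components: +-1 million
  expect_equal(tot$amount_krw[tot$subtype == "ischemic"] / 1e6,
               1488646, tolerance = 1.05 / 1488646)
  expect_equal(tot$amount_krw[tot$subtype == "hemorrhagic"] / 1e6,
               2715689, tolerance = 1.05 / 2715689)
  stroke_total <- sum(tot$amount_krw) / 1e6
  expect_equal(stroke_total, 4204334, tolerance = 2 / 4204334)
  expect_equal(sum(total_indirect(
    cost_component("morbidity_loss", c(ischemic = 0)),
    cost_component("mortality_loss", c(ischemic = 0)))$amount_krw), 0)
})
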