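test_that("CMI is the case-weighted mean DRG relative weight", {
  expect_equal(compute_cmi(c(1.0, 2.0), c(50, 50)), 1.5)
  expect_equal(compute_cmi(0.8, 120), 0.8)
  expect_equal(compute_cmi(c(0.5, 1.5), c(10, 30)), (5 + 45) / 40)
  expect_error(compute_cmi(c(1, 2), c(0, 0)), "total case count is zero")
  expect_error(compute_cmi(c(-1, 2), c(5, 5)), "> 0")
})

test_that("CMI stays within the weight range of non-empty groups", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(1:8, 1)
    w <- runif(k, 0.2, 4)
    cnt <- rpois(k, 20)
    if (sum(cnt) == 0) cnt[1] <- 1
    cmi <- compute_cmi(w, cnt)
    expect_gte(cmi, min(w[cnt > 0]))
    expect_lte(cmi, max(w[cnt > 0]))
  }
})

test_that("LOS is inpatient days per discharge", {
  expect_equal(compute_los(1000, 100), 10)
  expect_equal(compute_los(7, 7), 1)
  expect_equal(compute_los(6.87 * 1000, 1000), 6.87)
  expect_error(compute_los(100, 0), "undefined LOS")
})

test_that("generation rate uses calendar-day denominators, leap-year aware", {
  expect_equal(compute_generation_rate(3650, 10, 2017), 1)
  expect_equal(compute_generation_rate(0, 200, 2019), 0)
  expect_equal(compute_generation_rate(3660, 10, 2020), 1)
  expect_equal(compute_generation_rate(3650, 10, 2020, leap_years = FALSE), 1)
  expect_error(compute_generation_rate(100, 0, 2019), "beds")
})

test_that("CAWI is GR * CMI / LOS", {
  expect_equal(compute_cawi(0.5, 1.2, 6.0), 0.1)
  # computed from size-quintile means: differs from a mean of
  # institution-level CAWIs by construction (mean of ratios convention)
  expect_equal(compute_cawi(0.26, 0.76, 17.23), 0.011468369124,
               tolerance = 1e-9)
  expect_equal(compute_cawi(0, 1, 5), 0)
  expect_error(compute_cawi(0.5, 1.2, 0), "los")
})

test_that("CAWI is homogeneous in waste mass and inverse in LOS", {
  set.seed(42)
  gr <- runif(20, 0.05, 1)
  cmi <- runif(20, 0.3, 2.5)
  los <- runif(20, 2, 30)
  k <- 3.7
  expect_equal(compute_cawi(gr * k, cmi, los),
               k * compute_cawi(gr, cmi, los), tolerance = 1e-15)
  expect_equal(compute_cawi(gr, cmi, los * k),
               compute_cawi(gr, cmi, los) / k, tolerance = 1e-15)
})

test_that("index records satisfy cawi = gr * cmi / los and count institutions", {
  sim <- default_sim(seed = 5)
  rec <- compute_index_records(sim$panel)
  expect_equal(nrow(rec), 94)
  expect_equal(rec$cawi, rec$gr * rec$cmi / rec$los, tolerance = 1e-12)
  pooled <- compute_index_records(sim$panel, aggregation = "pooled")
  expect_equal(nrow(pooled), 470)
  expect_equal(pooled$cawi, pooled$gr * pooled$cmi / pooled$los,
               tolerance = 1e-12)
})

test_that("a single record indexes to its own component product", {
  one <- tibble::tibble(
    institution_id = "A", year = 2018L, beds = 100, hhcw_kg = 10000,
    inpatient_days = 30000, discharges = 3000, cmi = 1.2,
    icu_patients = 50, inpatients = 3000, mdr_incidence = 12, educational = 1
  )
  rec <- compute_index_records(one)
  expect_equal(nrow(rec), 1)
  gr <- 10000 / (100 * 365)
  expect_equal(rec$gr, gr)
  expect_equal(rec$los, 10)
  expect_equal(rec$cawi, gr * 1.2 / 10, tolerance = 1e-12)
})

test_that("pooled and institution-mean agree when all years are identical", {
  one_year <- tibble::tibble(
    institution_id = "A", year = 2017L, beds = 120, hhcw_kg = 9000,
    inpatient_days = 35040, discharges = 2920, cmi = 1.1,
    icu_patients = 60, inpatients = 2920, mdr_incidence = 8, educational = 0
  )
  five <- dplyr::bind_rows(lapply(0:4, function(k) {
    y <- one_year
    y$year <- 2017L + k
    # scale mass/days so the per-day rate is constant across leap years
    d <- days_in_year(y$year)
    y$hhcw_kg <- 9000 / 365 * d
    y$inpatient_days <- 35040 / 365 * d
    y$discharges <- 2920 / 365 * d
    y
  }))
  m <- compute_index_records(five, aggregation = "institution_mean")
  p <- compute_index_records(five, aggregation = "pooled")
  expect_equal(rep(m$cawi, 5), p$cawi, tolerance = 1e-12)
  expect_equal(m$gr, p$gr[1], tolerance = 1e-12)
})

test_that("records with undefined LOS or CMI are dropped and counted", {
  sim <- default_sim(seed = 6)
  panel <- sim$panel
  panel$discharges[3] <- 0
  panel$cmi[10] <- NA
  expect_warning(rec <- compute_index_records(panel, aggregation = "pooled"),
                 "dropping 2 record")
  expect_equal(nrow(rec), 468)
  expect_error(
    suppressWarnings(
      compute_index_records(dplyr::mutate(sim$panel[1, ], discharges = 0))
    ),
    "no valid records"
  )
})

test_that("a DRG case table takes precedence over a precomputed CMI", {
  panel <- tibble::tibble(
    institution_id = c("A", "B"), year = 2019L, beds = c(100, 200),
    hhcw_kg = c(10000, 30000), inpatient_days = c(30000, 60000),
    discharges = c(3000, 5000), cmi = c(1.0, 2.0)
  )
  drg <- tibble::tibble(
    institution_id = c("A", "A", "B"), year = 2019L,
    relative_weight = c(0.5, 1.5, 2.0), case_count = c(10, 30, 40)
  )
  expect_warning(rec <- compute_index_records(panel, drg = drg),
                 "DRG-derived CMI differs")
  expect_equal(rec$cmi[rec$institution_id == "A"], 1.25)  # (5 + 45)/40
  expect_equal(rec$cmi[rec$institution_id == "B"], 2.0)
  # without a cmi column the table is the only source
  rec2 <- compute_index_records(dplyr::select(panel, -cmi), drg = drg)
  expect_equal(sort(rec2$cmi), c(1.25, 2.0))
})

test_that("empty input errors", {
  expect_error(compute_index_records(tibble::tibble()), "empty panel")
})
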