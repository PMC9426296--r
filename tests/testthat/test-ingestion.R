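nt <- nuclide_table()
cf0 <- list(milk_local = 1, milk_shop = 0.95, milk_products = 0.7,
            meat = 0.9, potato = 0.18, root_veg = 0.18, mushrooms = 10)
df0 <- c(Cs134 = 1.9e-5, Cs137 = 1.3e-5)
w <- exposure_window(as.Date("2004-01-01"), "DOB38")

diet1 <- data.frame(foodstuff = c("milk", "potato"), rate = c(0.5, 0.3),
                    source = "local", stringsAsFactors = FALSE)

test_that("intake is zero without consumption and linear in rates", {
  none <- diet1; none$rate <- 0
  expect_equal(intake_function(c(1, 50, 200), none, cf0, 0.05),
               c(0, 0, 0))
  i1 <- intake_function(c(1, 50, 200), diet1, cf0, 0.05)
  d2 <- diet1; d2$rate <- 2 * d2$rate
  expect_equal(intake_function(c(1, 50, 200), d2, cf0, 0.05), 2 * i1)
  expect_error(intake_function(-1, diet1, cf0, 0.05), "precedes")
})

test_that("mushroom-to-potato intake ratio spans the conversion-factor band", {
  t2 <- 300  # root-uptake period
  mush <- data.frame(foodstuff = "mushrooms", rate = 0.02, source = "local")
  pot <- data.frame(foodstuff = "potato", rate = 0.02, source = "local")
  for (cfm in c(5, 15)) for (cfp in c(0.12, 0.24)) {
    cfv <- cf0; cfv$mushrooms <- cfm; cfv$potato <- cfp
    ratio <- intake_function(t2, mush, cfv, 0.05) /
      intake_function(t2, pot, cfv, 0.05)
    expect_gte(ratio, 5 / 0.24 - 1e-9)
    expect_lte(ratio, 15 / 0.12 + 1e-9)
  }
})

test_that("period-1 foods exclude root-uptake foodstuffs", {
  pot <- data.frame(foodstuff = "potato", rate = 1, source = "local")
  expect_equal(intake_function(10, pot, cf0, 0.05), 0)  # before 1 Aug 1986
  expect_gt(intake_function(200, pot, cf0, 0.05), 0)
})

test_that("ingestion dose matches the day-step rectangle integral exactly", {
  # piecewise-constant curves: the closed-form step sum is exact
  curves <- make_intake_curves()
  curves$p1$value[] <- 0.2
  curves$p2$value[] <- 0.05
  iv <- c(accident_date(), accident_date() + 100)
  got <- ingestion_dose(iv, w, sigma = 100, diet = diet1, cf = cf0,
                        tf = 0.05, df = c(Cs134 = 0, Cs137 = 1e-5),
                        curves = curves, cs134_ratio = 0)
  bd <- gonadose:::period_boundary_day()
  co1 <- 0.5 * 1           # milk only in period 1
  co2 <- 0.5 * 1 + 0.3 * 0.18
  oracle <- 100 * 1e-5 * (co1 * 0.2 * bd + co2 * 0.05 * 0.05 * (100 - bd))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("empty intersections and zero deposition give zero dose", {
  expect_equal(ingestion_dose(c(accident_date(), accident_date() + 300), w,
                              0, diet1, cf0, 0.05, df0), 0)
  w_early <- exposure_window(as.Date("1987-03-14"), "DOB51")  # zero length
  expect_equal(ingestion_dose(c(accident_date(), accident_date() + 300),
                              w_early, 100, diet1, cf0, 0.05, df0), 0)
  late <- c(as.Date("1995-01-01"), as.Date("1996-01-01"))
  w_before <- exposure_window(as.Date("1990-01-01"), "DOB38")
  expect_equal(ingestion_dose(late, w_before, 100, diet1, cf0, 0.05, df0), 0)
  expect_warning(
    d <- ingestion_dose(c(accident_date(), accident_date() + 300), w, 100,
                        diet1[0, ], cf0, 0.05, df0),
    "zero consumption")
  expect_equal(d, 0)
})

test_that("splitting the integral at the period boundary changes nothing", {
  bdate <- as.Date("1986-08-01")
  iv <- c(accident_date(), accident_date() + 400)
  whole <- ingestion_dose(iv, w, 80, diet1, cf0, 0.05, df0)
  left <- ingestion_dose(c(iv[1], bdate), w, 80, diet1, cf0, 0.05, df0)
  right <- ingestion_dose(c(bdate, iv[2]), w, 80, diet1, cf0, 0.05, df0)
  expect_equal(left + right, whole, tolerance = 1e-8)
  # and at an arbitrary split point
  mid <- accident_date() + 123
  expect_equal(ingestion_dose(c(iv[1], mid), w, 80, diet1, cf0, 0.05, df0) +
                 ingestion_dose(c(mid, iv[2]), w, 80, diet1, cf0, 0.05, df0),
               whole, tolerance = 1e-8)
})

test_that("ingestion dose is linear in sigma and DF and additive over isotopes", {
  iv <- c(accident_date(), accident_date() + 500)
  d <- ingestion_dose(iv, w, 50, diet1, cf0, 0.05, df0)
  expect_equal(ingestion_dose(iv, w, 100, diet1, cf0, 0.05, df0), 2 * d)
  d137 <- ingestion_dose(iv, w, 50, diet1, cf0, 0.05,
                         c(Cs134 = 0, Cs137 = df0[["Cs137"]]))
  d134 <- ingestion_dose(iv, w, 50, diet1, cf0, 0.05,
                         c(Cs134 = df0[["Cs134"]], Cs137 = 0))
  expect_equal(d137 + d134, d, tolerance = 1e-12)
  expect_equal(ingestion_dose(iv, w, 50, diet1, cf0, 0.05, 2 * df0), 2 * d)
})
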