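cut90 <- as.Date("1990-12-31")

test_that("deterministic mission dose is the central product sum", {
  grid <- flat_grid()
  expect_equal(mission_dose_deterministic(one_entry()[0, ], grid, 0.710,
                                          cut90), 0)
  expect_equal(mission_dose_deterministic(one_entry(), grid, 0.710, cut90),
               0.710)
  # 3-entry itinerary equals the term-by-term brute-force sum
  it <- rbind(one_entry(as.Date("1986-06-01"), dur = 2, lf = 0.3),
              one_entry(as.Date("1986-06-03"), dur = 5, lf = 0.45),
              one_entry(as.Date("1986-07-01"), dur = 8, lf = 0.2))
  grid2 <- rbind(flat_grid(akr = 2),
                 flat_grid(akr = 0.5, date = as.Date("1986-06-15")))
  oracle <- 0.710 * (2 * 2 * 0.3 + 2 * 5 * 0.45 + 0.5 * 8 * 0.2)
  expect_equal(mission_dose_deterministic(it, grid2, 0.710, cut90), oracle)
})

test_that("mission dose is linear in durations and additive over partitions", {
  it <- rbind(one_entry(as.Date("1986-06-01"), dur = 2, lf = 0.3),
              one_entry(as.Date("1986-06-03"), dur = 5, lf = 0.45))
  grid <- flat_grid(akr = 1.7)
  d <- mission_dose_deterministic(it, grid, 0.710, cut90)
  it2 <- transform(it, duration_am_h = duration_am_h * 3)
  expect_equal(mission_dose_deterministic(it2, grid, 0.710, cut90), 3 * d)
  d1 <- mission_dose_deterministic(it[1, ], grid, 0.710, cut90)
  d2 <- mission_dose_deterministic(it[2, ], grid, 0.710, cut90)
  expect_equal(d1 + d2, d)
})

test_that("dose is non-decreasing in the cutoff date and respects it", {
  it <- do.call(rbind, lapply(0:9, function(k)
    one_entry(as.Date("1986-06-01") + 10 * k)))
  grid <- flat_grid()
  cuts <- as.Date("1986-05-15") + c(0, 30, 60, 200)
  dd <- vapply(cuts, function(cc)
    mission_dose_deterministic(it, grid, 0.710, cc), numeric(1))
  expect_true(all(diff(dd) >= 0))
  # entries on/after the cutoff contribute nothing
  expect_equal(dd[1], 0)
  expect_equal(dd[4], mission_dose_deterministic(it, grid, 0.710, cut90))
})

test_that("unresolved air-kerma-rate references fail with the entry named", {
  expect_error(
    mission_dose_deterministic(one_entry(loc = "NOPE"), flat_grid(), 0.7,
                               cut90),
    "NOPE")
})

test_that("stochastic mission doses match the analytic mean and degenerate limits", {
  grid <- flat_grid()
  it <- one_entry()
  # all specs degenerate -> n copies of the deterministic dose
  p <- default_parameters()
  p$mission$lf_sd_frac <- 0; p$mission$cg_sd_frac <- 0
  d0 <- mission_dose_stochastic(transform(it, duration_cv = 0), grid,
                                dist_point(0.710), cut90, n = 50, seed = 1,
                                params = p)
  expect_equal(as.numeric(d0), rep(0.710, 50))
  # realization mean within 3 MC standard errors of the analytic mean
  it3 <- rbind(one_entry(as.Date("1986-06-01"), dur = 3, cv = 0.1, lf = 0.3),
               one_entry(as.Date("1986-06-05"), dur = 7, cv = 0.1, lf = 0.4))
  grid3 <- flat_grid(akr = 2, gsd = 1.5)
  cg <- dist_tnorm(0.710, 0.071)
  d <- mission_dose_stochastic(it3, grid3, cg, cut90, n = 10000, seed = 2)
  m_an <- gonadose:::mission_dose_mean(it3, grid3, cg, cut90)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - m_an), 3 * se)
})

test_that("one-factor stochastic model recovers the truncated parameter GSD", {
  # only the air kerma rate is stochastic: the dose GSD equals the GSD of
  # the truncated lognormal parameter.  Truncation at +/- 2 log-SD shrinks
  # the log-SD by the truncated-normal factor, the in-test oracle.
  p <- default_parameters(); p$mission$lf_sd_frac <- 0
  d <- mission_dose_stochastic(one_entry(cv = 0), flat_grid(gsd = 1.5),
                               dist_point(0.710), cut90, n = 10000, seed = 3,
                               params = p)
  g <- empirical_gsd(as.numeric(d))
  z <- pnorm(2) - pnorm(-2)
  shrink <- sqrt(1 - 2 * 2 * dnorm(2) / z)   # symmetric truncation at 2 sd
  g_expected <- 1.5^shrink
  expect_lt(abs(g - g_expected) / g_expected, 0.02)
})

test_that("subject substreams differ but are reproducible", {
  grid <- flat_grid(gsd = 1.4)
  a <- mission_dose_stochastic(one_entry(), grid, dist_point(0.7), cut90,
                               n = 20, seed = 9, subject = "P1")
  a2 <- mission_dose_stochastic(one_entry(), grid, dist_point(0.7), cut90,
                                n = 20, seed = 9, subject = "P1")
  b <- mission_dose_stochastic(one_entry(), grid, dist_point(0.7), cut90,
                               n = 20, seed = 9, subject = "P2")
  expect_identical(as.numeric(a), as.numeric(a2))
  expect_false(identical(as.numeric(a), as.numeric(b)))
})

test_that("Pripyat timeline doses are additive and respect LF bounds", {
  cg <- dist_point(0.586)
  tl <- data.frame(parent_id = "M", start_hour = c(0, 10),
                   end_hour = c(8, 20), location_kind = c("sleep", "indoor"),
                   akr_am = 2, akr_gsd = NA, lf_am = c(1, 0.5), lf_gsd = NA)
  d <- pripyat_dose(tl, cg, n = 1, seed = 1)
  expect_equal(as.numeric(d), 0.586 * (2 * 8 * 1 + 2 * 10 * 0.5))
  # additivity across a location split (deterministic parameters)
  d1 <- pripyat_dose(tl[1, ], cg, n = 1, seed = 1)
  d2 <- pripyat_dose(tl[2, ], cg, n = 1, seed = 1)
  expect_equal(as.numeric(d1) + as.numeric(d2), as.numeric(d))
  # overlap detection
  bad <- transform(tl, start_hour = c(0, 5))
  expect_error(pripyat_dose(bad, cg, n = 1, seed = 1), "overlap")
  # indoor TLN location factors stay within the 0.6-1.7 x GM band
  tl2 <- data.frame(parent_id = "M", start_hour = 0, end_hour = 10,
                    location_kind = "indoor", akr_am = 1, akr_gsd = NA,
                    lf_am = 0.049, lf_gsd = 1.3)
  d3 <- pripyat_dose(tl2, dist_point(1), n = 3000, seed = 4)
  lf_impl <- as.numeric(d3) / 10
  expect_true(all(lf_impl >= 0.6 * 0.049 - 1e-12))
  expect_true(all(lf_impl <= 1.7 * 0.049 + 1e-12))
})

test_that("daily-averaged location factors reproduce the tabulated values", {
  expect_equal(round(daily_average_lf(0.072, 0.0018, 8), 3), 0.049)
  expect_equal(round(daily_average_lf(0.038, 0.0001, 8), 3), 0.025)
  expect_equal(daily_average_lf(0.3, 0.3, 5), 0.3)
})
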