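nt <- nuclide_table()

test_that("deposition activity decays from the initial deposit", {
  sig <- 100
  r <- gonadose:::default_ratios(nt)
  for (nm in c("Cs137", "I131", "Zr95")) {
    expect_equal(deposition_activity(nm, 0, sig, r, nt), sig * r[[nm]])
    hl <- nt$half_life_d[nt$name == nm]
    expect_equal(deposition_activity(nm, hl, sig, r, nt),
                 sig * r[[nm]] / 2, tolerance = 1e-12)
  }
  expect_error(deposition_activity("Cs137", -1, sig, r, nt), "nonnegative")
})

test_that("Bateman daughter activities match an ODE integration to 0.1%", {
  skip_if_not_installed("deSolve")
  r <- gonadose:::default_ratios(nt)
  r["Ba140"] <- 1; r["La140"] <- 1  # unit initial deposits
  lp <- nt$lambda_d[nt$name == "Ba140"]
  ld <- nt$lambda_d[nt$name == "La140"]
  # activities A satisfy dAp/dt = -lp Ap; dAd/dt = ld (Ap - Ad)
  ode <- deSolve::ode(y = c(Ap = 1, Ad = 1),
                      times = seq(0, 30, by = 0.5),
                      func = function(t, y, p)
                        list(c(-lp * y["Ap"], ld * (y["Ap"] - y["Ad"]))),
                      parms = NULL, method = "ode45", rtol = 1e-10, atol = 1e-12)
  t10 <- which(ode[, "time"] == 10)
  impl <- deposition_activity("La140", 10, 1, r, nt)
  expect_equal(impl, unname(ode[t10, "Ad"]), tolerance = 1e-3)
  # whole trajectory, all three decay chains
  for (pair in list(c("Zr95", "Nb95"), c("Te132", "I132"),
                    c("Ba140", "La140"))) {
    lp2 <- nt$lambda_d[nt$name == pair[1]]
    ld2 <- nt$lambda_d[nt$name == pair[2]]
    r2 <- r; r2[pair] <- c(2, 0.5)
    ode2 <- deSolve::ode(y = c(Ap = 2, Ad = 0.5), times = c(0, 5, 15),
                         func = function(t, y, p)
                           list(c(-lp2 * y["Ap"], ld2 * (y["Ap"] - y["Ad"]))),
                         parms = NULL, method = "ode45", rtol = 1e-10, atol = 1e-12)
    impl2 <- deposition_activity(pair[2], c(0, 5, 15), 1, r2, nt)
    expect_equal(impl2, unname(ode2[, "Ad"]), tolerance = 1e-3)
  }
})

test_that("daughter ingrowth vanishes when the parent deposit is zero", {
  r <- gonadose:::default_ratios(nt)
  r["Ba140"] <- 0
  ld <- nt$lambda_d[nt$name == "La140"]
  expect_equal(deposition_activity("La140", 3, 50, r, nt),
               50 * r[["La140"]] * exp(-ld * 3))
})

test_that("attenuation function is normalized and evaluates correctly", {
  expect_equal(attenuation(0), 1.0)
  expect_equal(attenuation(1000),
               0.4 * exp(-1.27) + 0.6 * exp(-0.038), tolerance = 1e-12)
  expect_lt(attenuation(1e7), 1e-10)
})

test_that("single-nuclide dose matches the closed-form exponential integral", {
  w <- far_window()
  cs <- nt[nt$name == "Cs137", ]
  lam <- cs$lambda_d
  dc <- cs$dc_male
  # p(t) suppressed: integral is sigma*R*(1 - exp(-lam dt))/lam
  dt_d <- as.numeric(as.Date("1987-04-26") - accident_date())
  oracle <- 0.28 * 1.1 * dc * 100 * 1 * (1 - exp(-lam * dt_d)) / lam
  got <- residential_external_dose(
    c(accident_date(), as.Date("1987-04-26")), w, sigma = 100, bf = 0.28,
    iv = 1.1, atten = list(p1 = 0, lambda1 = 0, lambda2 = 0),
    nuclides = cs)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("analytic and adaptive-quadrature doses agree to 1e-6 relative", {
  w <- far_window()
  iv <- c(accident_date(), as.Date("1986-12-31"))
  d_an <- residential_external_dose(iv, w, 75, 0.24, 0.9)
  d_q <- residential_external_dose(iv, w, 75, 0.24, 0.9,
                                   method = "quadrature")
  expect_equal(d_an, d_q, tolerance = 1e-6)
  expect_gt(d_an, 0)
})

test_that("residential dose is linear in deposition and monotone in its factors", {
  w <- far_window()
  iv <- c(accident_date(), as.Date("1987-01-01"))
  d1 <- residential_external_dose(iv, w, 50, 0.3, 1)
  expect_equal(residential_external_dose(iv, w, 100, 0.3, 1), 2 * d1)
  expect_equal(residential_external_dose(iv, w, 0, 0.3, 1), 0)
  expect_gt(residential_external_dose(iv, w, 50, 0.34, 1), d1)
  expect_gt(residential_external_dose(iv, w, 50, 0.3, 1.3), d1)
  # longer window, larger dose
  w51 <- exposure_window(as.Date("1987-06-01"), "DOB51")
  w38 <- exposure_window(as.Date("1987-06-01"), "DOB38")
  expect_gte(residential_external_dose(iv, w38, 50, 0.3, 1),
             residential_external_dose(iv, w51, 50, 0.3, 1))
})

test_that("the 19-nuclide dose equals the sum of per-chain doses", {
  w <- far_window()
  iv <- c(accident_date(), as.Date("1986-05-26"))
  total <- residential_external_dose(iv, w, 100, 0.3)
  # isolate each nuclide's contribution by masking all other dose-rate
  # coefficients (keeps decay-chain ingrowth intact)
  parts2 <- vapply(nt$name, function(nm) {
    dc <- setNames(ifelse(nt$name == nm, nt$dc_male, 0), nt$name)
    residential_external_dose(iv, w, 100, 0.3, dc = dc)
  }, numeric(1))
  expect_equal(sum(parts2), total, tolerance = 1e-12)
})
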