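#' Ingestion dose from radiocesium during residence
#'
#' The ingestion model links Cs-137 deposition density to intake through
#' private cow's milk: `D = sigma * sum_k DF_k * integral I_k(t) dt` over
#' the residence interval clipped to the window, where `I_k(t)` is the
#' intake function of isotope k (Cs-134, Cs-137) normalized to Cs-137
#' deposition (Bq/day per kBq/m^2) and `DF_k` the gonadal dose per unit
#' ingested activity (mGy/Bq).  Two intake periods are modelled: from the
#' accident until 31 July 1986, vegetation (and hence milk, milk products
#' and meat) is contaminated by direct surface deposition; from 1 August
#' 1986 root uptake dominates, potatoes, root vegetables and mushrooms are
#' added, and the milk concentration scales with the settlement's
#' soil-to-milk transfer factor.  Cs-134 intake is derived from the Cs-137
#' intake via the initial deposition activity ratio and the isotopes'
#' decay-constant difference.
#'
#' @name ingestion
NULL

# day offset of 1986-08-01 (start of the root-uptake period)
period_boundary_day <- function() {
  days_since_accident(as.Date("1986-08-01"))
}

#' Normalized milk-concentration intake curves
#'
#' The time shapes of the two concentration curves come from external
#' intake studies, not from printed values; these defaults are synthetic
#' stand-ins with the right qualitative behaviour, and every dose identity
#' in the package is linear in them.  Period 1 (surface contamination) is a
#' single exponential with a 14-day effective half-time on pasture; period
#' 2 (root uptake, per unit soil-to-milk transfer) declines slowly with a
#' 550-day half-time.  Curves are daily step functions: the value at
#' integer day `d` applies over `[d, d+1)`.
#'
#' @param horizon_days Last day (since accident) covered by the curves.
#' @param c0 Period-1 milk concentration at day 0 (Bq/L per kBq/m^2).
#' @param half1 Period-1 effective half-time (days).
#' @param rel0 Period-2 relative concentration at the boundary (unitless,
#'   per unit soil-to-milk transfer).
#' @param half2 Period-2 decline half-time (days).
#' @return List with `p1`, `p2` (data frames `day`, `value`) and
#'   `boundary_day`.
#' @export
make_intake_curves <- function(horizon_days = 7300, c0 = 0.3, half1 = 14,
                               rel0 = 1.0, half2 = 550) {
  bd <- period_boundary_day()
  d1 <- 0:(bd - 1)
  d2 <- bd:horizon_days
  list(p1 = data.frame(day = d1, value = c0 * exp(-log(2) / half1 * d1)),
       p2 = data.frame(day = d2,
                       value = rel0 * exp(-log(2) / half2 * (d2 - bd))),
       boundary_day = bd)
}

# integral of a daily step curve over [a, b) in days, exact
step_curve_integral <- function(days, values, a, b) {
  if (b <= a) return(0)
  cum <- c(0, cumsum(values))
  d0 <- days[1]
  cumf <- function(x) {
    x <- min(max(x, d0), d0 + length(values))
    k <- floor(x - d0)
    cum[k + 1] + (if (k < length(values)) values[k + 1] else 0) * (x - d0 - k)
  }
  cumf(b) - cumf(a)
}

# foods contributing in each intake period
period1_foods <- c("milk", "milk_products", "meat")

# CF key for a diet row: milk distinguishes local vs shop sources
cf_key <- function(foodstuff, source) {
  ifelse(foodstuff == "milk",
         ifelse(source == "shop", "milk_shop", "milk_local"),
         foodstuff)
}

# summed rate * CF for the foods active in a period
diet_coefficient <- function(diet, cf, period) {
  if (is.null(diet) || nrow(diet) == 0) return(0)
  keep <- if (period == 1) diet$foodstuff %in% period1_foods
          else rep(TRUE, nrow(diet))
  d <- diet[keep & diet$source != "none", , drop = FALSE]
  if (nrow(d) == 0) return(0)
  sum(d$rate * unlist(cf[cf_key(d$foodstuff, d$source)]))
}

#' Intake function of a radiocesium isotope
#'
#' `I_k(t) = sum_f rate_f * CF_f * c_milk,k(t)`, normalized to Cs-137
#' deposition density.  Period 1 uses the surface-contamination milk curve;
#' period 2 the relative-concentration curve times the settlement
#' soil-to-milk transfer.  For Cs-134 the Cs-137 curve is scaled by the
#' initial activity ratio and corrected by `exp(-(l134 - l137) t)`.
#'
#' @param t Days since accident (>= 0), vectorized.
#' @param diet Data frame `foodstuff`, `rate` (kg/day or L/day), `source`
#'   (`"local"`, `"shop"`, `"none"`); realized rates.
#' @param cf Named list/vector of realized conversion factors (keys
#'   `milk_local`, `milk_shop`, `milk_products`, `meat`, `potato`,
#'   `root_veg`, `mushrooms`).
#' @param tf Realized soil-to-milk transfer (Bq/L per kBq/m^2).
#' @param isotope `"Cs137"` or `"Cs134"`.
#' @param curves Intake curves ([make_intake_curves()]).
#' @param scales Realized shared scale factors `c(p1, p2)` multiplying the
#'   two curves.
#' @param cs134_ratio Cs-134/Cs-137 deposition activity ratio at day 0.
#' @param nuclides Nuclide table (for the two decay constants).
#' @return Intake rate (Bq/day per kBq/m^2) at each `t`.
#' @export
intake_function <- function(t, diet, cf, tf, isotope = c("Cs137", "Cs134"),
                            curves = make_intake_curves(),
                            scales = c(1, 1), cs134_ratio = 0.5,
                            nuclides = nuclide_table()) {
  isotope <- match.arg(isotope)
  if (any(t < 0)) stop("t precedes the accident date")
  bd <- curves$boundary_day
  co1 <- diet_coefficient(diet, cf, 1)
  co2 <- diet_coefficient(diet, cf, 2)
  v1 <- curves$p1$value[pmin(pmax(floor(t) + 1, 1), nrow(curves$p1))]
  v2i <- pmin(pmax(floor(t) - bd + 1, 1), nrow(curves$p2))
  v2 <- curves$p2$value[v2i]
  conc <- ifelse(t < bd, scales[1] * v1, scales[2] * tf * v2)
  intake <- ifelse(t < bd, co1 * conc, co2 * conc)
  if (isotope == "Cs134") {
    dl <- nuclides$lambda_d[nuclides$name == "Cs134"] -
      nuclides$lambda_d[nuclides$name == "Cs137"]
    intake <- cs134_ratio * intake * exp(-dl * t)
  }
  intake
}

# cumulative-integral closure over a daily step curve: O(1) per query
step_curve_cum <- function(days, values) {
  d0 <- days[1]
  len <- length(values)
  cum <- c(0, cumsum(values))
  function(a, b) {
    if (b <= a) return(0)
    cumf <- function(x) {
      x <- min(max(x, d0), d0 + len)
      k <- floor(x - d0)
      cum[k + 1] + (if (k < len) values[k + 1] else 0) * (x - d0 - k)
    }
    cumf(b) - cumf(a)
  }
}

# precomputed cumulative integrals of the two curves, plain and weighted by
# the Cs-134 decay correction; reused across all subjects and MC sets
make_ingestion_basis <- function(curves = make_intake_curves(),
                                 nuclides = nuclide_table()) {
  dl <- nuclides$lambda_d[nuclides$name == "Cs134"] -
    nuclides$lambda_d[nuclides$name == "Cs137"]
  list(bd = curves$boundary_day,
       c1 = step_curve_cum(curves$p1$day, curves$p1$value),
       c2 = step_curve_cum(curves$p2$day, curves$p2$value),
       c1w = step_curve_cum(curves$p1$day,
                            curves$p1$value * exp(-dl * (curves$p1$day + 0.5))),
       c2w = step_curve_cum(curves$p2$day,
                            curves$p2$value * exp(-dl * (curves$p2$day + 0.5))))
}

# time integrals of the intake function per isotope, exact for the daily
# step curves (Cs-134's smooth decay correction is applied at day midpoints)
intake_integral <- function(a, b, diet, cf, tf, curves, scales, cs134_ratio,
                            nuclides, basis = NULL) {
  if (is.null(basis)) basis <- make_ingestion_basis(curves, nuclides)
  bd <- basis$bd
  co1 <- diet_coefficient(diet, cf, 1)
  co2 <- diet_coefficient(diet, cf, 2)
  int_one <- function(f1, f2) {
    co1 * scales[1] * f1(min(a, bd), min(b, bd)) +
      co2 * scales[2] * tf * f2(max(a, bd), max(b, bd))
  }
  list(Cs137 = int_one(basis$c1, basis$c2),
       Cs134 = cs134_ratio * int_one(basis$c1w, basis$c2w))
}

#' Ingestion dose for one residence interval
#'
#' `sigma * sum_k DF_k * integral I_k(t) dt` over the residence interval
#' clipped to the window (end-exclusive).  No individual-variability factor
#' is applied to ingestion.  A missing diet is treated as zero consumption
#' with a warning.
#'
#' @inheritParams intake_function
#' @param interval Length-2 `Date` vector: start/end of the stay.
#' @param window An [exposure_window()] or length-2 `Date` vector.
#' @param sigma Realized Cs-137 deposition density (kBq/m^2).
#' @param df Named vector of realized dose factors
#'   `c(Cs134 = ..., Cs137 = ...)` (mGy/Bq).
#' @param basis Optional precomputed cumulative-integral basis (internal
#'   speed-up for repeated calls); built from `curves` when `NULL`.
#' @return Dose in mGy (>= 0).
#' @export
ingestion_dose <- function(interval, window, sigma, diet, cf, tf, df,
                           curves = make_intake_curves(), scales = c(1, 1),
                           cs134_ratio = 0.5, nuclides = nuclide_table(),
                           basis = NULL) {
  win <- if (inherits(window, "exposure_window"))
    c(window$start, window$end) else as.Date(window)
  a <- max(days_since_accident(interval[1]), days_since_accident(win[1]), 0)
  b <- min(days_since_accident(interval[2]), days_since_accident(win[2]))
  if (b <= a || sigma <= 0) return(0)
  if (is.null(diet) || nrow(diet) == 0) {
    warning("no diet record; treating as zero consumption")
    return(0)
  }
  ii <- intake_integral(a, b, diet, cf, tf, curves, scales, cs134_ratio,
                        nuclides, basis)
  sigma * (df[["Cs134"]] * ii$Cs134 + df[["Cs137"]] * ii$Cs137)
}
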