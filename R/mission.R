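#' Time-and-motion external dose for the cleanup mission and Pripyat
#'
#' External gonadal dose is the product sum
#' `D = C_g * sum_ij AKR(t_ij) * dt_ij * LF_j`:
#' air kerma rate at the location and date of each activity (mGy/h), times
#' the activity duration (h), times the location factor encoding shielding,
#' all converted from air kerma to gonadal absorbed dose by the
#' sex-specific coefficient `C_g` (0.710 male / 0.586 female, isotropic
#' 0.3 MeV photons).  The same kernel serves the cleanup-mission itinerary
#' and the hour-by-hour Pripyat occupancy timeline.
#'
#' @name mission
NULL

# resolve AKR (am, gsd) for one itinerary entry; grids are piecewise
# constant in time: the cell at the latest grid date <= the entry date
akr_lookup <- function(akr_grid, location_id, date) {
  rows <- akr_grid[akr_grid$location_id == location_id &
                     as.Date(akr_grid$date) <= as.Date(date), , drop = FALSE]
  if (nrow(rows) == 0)
    stop(sprintf("no air-kerma-rate cell for location '%s' on or before %s",
                 location_id, format(date)))
  rows[which.max(as.Date(rows$date)), c("akr_am", "akr_gsd")]
}

check_itinerary <- function(itinerary) {
  need <- c("date", "location_id", "duration_am_h", "lf_am")
  miss <- setdiff(need, names(itinerary))
  if (length(miss))
    stop("itinerary lacks columns: ", paste(miss, collapse = ", "))
  if (any(itinerary$duration_am_h <= 0)) stop("durations must be positive")
  per_day <- tapply(itinerary$duration_am_h, as.character(itinerary$date), sum)
  if (any(per_day > 24)) stop("total duration exceeds 24 h on some day(s)")
  invisible(itinerary)
}

# per-entry central values and stochastic specs for an itinerary; entries
# are sorted by date so that a shorter cutoff keeps a prefix of the draw
# sequence (common random numbers across the DOB-51/DOB-38 windows)
itinerary_terms <- function(itinerary, akr_grid, params) {
  check_itinerary(itinerary)
  itinerary <- itinerary[order(as.Date(itinerary$date)), , drop = FALSE]
  cv <- if ("duration_cv" %in% names(itinerary)) itinerary$duration_cv
        else rep(NA_real_, nrow(itinerary))
  cv[is.na(cv)] <- params$mission$duration_cv_default
  akr <- do.call(rbind, lapply(seq_len(nrow(itinerary)), function(i)
    akr_lookup(akr_grid, itinerary$location_id[i], itinerary$date[i])))
  list(date = as.Date(itinerary$date),
       dur_am = itinerary$duration_am_h, dur_cv = cv,
       akr_am = akr$akr_am, akr_gsd = akr$akr_gsd,
       lf_am = itinerary$lf_am)
}

#' Deterministic cleanup-mission dose from central parameter values
#'
#' Entries strictly before `cutoff` (from [mission_cutoff()]) contribute
#' `c_g * AKR_am * dt_am * LF_am` each.
#'
#' @param itinerary Data frame with columns `date`, `location_id`,
#'   `duration_am_h`, `lf_am` and optional `duration_cv`.
#' @param akr_grid Data frame with columns `location_id`, `date`, `akr_am`
#'   (mGy/h), `akr_gsd`.
#' @param c_g Central kerma-to-gonad conversion coefficient.
#' @param cutoff Integration cutoff date (exclusive).
#' @param params Parameter library.
#' @return Dose in mGy.
#' @export
mission_dose_deterministic <- function(itinerary, akr_grid, c_g, cutoff,
                                       params = default_parameters()) {
  if (nrow(itinerary) == 0) return(0)
  tm <- itinerary_terms(itinerary, akr_grid, params)
  keep <- tm$date < as.Date(cutoff)
  c_g * sum(tm$akr_am[keep] * tm$dur_am[keep] * tm$lf_am[keep])
}

# analytic mean of the stochastic product-sum (independent factors)
mission_dose_mean <- function(itinerary, akr_grid, c_g_spec, cutoff,
                              params = default_parameters()) {
  if (nrow(itinerary) == 0) return(0)
  tm <- itinerary_terms(itinerary, akr_grid, params)
  keep <- which(tm$date < as.Date(cutoff))
  if (!length(keep)) return(0)
  s <- 0
  for (i in keep) {
    akr <- akr_term_spec(tm$akr_am[i], tm$akr_gsd[i], params)
    dur <- dist_unif((1 - tm$dur_cv[i]) * tm$dur_am[i],
                     (1 + tm$dur_cv[i]) * tm$dur_am[i])
    lf <- lf_site_spec(tm$lf_am[i], params)
    s <- s + dist_mean(akr) * dist_mean(dur) * dist_mean(lf)
  }
  dist_mean(c_g_spec) * s
}

akr_term_spec <- function(am, gsd, params) {
  if (is.na(gsd) || gsd <= 1) return(dist_point(am))
  gm <- gm_from_am_gsd(am, gsd, printed = params$gm_formula == "printed")
  dist_tlnorm(gm, gsd, gm / gsd^2, gm * gsd^2)
}

lf_site_spec <- function(am, params) {
  if (am == 0) return(dist_point(0))
  dist_tnorm(am, params$mission$lf_sd_frac * am)
}

cg_spec <- function(sex, params) {
  am <- params$mission$cg_am[[sex]]
  dist_tnorm(am, params$mission$cg_sd_frac * am)
}

#' Stochastic cleanup-mission doses
#'
#' Draws `n` dose realizations with every parameter (durations, air kerma
#' rates, location factors, `C_g`) redrawn independently per realization;
#' all mission parameters carry unshared errors.  `C_g` is drawn once per
#' realization (a property of the person, not the location).  The RNG
#' substream is keyed by `(seed, subject, "mission")`, so different
#' subjects under the same master seed get independent, reproducible
#' sequences.
#'
#' @inheritParams mission_dose_deterministic
#' @param c_g_spec A [dist_spec] for the conversion coefficient (see
#'   `cg_spec`); a point spec makes it deterministic.
#' @param n Number of realizations (study default 10000).
#' @param seed Master seed.
#' @param subject Subject key for substream separation.
#' @return A numeric vector of `n` doses (mGy) with attributes `subject`,
#'   `pathway`, `seed`; class `stochastic_doses`.
#' @export
mission_dose_stochastic <- function(itinerary, akr_grid, c_g_spec, cutoff,
                                    n = 10000, seed = 1, subject = "",
                                    params = default_parameters()) {
  stopifnot(n >= 1)
  if (nrow(itinerary) > 0) tm <- itinerary_terms(itinerary, akr_grid, params)
  with_substream(seed, paste0("mission/", subject), {
    if (nrow(itinerary) == 0) {
      d <- rep(0, n)
    } else {
      keep <- which(tm$date < as.Date(cutoff))
      cg <- dist_sample(c_g_spec, n)
      tot <- rep(0, n)
      for (i in keep) {
        akr <- dist_sample(akr_term_spec(tm$akr_am[i], tm$akr_gsd[i], params), n)
        dur <- dist_sample(dist_unif((1 - tm$dur_cv[i]) * tm$dur_am[i],
                                     (1 + tm$dur_cv[i]) * tm$dur_am[i]), n)
        lf <- dist_sample(lf_site_spec(tm$lf_am[i], params), n)
        tot <- tot + akr * dur * lf
      }
      d <- cg * tot
    }
    structure(d, subject = subject, pathway = "mission", seed = seed,
              class = "stochastic_doses")
  })
}

check_timeline <- function(timeline) {
  need <- c("start_hour", "end_hour", "akr_am", "lf_am")
  miss <- setdiff(need, names(timeline))
  if (length(miss))
    stop("timeline lacks columns: ", paste(miss, collapse = ", "))
  if (any(timeline$end_hour <= timeline$start_hour))
    stop("timeline entries must have end_hour > start_hour")
  o <- order(timeline$start_hour)
  tl <- timeline[o, , drop = FALSE]
  if (nrow(tl) > 1 &&
      any(tl$start_hour[-1] < tl$end_hour[-nrow(tl)] - 1e-9))
    stop("overlapping timeline entries")
  tl
}

#' Stochastic external doses during residence in Pripyat
#'
#' Same product-sum kernel as the cleanup mission, applied to an
#' hour-by-hour occupancy timeline (hours since the accident origin).
#' Indoor location factors follow `TLN(GM, 1.3, 0.6 GM, 1.7 GM)` about the
#' entry's central LF; entries with `lf_gsd` missing or 1 (e.g. outdoor
#' LF = 1) are treated as fixed.  Durations come from the timeline and are
#' not perturbed.  Entries are clipped to `max_hour` (evacuation or window
#' end).
#'
#' @param timeline Data frame with columns `start_hour`, `end_hour`,
#'   `akr_am`, `akr_gsd` (optional), `lf_am`, `lf_gsd` (optional).
#' @param c_g_spec Conversion-coefficient [dist_spec].
#' @param n Number of realizations (study default 10000).
#' @param seed,subject Substream key.
#' @param max_hour Clip the timeline at this hour offset (default none).
#' @param params Parameter library.
#' @return `stochastic_doses` vector of length `n` (mGy).
#' @export
pripyat_dose <- function(timeline, c_g_spec, n = 10000, seed = 1,
                         subject = "", max_hour = Inf,
                         params = default_parameters()) {
  stopifnot(n >= 1)
  tl <- check_timeline(timeline)
  tl$end_hour <- pmin(tl$end_hour, max_hour)
  tl <- tl[tl$end_hour > tl$start_hour, , drop = FALSE]
  with_substream(seed, paste0("pripyat/", subject), {
    if (nrow(tl) == 0) {
      d <- rep(0, n)
    } else {
      cg <- dist_sample(c_g_spec, n)
      tot <- rep(0, n)
      for (i in seq_len(nrow(tl))) {
        agsd <- if ("akr_gsd" %in% names(tl)) tl$akr_gsd[i] else NA
        akr <- dist_sample(akr_term_spec(tl$akr_am[i],
                                         if (is.na(agsd)) 1 else agsd,
                                         params), n)
        lgsd <- if ("lf_gsd" %in% names(tl)) tl$lf_gsd[i] else NA
        lf_spec <- if (is.na(lgsd) || lgsd <= 1 || tl$lf_am[i] == 0)
          dist_point(tl$lf_am[i])
        else dist_tlnorm(tl$lf_am[i], lgsd, 0.6 * tl$lf_am[i],
                         1.7 * tl$lf_am[i])
        lf <- dist_sample(lf_spec, n)
        tot <- tot + akr * (tl$end_hour[i] - tl$start_hour[i]) * lf
      }
      d <- cg * tot
    }
    structure(d, subject = subject, pathway = "pripyat", seed = seed,
              class = "stochastic_doses")
  })
}

# deterministic Pripyat dose from central values
pripyat_dose_deterministic <- function(timeline, c_g, max_hour = Inf) {
  tl <- check_timeline(timeline)
  tl$end_hour <- pmin(tl$end_hour, max_hour)
  tl <- tl[tl$end_hour > tl$start_hour, , drop = FALSE]
  if (nrow(tl) == 0) return(0)
  c_g * sum(tl$akr_am * (tl$end_hour - tl$start_hour) * tl$lf_am)
}

#' Daily-averaged indoor location factor
#'
#' Occupancy-weights a daytime and a night-time (sleeping) location factor
#' into a daily average: `((24 - sleep) * day + sleep * night) / 24`.  With
#' the standard 8 h sleeping this reproduces the tabulated daily values for
#' Pripyat apartments (e.g. day 0.072 / night 0.0018 -> 0.049 on the 1st
#' floor of a five-storey building; day 0.038 / night 0.0001 -> 0.025 on
#' the 5th floor).
#'
#' @param day_lf,night_lf Location factors (>= 0).
#' @param sleep_hours Hours asleep per day, in `[0, 24]` (default 8).
#' @return Daily-averaged location factor.
#' @export
daily_average_lf <- function(day_lf, night_lf, sleep_hours = 8) {
  stopifnot(sleep_hours >= 0, sleep_hours <= 24,
            all(day_lf >= 0), all(night_lf >= 0))
  ((24 - sleep_hours) * day_lf + sleep_hours * night_lf) / 24
}

#' @export
print.stochastic_doses <- function(x, ...) {
  v <- as.numeric(x)
  cat(sprintf("stochastic doses: n=%d, pathway=%s, mean=%.4g mGy\n",
              length(v), attr(x, "pathway") %||% "?", mean(v)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
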