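#' Synthetic cohort generation
#'
#' Emulates the questionnaire-derived inputs of a trio study — mission
#' itineraries with lognormally uncertain air-kerma-rate fields, Pripyat
#' occupancy timelines, residence histories over settlements with realistic
#' deposition spreads, and diet records — with the statistical structure
#' the dose engines assume, so the whole pipeline runs with no external
#' data.  Exposure categories: A exposed father (cleanup worker), B exposed
#' mother (cleanup worker or Pripyat resident), C both exposed, D neither
#' exposed, E father a highly exposed early emergency worker.
#'
#' Dose-scale targeting is input-side only: the configured median doses are
#' turned into air-kerma-rate magnitudes and itinerary lengths via the
#' deterministic product model; doses are never back-solved.
#'
#' @name synthetic
NULL

#' Cohort generator configuration
#'
#' @param n_trios Named vector of trios per exposure category
#'   (default 71 A / 51 B / 59 C / 51 D / 66 E).
#' @param children_weights Relative frequencies of 1-, 2- and 3-child
#'   families (default 242/52/4).
#' @param dob_range Eligible date-of-birth range.
#' @param frac_born_by_1990 Fraction of children born 1990 or earlier
#'   (default 0.4).
#' @param mission_median Target median mission dose (mGy) by parent sex
#'   (father 144, mother 7.4).
#' @param pripyat_median Target median Pripyat residence dose (mGy)
#'   (father 7.2, mother 6.2).
#' @param multi_settlement_frac Fraction of parents with more than one
#'   residence location (default 0.23).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_trios = c(A = 71, B = 51, C = 59, D = 51, E = 66),
                          children_weights = c(242, 52, 4),
                          dob_range = as.Date(c("1987-03-14", "2005-07-15")),
                          frac_born_by_1990 = 0.4,
                          mission_median = c(father = 144, mother = 7.4),
                          pripyat_median = c(father = 7.2, mother = 6.2),
                          multi_settlement_frac = 0.23) {
  structure(list(n_trios = n_trios, children_weights = children_weights,
                 dob_range = dob_range,
                 frac_born_by_1990 = frac_born_by_1990,
                 mission_median = mission_median,
                 pripyat_median = pripyat_median,
                 multi_settlement_frac = multi_settlement_frac),
            class = "cohort_config")
}

#' Synthetic air-kerma-rate grid
#'
#' Positive rates declining in time following a two-exponential fallout
#' decay profile, with per-cell lognormal uncertainty (GSD within the
#' configured bounds).
#'
#' @param locations Character vector of location ids.
#' @param dates `Date` vector of grid dates.
#' @param base Named vector of per-location base rates (mGy/h) at the first
#'   date; unnamed values are recycled.
#' @param decay_profile Function of days-since-first-date returning the
#'   relative rate (default mixed 45-day / 800-day halftimes).
#' @param gsd_range Per-cell GSD bounds (default `c(1.2, 3.0)`).
#' @param seed RNG seed.
#' @return Data frame `location_id`, `date`, `akr_am`, `akr_gsd`.
#' @export
generate_akr_grid <- function(locations, dates, base = 1,
                              decay_profile = function(t)
                                0.7 * exp(-log(2) * t / 45) +
                                0.3 * exp(-log(2) * t / 800),
                              gsd_range = c(1.2, 3.0), seed = 1) {
  stopifnot(length(locations) > 0, length(dates) > 0)
  base <- rep_len(base, length(locations))
  dates <- sort(as.Date(dates))
  t <- as.numeric(dates - dates[1])
  with_substream(seed, "akr_grid", {
    g <- expand.grid(location_id = locations, date = dates,
                     stringsAsFactors = FALSE)
    g <- g[order(g$location_id, g$date), ]
    rownames(g) <- NULL
    attr(g, "out.attrs") <- NULL
    g$akr_am <- base[match(g$location_id, locations)] *
      decay_profile(as.numeric(g$date - dates[1]))
    g$akr_gsd <- stats::runif(nrow(g), gsd_range[1], gsd_range[2])
    g
  })
}

#' Synthetic residence history for one parent
#'
#' Non-overlapping, gap-free intervals covering `from` to `to` over 1-3
#' settlements drawn from the pool.
#'
#' @param parent_id Parent identifier.
#' @param settlements Settlement pool (data frame with `settlement_id`).
#' @param from,to Covered period (`Date`).
#' @param multi_frac Probability of residing in more than one settlement.
#' @param seed RNG seed.
#' @return Data frame `parent_id`, `settlement_id`, `start_date`,
#'   `end_date`, `house_type`, `zone`.
#' @export
generate_residence_history <- function(parent_id, settlements, from, to,
                                       multi_frac = 0.23, seed = 1) {
  stopifnot(nrow(settlements) > 0)
  with_substream(seed, paste0("residence/", parent_id), {
    k <- if (stats::runif(1) < multi_frac) sample(2:3, 1) else 1L
    k <- min(k, nrow(settlements))
    ids <- sample(settlements$settlement_id, k)
    cuts <- sort(sample(seq(2, max(2, as.numeric(to - from) - 1)),
                        k - 1L))
    starts <- c(from, from + cuts)
    ends <- c(from + cuts, to)
    data.frame(parent_id = parent_id, settlement_id = ids,
               start_date = starts, end_date = ends,
               house_type = sample(c("wooden", "brick_one", "brick_multi"),
                                   k, replace = TRUE,
                                   prob = c(0.45, 0.35, 0.2)),
               zone = sample(c("zone30", "other"), k, replace = TRUE,
                             prob = c(0.05, 0.95)),
               stringsAsFactors = FALSE)
  })
}

# settlement pool emulating the deposition spreads of the study regions
make_settlements <- function(seed) {
  regions <- data.frame(
    area = c("Kyiv-city", "Kyiv", "Chernihiv", "Zhytomir", "Ukraine-other",
             "Gomel", "Belarus-other", "Russia"),
    country = c("Ukraine", "Ukraine", "Ukraine", "Ukraine", "Ukraine",
                "Belarus", "Belarus", "Russia"),
    n = c(1, 8, 4, 4, 6, 4, 2, 3),
    lo = c(26, 3.0, 1.7, 3.0, 1.4, 12, 1.7, 1.0),
    hi = c(26, 6040, 155, 380, 120, 18530, 95, 62),
    stringsAsFactors = FALSE)
  with_substream(seed, "settlements", {
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      lcs <- exp(stats::runif(r$n, log(r$lo), log(r$hi)))
      data.frame(settlement_id = sprintf("S_%s_%02d", r$area, seq_len(r$n)),
                 country = r$country, area = r$area,
                 cs137_am = round(lcs, 2),
                 tf_am = round(exp(stats::rnorm(r$n, log(0.05), 0.4)), 4),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# mission itinerary + matching AKR locations for one parent
make_itinerary <- function(parent_id, role, category, seed, cfg) {
  with_substream(seed, paste0("itinerary/", parent_id), {
    early <- category == "E"
    n_days <- max(3L, round(exp(stats::rnorm(
      1, log(if (role == "father") 30 else 10), log(2) ))))
    start <- accident_date() +
      (if (early) sample(0:3, 1) else sample(5:120, 1))
    # the first itinerary day is the mission start itself
    dates <- start + c(0, sort(sample(1:(2 * n_days), n_days - 1)))
    pool <- if (early) "hot" else if (role == "father") "site" else "aux"
    data.frame(parent_id = parent_id, date = dates,
               location_id = sprintf("L_%s_%02d", pool, sample(1:8, n_days,
                                                               TRUE)),
               activity = sample(c("decontamination", "construction",
                                   "transport", "guard"), n_days, TRUE),
               duration_am_h = round(stats::runif(n_days, 6, 10), 1),
               duration_cv = 0.1,
               lf_am = round(stats::runif(n_days, 0.2, 0.45), 3),
               stringsAsFactors = FALSE)
  })
}

# hour-by-hour Pripyat occupancy until evacuation
make_pripyat_timeline <- function(parent_id, seed, outdoor_base, extreme = FALSE) {
  with_substream(seed, paste0("pripyat/", parent_id), {
    evac <- stats::runif(1, 30, 40)  # hours after the accident origin
    floor_lv <- sample(c(1, 3, 5), 1)
    lf_day <- c(`1` = 0.072, `3` = 0.047, `5` = 0.038)[[as.character(floor_lv)]]
    lf_night <- c(`1` = 0.0018, `3` = 0.0012,
                  `5` = 0.0001)[[as.character(floor_lv)]]
    akr0 <- outdoor_base * exp(stats::rnorm(1, 0, log(1.5)))
    rows <- list(); h <- 0
    while (h < evac) {
      # sleep 8 h, indoor day, a few outdoor hours per day-cycle
      segs <- rbind(
        data.frame(kind = "sleep", len = 8, lf = lf_night, lf_gsd = 1.3),
        data.frame(kind = "indoor", len = stats::runif(1, 10, 13),
                   lf = lf_day, lf_gsd = 1.3),
        data.frame(kind = "outdoor", len = stats::runif(1, 3, 6), lf = 1,
                   lf_gsd = NA))
      for (i in seq_len(nrow(segs))) {
        if (h >= evac) break
        e <- min(h + segs$len[i], evac)
        rows[[length(rows) + 1]] <- data.frame(
          parent_id = parent_id, start_hour = h, end_hour = e,
          location_kind = segs$kind[i],
          akr_am = akr0 * exp(-log(2) * (h / 24) / 3.5),
          akr_gsd = 1.5, lf_am = segs$lf[i], lf_gsd = segs$lf_gsd[i],
          stringsAsFactors = FALSE)
        h <- e
      }
    }
    tl <- do.call(rbind, rows)
    if (extreme) {
      # walk near the NPP: short, very high-rate outdoor exposure
      tl <- rbind(tl, data.frame(parent_id = parent_id,
                                 start_hour = max(tl$end_hour),
                                 end_hour = max(tl$end_hour) + 0.7,
                                 location_kind = "outdoor",
                                 akr_am = 600, akr_gsd = 1.8,
                                 lf_am = 1, lf_gsd = NA))
    }
    tl
  })
}

make_diet <- function(parent_id, seed) {
  with_substream(seed, paste0("diet/", parent_id), {
    urban <- stats::runif(1) < 0.3
    rows <- data.frame(
      parent_id = parent_id,
      foodstuff = c("milk", "milk_products", "meat", "potato", "root_veg",
                    "mushrooms"),
      rate_am = c(round(stats::runif(1, 0.2, 0.6), 3),
                  round(stats::runif(1, 0.05, 0.2), 3),
                  round(stats::runif(1, 0.1, 0.25), 3),
                  round(stats::runif(1, 0.2, 0.4), 3),
                  round(stats::runif(1, 0.05, 0.2), 3),
                  NA),
      source = c(if (urban) "shop" else "local", "local", "local", "local",
                 "local",
                 if (stats::runif(1) < 0.5) "local" else "none"),
      stringsAsFactors = FALSE)
    rows[rows$source != "none" | rows$foodstuff != "mushrooms", ]
  })
}

#' Generate a complete synthetic cohort bundle
#'
#' Produces every input table the dose engines consume: children, parents,
#' mission itineraries, an air-kerma-rate grid, Pripyat occupancy
#' timelines, residence histories, settlements and diet records.  Category
#' A fathers get itineraries; category B mothers get itineraries or Pripyat
#' timelines; category C both parents are exposed; category D neither;
#' category E fathers get early high-rate itineraries.  Deterministic under
#' `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed.
#' @param include_extremes Add two tail-scenario trios (an early worker at
#'   the damaged unit; a Pripyat mother walking near the plant).
#' @return A named list of data frames (the cohort bundle).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            include_extremes = FALSE) {
  cfg <- config
  settlements <- make_settlements(seed)

  # deterministic input-side calibration of AKR base magnitudes from the
  # configured median doses via the central product model; the factor 0.6
  # is the typical fallout-decay attenuation of the grid at mission dates
  site_base <- cfg$mission_median[["father"]] /
    (0.710 * 30 * 8 * 0.32 * 0.6)      # ~typical father mission
  aux_base <- cfg$mission_median[["mother"]] / (0.586 * 10 * 8 * 0.32 * 0.6)
  hot_base <- site_base * 12           # early emergency-work fields
  # Pripyat outdoor base from the occupancy mix (~5 outdoor h + indoor rest)
  prip_base_f <- cfg$pripyat_median[["father"]] / (0.710 * 8)
  prip_base_m <- cfg$pripyat_median[["mother"]] / (0.586 * 8)

  akr_dates <- seq(accident_date(), as.Date("1990-12-31"), by = "month")
  akr_grid <- rbind(
    generate_akr_grid(sprintf("L_site_%02d", 1:8), akr_dates,
                      base = site_base * exp(stats::qnorm(
                        (1:8) / 9) * log(1.6)), seed = seed + 11),
    generate_akr_grid(sprintf("L_aux_%02d", 1:8), akr_dates,
                      base = aux_base * exp(stats::qnorm(
                        (1:8) / 9) * log(1.6)), seed = seed + 12),
    generate_akr_grid(sprintf("L_hot_%02d", 1:8), akr_dates,
                      base = hot_base * exp(stats::qnorm(
                        (1:8) / 9) * log(1.6)), seed = seed + 13))

  cats <- rep(names(cfg$n_trios), cfg$n_trios)
  n_tr <- length(cats)
  with_substream(seed, "cohort/structure", {
    n_children <- sample(1:3, n_tr, TRUE, prob = cfg$children_weights)
    yr_lo <- 1987:1990
    yr_hi <- 1991:2005
    years_pool <- c(yr_lo, yr_hi)
    wts <- c(rep(cfg$frac_born_by_1990 / length(yr_lo), length(yr_lo)),
             rep((1 - cfg$frac_born_by_1990) / length(yr_hi), length(yr_hi)))
    dob_list <- lapply(seq_len(n_tr), function(i) {
      y <- sample(years_pool, n_children[i], TRUE, prob = wts)
      d <- as.Date(sprintf("%d-01-01", y)) + sample(0:364, n_children[i], TRUE)
      sort(pmin(pmax(d, cfg$dob_range[1]), cfg$dob_range[2]))
    })
  })

  children <- parents <- itineraries <- pripyat <- residences <- diets <-
    list()
  for (i in seq_len(n_tr)) {
    trio <- sprintf("T%03d", i)
    fid <- paste0(trio, "_F"); mid <- paste0(trio, "_M")
    cat_i <- cats[i]
    dobs <- dob_list[[i]]
    children[[i]] <- data.frame(
      child_id = sprintf("%s_C%d", trio, seq_along(dobs)), trio_id = trio,
      category = cat_i, dob = dobs, father_id = fid, mother_id = mid,
      stringsAsFactors = FALSE)

    f_mission <- cat_i %in% c("A", "C", "E")
    m_mission <- m_pripyat <- f_pripyat <- FALSE
    if (cat_i == "B") {
      m_mission <- with_substream(seed, paste0("bm/", trio),
                                  stats::runif(1) < 0.5)
      m_pripyat <- !m_mission
    } else if (cat_i == "C") {
      m_pripyat <- with_substream(seed, paste0("cm/", trio),
                                  stats::runif(1) < 0.6)
      m_mission <- !m_pripyat
      f_pripyat <- with_substream(seed, paste0("cf/", trio),
                                  stats::runif(1) < 0.3)
    }
    parents[[i]] <- data.frame(
      parent_id = c(fid, mid), sex = c("male", "female"),
      has_mission = c(f_mission, m_mission),
      has_pripyat = c(f_pripyat, m_pripyat), stringsAsFactors = FALSE)

    if (f_mission)
      itineraries[[paste0(fid, "i")]] <-
        make_itinerary(fid, "father", cat_i, seed, cfg)
    if (m_mission)
      itineraries[[paste0(mid, "i")]] <-
        make_itinerary(mid, "mother", cat_i, seed, cfg)
    if (f_pripyat)
      pripyat[[fid]] <- make_pripyat_timeline(fid, seed, prip_base_f)
    if (m_pripyat)
      pripyat[[mid]] <- make_pripyat_timeline(mid, seed, prip_base_m)

    # category D trios reside in low-deposition settlements only
    pool <- if (cat_i == "D")
      settlements[settlements$cs137_am <
                    stats::quantile(settlements$cs137_am, 0.5), ]
    else settlements
    horizon <- max(dobs) + 30
    for (pid in c(fid, mid)) {
      residences[[pid]] <- generate_residence_history(
        pid, pool, accident_date(), horizon, cfg$multi_settlement_frac, seed)
      diets[[pid]] <- make_diet(pid, seed)
    }
  }

  bundle <- list(children = do.call(rbind, children),
                 parents = do.call(rbind, parents),
                 itineraries = if (length(itineraries))
                   do.call(rbind, itineraries) else
                     data.frame(parent_id = character(), date = as.Date(character()),
                                location_id = character(), activity = character(),
                                duration_am_h = numeric(), duration_cv = numeric(),
                                lf_am = numeric()),
                 akr_grid = akr_grid,
                 pripyat = if (length(pripyat)) do.call(rbind, pripyat) else
                   data.frame(parent_id = character(), start_hour = numeric(),
                              end_hour = numeric(), location_kind = character(),
                              akr_am = numeric(), akr_gsd = numeric(),
                              lf_am = numeric(), lf_gsd = numeric()),
                 residences = do.call(rbind, residences),
                 settlements = settlements,
                 diets = do.call(rbind, diets))
  rownames(bundle$itineraries) <- rownames(bundle$pripyat) <- NULL
  rownames(bundle$residences) <- rownames(bundle$diets) <- NULL

  if (include_extremes) bundle <- add_extreme_trios(bundle, seed)
  bundle
}

# two tail-scenario trios: an emergency worker present at the damaged unit
# during the accident, and a Pripyat mother who walked near the plant
add_extreme_trios <- function(bundle, seed) {
  trio <- "TX01"; fid <- paste0(trio, "_F"); mid <- paste0(trio, "_M")
  dob <- as.Date("1988-06-15")
  bundle$children <- rbind(bundle$children, data.frame(
    child_id = paste0(trio, "_C1"), trio_id = trio, category = "E",
    dob = dob, father_id = fid, mother_id = mid, stringsAsFactors = FALSE))
  bundle$parents <- rbind(bundle$parents, data.frame(
    parent_id = c(fid, mid), sex = c("male", "female"),
    has_mission = c(TRUE, FALSE), has_pripyat = c(FALSE, TRUE),
    stringsAsFactors = FALSE))
  it <- data.frame(parent_id = fid,
                   date = accident_date() + 0:2,
                   location_id = "L_hot_01", activity = "emergency",
                   duration_am_h = 10, duration_cv = 0.1, lf_am = 0.6,
                   stringsAsFactors = FALSE)
  bundle$itineraries <- rbind(bundle$itineraries, it)
  bundle$pripyat <- rbind(bundle$pripyat,
                          make_pripyat_timeline(mid, seed,
                                                outdoor_base = 0.9,
                                                extreme = TRUE))
  for (pid in c(fid, mid)) {
    bundle$residences <- rbind(bundle$residences, generate_residence_history(
      pid, bundle$settlements, accident_date(), dob + 30, 0, seed))
    bundle$diets <- rbind(bundle$diets, make_diet(pid, seed))
  }
  bundle
}
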