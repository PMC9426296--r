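#' Monte Carlo orchestration of stochastic doses
#'
#' Mission and Pripyat external doses are propagated by plain Monte Carlo —
#' every parameter carries unshared (subject-dependent) error, since the
#' shared component of cleanup-site exposure is known to contribute less
#' than 1% of dose.  Residential pathways use two-dimensional Monte Carlo:
#' an outer loop draws one value per shared parameter (deposition density
#' and soil-to-milk transfer per settlement, deposition ratios per area,
#' behaviour factors, attenuation, conversion factors and intake-curve
#' scales globally) and every subject in the same scope sees the identical
#' realized value within that set; the inner step draws the unshared
#' parameters (individual outdoor-time variability, consumption rates,
#' ingestion dose factors) per subject, producing one dose per subject per
#' set.
#'
#' @name mc_engine
NULL

# realized deposition-ratio set for one area, honouring the correlation
# structure (Gaussian copula with the stated r; r = 1 anchored to the
# Cs-137 deposition itself means a deterministic fixed ratio).  Must be
# called with the RNG positioned in the desired substream.
draw_ratio_set <- function(nuclides = nuclide_table()) {
  nm <- nuclides$name
  ratios <- stats::setNames(nuclides$ratio_am, nm)
  z <- stats::setNames(rep(NA_real_, length(nm)), nm)
  has_spec <- !is.na(nuclides$ratio_rel_min)
  z[!has_spec] <- 0
  z[!is.na(nuclides$corr_r) & nuclides$corr_r == 1] <- 0  # fixed ratio
  repeat {
    todo <- which(is.na(z))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      anc <- nuclides$corr_anchor[i]
      if (is.na(anc)) {
        z[i] <- stats::qnorm(pclamp(stats::runif(1)))
        progressed <- TRUE
      } else if (!is.na(z[anc])) {
        r <- nuclides$corr_r[i]
        e <- stats::qnorm(pclamp(stats::runif(1)))
        z[i] <- r * z[anc] + sqrt(1 - r^2) * e
        progressed <- TRUE
      }
    }
    if (!progressed) stop("unresolvable correlation anchors in nuclide table")
  }
  for (i in which(has_spec & !(nm %in% c("Cs134", "Cs136")))) {
    spec <- dist_tri(nuclides$ratio_rel_min[i] * nuclides$ratio_am[i],
                     nuclides$ratio_am[i],
                     nuclides$ratio_rel_max[i] * nuclides$ratio_am[i])
    ratios[i] <- dist_quantile(spec, stats::pnorm(z[i]))
  }
  ratios
}

# one shared-parameter set: all scoped values drawn once; RNG must already
# be positioned in the set's substream
draw_shared_set <- function(settlements, params, nuclides) {
  rp <- params$residential
  sig <- vapply(seq_len(nrow(settlements)), function(i)
    dist_sample(sigma_spec(settlements$country[i], settlements$cs137_am[i],
                           params), 1), numeric(1))
  names(sig) <- settlements$settlement_id
  tf <- vapply(seq_len(nrow(settlements)), function(i)
    dist_sample(realize_spec(params$ingestion$tf_rel,
                             settlements$tf_am[i]), 1), numeric(1))
  names(tf) <- settlements$settlement_id
  areas <- sort(unique(settlements$area))
  ratios <- lapply(areas, function(a) draw_ratio_set(nuclides))
  names(ratios) <- areas
  bf <- lapply(names(rp$behaviour_factor$central), function(ht) {
    ct <- rp$behaviour_factor$central[[ht]]
    sp <- rp$behaviour_factor$spec[[ht]]
    c(zone30 = dist_sample(realize_spec(sp, ct[["zone30"]]), 1),
      other = dist_sample(realize_spec(sp, ct[["other"]]), 1))
  })
  names(bf) <- names(rp$behaviour_factor$central)
  atten <- list(p1 = dist_sample(rp$attenuation$p1, 1),
                lambda1 = dist_sample(rp$attenuation$lambda1, 1),
                lambda2 = dist_sample(rp$attenuation$lambda2, 1))
  cf <- lapply(params$ingestion$cf, dist_sample, n = 1)
  scales <- c(dist_sample(realize_spec(params$ingestion$period1_scale, 1), 1),
              dist_sample(realize_spec(params$ingestion$period2_scale, 1), 1))
  list(sigma = sig, tf = tf, ratios = ratios, bf = bf, atten = atten,
       cf = cf, scales = scales)
}

#' Plain (all-unshared) Monte Carlo for mission / Pripyat doses
#'
#' @param bundle Cohort bundle (see [generate_cohort()] /
#'   [validate_bundle()]).
#' @param parent_id Parent identifier.
#' @param pathway `"mission"` or `"pripyat"`.
#' @param window_end Window end date for dose truncation.
#' @param n Number of realizations (study default 10000).
#' @param seed Master seed.
#' @param params Parameter library.
#' @return A `stochastic_doses` vector; if the parent lacks the pathway,
#'   `n` zeros flagged with attribute `structural_zero = TRUE`.
#' @export
run_unshared_mc <- function(bundle, parent_id, pathway = c("mission", "pripyat"),
                            window_end, n = 10000, seed = 1,
                            params = default_parameters()) {
  pathway <- match.arg(pathway)
  prow <- bundle$parents[bundle$parents$parent_id == parent_id, , drop = FALSE]
  if (nrow(prow) != 1) stop("unknown parent: ", parent_id)
  cgs <- cg_spec(prow$sex, params)
  if (pathway == "mission") {
    it <- bundle$itineraries[bundle$itineraries$parent_id == parent_id, ,
                             drop = FALSE]
    if (nrow(it) == 0)
      return(structure(rep(0, n), structural_zero = TRUE, subject = parent_id,
                       pathway = pathway, seed = seed,
                       class = "stochastic_doses"))
    cutoff <- mission_cutoff(window_end, max(as.Date(it$date)) + 1L)
    mission_dose_stochastic(it, bundle$akr_grid, cgs, cutoff, n, seed,
                            subject = parent_id, params = params)
  } else {
    tl <- bundle$pripyat[bundle$pripyat$parent_id == parent_id, , drop = FALSE]
    if (nrow(tl) == 0)
      return(structure(rep(0, n), structural_zero = TRUE, subject = parent_id,
                       pathway = pathway, seed = seed,
                       class = "stochastic_doses"))
    max_hour <- days_since_accident(window_end) * 24
    pripyat_dose(tl, cgs, n, seed, subject = parent_id, max_hour = max_hour,
                 params = params)
  }
}

#' Two-dimensional Monte Carlo for residential pathways
#'
#' Outer loop over `n_sets` shared-parameter sets, inner draw of unshared
#' parameters per subject; both preconception windows (DOB-51, DOB-38) are
#' evaluated with common random numbers, so DOB-38 >= DOB-51 holds per
#' realization.  Within any set, subjects resident in the same settlement
#' share the identical realized deposition density and soil-to-milk
#' transfer; subjects in the same area share the realized deposition
#' ratios.
#'
#' @param bundle Cohort bundle.
#' @param pathway `"residential_external"` or `"residential_ingestion"`.
#' @param n_sets Number of shared-parameter sets (study default 1000).
#' @param seed Master seed.
#' @param params Parameter library.
#' @param nuclides Nuclide table ([nuclide_table()]); pass an edited table
#'   to change the inventory or switch off ratio uncertainty.
#' @return An object of class `mc2d_result`: list with `subjects` (one row
#'   per child x parent role), `doses` (list `DOB51`, `DOB38` of
#'   subjects-by-sets matrices, mGy), `sigma` and `tf` (settlements-by-sets
#'   matrices of realized shared values), `pathway`, `n_sets`, `seed`.
#' @export
run_2d_mc <- function(bundle,
                      pathway = c("residential_external",
                                  "residential_ingestion"),
                      n_sets = 1000, seed = 1,
                      params = default_parameters(),
                      nuclides = nuclide_table()) {
  pathway <- match.arg(pathway)
  stopifnot(n_sets >= 1)
  stl <- bundle$settlements
  bad <- setdiff(bundle$residences$settlement_id, stl$settlement_id)
  if (length(bad))
    stop("residence records reference unknown settlement(s): ",
         paste(unique(bad), collapse = ", "))
  np <- prep_nuclides(nuclides)
  basis <- make_ingestion_basis(make_intake_curves(), nuclides)
  curves <- make_intake_curves()

  ch <- bundle$children
  subjects <- rbind(
    data.frame(child_id = ch$child_id, role = "father",
               parent_id = ch$father_id, dob = as.Date(ch$dob),
               stringsAsFactors = FALSE),
    data.frame(child_id = ch$child_id, role = "mother",
               parent_id = ch$mother_id, dob = as.Date(ch$dob),
               stringsAsFactors = FALSE))
  subjects$sex <- bundle$parents$sex[match(subjects$parent_id,
                                           bundle$parents$parent_id)]
  ns <- nrow(subjects)

  res_by_parent <- split(bundle$residences,
                         bundle$residences$parent_id)
  diet_by_parent <- split(bundle$diets, bundle$diets$parent_id)
  win51 <- days_since_accident(window_end(subjects$dob, 51))
  win38 <- days_since_accident(window_end(subjects$dob, 38))

  d51 <- matrix(0, ns, n_sets)
  d38 <- matrix(0, ns, n_sets)
  sig_m <- matrix(NA_real_, nrow(stl), n_sets,
                  dimnames = list(stl$settlement_id, NULL))
  tf_m <- sig_m

  for (s in seq_len(n_sets)) {
    shared <- with_substream(seed, paste0("2d/", pathway, "/shared/", s),
                             draw_shared_set(stl, params, nuclides))
    sig_m[, s] <- shared$sigma
    tf_m[, s] <- shared$tf
    for (k in seq_len(ns)) {
      pid <- subjects$parent_id[k]
      res <- res_by_parent[[pid]]
      if (is.null(res) || nrow(res) == 0) next
      un <- with_substream(
        seed, paste0("2d/", pathway, "/unshared/", s, "/",
                     subjects$child_id[k], "/", subjects$role[k]), {
        diet <- diet_by_parent[[pid]]
        iv <- dist_sample(params$residential$iv, 1)
        rates <- if (!is.null(diet) && nrow(diet) > 0) {
          diet <- diet[order(diet$foodstuff), , drop = FALSE]
          r <- vapply(seq_len(nrow(diet)), function(j) {
            if (diet$foodstuff[j] == "mushrooms" && is.na(diet$rate_am[j]))
              dist_sample(params$ingestion$mushroom_yes, 1)
            else dist_sample(realize_spec(params$ingestion$consumption_rel,
                                          diet$rate_am[j]), 1)
          }, numeric(1))
          transform(diet, rate = r)
        } else NULL
        dfa <- params$ingestion$df_am[[subjects$sex[k]]]
        df <- c(Cs134 = dist_sample(realize_spec(params$ingestion$df_rel,
                                                 dfa[["Cs134"]]), 1),
                Cs137 = dist_sample(realize_spec(params$ingestion$df_rel,
                                                 dfa[["Cs137"]]), 1))
        list(iv = iv, rates = rates, df = df)
      })
      dcv <- if (subjects$sex[k] == "male") np$dc_male else np$dc_female
      acc51 <- 0; acc38 <- 0
      for (j in seq_len(nrow(res))) {
        sid <- res$settlement_id[j]
        srow <- match(sid, stl$settlement_id)
        a0 <- max(days_since_accident(res$start_date[j]), 0)
        b0 <- days_since_accident(res$end_date[j])
        for (w in 1:2) {
          b <- min(b0, if (w == 1) win51[k] else win38[k])
          if (b <= a0) next
          d <- if (pathway == "residential_external") {
            bfv <- shared$bf[[res$house_type[j]]][[res$zone[j]]]
            f <- res_ext_unit_integral(a0, b, shared$ratios[[stl$area[srow]]],
                                       shared$atten, np)
            bfv * un$iv * shared$sigma[[sid]] * sum(dcv[np$name] * f)
          } else {
            if (is.null(un$rates)) 0 else {
              ii <- intake_integral(a0, b, un$rates, shared$cf,
                                    shared$tf[[sid]], curves, shared$scales,
                                    params$ingestion$cs134_ratio, nuclides,
                                    basis)
              shared$sigma[[sid]] *
                (un$df[["Cs134"]] * ii$Cs134 + un$df[["Cs137"]] * ii$Cs137)
            }
          }
          if (w == 1) acc51 <- acc51 + d else acc38 <- acc38 + d
        }
      }
      d51[k, s] <- acc51
      d38[k, s] <- acc38
    }
  }
  structure(list(subjects = subjects,
                 doses = list(DOB51 = d51, DOB38 = d38),
                 sigma = sig_m, tf = tf_m, pathway = pathway,
                 n_sets = n_sets, seed = seed),
            class = "mc2d_result")
}

#' @export
print.mc2d_result <- function(x, ...) {
  cat(sprintf("2D Monte Carlo result: %s, %d subjects x %d sets\n",
              x$pathway, nrow(x$subjects), x$n_sets))
  invisible(x)
}

#' Central estimate of a stochastic dose distribution
#'
#' The arithmetic mean of the individual stochastic dose realizations.
#'
#' @param doses Numeric vector of realizations (nonempty).
#' @return Mean dose (mGy).
#' @export
central_estimate <- function(doses) {
  if (length(doses) == 0) stop("empty dose vector")
  mean(as.numeric(doses))
}

#' Pathway dose summary for one subject
#'
#' @param realizations Stochastic dose vector.
#' @param pathway Pathway tag.
#' @param window Window kind (`"DOB51"`/`"DOB38"`).
#' @return A `pathway_dose` object: central estimate (arithmetic mean of
#'   the realizations), GSD (NA when any realization is zero — structurally
#'   unexposed or empty-window subjects carry no GSD), realization count.
#' @export
pathway_dose <- function(realizations, pathway, window) {
  r <- as.numeric(realizations)
  structure(list(pathway = pathway, window = window,
                 central = central_estimate(r),
                 gsd = if (all(r > 0) && length(r) >= 2) empirical_gsd(r)
                       else NA_real_,
                 n = length(r),
                 structural_zero = isTRUE(attr(realizations,
                                               "structural_zero"))),
            class = "pathway_dose")
}

#' @export
print.pathway_dose <- function(x, ...) {
  cat(sprintf("%s %s: %.4g mGy (GSD %s, n=%d)\n", x$pathway, x$window,
              x$central, ifelse(is.na(x$gsd), "-", sprintf("%.3g", x$gsd)),
              x$n))
  invisible(x)
}

#' Total parental gonadal dose across pathways
#'
#' Sum of the per-pathway central estimates (arithmetic means); missing
#' pathways contribute zero, duplicated pathways are an error.
#'
#' @param pathway_doses List of [pathway_dose] objects (or a named numeric
#'   vector of central estimates, names = pathways).
#' @return Total dose (mGy).
#' @export
total_parent_dose <- function(pathway_doses) {
  if (length(pathway_doses) == 0) return(0)
  if (is.numeric(pathway_doses)) {
    pw <- names(pathway_doses)
    vals <- pathway_doses
  } else {
    pw <- vapply(pathway_doses, function(p) p$pathway, character(1))
    vals <- vapply(pathway_doses, function(p) p$central, numeric(1))
  }
  if (anyDuplicated(pw)) stop("duplicate pathway in dose list")
  sum(vals)
}
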