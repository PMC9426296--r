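#' Relative distribution templates
#'
#' Most parameter uncertainties in the dosimetry tables are expressed
#' relative to a central value taken from a database (e.g.
#' `TR(0.75*AM, AM, 1.25*AM)` for a consumption rate, or
#' `TLN(0.96*AM, 1.4, 0.5*GM, 2.0*GM)` for a deposition density).  A
#' `rel_spec` stores the family and the relative factors; [realize_spec()]
#' composes it with a central value into a concrete [dist_spec].  A
#' `"point"` template makes any parameter degenerate, which is how shared
#' uncertainties are switched off in collapse tests.
#'
#' @param family One of `"point"`, `"U"`, `"TR"`, `"TN"`, `"TLN"`.
#' @param ... Family-specific relative factors: `min`/`max` (times AM) for
#'   `U`; `min`/`max` (times AM, mode = AM) for `TR`; `sd` (times AM, bounds
#'   AM +/- 2 SD) for `TN`; `gm` (times AM), `gsd`, `min`/`max` (times GM)
#'   for `TLN`.
#' @return An object of class `rel_spec`.
#' @export
rel_spec <- function(family = c("point", "U", "TR", "TN", "TLN"), ...) {
  family <- match.arg(family)
  structure(c(list(family = family), list(...)), class = "rel_spec")
}

#' Compose a relative template with a central value
#'
#' @param rel A [rel_spec].
#' @param am Central (arithmetic mean) value.
#' @return A concrete [dist_spec].
#' @export
realize_spec <- function(rel, am) {
  stopifnot(inherits(rel, "rel_spec"))
  switch(rel$family,
    point = dist_point(am),
    U = dist_unif(rel$min * am, rel$max * am),
    TR = dist_tri(rel$min * am, am, rel$max * am),
    TN = dist_tnorm(am, rel$sd * am),
    TLN = {
      gm <- if (is.null(rel$gm)) am else rel$gm * am
      dist_tlnorm(gm, rel$gsd, rel$min * gm, rel$max * gm)
    })
}

#' Embedded radionuclide inventory for residential external dose
#'
#' The ground-deposition inventory driving external dose in contaminated
#' settlements: 19 gamma-emitting radionuclides with half-lives from
#' standard decay data, decay-product links (Zr-95 -> Nb-95,
#' Te-132 -> I-132, Ba-140 -> La-140), deposition-activity ratios to Cs-137
#' at the accident date, the relative width class of each ratio's
#' triangular uncertainty, and the correlation structure between ratios.
#'
#' Ratios and ground-shine dose-rate coefficients are *representative*
#' defaults (the study's own values come from non-public databases); every
#' oracle test in the package is constructed to be independent of their
#' absolute magnitudes, and users can pass an edited table to any engine
#' function.  Dose-rate coefficients `dc_male`/`dc_female` are gonadal
#' absorbed dose rate per unit areal activity (mGy/day per kBq/m^2).
#'
#' @return A data.frame, one row per radionuclide.
#' @export
nuclide_table <- function() {
  hl_d <- function(years = 0, days = 0, hours = 0)
    years * 365.25 + days + hours / 24
  tab <- data.frame(
    name = c("Zr95", "Nb95", "Mo99", "Ru103", "Ru106", "Te131m", "Te132",
             "I131", "I132", "I133", "I135", "Cs134", "Cs136", "Cs137",
             "Ba140", "La140", "Ce141", "Ce144", "Np239"),
    half_life_d = c(hl_d(days = 64.03), hl_d(days = 34.99),
                    hl_d(hours = 65.98), hl_d(days = 39.25),
                    hl_d(days = 371.8), hl_d(hours = 30.0),
                    hl_d(days = 3.20), hl_d(days = 8.02),
                    hl_d(hours = 2.30), hl_d(hours = 20.83),
                    hl_d(hours = 6.58), hl_d(years = 2.065),
                    hl_d(days = 13.16), hl_d(years = 30.05),
                    hl_d(days = 12.75), hl_d(days = 1.678),
                    hl_d(days = 32.5), hl_d(days = 284.9),
                    hl_d(days = 2.356)),
    parent = c(NA, "Zr95", NA, NA, NA, NA, NA,
               NA, "Te132", NA, NA, NA, NA, NA,
               NA, "Ba140", NA, NA, NA),
    ratio_am = c(1.5, 1.5, 2.0, 3.0, 0.7, 1.0, 8.0,
                 10.0, 8.0, 5.0, 2.0, 0.5, 0.25, 1.0,
                 2.5, 2.5, 1.4, 1.0, 10.0),
    # half-width class of the triangular ratio uncertainty
    ratio_rel_min = c(0.80, 0.80, 0.75, 0.75, 0.75, 0.85, 0.85,
                      0.85, 0.85, 0.85, 0.85, NA, NA, NA,
                      0.75, 0.75, 0.80, 0.80, 0.75),
    ratio_rel_max = c(1.20, 1.20, 1.25, 1.25, 1.25, 1.15, 1.15,
                      1.15, 1.15, 1.15, 1.15, NA, NA, NA,
                      1.25, 1.25, 1.20, 1.20, 1.25),
    # Gaussian-copula anchor for the ratio draw, and the stated r;
    # Cs-134/136 are locked (r = 1) to the Cs-137 deposition itself
    corr_anchor = c(NA, "Zr95", NA, NA, "Ru103", NA, NA,
                    NA, "Te132", "I131", "I131", "Cs137", "Cs137", NA,
                    "La140", NA, "Ce144", "Zr95", NA),
    corr_r = c(NA, 0.95, NA, NA, 0.90, NA, NA,
               NA, 0.95, 0.90, 0.90, 1.0, 1.0, NA,
               0.95, NA, 0.90, 0.95, NA),
    # representative air-kerma-rate coefficients (nGy/h per kBq/m^2)
    akr_coef = c(2.0, 2.1, 0.4, 1.3, 0.6, 3.9, 0.6,
                 1.0, 6.2, 1.6, 4.5, 4.2, 5.8, 1.6,
                 0.5, 6.4, 0.2, 0.15, 0.4),
    stringsAsFactors = FALSE)
  # kerma -> gonadal absorbed dose (0.3 MeV isotropic), per day
  tab$dc_male <- tab$akr_coef * 1e-6 * 24 * 0.710
  tab$dc_female <- tab$akr_coef * 1e-6 * 24 * 0.586
  tab$lambda_d <- log(2) / tab$half_life_d
  tab
}

#' Default parameter library
#'
#' All distributional assumptions of the uncertainty model in one editable
#' list, grouped by engine, each entry a [rel_spec] (or concrete
#' [dist_spec]) with its shared/unshared role documented here:
#'
#' * `mission` (all **unshared**): task duration `U((1-CV)AM, (1+CV)AM)`
#'   with default CV 0.1; air kerma rate `TLN(GM, GSD, GM/GSD^2, GM*GSD^2)`
#'   with GM from [gm_from_am_gsd()]; Chornobyl-site location factor
#'   `TN(AM, 0.25 AM, AM +/- 2 SD)`; kerma-to-gonad conversion coefficient
#'   `TN(AM, 0.1 AM, AM +/- 2 SD)` with AM 0.710 (male) / 0.586 (female);
#'   Pripyat location factor `TLN(GM, 1.3, 0.6 GM, 1.7 GM)`.
#' * `residential` shared: settlement Cs-137 deposition density (TLN, scope
#'   = settlement, country-dependent form with a 185 kBq/m^2 threshold for
#'   Belarus); deposition ratios (TR, scope = area); behaviour factors (TR,
#'   global) by house type and zone; attenuation-function parameters
#'   (global); foodstuff-to-milk conversion factors (U, global); period-1
#'   milk-concentration and period-2 relative-concentration scale factors
#'   (TR, global); soil-to-milk transfer (TR, scope = settlement).
#' * `residential` unshared: individual outdoor-time variability
#'   `U(0.7, 1.3)`; consumption rates `TR(0.75 AM, AM, 1.25 AM)`; mushroom
#'   rate `U(0.010, 0.030)` kg/day when reported only as yes; ingestion
#'   dose factors `TLN(AM, 1.3, 0.4 AM, 1.7 AM)`.
#'
#' @param gm_formula `"standard"` (`GM = AM exp(-(ln GSD)^2/2)`) or
#'   `"printed"` (no 1/2 factor) for deriving lognormal GMs from AMs.
#' @return A nested list; pass (possibly edited) to the engines.
#' @export
default_parameters <- function(gm_formula = c("standard", "printed")) {
  gm_formula <- match.arg(gm_formula)
  list(
    gm_formula = gm_formula,
    mission = list(
      duration_cv_default = 0.1,
      lf_sd_frac = 0.25,
      cg_sd_frac = 0.1,
      cg_am = c(male = 0.710, female = 0.586),
      pripyat_lf_gsd = 1.3
    ),
    residential = list(
      sigma = list(
        # TLN(gm_factor * AM, gsd, min_factor * GM, max_factor * GM)
        narrow = rel_spec("TLN", gm = 0.96, gsd = 1.4, min = 0.5, max = 2.0),
        wide = rel_spec("TLN", gm = 0.90, gsd = 1.6, min = 0.4, max = 2.6),
        belarus_threshold = 185  # kBq/m^2
      ),
      behaviour_factor = list(
        central = list(
          wooden = c(zone30 = 0.34, other = 0.28),
          brick_one = c(zone30 = 0.24, other = 0.21),
          brick_multi = c(zone30 = 0.15, other = 0.13)),
        spec = list(
          wooden = rel_spec("TR", min = 0.8, max = 1.2),
          brick_one = rel_spec("TR", min = 0.8, max = 1.2),
          brick_multi = rel_spec("TR", min = 0.7, max = 1.3))
      ),
      attenuation = list(
        p1 = dist_unif(0.35, 0.45),
        lambda1 = dist_tri(1.17e-3, 1.27e-3, 1.39e-3),
        lambda2 = dist_tri(3.2e-5, 3.8e-5, 4.7e-5)
      ),
      iv = dist_unif(0.7, 1.3),
      ratio_rel = rel_spec("TR", min = 0.8, max = 1.2)  # overridden per nuclide
    ),
    ingestion = list(
      cf = list(
        milk_local = dist_point(1),
        milk_shop = dist_unif(0.9, 1),
        milk_products = dist_unif(0.5, 0.9),
        meat = dist_unif(0.8, 1),
        potato = dist_unif(0.12, 0.24),
        root_veg = dist_unif(0.12, 0.24),
        mushrooms = dist_unif(5, 15)
      ),
      consumption_rel = rel_spec("TR", min = 0.75, max = 1.25),
      mushroom_yes = dist_unif(0.010, 0.030),     # kg/day
      period1_scale = rel_spec("TR", min = 0.7, max = 1.3),
      period2_scale = rel_spec("TR", min = 0.7, max = 1.3),
      tf_rel = rel_spec("TR", min = 0.6, max = 1.4),
      # TLN(GM = AM, GSD, 0.4 AM, 1.7 AM)
      df_rel = rel_spec("TLN", gsd = 1.3, min = 0.4, max = 1.7),
      # gonadal dose per unit ingested activity, mGy/Bq (representative)
      df_am = list(male = c(Cs134 = 1.9e-5, Cs137 = 1.3e-5),
                   female = c(Cs134 = 2.1e-5, Cs137 = 1.4e-5)),
      cs134_ratio = 0.5  # Cs-134/Cs-137 deposition activity ratio at origin
    )
  )
}

#' Settlement Cs-137 deposition-density spec
#'
#' Selects the country- and level-dependent truncated-lognormal form for a
#' settlement's Cs-137 deposition density: Ukraine and low-deposition
#' Belarus use `TLN(0.96 AM, 1.4, 0.5 GM, 2.0 GM)`; Belarus at or above the
#' 185 kBq/m^2 threshold and Russia use `TLN(0.9 AM, 1.6, 0.4 GM, 2.6 GM)`.
#'
#' @param country `"Ukraine"`, `"Belarus"` or `"Russia"`.
#' @param am Central deposition density (kBq/m^2).
#' @param params Parameter library ([default_parameters()]).
#' @return A [dist_spec].
#' @export
sigma_spec <- function(country, am, params = default_parameters()) {
  sg <- params$residential$sigma
  wide <- country == "Russia" ||
    (country == "Belarus" && am >= sg$belarus_threshold)
  realize_spec(if (wide) sg$wide else sg$narrow, am)
}

#' Serialize / load a parameter library as JSON
#'
#' @param params Parameter library list.
#' @param path File path.
#' @return `read_parameters` returns the parameter library.
#' @export
write_parameters <- function(params, path) {
  jsonlite::write_json(unclass_specs(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  reclass_specs(jsonlite::read_json(path, simplifyVector = TRUE))
}

unclass_specs <- function(x) {
  if (inherits(x, "dist_spec"))
    return(c(list(.spec = "dist"), list(family = x$family), x$params))
  if (inherits(x, "rel_spec"))
    return(c(list(.spec = "rel"), unclass(x)))
  if (is.list(x)) return(lapply(x, unclass_specs))
  # keep names of atomic vectors by serializing them as JSON objects
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

reclass_specs <- function(x) {
  if (is.list(x) && !is.null(x$.spec)) {
    if (x$.spec == "rel")
      return(structure(x[setdiff(names(x), ".spec")], class = "rel_spec"))
    fam <- x$family
    pr <- x[setdiff(names(x), c(".spec", "family"))]
    return(new_dist_spec(fam, pr))
  }
  if (is.list(x)) return(lapply(x, reclass_specs))
  x
}
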