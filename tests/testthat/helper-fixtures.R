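# small in-code fixtures shared across test files

flat_grid <- function(loc = "L1", akr = 1, gsd = 1,
                      date = as.Date("1986-05-01")) {
  data.frame(location_id = loc, date = date, akr_am = akr, akr_gsd = gsd,
             stringsAsFactors = FALSE)
}

one_entry <- function(date = as.Date("1986-06-01"), loc = "L1",
                      dur = 1, cv = 0, lf = 1) {
  data.frame(date = date, location_id = loc, activity = "work",
             duration_am_h = dur, duration_cv = cv, lf_am = lf,
             stringsAsFactors = FALSE)
}

tiny_cohort <- function(seed = 42)
  generate_cohort(cohort_config(n_trios = c(A = 2, B = 1, C = 1, D = 1,
                                            E = 1)), seed = seed)

far_window <- function() exposure_window(as.Date("2004-01-01"), "DOB38")

# parameter library with every shared residential/ingestion uncertainty
# switched off (point specs); unshared specs untouched
degenerate_shared_params <- function() {
  p <- default_parameters()
  p$residential$sigma$narrow <- rel_spec("point")
  p$residential$sigma$wide <- rel_spec("point")
  for (ht in names(p$residential$behaviour_factor$spec))
    p$residential$behaviour_factor$spec[[ht]] <- rel_spec("point")
  p$residential$attenuation <- list(p1 = dist_point(0.4),
                                    lambda1 = dist_point(1.27e-3),
                                    lambda2 = dist_point(3.8e-5))
  p$ingestion$cf <- lapply(p$ingestion$cf, function(s) dist_point(dist_mean(s)))
  p$ingestion$period1_scale <- rel_spec("point")
  p$ingestion$period2_scale <- rel_spec("point")
  p$ingestion$tf_rel <- rel_spec("point")
  p
}

# nuclide table with ratio uncertainty switched off
fixed_ratio_nuclides <- function() {
  nt <- nuclide_table()
  nt$ratio_rel_min <- NA_real_
  nt$ratio_rel_max <- NA_real_
  nt
}
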