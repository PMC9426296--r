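#' Reporting tables for reconstructed doses
#'
#' Mirrors the study's reporting surfaces: per-pathway dose-interval
#' distributions, the DOB-51 x DOB-38 cross-tabulation, GSD distribution
#' tables and dose vs birth-year correlations.  Percentages are printed to
#' one decimal with half-up rounding; medians use the lower-interpolation
#' convention for even n.
#'
#' @name reporting
NULL

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

median_lower <- function(x) {
  x <- sort(x)
  x[max(1L, floor((length(x) + 1) / 2))]
}

#' Dose-interval summary for one pathway
#'
#' Bins a dose vector into the seven reporting intervals and tabulates
#' count, percent and arithmetic mean per bin, plus an entire-study row.
#'
#' @param doses Dose vector (mGy); subset upstream (e.g. exposed-only vs
#'   including-zero) per the table's footnote conventions.
#' @return A data.frame with columns `bin`, `n`, `percent`, `mean_mGy`,
#'   `median_mGy`.
#' @export
pathway_summary <- function(doses) {
  bins <- dose_category(doses)
  n <- as.vector(table(bins))
  out <- data.frame(bin = levels(bins), n = n,
                    percent = round_half_up(100 * n / length(doses)),
                    mean_mGy = as.vector(tapply(doses, bins, mean)),
                    median_mGy = as.vector(tapply(doses, bins, median_lower)),
                    stringsAsFactors = FALSE)
  rbind(out,
        data.frame(bin = "Entire study", n = length(doses), percent = 100,
                   mean_mGy = mean(doses), median_mGy = median_lower(doses)))
}

#' Cross-tabulation of DOB-51 and DOB-38 dose categories
#'
#' 7 x 7 matrix of child counts, rows = DOB-51 bin, columns = DOB-38 bin.
#' With common random numbers across windows all mass lies on or above the
#' diagonal (the DOB-38 dose can only be larger).
#'
#' @param dose51,dose38 Paired dose vectors (same children, same order).
#' @return An integer matrix with dimnames of the dose-interval labels.
#' @export
crosstab_windows <- function(dose51, dose38) {
  if (length(dose51) != length(dose38))
    stop("dose vectors must be paired by child")
  b51 <- dose_category(dose51)
  b38 <- dose_category(dose38)
  table(DOB51 = b51, DOB38 = b38)
}

gsd_bin_breaks <- c(1, 1.3, 1.5, 2, 2.5, 3, 3.5, Inf)
gsd_bin_labels <- c("<1.3", "1.3-1.49", "1.5-1.99", "2-2.49", "2.5-2.99",
                    "3-3.49", ">=3.5")

#' GSD distribution table
#'
#' Tabulates the GSDs attached to individual stochastic doses into the
#' seven reporting intervals together with the mean central dose per
#' interval.  Only subjects with nonzero dose carry a GSD; filter upstream.
#'
#' @param gsd Vector of per-subject GSDs (>= 1).
#' @param doses Matching central dose estimates (mGy).
#' @return Data.frame `bin`, `n`, `percent`, `mean_dose_mGy` plus an
#'   entire-study row.
#' @export
gsd_table <- function(gsd, doses) {
  stopifnot(length(gsd) == length(doses))
  keep <- !is.na(gsd)
  gsd <- gsd[keep]; doses <- doses[keep]
  if (any(gsd < 1)) stop("GSD must be >= 1")
  bins <- cut(gsd, gsd_bin_breaks, labels = gsd_bin_labels, right = FALSE,
              include.lowest = TRUE)
  n <- as.vector(table(bins))
  out <- data.frame(bin = gsd_bin_labels, n = n,
                    percent = round_half_up(100 * n / length(gsd)),
                    mean_dose_mGy = as.vector(tapply(doses, bins, mean)),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(bin = "Entire study", n = length(gsd), percent = 100,
                        mean_dose_mGy = mean(doses)))
}

#' Correlation between parental dose and child's birth year
#'
#' Pearson correlation of dose (linear or log scale) with year of birth,
#' with the two-sided p-value from the t transform.  On the log scale,
#' zero doses are dropped (with a message giving the count).
#'
#' @param doses Dose vector (mGy).
#' @param dobs Child dates of birth (`Date`).
#' @param scale `"linear"` or `"log"`.
#' @return List with `r`, `p_value`, `n`.
#' @export
dose_birthyear_correlation <- function(doses, dobs,
                                       scale = c("linear", "log")) {
  scale <- match.arg(scale)
  year <- as.integer(format(as.Date(dobs), "%Y"))
  if (scale == "log") {
    drop <- doses <= 0
    if (any(drop)) message(sum(drop), " zero dose(s) excluded on log scale")
    doses <- log(doses[!drop]); year <- year[!drop]
  }
  if (length(doses) < 3) stop("need at least 3 paired observations")
  if (stats::sd(doses) == 0 || stats::sd(year) == 0)
    stop("degenerate variance")
  ct <- stats::cor.test(doses, year, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(doses))
}
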