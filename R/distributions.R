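#' Parametric distribution specifications
#'
#' The uncertainty model uses four parametric families, following the
#' notation of environmental-dosimetry parameter tables:
#' `U(min, max)` uniform, `TR(min, mode, max)` triangular,
#' `TN(AM, SD, min, max)` truncated normal and `TLN(GM, GSD, min, max)`
#' truncated lognormal, plus a degenerate point mass.  Sampling is by
#' inverse CDF on the truncated quantile range (never rejection), so the
#' number of uniform deviates consumed per draw is deterministic — a
#' requirement for reproducible substreams.
#'
#' @param value Point-mass value.
#' @param min,max Support bounds.
#' @param mode Triangular mode.
#' @param mean,sd Normal mean (AM) and standard deviation before truncation.
#' @param gm,gsd Geometric mean and geometric standard deviation of the
#'   lognormal before truncation (`gsd >= 1`).
#' @return An object of class `dist_spec`.
#' @name dist_spec
NULL

new_dist_spec <- function(family, params) {
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  stopifnot(is.finite(value))
  new_dist_spec("point", list(value = value))
}

#' @rdname dist_spec
#' @export
dist_unif <- function(min, max) {
  if (min > max) stop("min > max in uniform spec")
  new_dist_spec("U", list(min = min, max = max))
}

#' @rdname dist_spec
#' @export
dist_tri <- function(min, mode, max) {
  if (!(min <= mode && mode <= max)) stop("need min <= mode <= max")
  new_dist_spec("TR", list(min = min, mode = mode, max = max))
}

#' @rdname dist_spec
#' @export
dist_tnorm <- function(mean, sd, min = mean - 2 * sd, max = mean + 2 * sd) {
  if (sd < 0) stop("sd must be nonnegative")
  if (min > max) stop("min > max in truncated normal spec")
  plo <- stats::pnorm(min, mean, sd)
  phi <- stats::pnorm(max, mean, sd)
  if (sd > 0 && phi <= plo) stop("truncation interval has zero probability mass")
  new_dist_spec("TN", list(mean = mean, sd = sd, min = min, max = max))
}

#' @rdname dist_spec
#' @export
dist_tlnorm <- function(gm, gsd, min = gm / gsd^2, max = gm * gsd^2) {
  if (gm <= 0) stop("gm must be positive")
  if (gsd < 1) stop("gsd must be >= 1")
  if (min > max) stop("min > max in truncated lognormal spec")
  if (min <= 0) stop("lognormal support requires min > 0")
  if (gsd > 1) {
    plo <- stats::plnorm(min, log(gm), log(gsd))
    phi <- stats::plnorm(max, log(gm), log(gsd))
    if (phi <= plo) stop("truncation interval has zero probability mass")
  }
  new_dist_spec("TLN", list(gm = gm, gsd = gsd, min = min, max = max))
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- unlist(x$params)
  cat(sprintf("%s(%s)\n", x$family,
              paste(sprintf("%s=%.4g", names(p), p), collapse = ", ")))
  invisible(x)
}

#' Quantile function of a distribution spec
#'
#' @param spec A [dist_spec] object.
#' @param p Probabilities in `[0, 1]`.
#' @return Quantiles; always within the spec's truncation bounds.
#' @export
dist_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "dist_spec"), all(p >= 0 & p <= 1))
  pr <- spec$params
  switch(spec$family,
    point = rep(pr$value, length(p)),
    U = pr$min + (pr$max - pr$min) * p,
    TR = {
      rng <- pr$max - pr$min
      if (rng == 0) rep(pr$min, length(p)) else {
        fc <- (pr$mode - pr$min) / rng
        lo <- p < fc
        q <- numeric(length(p))
        q[lo] <- pr$min + sqrt(p[lo] * rng * (pr$mode - pr$min))
        q[!lo] <- pr$max - sqrt((1 - p[!lo]) * rng * (pr$max - pr$mode))
        q
      }
    },
    TN = {
      if (pr$sd == 0) rep(pr$mean, length(p)) else {
        plo <- stats::pnorm(pr$min, pr$mean, pr$sd)
        phi <- stats::pnorm(pr$max, pr$mean, pr$sd)
        pmin(pmax(stats::qnorm(plo + p * (phi - plo), pr$mean, pr$sd),
                  pr$min), pr$max)
      }
    },
    TLN = {
      if (pr$gsd == 1) rep(pmin(pmax(pr$gm, pr$min), pr$max), length(p)) else {
        mu <- log(pr$gm); s <- log(pr$gsd)
        plo <- stats::plnorm(pr$min, mu, s)
        phi <- stats::plnorm(pr$max, mu, s)
        pmin(pmax(stats::qlnorm(plo + p * (phi - plo), mu, s),
                  pr$min), pr$max)
      }
    },
    stop("unknown distribution family: ", spec$family))
}

#' Draw from a distribution spec
#'
#' Inverse-CDF sampling: exactly `n` uniforms are consumed from the current
#' RNG state (or taken from `u`), so draws are reproducible under substream
#' seeding regardless of the family.
#'
#' @param spec A [dist_spec].
#' @param n Number of draws.
#' @param u Optional uniforms in `[0,1]` (length `n`) to transform instead
#'   of drawing fresh ones; used for correlated/common-random-number
#'   coupling.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n, u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  stopifnot(length(u) == n)
  dist_quantile(spec, u)
}

#' Analytic mean of a (truncated) distribution spec
#'
#' Used for deterministic "central value" dose calculations and as the
#' oracle for Monte Carlo mean-recovery checks.
#'
#' @param spec A [dist_spec].
#' @return The expectation of the truncated distribution.
#' @export
dist_mean <- function(spec) {
  pr <- spec$params
  switch(spec$family,
    point = pr$value,
    U = (pr$min + pr$max) / 2,
    TR = (pr$min + pr$mode + pr$max) / 3,
    TN = {
      if (pr$sd == 0) return(pr$mean)
      a <- (pr$min - pr$mean) / pr$sd
      b <- (pr$max - pr$mean) / pr$sd
      z <- stats::pnorm(b) - stats::pnorm(a)
      pr$mean + pr$sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    },
    TLN = {
      mu <- log(pr$gm); s <- log(pr$gsd)
      if (s == 0) return(min(max(pr$gm, pr$min), pr$max))
      a <- (log(pr$min) - mu) / s
      b <- (log(pr$max) - mu) / s
      z <- stats::pnorm(b) - stats::pnorm(a)
      exp(mu + s^2 / 2) * (stats::pnorm(b - s) - stats::pnorm(a - s)) / z
    },
    stop("unknown distribution family: ", spec$family))
}

#' Geometric mean consistent with an arithmetic mean and GSD
#'
#' For an untruncated lognormal with arithmetic mean `am` and geometric
#' standard deviation `gsd`, the geometric mean is
#' `GM = AM * exp(-(ln GSD)^2 / 2)` (the default).  Some parameter tables in
#' the environmental-dosimetry literature print the variant without the 1/2
#' factor, `GM = AM * exp(-(ln GSD)^2)`; it is available with
#' `printed = TRUE` and the choice is recorded in pipeline run manifests.
#'
#' @param am Arithmetic mean (> 0).
#' @param gsd Geometric standard deviation (>= 1).
#' @param printed Use the no-half-factor variant.
#' @return Geometric mean.
#' @export
gm_from_am_gsd <- function(am, gsd, printed = FALSE) {
  if (any(am <= 0)) stop("am must be positive")
  if (any(gsd < 1)) stop("gsd must be >= 1")
  fac <- if (printed) 1 else 0.5
  am * exp(-fac * log(gsd)^2)
}

#' Correlated sampling through a Gaussian copula
#'
#' Draws from several marginal specs with a stated Pearson correlation `r`
#' of each partner against the first (anchor) spec.  A standard-normal
#' anchor `z0` is drawn; each partner uses `z = r*z0 + sqrt(1-r^2)*e` with
#' independent `e`, then the normal scores are mapped through each
#' marginal's inverse CDF.  `r = 1` gives comonotone (identical-quantile)
#' coupling; a group of one spec is plain [dist_sample()].
#'
#' @param specs List of [dist_spec] objects; the first is the anchor.
#' @param r Correlations of specs 2..K against the anchor (length
#'   `length(specs) - 1`, or a single value recycled); `|r| <= 1`.
#' @param n Number of joint draws.
#' @return An `n x K` matrix, one column per spec.
#' @export
sample_correlated <- function(specs, r = numeric(0), n) {
  k <- length(specs)
  stopifnot(k >= 1)
  if (k == 1) return(matrix(dist_sample(specs[[1]], n), ncol = 1))
  r <- rep_len(r, k - 1)
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  z0 <- stats::qnorm(pclamp(stats::runif(n)))
  out <- matrix(NA_real_, n, k)
  out[, 1] <- dist_quantile(specs[[1]], stats::pnorm(z0))
  for (j in 2:k) {
    e <- stats::qnorm(pclamp(stats::runif(n)))
    z <- r[j - 1] * z0 + sqrt(1 - r[j - 1]^2) * e
    out[, j] <- dist_quantile(specs[[j]], stats::pnorm(z))
  }
  out
}

# keep uniforms strictly inside (0,1) for qnorm
pclamp <- function(u) pmin(pmax(u, 1e-12), 1 - 1e-12)

#' Empirical geometric standard deviation
#'
#' `exp` of the population (1/n) standard deviation of log values — the
#' summary used to characterize the spread of individual stochastic dose
#' realizations.  Zero doses must be excluded upstream (structurally
#' unexposed pathways are reported without a GSD).
#'
#' @param values Positive numeric vector, length >= 2.
#' @return GSD (>= 1).
#' @export
empirical_gsd <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive")
  l <- log(values)
  exp(sqrt(mean((l - mean(l))^2)))
}

# -- hierarchical substream seeding ------------------------------------------

# 32-bit FNV-1a over the bytes of a string, with arithmetic kept exact in
# doubles by splitting the multiply (prime = 2^24 + 0x193)
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXorDouble(h, b)
    h <- (h %% 256) * 16777216 + h * 403  # h * 0x01000193 mod 2^32, split
    h <- h %% 4294967296
  }
  h
}

bitwXorDouble <- function(a, b) {
  # xor of a (< 2^32) with a byte, via 16-bit halves to stay in int range
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b))
  hi <- as.integer(a %/% 65536)
  hi * 65536 + lo
}

#' Derive a substream seed from a master seed and a key
#'
#' Hashes `(seed, key)` to a 31-bit integer so that every (subject,
#' pathway, realization-set, parameter) combination gets its own
#' reproducible RNG stream: the same pair always yields the same seed and
#' distinct keys yield effectively independent streams.
#'
#' @param seed Master integer seed.
#' @param key Character key identifying the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, key) {
  as.integer(fnv1a32(paste0(format(seed), "/", key)) %% 2147483647)
}

#' Evaluate an expression under a substream seed
#'
#' Positions the RNG at `substream_seed(seed, key)`, evaluates `expr`, and
#' restores the caller's RNG state afterwards, so keyed draws never disturb
#' the surrounding random sequence.
#'
#' @param seed Master integer seed.
#' @param key Character substream key.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_substream <- function(seed, key, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, key))
  expr
}
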