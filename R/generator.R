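# Synthetic-cohort generator.
#
# Marginals: truncated normal or truncated log-normal per feature, with the
# location parameter solved so the truncated mean hits the configured cohort
# mean. Dependence: Gaussian copula over the continuous block (inverse-CDF
# marginals preserve the calibrated distributions exactly). Outcome: additive
# structural function of transformed, standardized features plus categorical
# level offsets and Gaussian noise, rounded and clipped to the admissible
# oocyte range.

# ---- truncated distribution helpers ------------------------------------

.ptr <- function(q, dist, location, scale) {
  switch(dist,
         truncnorm = stats::pnorm(q, location, scale),
         trunclnorm = stats::plnorm(pmax(q, 0), location, scale),
         stop("unknown distribution: ", dist))
}

.qtr <- function(p, dist, location, scale) {
  switch(dist,
         truncnorm = stats::qnorm(p, location, scale),
         trunclnorm = stats::qlnorm(p, location, scale),
         stop("unknown distribution: ", dist))
}

.dtr <- function(x, dist, location, scale) {
  switch(dist,
         truncnorm = stats::dnorm(x, location, scale),
         trunclnorm = stats::dlnorm(pmax(x, .Machine$double.xmin), location, scale),
         stop("unknown distribution: ", dist))
}

# quantile of the [lower, upper]-truncated distribution
qtrunc <- function(u, dist, location, scale, lower, upper) {
  pl <- .ptr(lower, dist, location, scale)
  pu <- .ptr(upper, dist, location, scale)
  .qtr(pl + u * (pu - pl), dist, location, scale)
}

# closed-form mean of the truncated distribution
trunc_mean <- function(dist, location, scale, lower, upper) {
  if (dist == "truncnorm") {
    a <- (lower - location) / scale
    b <- (upper - location) / scale
    z <- stats::pnorm(b) - stats::pnorm(a)
    location + scale * (stats::dnorm(a) - stats::dnorm(b)) / z
  } else {
    la <- if (lower <= 0) -Inf else (log(lower) - location) / scale
    lb <- (log(upper) - location) / scale
    z <- stats::pnorm(lb) - stats::pnorm(la)
    num <- stats::pnorm(lb - scale) - stats::pnorm(la - scale)
    exp(location + scale^2 / 2) * num / z
  }
}

# solve the location parameter so the truncated mean equals `target`
solve_location <- function(dist, scale, lower, upper, target) {
  f <- function(loc) trunc_mean(dist, loc, scale, lower, upper) - target
  # trunc_mean is increasing in the location parameter, and the target mean
  # lies strictly inside the truncation bounds, so a root exists within the
  # (log-)bounds themselves; extendInt covers targets near a bound.
  if (dist == "truncnorm") {
    interval <- c(lower, upper)
  } else {
    lo <- if (lower > 0) log(lower) else log(target) - 5 * scale
    interval <- c(lo, log(upper))
  }
  stats::uniroot(f, interval, extendInt = "upX", tol = 1e-10)$root
}

# ---- structural transforms ---------------------------------------------

apply_transform <- function(x, feat) {
  if (identical(feat$transform, "logistic")) {
    1 / (1 + exp(-(x - feat$center) / feat$width))
  } else {
    x
  }
}

# mean and sd of t(X) under the truncated marginal (numeric quadrature)
transform_moments <- function(feat, lower, upper) {
  pl <- .ptr(lower, feat$dist, feat$location, feat$scale)
  pu <- .ptr(upper, feat$dist, feat$location, feat$scale)
  dens <- function(x) .dtr(x, feat$dist, feat$location, feat$scale) / (pu - pl)
  lo <- max(lower, 1e-12)
  m1 <- stats::integrate(function(x) apply_transform(x, feat) * dens(x),
                         lo, upper, rel.tol = 1e-9)$value
  m2 <- stats::integrate(function(x) apply_transform(x, feat)^2 * dens(x),
                         lo, upper, rel.tol = 1e-9)$value
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# ---- configuration ------------------------------------------------------

#' Build a validated cohort generator configuration
#'
#' Takes a raw specification (typically parsed from YAML, see
#' [default_generator_config()]), validates it against the [cohort_schema()],
#' solves each continuous feature's location parameter so its truncated mean
#' matches the configured target, pre-computes the standardization moments of
#' the transformed features, and assembles the Gaussian-copula correlation
#' matrix for the continuous block.
#'
#' @param spec a named list: `n`, `seed`, `noise_sd`, `intercept`, `features`
#'   (per-feature marginal/effect parameters), `copula` (list of
#'   `(feature_a, feature_b, rho)` triples).
#' @return An object of class `ovr_generator_config`.
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(spec) {
  schema <- cohort_schema()
  if (is.null(spec$n) || spec$n < 2)
    stop("cohort size n must be at least 2")
  if (is.null(spec$noise_sd) || spec$noise_sd < 0)
    stop("noise_sd must be nonnegative")
  ft <- schema$features
  cont <- ft$name[ft$kind == "continuous"]
  cats <- ft$name[ft$kind == "categorical"]
  miss <- setdiff(ft$name, names(spec$features))
  if (length(miss))
    stop("missing feature configuration: ", paste(miss, collapse = ", "))

  for (f in cont) {
    fc <- spec$features[[f]]
    i <- match(f, ft$name)
    fc$lower <- ft$lower[i]
    fc$upper <- ft$upper[i]
    if (!fc$dist %in% c("truncnorm", "trunclnorm"))
      stop("feature '", f, "': unknown distribution ", fc$dist)
    if (fc$scale <= 0) stop("feature '", f, "': scale must be positive")
    if (is.null(fc$transform)) fc$transform <- "linear"
    fc$location <- solve_location(fc$dist, fc$scale, fc$lower, fc$upper, fc$mean)
    mom <- transform_moments(fc, fc$lower, fc$upper)
    fc$t_mean <- mom$mean
    fc$t_sd <- mom$sd
    if (is.null(fc$weight)) fc$weight <- 0
    spec$features[[f]] <- fc
  }
  for (f in cats) {
    fc <- spec$features[[f]]
    k <- length(schema$levels[[f]])
    if (!is.null(fc$counts)) {
      if (length(fc$counts) != k || any(fc$counts <= 0))
        stop("feature '", f, "': counts must be ", k, " positive values")
      fc$probs <- fc$counts / sum(fc$counts)
    }
    if (length(fc$probs) != k)
      stop("feature '", f, "': needs ", k, " level probabilities")
    if (any(fc$probs < 0) || abs(sum(fc$probs) - 1) > 1e-8)
      stop("feature '", f, "': level probabilities must be nonnegative and sum to 1")
    if (is.null(fc$offsets)) fc$offsets <- rep(0, k)
    if (length(fc$offsets) != k)
      stop("feature '", f, "': needs ", k, " level offsets")
    # center offsets under the level probabilities so the intercept is the
    # marginal outcome mean
    fc$offsets <- fc$offsets - sum(fc$probs * fc$offsets)
    spec$features[[f]] <- fc
  }

  R <- diag(length(cont))
  dimnames(R) <- list(cont, cont)
  for (tri in spec$copula) {
    a <- tri[[1]]; b <- tri[[2]]; rho <- as.numeric(tri[[3]])
    if (!a %in% cont || !b %in% cont)
      stop("copula entries must name continuous features: ", a, ", ", b)
    if (abs(rho) >= 1) stop("copula correlation must lie in (-1, 1)")
    R[a, b] <- R[b, a] <- rho
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    # project to the nearest well-conditioned correlation matrix
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    dimnames(R) <- list(cont, cont)
  }
  spec$copula_matrix <- R
  spec$continuous <- cont
  spec$categorical <- cats
  spec$schema <- schema
  if (is.null(spec$intercept)) spec$intercept <- 11.18
  class(spec) <- "ovr_generator_config"
  spec
}

#' Default generator configuration (calibrated clinical cohort)
#'
#' Loads the packaged calibration: marginal means and ranges of the 13
#' candidate features and the oocyte-count outcome of a 1365-woman IVF cohort,
#' signed effect weights (zero for BMI and basal E2, which carry no
#' association with the outcome by design), saturating transforms on AFC and
#' E2-on-HCG-day, and a clinically motivated copula (ovarian-reserve cluster,
#' age effects, dose-by-indication confounding of the Gn dosage, which gives
#' it a negative marginal correlation with the outcome despite its positive
#' causal effect).
#'
#' @param n cohort size; default is the packaged value (1365).
#' @param seed RNG seed stored in the config (a call to [generate_cohort()]
#'   may override it).
#' @param overrides named list merged into the raw specification before
#'   validation, e.g. `list(noise_sd = 0)` or
#'   `list(features = list(afc = list(weight = 3)))`.
#' @return An `ovr_generator_config`.
#' @examples
#' cfg <- default_generator_config(n = 200, seed = 1)
#' cohort <- generate_cohort(cfg)
#' mean(cohort$oocytes_retrieved)
#' @export
default_generator_config <- function(n = NULL, seed = NULL, overrides = list()) {
  path <- system.file("extdata", "default_cohort.yaml", package = "ovaresp")
  spec <- yaml::read_yaml(path)
  if (!is.null(n)) spec$n <- n
  if (!is.null(seed)) spec$seed <- seed
  if (!is.null(overrides$copula)) {
    # the copula is an unnamed list of triples: replace it wholesale
    # (modifyList merges by name and would leave it untouched)
    spec$copula <- overrides$copula
    overrides$copula <- NULL
  }
  if (length(overrides)) spec <- utils::modifyList(spec, overrides)
  generator_config(spec)
}

#' @export
print.ovr_generator_config <- function(x, ...) {
  cat("Synthetic cohort generator config: n =", x$n,
      " noise_sd =", x$noise_sd, " seed =", x$seed, "\n")
  w <- vapply(x$features[x$continuous], function(f) f$weight, numeric(1))
  cat("  nonzero continuous effects:",
      paste(names(w)[w != 0], collapse = ", "), "\n")
  invisible(x)
}

# ---- structural outcome function ---------------------------------------

#' Structural mean outcome of the generator
#'
#' Evaluates the generator's noiseless structural function g(h) on an
#' integer-encoded cohort: the configured intercept plus the weighted sum of
#' transformed, standardized continuous features plus the centered categorical
#' level offsets. This is the ground-truth regression function that the
#' trained models attempt to recover, exposed for calibration and testing.
#'
#' @param config an `ovr_generator_config`.
#' @param encoded a data frame with numeric feature columns (categoricals as
#'   integer codes), e.g. from [encode_cohort()].
#' @return Numeric vector of expected oocyte counts (unrounded, unclipped).
#' @export
structural_mean <- function(config, encoded) {
  g <- rep(config$intercept, nrow(encoded))
  for (f in config$continuous) {
    fc <- config$features[[f]]
    if (fc$weight == 0) next
    g <- g + fc$weight * (apply_transform(encoded[[f]], fc) - fc$t_mean) / fc$t_sd
  }
  for (f in config$categorical) {
    fc <- config$features[[f]]
    k <- length(fc$offsets)
    # piecewise-linear in the integer code, clamped at the outer levels, so
    # the structural function is also defined on perturbed (non-integer) codes
    code <- pmin(pmax(encoded[[f]], 1), k)
    g <- g + stats::approx(seq_len(k), fc$offsets, xout = code)$y
  }
  g
}

# ---- generation ---------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws `config$n` records: the continuous block from a Gaussian copula with
#' the configured correlation structure and truncated marginals (via inverse
#' CDF, so marginals are exact), categoricals from their level probabilities,
#' and the outcome as `clip(round(g(h) + eps), 0, 29)` with
#' `eps ~ N(0, noise_sd)`. Fully reproducible: the same config and seed give a
#' bitwise-identical cohort.
#'
#' @param config an [generator_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A data frame (class `ovr_cohort`) with the 13 feature columns in
#'   schema order (categoricals as labels) and the outcome column.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "ovr_generator_config"))
    stop("config must be built with generator_config()")
  if (is.null(seed)) stop("a seed is required for reproducible generation")
  n <- config$n
  schema <- config$schema
  set.seed(as.integer(seed))

  cont <- config$continuous
  L <- chol(config$copula_matrix)
  Z <- matrix(stats::rnorm(n * length(cont)), nrow = n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- cont

  out <- vector("list", length(schema$features$name))
  names(out) <- schema$features$name
  for (f in cont) {
    fc <- config$features[[f]]
    out[[f]] <- qtrunc(U[, f], fc$dist, fc$location, fc$scale,
                       fc$lower, fc$upper)
  }
  for (f in config$categorical) {
    fc <- config$features[[f]]
    u <- stats::runif(n)
    code <- findInterval(u, cumsum(fc$probs)[-length(fc$probs)]) + 1L
    out[[f]] <- schema$levels[[f]][code]
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)

  eps <- stats::rnorm(n, 0, config$noise_sd)
  g <- structural_mean(config, encode_cohort(df, schema))
  ob <- schema$outcome_bounds
  # `+ 0` normalizes IEEE negative zero from round(), keeping CSV output clean
  df[[schema$outcome]] <- pmin(pmax(round(g + eps), ob[1]), ob[2]) + 0

  class(df) <- c("ovr_cohort", "data.frame")
  attr(df, "seed") <- as.integer(seed)
  validate_cohort(df, schema)
  df
}

#' @export
print.ovr_cohort <- function(x, ...) {
  sch <- cohort_schema()
  cat("Synthetic COS cohort:", nrow(x), "women\n")
  cat("  mean oocytes retrieved:",
      round(mean(x[[sch$outcome]]), 2), "\n")
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat("  ...", nrow(x) - 4, "more rows\n")
  invisible(x)
}
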