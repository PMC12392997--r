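#' Distribution specification for probabilistic sensitivity analysis
#'
#' A `dist_spec` names the sampling family attached to a model parameter and
#' its parameters as printed in a parameter table: `triangular` carries
#' (min, mode, max), `beta` (shape1, shape2), `gamma` (shape, rate) and
#' `fixed` a single value.  An optional truncation interval restricts
#' samples; draws falling outside are resampled.
#'
#' @param family One of `"triangular"`, `"beta"`, `"gamma"`, `"fixed"`.
#' @param params Numeric vector of family parameters (see Details).
#' @param truncation Optional length-2 numeric `c(lo, hi)` with `lo < hi`.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("triangular", c(0.30, 0.60, 0.80))
#' dist_spec("gamma", c(2.16, 0.003))
#' @export
dist_spec <- function(family, params, truncation = NULL) {
  family <- match.arg(family, c("triangular", "beta", "gamma", "fixed"))
  params <- as.numeric(params)
  if (family == "triangular") {
    if (length(params) != 3L)
      stop("triangular needs (min, mode, max)", call. = FALSE)
    if (!(params[1] <= params[2] && params[2] <= params[3]))
      stop("triangular requires min <= mode <= max", call. = FALSE)
  } else if (family %in% c("beta", "gamma")) {
    if (length(params) != 2L || any(params <= 0))
      stop(sprintf("%s needs two positive parameters", family), call. = FALSE)
  } else {
    if (length(params) != 1L)
      stop("fixed needs a single value", call. = FALSE)
  }
  if (!is.null(truncation)) {
    truncation <- as.numeric(truncation)
    if (length(truncation) != 2L || !(truncation[1] < truncation[2]))
      stop("truncation must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  structure(list(family = family, params = params, truncation = truncation),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s)%s\n", x$family,
              paste(format(x$params), collapse = ", "),
              if (is.null(x$truncation)) "" else
                sprintf(" truncated to [%g, %g]", x$truncation[1], x$truncation[2])))
  invisible(x)
}

# Inverse-CDF triangular sampler; u uniform on [0,1].
qtriangular <- function(u, a, c, b) {
  # a = min, c = mode, b = max (classical parameterisation)
  fc <- if (b > a) (c - a) / (b - a) else 0
  out <- numeric(length(u))
  lo <- u < fc
  out[lo]  <- a + sqrt(u[lo] * (b - a) * (c - a))
  out[!lo] <- b - sqrt((1 - u[!lo]) * (b - a) * (b - c))
  out
}

#' Draw samples from a distribution specification
#'
#' Respects the spec's truncation interval by resampling (up to `max_iter`
#' rounds, then an error).  Uses the current RNG stream; seed management is
#' the caller's responsibility (see [sample_parameter_set()]).
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param max_iter Resampling rounds permitted to satisfy truncation.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1L, max_iter = 100L) {
  stopifnot(inherits(spec, "dist_spec"))
  draw <- switch(spec$family,
    triangular = function(m) qtriangular(stats::runif(m), spec$params[1],
                                         spec$params[2], spec$params[3]),
    beta  = function(m) stats::rbeta(m, spec$params[1], spec$params[2]),
    gamma = function(m) stats::rgamma(m, shape = spec$params[1],
                                      rate = spec$params[2]),
    fixed = function(m) rep(spec$params[1], m)
  )
  x <- draw(n)
  if (!is.null(spec$truncation)) {
    lo <- spec$truncation[1]; hi <- spec$truncation[2]
    it <- 0L
    bad <- which(x < lo | x > hi)
    while (length(bad) > 0L) {
      it <- it + 1L
      if (it > max_iter)
        stop("truncation resampling cap exceeded; distribution mass outside [",
             lo, ", ", hi, "]", call. = FALSE)
      x[bad] <- draw(length(bad))
      bad <- which(x < lo | x > hi)
    }
  }
  x
}

#' Closed-form mean of a distribution specification
#'
#' Used by calibration tests; ignores truncation.
#' @param spec A [dist_spec()].
#' @return The untruncated mean.
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
    triangular = sum(spec$params) / 3,
    beta  = spec$params[1] / (spec$params[1] + spec$params[2]),
    gamma = spec$params[1] / spec$params[2],
    fixed = spec$params[1]
  )
}

#' Closed-form variance of a distribution specification
#' @param spec A [dist_spec()].
#' @return The untruncated variance.
#' @export
dist_var <- function(spec) {
  p <- spec$params
  switch(spec$family,
    triangular = (p[1]^2 + p[2]^2 + p[3]^2 -
                    p[1] * p[2] - p[1] * p[3] - p[2] * p[3]) / 18,
    beta  = p[1] * p[2] / ((p[1] + p[2])^2 * (p[1] + p[2] + 1)),
    gamma = p[1] / p[2]^2,
    fixed = 0
  )
}

#' A single model parameter: base value, range and PSA distribution
#'
#' @param name Identifier.
#' @param base Base-case value.
#' @param low,high Deterministic sensitivity range.
#' @param dist A [dist_spec()]; defaults to `fixed` at `base`.
#' @param units Free-text units label.
#' @return An object of class `param_value`.
#' @export
param_value <- function(name, base, low = base, high = base,
                        dist = NULL, units = "") {
  if (is.null(dist)) dist <- dist_spec("fixed", base)
  if (!(low <= base && base <= high))
    stop(sprintf("parameter '%s': need low <= base <= high (%g, %g, %g)",
                 name, low, base, high), call. = FALSE)
  structure(list(name = name, base = as.numeric(base),
                 low = as.numeric(low), high = as.numeric(high),
                 dist = dist, units = units),
            class = "param_value")
}

#' @export
print.param_value <- function(x, ...) {
  cat(sprintf("<param_value> %s = %g [%g, %g] ~ %s(%s)\n", x$name, x$base,
              x$low, x$high, x$dist$family,
              paste(format(x$dist$params), collapse = ", ")))
  invisible(x)
}

# Refit a beta/gamma spec so its mean equals the base value, reading the
# printed range as approximately mean +/- 2 SD (method of moments).  The
# printed (shape1, shape2)/(shape, rate) pairs are retained verbatim in
# "raw" mode.
recenter_dist <- function(pv) {
  d <- pv$dist
  if (!d$family %in% c("beta", "gamma")) return(d)
  m <- pv$base
  sdev <- (pv$high - pv$low) / 4
  if (sdev <= 0) return(dist_spec("fixed", m))
  v <- sdev^2
  if (d$family == "beta") {
    if (m <= 0 || m >= 1 || v >= m * (1 - m))
      stop(sprintf("cannot recenter beta for '%s'", pv$name), call. = FALSE)
    nu <- m * (1 - m) / v - 1
    dist_spec("beta", c(m * nu, (1 - m) * nu), truncation = d$truncation)
  } else {
    dist_spec("gamma", c(m^2 / v, m / v), truncation = d$truncation)
  }
}

# Effective sampling spec for a param_value under a beta/gamma handling mode.
effective_dist <- function(pv, mode = c("recentered", "raw")) {
  mode <- match.arg(mode)
  if (mode == "recentered") recenter_dist(pv) else pv$dist
}

# Draw one value for a param_value, applying domain clamps: utilities are
# capped at 1, probabilities kept in [0,1], costs kept >= 0.
sample_param <- function(pv, mode = "recentered",
                         kind = c("generic", "probability", "utility", "cost")) {
  kind <- match.arg(kind)
  x <- sample_dist(effective_dist(pv, mode), 1L)
  switch(kind,
    probability = min(max(x, 0), 1),
    utility     = min(x, 1),
    cost        = max(x, 0),
    generic     = x
  )
}
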