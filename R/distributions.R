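## Location-scale probability families used for the flow distributions.
##
## The Jones-Faddy skew-t has the convenient property that, for the
## standardised variate t, u = (1 + t / sqrt(a + b + t^2)) / 2 is
## Beta(a, b); density, CDF, quantile and sampling all route through the
## beta distribution.  The Weibull-maximum family is the reversed Weibull
## with support (-Inf, mu].  The Student t is the usual location-scale
## extension of stats::dt.

#' Jones--Faddy skew-t distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Jones--Faddy skew-t with location `mu`, scale `sigma` and shape
#' parameters `a`, `b` (both positive).  `a = b` gives a symmetric Student-t
#' like shape with `2a` degrees of freedom; `a > b` skews the distribution
#' to the right (the right tail decays as `t^-(2b+1)`).
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param n Number of draws.
#' @param mu Location.
#' @param sigma Scale, positive.
#' @param a,b Shape parameters, positive.
#' @param log Return log-density?
#' @return Numeric vector.
#' @references Jones, M. C. and Faddy, M. J. (2003) A skew extension of the
#'   t-distribution, with applications. JRSS-B 65, 159-174.
#' @name jones_faddy
NULL

#' @rdname jones_faddy
#' @export
djfst <- function(x, mu = 0, sigma = 1, a = 2, b = 2, log = FALSE) {
  stopifnot(sigma > 0, a > 0, b > 0)
  t <- (x - mu) / sigma
  s <- pmin(pmax(t / sqrt(a + b + t^2), -1), 1)
  ld <- (a + 0.5) * log1p(s) + (b + 0.5) * log1p(-s) -
    ((a + b - 1) * base::log(2) + lbeta(a, b) + 0.5 * base::log(a + b)) -
    base::log(sigma)
  if (log) ld else exp(ld)
}

#' @rdname jones_faddy
#' @export
pjfst <- function(q, mu = 0, sigma = 1, a = 2, b = 2) {
  stopifnot(sigma > 0, a > 0, b > 0)
  t <- (q - mu) / sigma
  stats::pbeta((1 + t / sqrt(a + b + t^2)) / 2, a, b)
}

#' @rdname jones_faddy
#' @export
qjfst <- function(p, mu = 0, sigma = 1, a = 2, b = 2) {
  stopifnot(sigma > 0, a > 0, b > 0)
  u <- stats::qbeta(p, a, b)
  t <- ifelse(u <= 0, -Inf,
       ifelse(u >= 1, Inf,
              sqrt(a + b) * (2 * u - 1) / (2 * sqrt(u * (1 - u)))))
  mu + sigma * t
}

#' @rdname jones_faddy
#' @export
rjfst <- function(n, mu = 0, sigma = 1, a = 2, b = 2) {
  stopifnot(sigma > 0, a > 0, b > 0)
  u <- stats::rbeta(n, a, b)
  t <- sqrt(a + b) * (2 * u - 1) / (2 * sqrt(u * (1 - u)))
  mu + sigma * t
}

#' Weibull-maximum (reversed Weibull) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the reversed Weibull with shape `shape`, location `mu` and scale
#' `sigma`.  The support is `x <= mu`; `F(x) = exp(-((mu - x)/sigma)^shape)`.
#'
#' @inheritParams jones_faddy
#' @param shape Shape parameter, positive.
#' @return Numeric vector.
#' @name weibull_max
NULL

#' @rdname weibull_max
#' @export
dweibmax <- function(x, shape = 1, mu = 0, sigma = 1, log = FALSE) {
  stopifnot(shape > 0, sigma > 0)
  z <- (mu - x) / sigma
  ld <- ifelse(z > 0,
               base::log(shape) - base::log(sigma) + (shape - 1) * base::log(z) - z^shape,
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname weibull_max
#' @export
pweibmax <- function(q, shape = 1, mu = 0, sigma = 1) {
  stopifnot(shape > 0, sigma > 0)
  z <- (mu - q) / sigma
  ifelse(z > 0, exp(-z^shape), 1)
}

#' @rdname weibull_max
#' @export
qweibmax <- function(p, shape = 1, mu = 0, sigma = 1) {
  stopifnot(shape > 0, sigma > 0, p >= 0, p <= 1)
  mu - sigma * (-base::log(p))^(1 / shape)
}

#' @rdname weibull_max
#' @export
rweibmax <- function(n, shape = 1, mu = 0, sigma = 1) {
  qweibmax(stats::runif(n), shape, mu, sigma)
}

#' Location-scale Student t distribution
#'
#' @inheritParams jones_faddy
#' @param df Degrees of freedom, positive.
#' @return Numeric vector.
#' @name student_t_ls
NULL

#' @rdname student_t_ls
#' @export
dstt <- function(x, mu = 0, sigma = 1, df = 5, log = FALSE) {
  stopifnot(sigma > 0, df > 0)
  ld <- stats::dt((x - mu) / sigma, df, log = TRUE) - base::log(sigma)
  if (log) ld else exp(ld)
}

#' @rdname student_t_ls
#' @export
pstt <- function(q, mu = 0, sigma = 1, df = 5) {
  stats::pt((q - mu) / sigma, df)
}

#' @rdname student_t_ls
#' @export
qstt <- function(p, mu = 0, sigma = 1, df = 5) {
  mu + sigma * stats::qt(p, df)
}

#' @rdname student_t_ls
#' @export
rstt <- function(n, mu = 0, sigma = 1, df = 5) {
  mu + sigma * stats::rt(n, df)
}

## ---------------------------------------------------------------------------
## Family registry: a uniform interface over the candidate families so the
## fitting, ranking and sampling code is family-agnostic.  Each entry maps a
## named parameter vector to d/p/q/r calls, provides a moment-based start for
## the optimiser and a transform to an unconstrained optimisation space.

family_registry <- function() {
  list(
    jones_faddy_skew_t = list(
      params = c("mu", "sigma", "a", "b"),
      d = function(x, p, log = FALSE) djfst(x, p[["mu"]], p[["sigma"]], p[["a"]], p[["b"]], log = log),
      p = function(q, p) pjfst(q, p[["mu"]], p[["sigma"]], p[["a"]], p[["b"]]),
      q = function(pr, p) qjfst(pr, p[["mu"]], p[["sigma"]], p[["a"]], p[["b"]]),
      r = function(n, p) rjfst(n, p[["mu"]], p[["sigma"]], p[["a"]], p[["b"]]),
      init = function(x) c(mu = stats::median(x),
                           sigma = max(stats::mad(x), stats::sd(x) / 2, 1e-12),
                           a = 2, b = 2),
      to_free = function(p) c(p[["mu"]], log(p[["sigma"]]), log(p[["a"]]), log(p[["b"]])),
      from_free = function(th) c(mu = th[1], sigma = exp(th[2]),
                                 a = min(exp(th[3]), 1e4), b = min(exp(th[4]), 1e4))
    ),
    weibull_max = list(
      params = c("shape", "mu", "sigma"),
      d = function(x, p, log = FALSE) dweibmax(x, p[["shape"]], p[["mu"]], p[["sigma"]], log = log),
      p = function(q, p) pweibmax(q, p[["shape"]], p[["mu"]], p[["sigma"]]),
      q = function(pr, p) qweibmax(pr, p[["shape"]], p[["mu"]], p[["sigma"]]),
      r = function(n, p) rweibmax(n, p[["shape"]], p[["mu"]], p[["sigma"]]),
      ## location must sit above the sample maximum; optimise its log-offset
      init = function(x) c(shape = 1.5,
                           mu = max(x) + max(stats::sd(x), 1e-12) / 2,
                           sigma = max(stats::sd(x), 1e-12)),
      to_free = function(p) c(log(p[["shape"]]), p[["mu"]], log(p[["sigma"]])),
      from_free = function(th) c(shape = min(exp(th[1]), 1e4), mu = th[2], sigma = exp(th[3])),
      support_shift = TRUE
    ),
    student_t = list(
      params = c("mu", "sigma", "df"),
      d = function(x, p, log = FALSE) dstt(x, p[["mu"]], p[["sigma"]], p[["df"]], log = log),
      p = function(q, p) pstt(q, p[["mu"]], p[["sigma"]], p[["df"]]),
      q = function(pr, p) qstt(pr, p[["mu"]], p[["sigma"]], p[["df"]]),
      r = function(n, p) rstt(n, p[["mu"]], p[["sigma"]], p[["df"]]),
      init = function(x) c(mu = stats::median(x),
                           sigma = max(stats::mad(x), stats::sd(x) / 2, 1e-12),
                           df = 5),
      to_free = function(p) c(p[["mu"]], log(p[["sigma"]]), log(p[["df"]])),
      from_free = function(th) c(mu = th[1], sigma = exp(th[2]), df = min(exp(th[3]), 1e4))
    ),
    normal = list(
      params = c("mu", "sigma"),
      d = function(x, p, log = FALSE) stats::dnorm(x, p[["mu"]], p[["sigma"]], log = log),
      p = function(q, p) stats::pnorm(q, p[["mu"]], p[["sigma"]]),
      q = function(pr, p) stats::qnorm(pr, p[["mu"]], p[["sigma"]]),
      r = function(n, p) stats::rnorm(n, p[["mu"]], p[["sigma"]]),
      init = function(x) c(mu = mean(x), sigma = max(stats::sd(x), 1e-12)),
      to_free = function(p) c(p[["mu"]], log(p[["sigma"]])),
      from_free = function(th) c(mu = th[1], sigma = exp(th[2])),
      closed_form = function(x) c(mu = mean(x), sigma = sqrt(mean((x - mean(x))^2)))
    ),
    logistic = list(
      params = c("mu", "sigma"),
      d = function(x, p, log = FALSE) stats::dlogis(x, p[["mu"]], p[["sigma"]], log = log),
      p = function(q, p) stats::plogis(q, p[["mu"]], p[["sigma"]]),
      q = function(pr, p) stats::qlogis(pr, p[["mu"]], p[["sigma"]]),
      r = function(n, p) stats::rlogis(n, p[["mu"]], p[["sigma"]]),
      init = function(x) c(mu = stats::median(x),
                           sigma = max(stats::sd(x) * sqrt(3) / pi, 1e-12)),
      to_free = function(p) c(p[["mu"]], log(p[["sigma"]])),
      from_free = function(th) c(mu = th[1], sigma = exp(th[2]))
    )
  )
}

get_family <- function(family) {
  reg <- family_registry()
  if (!family %in% names(reg))
    stop("unknown distribution family: ", family,
         " (available: ", paste(names(reg), collapse = ", "), ")", call. = FALSE)
  reg[[family]]
}

#' Names of the candidate distribution families
#' @return Character vector of family names usable in [fit_distribution()].
#' @export
candidate_families <- function() names(family_registry())
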