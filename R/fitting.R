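#' Fit a candidate distribution family to a rate or share sample
#'
#' Parameters are estimated by maximum likelihood (Nelder--Mead over an
#' unconstrained reparameterisation, with deterministic perturbed restarts
#' when the first fit fails to converge).  The sum of squared errors (SSE)
#' between the fitted density and the sample histogram density -- evaluated
#' at the centres of `bins` equal-width bins spanning the sample range -- is
#' recorded for family comparison; it is a ranking score, not the fitting
#' loss.
#'
#' @param samples A [labeled_samples()] object or a numeric vector of
#'   observations.
#' @param family Family name, one of [candidate_families()].
#' @param min_n Minimum sample count; below it an empty fit is returned so
#'   the caller can apply its fallback policy.
#' @param bins Number of histogram bins for the SSE score.
#' @return A `migsim_fit` object (fields `family`, `params`, `sse`,
#'   `loglik`, `n_fit`, `convergence`), or a `migsim_empty_fit` when
#'   `samples` has fewer than `min_n` observations.
#' @export
fit_distribution <- function(samples, family, min_n = 30, bins = 100) {
  x <- sample_values(samples)
  if (length(x) < min_n)
    return(empty_fit(sprintf("%d observations < min_n = %d", length(x), min_n)))
  if (stats::sd(x) == 0)
    stop("degenerate sample: all ", length(x), " values equal ", x[1], call. = FALSE)
  fam <- get_family(family)

  if (!is.null(fam$closed_form)) {
    par <- fam$closed_form(x)
    ll <- sum(fam$d(x, par, log = TRUE))
    return(new_fit(family, par, x, ll, bins, convergence = 0L))
  }

  nll <- function(th) {
    par <- fam$from_free(th)
    if (isTRUE(fam$support_shift) && par[["mu"]] <= max(x)) return(1e12)
    v <- -sum(fam$d(x, par, log = TRUE))
    if (!is.finite(v)) 1e12 else v
  }
  start <- fam$to_free(as.list(fam$init(x)))
  ## deterministic restart ladder: scale perturbations of the start
  perturb <- list(0, c(0.25), c(-0.25), c(0.5), c(-0.5))
  best <- NULL
  for (dp in perturb) {
    th0 <- start + dp
    opt <- tryCatch(
      stats::optim(th0, nll, method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0 && identical(dp, perturb[[1]])) break
  }
  if (is.null(best))
    stop("maximum-likelihood fit failed for family ", family, call. = FALSE)
  par <- fam$from_free(best$par)
  new_fit(family, par, x, -best$value, bins, convergence = best$convergence)
}

new_fit <- function(family, params, x, loglik, bins, convergence) {
  structure(list(family = family,
                 params = params,
                 sse = density_sse(family, params, x, bins),
                 loglik = loglik,
                 n_fit = length(x),
                 convergence = convergence),
            class = "migsim_fit")
}

empty_fit <- function(reason) {
  structure(list(reason = reason), class = "migsim_empty_fit")
}

#' @export
is_empty_fit <- function(fit) inherits(fit, "migsim_empty_fit")

#' @export
print.migsim_fit <- function(x, ...) {
  cat(sprintf("<%s fit on n = %d>\n", x$family, x$n_fit))
  print(signif(x$params, 5))
  cat(sprintf("  loglik = %.2f, SSE = %.4g\n", x$loglik, x$sse))
  invisible(x)
}

#' @export
print.migsim_empty_fit <- function(x, ...) {
  cat("<empty fit:", x$reason, ">\n")
  invisible(x)
}

## SSE between histogram density and fitted density at bin centres
density_sse <- function(family, params, x, bins = 100) {
  fam <- get_family(family)
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng), 1) * 1e-6
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  mids <- h$mids
  sum((h$density - fam$d(mids, params)) ^ 2)
}

#' Density, CDF, quantile, sampling and median of a fitted distribution
#'
#' @param fit A `migsim_fit` object.
#' @param x,q,p,n As in the underlying d/p/q/r functions.
#' @name fit_accessors
NULL

#' @rdname fit_accessors
#' @export
fit_density <- function(fit, x) get_family(fit$family)$d(x, fit$params)

#' @rdname fit_accessors
#' @export
fit_cdf <- function(fit, q) get_family(fit$family)$p(q, fit$params)

#' @rdname fit_accessors
#' @export
fit_quantile <- function(fit, p) get_family(fit$family)$q(p, fit$params)

#' @rdname fit_accessors
#' @export
fit_random <- function(fit, n) get_family(fit$family)$r(n, fit$params)

#' @rdname fit_accessors
#' @export
fit_median <- function(fit) fit_quantile(fit, 0.5)

#' Quantile of a fitted distribution truncated to an interval
#'
#' The sampler restricts all rates and shares to `[0, 1]`; the deterministic
#' model mode substitutes the median of the truncated distribution, computed
#' here by mapping the probability through the untruncated CDF.
#'
#' @param fit A `migsim_fit`.
#' @param p Probabilities.
#' @param lower,upper Truncation interval.
#' @export
trunc_quantile <- function(fit, p, lower = 0, upper = 1) {
  f0 <- fit_cdf(fit, lower)
  f1 <- fit_cdf(fit, upper)
  if (f1 <= f0) return(rep(pmin(pmax(fit_quantile(fit, 0.5), lower), upper), length(p)))
  pmin(pmax(fit_quantile(fit, f0 + p * (f1 - f0)), lower), upper)
}

#' Fit several families and rank them by histogram SSE
#'
#' Reproduces the family-selection procedure used for the calibration: each
#' candidate is fitted by maximum likelihood and families are ordered by
#' ascending SSE between fitted density and sample histogram.  Ties are
#' broken by fewer parameters, then lexical family name.
#'
#' @inheritParams fit_distribution
#' @param families Character vector of candidate family names (at least 1).
#' @return List of `migsim_fit` objects sorted best-first; attribute
#'   `"failures"` names families whose fit failed.
#' @export
rank_families <- function(samples, families = candidate_families(),
                          min_n = 30, bins = 100) {
  if (length(families) < 1) stop("need at least one candidate family", call. = FALSE)
  fits <- list(); failures <- character()
  for (f in families) {
    res <- tryCatch(fit_distribution(samples, f, min_n = min_n, bins = bins),
                    error = function(e) conditionMessage(e))
    if (is.character(res) || is_empty_fit(res)) {
      failures[f] <- if (is.character(res)) res else res$reason
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }
  if (!length(fits))
    stop("all candidate fits failed: ",
         paste(names(failures), failures, sep = ": ", collapse = "; "), call. = FALSE)
  npar <- vapply(fits, function(f) length(f$params), numeric(1))
  sse <- vapply(fits, function(f) f$sse, numeric(1))
  fam <- vapply(fits, function(f) f$family, character(1))
  fits <- fits[order(sse, npar, fam)]
  attr(fits, "failures") <- failures
  fits
}
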