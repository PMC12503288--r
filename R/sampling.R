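#' Sampler context: mode, reproducibility and truncation policy
#'
#' Carries the sampling mode and truncation policy through the flow-drawing
#' functions.  In `"stochastic"` mode draws come from R's RNG stream; set
#' the stream with `set.seed()` (or pass `seed`, which seeds on creation).
#' Identical seed, inputs and mode give bit-identical flows.  In
#' `"deterministic"` mode every draw is replaced by the median of the
#' truncated distribution; no RNG state is consumed.
#'
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param seed Optional integer; if given, `set.seed(seed)` is called.
#' @param max_attempts Rejection-sampling rounds for truncation to
#'   `[0, 1]` before clamping the remaining draws.
#' @return A `sampler_context`.
#' @export
sampler_context <- function(mode = c("stochastic", "deterministic"),
                            seed = NULL, max_attempts = 1000) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  structure(list(mode = mode, seed = seed, max_attempts = max_attempts,
                 cache = new.env(parent = emptyenv())),
            class = "sampler_context")
}

## median of the [0,1]-truncated distribution, cached per fit in the context
trunc_median_cached <- function(fit, ctx) {
  key <- paste0(fit$family, ":", paste(signif(fit$params, 15), collapse = ","))
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  m <- trunc_quantile(fit, 0.5)
  ctx$cache[[key]] <- m
  m
}

## n draws from `fit` truncated to [0,1]: vectorised rejection sampling,
## clamping whatever is still outside after max_attempts rounds
rtrunc01 <- function(fit, n, ctx) {
  if (n == 0) return(numeric())
  ## no mass on the valid support: clamp the median directly
  if (fit_cdf(fit, 1) - fit_cdf(fit, 0) <= 0)
    return(rep(pmin(pmax(fit_quantile(fit, 0.5), 0), 1), n))
  x <- fit_random(fit, n)
  bad <- which(x < 0 | x > 1)
  attempts <- 0L
  while (length(bad) && attempts < ctx$max_attempts) {
    x[bad] <- fit_random(fit, length(bad))
    bad <- bad[x[bad] < 0 | x[bad] > 1]
    attempts <- attempts + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], 0), 1)
  x
}

## one [0,1] draw (or truncated median) per element, grouped by a label
## vector so each group costs one vectorised call
draw_by_label <- function(labels, fit_for_label, ctx) {
  out <- numeric(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    fit <- fit_for_label(lab)
    out[idx] <- if (ctx$mode == "deterministic")
      trunc_median_cached(fit, ctx)
    else rtrunc01(fit, length(idx), ctx)
  }
  out
}

#' Draw an emigration rate for a country
#'
#' Stochastic mode: one draw from the population bin's fitted distribution,
#' truncated to `[0, 1]`.  Deterministic mode: the truncated distribution's
#' median.
#'
#' @param P Native population size(s); one rate is returned per element.
#' @param dists A [flow_distribution_set()].
#' @param ctx A [sampler_context()].
#' @param scheme A [partition_scheme()].
#' @return Rate(s) in `[0, 1]`.
#' @export
sample_emigration_rate <- function(P, dists, ctx, scheme = partition_scheme()) {
  labs <- population_label(P, scheme)
  missing <- setdiff(unique(labs), names(dists$emigration))
  if (length(missing))
    stop("no emigration calibration for bin(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  draw_by_label(labs, function(l) dists$emigration[[l]], ctx)
}

#' Draw normalized destination shares for one origin
#'
#' For every destination a raw share is drawn from the Weibull-maximum fit
#' of its `(g, d)` cell (deterministic mode: the cell's truncated median),
#' where `g` is the origin/destination GDPc ratio and `d` the relative
#' diaspora size.  Raw shares generally do not sum to one and are uniformly
#' renormalized; if every raw share is zero the shares degenerate to
#' uniform (with a warning).
#'
#' @param origin Country id of the origin.
#' @param state A [world_state()] (supplies the diaspora covariate).
#' @param gdpc Named vector of GDP per capita for the current year.
#' @param dists A [flow_distribution_set()].
#' @param ctx A [sampler_context()].
#' @param scheme A [partition_scheme()].
#' @param diaspora_mode `"bilateral"` (existing origin-born stock in each
#'   destination over the origin population) or `"origin_total"`.
#' @return Named share vector over all countries: nonnegative, summing to
#'   1, zero at the origin itself.
#' @export
sample_destination_shares <- function(origin, state, gdpc, dists, ctx,
                                      scheme = partition_scheme(),
                                      diaspora_mode = c("bilateral", "origin_total")) {
  diaspora_mode <- match.arg(diaspora_mode)
  countries <- names(state$P)
  dest <- setdiff(countries, origin)
  if (!length(dest)) stop("need at least one destination", call. = FALSE)
  if (anyNA(gdpc[c(origin, dest)]))
    stop("GDPc missing for origin or destination", call. = FALSE)
  g <- gdpc[[origin]] / gdpc[dest]
  Pi <- state$P[[origin]]
  dcov <- if (diaspora_mode == "bilateral") {
    if (Pi > 0) state$D[dest, origin] / Pi else rep(0, length(dest))
  } else {
    rep(if (Pi > 0) sum(state$D[, origin]) / Pi else 0, length(dest))
  }
  cells <- paste(gdp_ratio_label(g, scheme), diaspora_label(dcov, scheme), sep = ":")
  raw <- draw_by_label(cells, function(cl) {
    gl <- sub(":.*$", "", cl); dl <- sub("^.*:", "", cl)
    share_fit_for(dists, gl, dl)
  }, ctx)
  tot <- sum(raw)
  share <- if (tot > 0) raw / tot else {
    warning("all raw destination shares zero for origin ", origin,
            "; using uniform shares", call. = FALSE)
    rep(1 / length(dest), length(dest))
  }
  out <- stats::setNames(numeric(length(countries)), countries)
  out[dest] <- share
  out
}

#' Bilateral emigration flows from a rate and a share vector
#'
#' `M_ij = P_i * rate * share_j`; the total outflow is `P_i * rate` and can
#' never exceed the native population.
#'
#' @param P_i Origin native population (persons).
#' @param rate Emigration rate in `[0, 1]`.
#' @param shares Normalized share vector (sums to 1).
#' @return Flow vector (persons per year), same names as `shares`.
#' @export
bilateral_flows <- function(P_i, rate, shares) {
  stopifnot(P_i >= 0, rate >= 0, rate <= 1)
  if (abs(sum(shares) - 1) > 1e-9)
    stop("shares must sum to 1", call. = FALSE)
  P_i * rate * shares
}

#' Draw return flows for every migrant stock
#'
#' One independent `[0, 1]`-truncated draw from the pooled return-rate
#' distribution per (residence, origin) pair with positive stock
#' (deterministic mode: the truncated median for all pairs);
#' `R[i, k] = D[i, k] * r`.
#'
#' @param state A [world_state()].
#' @param dists A [flow_distribution_set()].
#' @param ctx A [sampler_context()].
#' @return Return flow matrix `[residence, origin]`, elementwise `<= D`.
#' @export
sample_return_flows <- function(state, dists, ctx) {
  D <- state$D
  R <- D * 0
  pos <- which(D > 0)
  if (length(pos)) {
    r <- if (ctx$mode == "deterministic")
      rep(trunc_median_cached(dists$return_rate, ctx), length(pos))
    else rtrunc01(dists$return_rate, length(pos), ctx)
    R[pos] <- D[pos] * r
  }
  R
}

#' Birth flows from migrant populations into native populations
#'
#' `B[i, l] = D[i, l] * c_birth_l`: births to the origin-`l` migrant stock
#' resident in `i`, entering `i`'s native population.  Migrant birth rates
#' are taken from the origin country.  Deterministic (no sampling).
#'
#' @param state A [world_state()].
#' @param c_birth Named vector of natural birth rates by country.
#' @return Birth flow matrix `[residence, origin]`.
#' @export
birth_flows <- function(state, c_birth) {
  countries <- names(state$P)
  if (anyNA(c_birth[countries]))
    stop("birth rate missing for some countries", call. = FALSE)
  sweep(state$D, 2, c_birth[countries], `*`)
}
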