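#' Default ground-truth distribution set for the synthetic world
#'
#' A complete [flow_distribution_set()] with plausible orders of magnitude:
#' right-skewed Jones--Faddy skew-t emigration rates whose medians decrease
#' with population size (about 0.006 per year for the smallest countries
#' down to 0.001 for the largest), Weibull-maximum destination shares whose
#' medians grow by orders of magnitude with the diaspora bin and only
#' weakly with the GDPc-ratio bin, and a tight Student-t return rate centred near 0.004 per
#' year.
#'
#' @param scheme A [partition_scheme()].
#' @return A [flow_distribution_set()] usable directly for sampling (fits
#'   carry `n_fit = 0` since they are postulated, not estimated).
#' @export
default_truth_dists <- function(scheme = partition_scheme()) {
  truth_fit <- function(family, params) {
    structure(list(family = family, params = params, sse = NA_real_,
                   loglik = NA_real_, n_fit = 0L, convergence = 0L),
              class = "migsim_fit")
  }
  ## standardised JF(3, 2) has median ~0.5249; shift mu so the [0,1]
  ## truncated median lands near the target per-bin medians
  jf_med <- qjfst(0.5, 0, 1, 3, 2)
  emi_target <- c(P1 = 0.006, P2 = 0.004, P3 = 0.002, P4 = 0.001)
  emi_sigma <- c(P1 = 0.0015, P2 = 0.001, P3 = 5e-4, P4 = 2.5e-4)
  plabs <- bin_labels("P", scheme$population_edges)
  if (!all(plabs %in% names(emi_target))) {
    ## non-default schemes: interpolate targets across bins
    emi_target <- stats::setNames(
      exp(seq(log(0.006), log(0.001), length.out = length(plabs))), plabs)
    emi_sigma <- emi_target / 4
  }
  emigration <- stats::setNames(lapply(plabs, function(l) {
    truth_fit("jones_faddy_skew_t",
              c(mu = unname(emi_target[l] - jf_med * emi_sigma[l]),
                sigma = unname(emi_sigma[l]), a = 3, b = 2))
  }), plabs)

  glabs <- bin_labels("g", scheme$gdp_ratio_edges)
  dlabs <- bin_labels("d", scheme$diaspora_edges)
  d_median <- stats::setNames(
    exp(seq(log(1e-5), log(0.3), length.out = length(dlabs))), dlabs)
  g_mult <- stats::setNames(
    seq(0.9, 1.1, length.out = length(glabs)), glabs)
  shares <- list()
  for (gl in glabs) for (dl in dlabs) {
    med <- d_median[[dl]] * g_mult[[gl]]
    sigma <- med / 2
    shares[[paste(gl, dl, sep = ":")]] <-
      truth_fit("weibull_max",
                c(shape = 2, mu = med + sigma * sqrt(log(2)), sigma = sigma))
  }

  flow_distribution_set(
    emigration = emigration, shares = shares,
    return_rate = truth_fit("student_t", c(mu = 0.004, sigma = 8e-4, df = 5)),
    provenance = list(source = "synthetic ground truth"))
}

#' Configuration of the synthetic world generator
#'
#' @param n_countries Number of countries (>= number of population bins so
#'   every bin can be covered).
#' @param start_year First simulated year.
#' @param n_periods Number of 5-year calibration periods the flow history
#'   spans.
#' @param gdpc_range Log-uniform range of GDP per capita.
#' @param stock_sparsity Probability that an ordered country pair starts
#'   with a nonzero migrant stock.
#' @param stock_rel_range Log-uniform range of initial stocks relative to
#'   the origin population (spans all diaspora bins at the defaults).
#' @param host_cap Upper bound on the total initial stock hosted by a
#'   country, as a fraction of its native population (rows of the stock
#'   matrix are scaled down proportionally when the draw exceeds it);
#'   keeps small countries from hosting migrant populations larger than
#'   themselves.
#' @param diaspora_cap Upper bound on a country's total diaspora as a
#'   fraction of its native population (columns scaled down analogously).
#' @param birth_rate_range,death_rate_range Uniform ranges of yearly
#'   natural birth/death rates; the natural change rate is their
#'   difference.
#' @param truth Ground-truth [flow_distribution_set()].
#' @param scheme A [partition_scheme()].
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_countries = 40, start_year = 1990, n_periods = 6,
                             gdpc_range = c(300, 1e5),
                             stock_sparsity = 0.6,
                             stock_rel_range = c(1e-8, 0.3),
                             host_cap = 0.2,
                             diaspora_cap = 0.5,
                             birth_rate_range = c(0.008, 0.035),
                             death_rate_range = c(0.004, 0.02),
                             truth = default_truth_dists(scheme),
                             scheme = partition_scheme(),
                             seed = 1) {
  structure(list(n_countries = as.integer(n_countries), start_year = as.integer(start_year),
                 n_periods = as.integer(n_periods), gdpc_range = gdpc_range,
                 stock_sparsity = stock_sparsity, stock_rel_range = stock_rel_range,
                 host_cap = host_cap, diaspora_cap = diaspora_cap,
                 birth_rate_range = birth_rate_range, death_rate_range = death_rate_range,
                 truth = truth, scheme = scheme, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic country panel and initial world state
#'
#' Countries are assigned round-robin to the population bins (so every bin
#' is covered) with log-uniform populations within each bin, log-uniform
#' GDP per capita, uniform natural birth and death rates (the natural
#' change rate is their difference, constant over the panel years), and
#' round-robin region and income-group labels.  The initial migrant stock
#' matrix is sparse, with nonzero entries log-uniform relative to the
#' origin population so all diaspora bins occur.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `panel` (a [country_panel()] covering
#'   `start_year .. start_year + 5 * n_periods`) and `state` (the initial
#'   [world_state()]).
#' @export
generate_world <- function(cfg = synthetic_config()) {
  scheme <- cfg$scheme
  plabs <- bin_labels("P", scheme$population_edges)
  if (cfg$n_countries < length(plabs))
    stop("cannot cover population bin ", plabs[cfg$n_countries + 1L],
         ": need at least ", length(plabs), " countries", call. = FALSE)
  set.seed(cfg$seed)
  n <- cfg$n_countries
  ids <- sprintf("C%02d", seq_len(n))
  bin_idx <- rep(seq_along(plabs), length.out = n)
  edges <- scheme$population_edges
  lo <- pmax(edges[bin_idx], 1e4)
  hi <- pmin(edges[bin_idx + 1L], 1e9)
  P <- 10^stats::runif(n, log10(lo), log10(hi))
  gdpc <- 10^stats::runif(n, log10(cfg$gdpc_range[1]), log10(cfg$gdpc_range[2]))
  c_birth <- stats::runif(n, cfg$birth_rate_range[1], cfg$birth_rate_range[2])
  c_death <- stats::runif(n, cfg$death_rate_range[1], cfg$death_rate_range[2])
  region <- rep(c("Africa", "Americas", "Asia", "Europe", "Oceania"), length.out = n)
  income <- rep(c("low", "lower_middle", "upper_middle", "high"), length.out = n)

  years <- cfg$start_year + 0:(5 * cfg$n_periods)
  panel <- country_panel(data.frame(
    country_id = rep(ids, each = length(years)),
    year = rep(years, n),
    population = rep(P, each = length(years)),
    natural_change_rate = rep(c_birth - c_death, each = length(years)),
    birth_rate = rep(c_birth, each = length(years)),
    death_rate = rep(c_death, each = length(years)),
    gdpc = rep(gdpc, each = length(years)),
    region = rep(region, each = length(years)),
    income_group = rep(income, each = length(years))))

  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (stats::runif(1) < cfg$stock_sparsity) {
      rel <- 10^stats::runif(1, log10(cfg$stock_rel_range[1]),
                             log10(cfg$stock_rel_range[2]))
      ## gravity-style destination weighting: diasporas concentrate in
      ## large host countries, as in observed stock matrices
      D[j, i] <- P[i] * rel * sqrt(P[j] / max(P))   # origin-i stock resident in j
    }
  }
  ## anchor corridors: every origin's diaspora is concentrated in a few
  ## dominant corridors hosted by comparably sized or larger countries,
  ## as in observed bilateral stock matrices
  anchor_rel <- c(0.15, 0.1, 0.05)
  for (i in seq_len(n)) {
    cand <- setdiff(which(P >= 0.75 * P[i]), i)
    if (!length(cand)) cand <- setdiff(order(P, decreasing = TRUE), i)[1:3]
    pick <- if (length(cand) <= length(anchor_rel)) cand
            else sample(cand, length(anchor_rel))
    D[cbind(pick, i)] <- pmax(D[cbind(pick, i)],
                              P[i] * anchor_rel[seq_along(pick)])
  }
  ## keep total hosted stock plausible relative to the residence
  ## population, and total diaspora plausible relative to the origin
  hosted <- rowSums(D)
  over <- hosted > cfg$host_cap * P
  if (any(over)) D[over, ] <- D[over, ] * (cfg$host_cap * P / hosted)[over]
  abroad <- colSums(D)
  over <- abroad > cfg$diaspora_cap * P
  if (any(over)) D[, over] <- D[, over] %*% diag(x = (cfg$diaspora_cap * P / abroad)[over],
                                                 nrow = sum(over))
  list(panel = country_panel(data.frame(panel)),
       state = world_state(cfg$start_year, stats::setNames(P, ids), D))
}

#' Forward-simulate a flow history from a known ground truth
#'
#' Runs the sampling and evolution machinery with the ground-truth
#' distribution set, then exports what a calibration dataset looks like:
#' yearly emigration and return flows summed to 5-year periods, stock
#' snapshots at period boundaries, and the panel updated with the realized
#' native populations.  The outputs use exactly the tables
#' [calibrate_model()] consumes, closing the generate-calibrate loop.
#'
#' @param world Output of [generate_world()].
#' @param truth Ground-truth [flow_distribution_set()].
#' @param periods Number of 5-year periods to simulate.
#' @param seed Integer seed for the flow draws.
#' @param scheme A [partition_scheme()].
#' @param diaspora_mode Passed to the sampler.
#' @return List with `flows`, `return_flows`, `stocks` (long data frames),
#'   `panel` (realized populations) and `trajectory`.
#' @export
generate_flow_history <- function(world, truth, periods, seed,
                                  scheme = partition_scheme(),
                                  diaspora_mode = c("bilateral", "origin_total")) {
  diaspora_mode <- match.arg(diaspora_mode)
  ctx <- sampler_context("stochastic", seed = seed)
  horizon <- 5L * as.integer(periods)
  traj <- simulate_trajectory(world$state, world$panel, truth, horizon, ctx,
                              scheme, diaspora_mode)
  countries <- names(world$state$P)
  n <- length(countries)
  start <- world$state$year

  flows <- NULL; rflows <- NULL; stock_rows <- NULL
  for (p in seq_len(periods)) {
    yrs <- (p - 1L) * 5L + 1:5
    Msum <- Reduce(`+`, lapply(traj$flows[yrs], function(f) f$M))
    Rsum <- Reduce(`+`, lapply(traj$flows[yrs], function(f) f$R))
    ps <- start + (p - 1L) * 5L
    nz <- which(Msum > 0, arr.ind = TRUE)
    if (nrow(nz)) flows <- rbind(flows, data.frame(
      origin = countries[nz[, 1]], destination = countries[nz[, 2]],
      period_start = ps, period_end = ps + 5L, flow = Msum[nz]))
    nzr <- which(Rsum > 0, arr.ind = TRUE)
    if (nrow(nzr)) rflows <- rbind(rflows, data.frame(
      residence = countries[nzr[, 1]], origin = countries[nzr[, 2]],
      period_start = ps, period_end = ps + 5L, flow = Rsum[nzr]))
    Dp <- traj$states[[(p - 1L) * 5L + 1L]]$D
    nzd <- which(Dp > 0, arr.ind = TRUE)
    if (nrow(nzd)) stock_rows <- rbind(stock_rows, data.frame(
      residence = countries[nzd[, 1]], origin = countries[nzd[, 2]],
      year = ps, stock = Dp[nzd]))
  }
  empty_flow <- data.frame(origin = character(), destination = character(),
                           period_start = integer(), period_end = integer(),
                           flow = numeric())
  empty_ret <- data.frame(residence = character(), origin = character(),
                          period_start = integer(), period_end = integer(),
                          flow = numeric())
  empty_stock <- data.frame(residence = character(), origin = character(),
                            year = integer(), stock = numeric())

  ## panel with the realized native populations along the trajectory
  panel <- world$panel
  for (h in seq_along(traj$states)) {
    yr <- start + h - 1L
    idx <- match(paste(countries, yr), paste(panel$country_id, panel$year))
    panel$population[idx] <- traj$states[[h]]$P
  }
  list(flows = if (is.null(flows)) empty_flow else flows,
       return_flows = if (is.null(rflows)) empty_ret else rflows,
       stocks = if (is.null(stock_rows)) empty_stock else stock_rows,
       panel = country_panel(data.frame(panel)),
       trajectory = traj)
}
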