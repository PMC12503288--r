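#' Advance the world by one year
#'
#' Draws all flows from the state at year `t` and applies the demographic
#' accounting equations simultaneously:
#' native populations lose emigrants, are propagated through the natural
#' change rate, and gain incoming returns and migrant births
#' (`P'_i = (P_i - sum_l M_il) (1 + c_i) + sum_l R_li + sum_l B_il`);
#' migrant stocks shrink by origin-country mortality and returns and gain
#' the year's immigration
#' (`D'[i,k] = D[i,k] (1 - c_death_k) - R[i,k] + M[k,i]`).  Immigration
#' inflows are not rescaled by births/deaths within the year.  Any negative
#' result (possible when mortality and a large return draw overdraw a
#' stock) is clamped to zero and counted in the `clamped` attribute.
#'
#' @param state A [world_state()] at year `t`.
#' @param panel A [country_panel()] covering year `t`.
#' @param dists A [flow_distribution_set()].
#' @param ctx A [sampler_context()].
#' @param scheme A [partition_scheme()].
#' @param diaspora_mode Passed to [sample_destination_shares()].
#' @return List with `state` (the [world_state()] at `t + 1`, attribute
#'   `clamped` = number of clamped entries) and `flows` (the
#'   [flow_matrices()] drawn at `t`).
#' @export
step_year <- function(state, panel, dists, ctx, scheme = partition_scheme(),
                 diaspora_mode = c("bilateral", "origin_total")) {
  diaspora_mode <- match.arg(diaspora_mode)
  countries <- names(state$P)
  py <- panel_year(panel, state$year, countries)

  rate <- sample_emigration_rate(state$P, dists, ctx, scheme)
  S <- draw_share_matrix(state, py$gdpc, dists, ctx, scheme, diaspora_mode)
  M <- (state$P * rate) * S
  R <- sample_return_flows(state, dists, ctx)
  B <- birth_flows(state, py$c_birth)

  res <- apply_flows(state, flow_matrices(M, R, B), py)
  list(state = res$state, flows = flow_matrices(M, R, B))
}

## one share draw per ordered (origin, destination) pair, grouped by
## partition cell; rows renormalized to sum to 1
draw_share_matrix <- function(state, gdpc, dists, ctx, scheme, diaspora_mode) {
  countries <- names(state$P)
  n <- length(countries)
  g <- outer(gdpc[countries], gdpc[countries], `/`)      # g[o, d]
  dcov <- if (diaspora_mode == "bilateral") {
    t(state$D) / pmax(state$P, 1e-300)                   # dcov[o, d] = D[d, o] / P_o
  } else {
    matrix(colSums(state$D) / pmax(state$P, 1e-300), n, n)
  }
  off <- which(row(g) != col(g))
  cells <- paste(gdp_ratio_label(g[off], scheme),
                 diaspora_label(dcov[off], scheme), sep = ":")
  raw <- matrix(0, n, n, dimnames = list(countries, countries))
  raw[off] <- draw_by_label(cells, function(cl) {
    share_fit_for(dists, sub(":.*$", "", cl), sub("^.*:", "", cl))
  }, ctx)
  tot <- rowSums(raw)
  zero <- tot <= 0
  if (any(zero)) {
    warning("all raw destination shares zero for ",
            paste(countries[zero], collapse = ", "), "; using uniform shares",
            call. = FALSE)
    raw[zero, ] <- 1 / (n - 1)
    diag(raw) <- 0
    tot <- rowSums(raw)
  }
  raw / tot
}

## deterministic bookkeeping shared by step_year() and replay_trajectory()
apply_flows <- function(state, flows, py) {
  P_new <- (state$P - rowSums(flows$M)) * (1 + py$c) +
    colSums(flows$R) + rowSums(flows$B)
  D_new <- sweep(state$D, 2, 1 - py$c_death, `*`) - flows$R + t(flows$M)
  diag(D_new) <- 0
  clamped <- sum(P_new < 0) + sum(D_new < 0)
  P_new[P_new < 0] <- 0
  D_new[D_new < 0] <- 0
  st <- world_state(state$year + 1L, P_new, D_new)
  attr(st, "clamped") <- clamped
  list(state = st, clamped = clamped)
}

#' Simulate a trajectory of world states
#'
#' Repeated application of [step_year()] from the initial state over `horizon`
#' years, recording every state and the flows that produced it.
#'
#' @param initial A [world_state()].
#' @param panel A [country_panel()] covering `initial$year` to
#'   `initial$year + horizon - 1`.
#' @param dists A [flow_distribution_set()].
#' @param horizon Number of years to simulate (>= 0).
#' @param ctx A [sampler_context()].
#' @inheritParams step_year
#' @return A `migsim_trajectory`: list with `states` (length
#'   `horizon + 1`), `flows` (length `horizon`), `mode`, `seed`, `clamped`.
#' @export
simulate_trajectory <- function(initial, panel, dists, horizon,
                                ctx = sampler_context(),
                                scheme = partition_scheme(),
                                diaspora_mode = c("bilateral", "origin_total")) {
  diaspora_mode <- match.arg(diaspora_mode)
  stopifnot(horizon >= 0)
  states <- vector("list", horizon + 1)
  flows <- vector("list", horizon)
  states[[1]] <- initial
  clamped <- 0L
  for (h in seq_len(horizon)) {
    res <- step_year(states[[h]], panel, dists, ctx, scheme, diaspora_mode)
    states[[h + 1]] <- res$state
    flows[[h]] <- res$flows
    clamped <- clamped + attr(res$state, "clamped")
  }
  structure(list(states = states, flows = flows, mode = ctx$mode,
                 seed = ctx$seed, clamped = clamped),
            class = "migsim_trajectory")
}

#' Deterministic model run
#'
#' Single trajectory with every random draw replaced by the median of its
#' truncated distribution.
#'
#' @inheritParams simulate_trajectory
#' @export
deterministic_run <- function(initial, panel, dists, horizon,
                              scheme = partition_scheme(),
                              diaspora_mode = c("bilateral", "origin_total")) {
  simulate_trajectory(initial, panel, dists, horizon,
                      ctx = sampler_context("deterministic"),
                      scheme = scheme, diaspora_mode = diaspora_mode)
}

#' Recompute a trajectory's states from its recorded flows
#'
#' Replays the accounting equations with the stored flow matrices; the
#' recomputed states must match the recorded ones bit-exactly.
#'
#' @param traj A `migsim_trajectory`.
#' @param panel The panel it was simulated with.
#' @return Maximum absolute difference between recorded and replayed
#'   states (0 for a consistent trajectory).
#' @export
replay_trajectory <- function(traj, panel) {
  maxdiff <- 0
  st <- traj$states[[1]]
  countries <- names(st$P)
  for (h in seq_along(traj$flows)) {
    py <- panel_year(panel, st$year, countries)
    st <- apply_flows(st, traj$flows[[h]], py)$state
    rec <- traj$states[[h + 1]]
    maxdiff <- max(maxdiff, abs(st$P - rec$P), abs(st$D - rec$D))
  }
  maxdiff
}

## per-sample seed derived from the master seed; depends only on (seed, k)
## so ensembles are reproducible, nestable across sizes, and order-free
sample_seed <- function(master_seed, k) {
  (as.numeric(master_seed) %% 1e6) * 2039 + k * 7919
}

trajectory_series <- function(traj) {
  P <- vapply(traj$states, function(s) sum(s$P), numeric(1))
  D <- vapply(traj$states, function(s) sum(s$D), numeric(1))
  origin <- vapply(traj$states, function(s) colSums(s$D),
                   numeric(length(traj$states[[1]]$P)))
  residence <- vapply(traj$states, function(s) rowSums(s$D),
                      numeric(length(traj$states[[1]]$P)))
  list(total_population = P, total_migrant_stock = D,
       origin_stock = origin, residence_stock = residence)
}

ens_stats <- c(q2.5 = 0.025, q25 = 0.25, median = 0.5, q75 = 0.75, q97.5 = 0.975)

summarise_samples <- function(mat, series, years) {
  ## mat: [year, sample]
  qs <- apply(mat, 1, stats::quantile, probs = ens_stats, names = FALSE, type = 7)
  data.frame(series = series,
             year = rep(years, each = length(ens_stats)),
             stat = rep(names(ens_stats), length(years)),
             value = as.vector(qs))
}

#' Run a Monte-Carlo ensemble
#'
#' Simulates `n_samples` independent stochastic trajectories, each seeded
#' by a deterministic function of `(seed, k)` so results do not depend on
#' execution order and ensembles of different sizes share their leading
#' samples.  Summaries are the per-year empirical median and central 50%
#' and 95% intervals of each tracked series (total population, total
#' migrant stock, per-country origin- and residence-side stocks).
#'
#' @inheritParams simulate_trajectory
#' @param n_samples Number of ensemble members (>= 1).
#' @param seed Master seed (integer).
#' @return An `ensemble_summary`: `summary` (tidy data frame
#'   `series, year, stat, value` with stats `median`, `q25`, `q75`,
#'   `q2.5`, `q97.5`), per-sample arrays in `samples`, plus `n_samples`,
#'   `seed`, `years`, `countries`.
#' @export
run_ensemble <- function(initial, panel, dists, horizon, n_samples, seed,
                         scheme = partition_scheme(),
                         diaspora_mode = c("bilateral", "origin_total")) {
  diaspora_mode <- match.arg(diaspora_mode)
  stopifnot(n_samples >= 1)
  countries <- names(initial$P)
  years <- initial$year + 0:horizon
  totP <- matrix(NA_real_, horizon + 1, n_samples)
  totD <- matrix(NA_real_, horizon + 1, n_samples)
  orig <- array(NA_real_, c(length(countries), horizon + 1, n_samples),
                dimnames = list(countries, NULL, NULL))
  resid <- orig
  for (k in seq_len(n_samples)) {
    ctx <- sampler_context("stochastic", seed = sample_seed(seed, k))
    tr <- simulate_trajectory(initial, panel, dists, horizon, ctx, scheme,
                              diaspora_mode)
    ser <- trajectory_series(tr)
    totP[, k] <- ser$total_population
    totD[, k] <- ser$total_migrant_stock
    orig[, , k] <- ser$origin_stock
    resid[, , k] <- ser$residence_stock
  }
  summary <- rbind(summarise_samples(totP, "total_population", years),
                   summarise_samples(totD, "total_migrant_stock", years))
  structure(list(summary = summary,
                 samples = list(total_population = totP,
                                total_migrant_stock = totD,
                                origin_stock = orig,
                                residence_stock = resid),
                 n_samples = n_samples, seed = seed, years = years,
                 countries = countries),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary: %d samples, years %d-%d, %d countries>\n",
              x$n_samples, min(x$years), max(x$years), length(x$countries)))
  invisible(x)
}

#' Convergence of the ensemble median with sample size
#'
#' Runs the largest requested ensemble once and reports, for each sample
#' size, the median horizon-year total migrant stock over the leading
#' samples, together with successive absolute differences.  Because
#' per-sample seeds depend only on `(seed, k)`, the smaller ensembles are
#' exact prefixes of the largest one.
#'
#' @inheritParams run_ensemble
#' @param sample_sizes Increasing integer vector of ensemble sizes
#'   (length >= 2).
#' @return Data frame with columns `n_samples`, `median_total_stock`,
#'   `diff_prev` (absolute change from the previous size; `NA` for the
#'   first).
#' @export
convergence_diagnostic <- function(initial, panel, dists, horizon,
                                   sample_sizes, seed,
                                   scheme = partition_scheme(),
                                   diaspora_mode = c("bilateral", "origin_total")) {
  diaspora_mode <- match.arg(diaspora_mode)
  sample_sizes <- sort(unique(as.integer(sample_sizes)))
  if (length(sample_sizes) < 2) stop("need at least two sample sizes", call. = FALSE)
  n_max <- max(sample_sizes)
  finals <- numeric(n_max)
  for (k in seq_len(n_max)) {
    ctx <- sampler_context("stochastic", seed = sample_seed(seed, k))
    tr <- simulate_trajectory(initial, panel, dists, horizon, ctx, scheme,
                              diaspora_mode)
    finals[k] <- sum(tr$states[[horizon + 1]]$D)
  }
  med <- vapply(sample_sizes, function(n) stats::median(finals[seq_len(n)]), numeric(1))
  data.frame(n_samples = sample_sizes,
             median_total_stock = med,
             diff_prev = c(NA, abs(diff(med))))
}
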