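truth <- default_truth_dists()

test_that("accounting equations match hand-evaluated examples", {
  ids <- c("AAA", "BBB")
  ## native side: P' = (1000 - 10) * 1.01 + 2 + 1 = 1002.9
  st <- tiny_state(ids, c(1000, 5000),
                   matrix(c(0, 0, 100, 0), 2, 2, dimnames = list(ids, ids)))
  M <- matrix(c(0, 7, 10, 0), 2, 2, dimnames = list(ids, ids))   # AAA -> BBB: 10, BBB -> AAA: 7
  R <- matrix(c(0, 2, 5, 0), 2, 2, dimnames = list(ids, ids))    # returns
  B <- matrix(c(0, 0, 1, 0), 2, 2, dimnames = list(ids, ids))    # births in AAA
  py <- list(c = c(AAA = 0.01, BBB = 0),
             c_birth = c(AAA = 0, BBB = 0.01),
             c_death = c(AAA = 0, BBB = 0.01))
  res <- migsim:::apply_flows(st, flow_matrices(M, R, B), py)
  ## AAA: returns arriving from BBB's diaspora of AAA = R[BBB, AAA] = 2
  expect_equal(unname(res$state$P[["AAA"]]), (1000 - 10) * 1.01 + 2 + 1)
  ## migrant side: D'[AAA, BBB] = 100 * (1 - 0.01) - 5 + M[BBB, AAA] = 101
  expect_equal(unname(res$state$D["AAA", "BBB"]), 100 * 0.99 - 5 + 7)
  ## stock created by the AAA -> BBB flow, net of the recorded return
  expect_equal(unname(res$state$D["BBB", "AAA"]), 0 - 2 + 10)
})

test_that("a world without flows or natural change is a fixed point", {
  ids <- sprintf("C%02d", 1:4)
  panel <- tiny_panel(ids, 1990:1995, c(5e5, 5e6, 5e7, 5e8))
  D <- matrix(0, 4, 4, dimnames = list(ids, ids)); D[1, 2] <- 1000
  st <- tiny_state(ids, c(5e5, 5e6, 5e7, 5e8), D)
  tr <- suppressWarnings(
    simulate_trajectory(st, panel, null_dists(), 5,
                        sampler_context("stochastic", seed = 1)))
  expect_equal(tr$states[[6]]$P, st$P)
  expect_equal(tr$states[[6]]$D, st$D)
})

test_that("total persons are conserved when natural rates are zero", {
  cfg <- synthetic_config(n_countries = 10, n_periods = 2, seed = 6,
                          birth_rate_range = c(0, 0), death_rate_range = c(0, 0))
  w <- generate_world(cfg)
  tr <- simulate_trajectory(w$state, w$panel, truth, 10,
                            sampler_context("stochastic", seed = 3))
  tot <- vapply(tr$states, function(s) sum(s$P) + sum(s$D), numeric(1))
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
  expect_equal(tr$clamped, 0L)
})

test_that("trajectories replay bit-exactly from their recorded flows", {
  cfg <- synthetic_config(n_countries = 8, n_periods = 2, seed = 9)
  w <- generate_world(cfg)
  tr <- simulate_trajectory(w$state, w$panel, truth, 8,
                            sampler_context("stochastic", seed = 31))
  expect_identical(replay_trajectory(tr, w$panel), 0)
})

test_that("horizon zero returns only the initial state", {
  cfg <- synthetic_config(n_countries = 6, n_periods = 1, seed = 4)
  w <- generate_world(cfg)
  tr <- simulate_trajectory(w$state, w$panel, truth, 0)
  expect_length(tr$states, 1)
  expect_length(tr$flows, 0)
})

test_that("deterministic runs are exactly reproducible without a seed", {
  cfg <- synthetic_config(n_countries = 6, n_periods = 1, seed = 4)
  w <- generate_world(cfg)
  d1 <- deterministic_run(w$state, w$panel, truth, 5)
  d2 <- deterministic_run(w$state, w$panel, truth, 5)
  expect_identical(d1$states, d2$states)
})

test_that("ensemble summaries have nested, ordered quantile bands", {
  cfg <- synthetic_config(n_countries = 6, n_periods = 2, seed = 12)
  w <- generate_world(cfg)
  ens <- run_ensemble(w$state, w$panel, truth, 8, n_samples = 30, seed = 17)
  wide <- stats::reshape(ens$summary, idvar = c("series", "year"),
                         timevar = "stat", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  expect_true(all(wide$q2.5 <= wide$q25 + 1e-12))
  expect_true(all(wide$q25 <= wide$median + 1e-12))
  expect_true(all(wide$median <= wide$q75 + 1e-12))
  expect_true(all(wide$q75 <= wide$q97.5 + 1e-12))
  ## same seed, same summary
  ens2 <- run_ensemble(w$state, w$panel, truth, 8, n_samples = 30, seed = 17)
  expect_identical(ens$summary, ens2$summary)
})

test_that("a single-sample ensemble degenerates to its trajectory", {
  cfg <- synthetic_config(n_countries = 6, n_periods = 1, seed = 5)
  w <- generate_world(cfg)
  ens <- run_ensemble(w$state, w$panel, truth, 4, n_samples = 1, seed = 23)
  ss <- ens$summary[ens$summary$series == "total_migrant_stock", ]
  for (y in unique(ss$year))
    expect_equal(length(unique(ss$value[ss$year == y])), 1)
})

test_that("convergence diagnostics are nested prefixes of one ensemble", {
  cfg <- synthetic_config(n_countries = 6, n_periods = 1, seed = 5)
  w <- generate_world(cfg)
  cd <- convergence_diagnostic(w$state, w$panel, truth, 4, c(10, 20), seed = 23)
  expect_equal(cd$n_samples, c(10L, 20L))
  expect_true(is.na(cd$diff_prev[1]))
  ## identical call reproduces identical medians
  cd2 <- convergence_diagnostic(w$state, w$panel, truth, 4, c(10, 20), seed = 23)
  expect_identical(cd, cd2)
  ## the n = 20 median matches a directly run 20-sample ensemble
  ens <- run_ensemble(w$state, w$panel, truth, 4, n_samples = 20, seed = 23)
  fin <- ens$summary[ens$summary$series == "total_migrant_stock" &
                     ens$summary$year == max(ens$years) &
                     ens$summary$stat == "median", "value"]
  expect_equal(cd$median_total_stock[2], fin)
})
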