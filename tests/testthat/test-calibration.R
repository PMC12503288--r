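make_history <- function(n = 10, periods = 2, seed = 25) {
  cfg <- synthetic_config(n_countries = n, n_periods = periods, seed = seed)
  w <- generate_world(cfg)
  generate_flow_history(w, cfg$truth, periods = periods, seed = seed + 1)
}

test_that("calibration assembles all components with fallbacks", {
  hist <- make_history()
  cal <- suppressWarnings(calibrate_model(hist$flows, hist$return_flows,
                                          hist$stocks, hist$panel, min_n = 15))
  expect_s3_class(cal, "flow_distribution_set")
  expect_setequal(names(cal$emigration), paste0("P", 1:4))
  expect_true(all(vapply(cal$emigration, inherits, logical(1), "migsim_fit")))
  expect_s3_class(cal$return_rate, "migsim_fit")
  expect_equal(cal$emigration$P1$family, "jones_faddy_skew_t")
  expect_equal(cal$return_rate$family, "student_t")
  fitted <- Filter(Negate(is_empty_fit), cal$shares)
  expect_true(all(vapply(fitted, function(f) f$family, character(1)) ==
                    "weibull_max"))
  ## every empty cell resolves to a usable pooled fit
  for (key in names(cal$fallback)) {
    gl <- sub(":.*$", "", key); dl <- sub("^.*:", "", key)
    f <- share_fit_for(cal, gl, dl)
    expect_s3_class(f, "migsim_fit")
  }
  ## provenance records sample counts and options
  expect_equal(sum(cal$provenance$n_emigration), 10 * 2)
  expect_equal(cal$provenance$options$min_n, 15)
})

test_that("calibration is deterministic given identical inputs", {
  hist <- make_history(12, 2, seed = 33)
  c1 <- suppressWarnings(calibrate_model(hist$flows, hist$return_flows,
                                         hist$stocks, hist$panel, min_n = 10))
  c2 <- suppressWarnings(calibrate_model(hist$flows, hist$return_flows,
                                         hist$stocks, hist$panel, min_n = 10))
  expect_identical(c1$emigration, c2$emigration)
  expect_identical(c1$shares, c2$shares)
  expect_identical(c1$return_rate, c2$return_rate)
})

test_that("an empty population bin aborts calibration", {
  ## world confined to P2/P3 only: no P1 or P4 observations possible
  ids <- c("AAA", "BBB", "CCC")
  panel <- tiny_panel(ids, c(1990, 1995), c(2e6, 5e6, 2e7),
                      c_birth = 0.01, c_death = 0.01, gdpc = c(1e3, 1e4, 2e4))
  flows <- data.frame(origin = ids, destination = c("BBB", "CCC", "AAA"),
                      period_start = 1990, period_end = 1995, flow = 1000)
  stocks <- data.frame(residence = "BBB", origin = "AAA", year = 1990,
                       stock = 1e4)
  rflows <- data.frame(residence = "BBB", origin = "AAA",
                       period_start = 1990, period_end = 1995, flow = 10)
  expect_error(calibrate_model(flows, rflows, stocks, panel),
               "population bin")
})

test_that("thin share cells fall back to the pooled d-bin distribution", {
  hist <- make_history(10, 2, seed = 45)
  cal <- suppressWarnings(calibrate_model(hist$flows, hist$return_flows,
                                          hist$stocks, hist$panel,
                                          min_n = 1e5))   # force all cells empty
  expect_true(all(vapply(cal$shares, is_empty_fit, logical(1))))
  expect_true(all(names(cal$shares) %in% names(cal$fallback)))
  ## the global pool always exists when any share data exists
  f <- share_fit_for(cal, "g1", "d1")
  expect_s3_class(f, "migsim_fit")
})
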