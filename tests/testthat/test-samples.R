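test_that("emigration rate samples are binned, rescaled 5-year totals", {
  panel <- tiny_panel(c("AAA", "BBB"), c(1990, 1995), c(1e6, 5e7))
  flows <- data.frame(origin = c("AAA", "AAA", "BBB"),
                      destination = c("BBB", "BBB", "AAA"),
                      period_start = c(1990, 1995, 1990),
                      period_end = c(1995, 2000, 1995),
                      flow = c(5e4, 0, 1e5))
  s <- build_emigration_rate_samples(flows, panel)
  ## P = 1e6, 5-year outflow 5e4: rate 0.05 -> yearly 0.0102062, bin P1
  expect_equal(s$P1$values, c(0.010206218313011495, 0),
               tolerance = 1e-12)
  ## zero outflow is retained as a zero rate in its bin
  expect_equal(s$P1$n, 2L)
  expect_equal(s$P3$values, rescale_five_year_rate(1e5 / 5e7), tolerance = 1e-12)
  expect_equal(s$P2$n, 0L)
})

test_that("a country straddling a bin boundary contributes to both bins", {
  panel <- country_panel(data.frame(
    country_id = "AAA", year = c(1990, 1995),
    population = c(9e5, 2e6), natural_change_rate = 0,
    birth_rate = 0, death_rate = 0, gdpc = 1e4,
    region = "R", income_group = "m"))
  flows <- data.frame(origin = "AAA", destination = "BBB",
                      period_start = c(1990, 1995), period_end = c(1995, 2000),
                      flow = c(1e4, 1e4))
  s <- build_emigration_rate_samples(flows, panel)
  expect_equal(s$P1$n, 1L)
  expect_equal(s$P2$n, 1L)
})

test_that("zero-population origins are skipped with a warning", {
  panel <- tiny_panel(c("AAA", "BBB"), 1990, c(0, 1e6))
  flows <- data.frame(origin = c("AAA", "BBB"), destination = c("BBB", "AAA"),
                      period_start = 1990, period_end = 1995, flow = c(10, 10))
  expect_warning(s <- build_emigration_rate_samples(flows, panel), "skipped")
  expect_equal(sum(vapply(s, function(x) x$n, integer(1))), 1L)
})

test_that("share samples carry the (g, d) cell labels", {
  ids <- c("AAA", "BBB", "CCC")
  panel <- tiny_panel(ids, 1990, c(1e6, 1e7, 1e7), gdpc = c(1000, 20000, 1000))
  flows <- data.frame(origin = "AAA", destination = c("BBB", "CCC"),
                      period_start = 1990, period_end = 1995,
                      flow = c(25, 75))
  ## AAA-born stock: 0.2 * P_AAA in BBB (d5), none in CCC (d1)
  stocks <- data.frame(residence = "BBB", origin = "AAA", year = 1990,
                       stock = 0.2 * 1e6)
  s <- build_share_samples(flows, stocks, panel)
  ## g(AAA/BBB) = 1000/20000 = 0.05 -> g1; d = 0.2 -> d5
  expect_equal(s[["g1:d5"]]$values, 0.25)
  ## g(AAA/CCC) = 1 -> g3 (left-closed); no stock -> d1
  expect_equal(s[["g3:d1"]]$values, 0.75)
  expect_equal(sum(vapply(s, function(x) x$n, integer(1))), 2L)
})

test_that("origins with zero total outflow are excluded from shares", {
  ids <- c("AAA", "BBB")
  panel <- tiny_panel(ids, 1990, c(1e6, 1e6))
  flows <- data.frame(origin = "AAA", destination = "BBB",
                      period_start = 1990, period_end = 1995, flow = 0)
  stocks <- data.frame(residence = character(), origin = character(),
                       year = integer(), stock = numeric())
  s <- build_share_samples(flows, stocks, panel)
  expect_equal(sum(vapply(s, function(x) x$n, integer(1))), 0L)
})

test_that("return rates rescale, pool, and discard rates above 100%", {
  stocks <- data.frame(residence = c("AAA", "AAA", "BBB"),
                       origin = c("BBB", "CCC", "CCC"),
                       year = 1990, stock = c(1000, 1000, 500))
  rflows <- data.frame(residence = c("AAA", "AAA", "BBB"),
                       origin = c("BBB", "CCC", "CCC"),
                       period_start = 1990, period_end = 1995,
                       flow = c(10, 1200, 0))
  s <- build_return_rate_samples(rflows, stocks)
  ## R = 10, D = 1000: 5-year rate 0.01 -> yearly 0.0020080
  expect_equal(sort(s$values), c(0, 0.002008048338574153), tolerance = 1e-12)
  expect_equal(attr(s, "n_discarded"), 1L)   # exactly the > 100% record
  expect_equal(s$label, "return")
})

test_that("return flows with no matching stock are discarded and counted", {
  stocks <- data.frame(residence = "AAA", origin = "BBB", year = 1990, stock = 0)
  rflows <- data.frame(residence = "AAA", origin = "BBB",
                       period_start = 1990, period_end = 1995, flow = 5)
  s <- build_return_rate_samples(rflows, stocks)
  expect_equal(s$n, 0L)
  expect_equal(attr(s, "n_discarded"), 1L)
})

test_that("all-zero return flows yield zero rates and no discards", {
  stocks <- data.frame(residence = "AAA", origin = "BBB", year = 1990, stock = 100)
  rflows <- data.frame(residence = "AAA", origin = "BBB",
                       period_start = 1990, period_end = 1995, flow = 0)
  s <- build_return_rate_samples(rflows, stocks)
  expect_equal(s$values, 0)
  expect_equal(attr(s, "n_discarded"), 0L)
})
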