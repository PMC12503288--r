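test_that("population bins follow the right-closed default edges", {
  expect_equal(population_label(5e5), "P1")
  expect_equal(population_label(1e6), "P1")   # boundary belongs below
  expect_equal(population_label(1e6 + 1), "P2")
  expect_equal(population_label(2e8), "P4")
  expect_equal(population_label(0), "P1")
  expect_error(population_label(-1), "nonnegative")
})

test_that("gdp ratio and diaspora bins follow the left-closed default edges", {
  expect_equal(gdp_ratio_label(0.05), "g1")
  expect_equal(gdp_ratio_label(0.1), "g2")    # boundary belongs above
  expect_equal(gdp_ratio_label(1), "g3")
  expect_equal(gdp_ratio_label(50), "g4")
  expect_error(gdp_ratio_label(0), "positive")

  expect_equal(diaspora_label(0), "d1")
  expect_equal(diaspora_label(1e-7), "d2")
  expect_equal(diaspora_label(1e-4), "d3")
  expect_equal(diaspora_label(0.2), "d5")
  expect_error(diaspora_label(-1e-9), "nonnegative")
})

test_that("default scheme stores the canonical bin edges exactly", {
  sch <- partition_scheme()
  expect_identical(sch$population_edges, c(0, 1e6, 1e7, 1e8, Inf))
  expect_identical(sch$gdp_ratio_edges, c(-Inf, 1e-1, 1, 1e1, Inf))
  expect_identical(sch$diaspora_edges, c(-Inf, 1e-7, 1e-5, 1e-3, 0.1, Inf))
})

test_that("partition lookups are total: each input maps to exactly one bin", {
  sch <- partition_scheme()
  eps <- 1e-9
  ## grids straddling every boundary
  pgrid <- sort(c(0, 1, outer(c(1e6, 1e7, 1e8), c(1 - eps, 1, 1 + eps)), 1e12))
  expect_true(all(population_label(pgrid, sch) %in% paste0("P", 1:4)))
  expect_equal(length(population_label(pgrid, sch)), length(pgrid))
  ## boundaries flip exactly at the closure side
  expect_equal(population_label(c(1e7, 1e7 * (1 + eps)), sch), c("P2", "P3"))

  ggrid <- sort(c(1e-6, outer(c(0.1, 1, 10), c(1 - eps, 1, 1 + eps)), 1e6))
  expect_true(all(gdp_ratio_label(ggrid, sch) %in% paste0("g", 1:4)))
  expect_equal(gdp_ratio_label(c(10 * (1 - eps), 10), sch), c("g3", "g4"))

  dgrid <- sort(c(0, outer(c(1e-7, 1e-5, 1e-3, 0.1), c(1 - eps, 1, 1 + eps)), 5))
  expect_true(all(diaspora_label(dgrid, sch) %in% paste0("d", 1:5)))
  expect_equal(diaspora_label(c(0.1 * (1 - eps), 0.1), sch), c("d4", "d5"))
})

test_that("5-year/yearly rate conversions match direct evaluation and invert", {
  expect_equal(rescale_five_year_rate(0), 0)
  expect_equal(rescale_five_year_rate(1), 1)
  expect_equal(rescale_five_year_rate(0.05), 0.010206218313011495, tolerance = 1e-12)
  expect_equal(compound_yearly_rate(0), 0)
  expect_equal(compound_yearly_rate(0.01), 0.04900995010000009, tolerance = 1e-12)
  expect_equal(compound_yearly_rate(rescale_five_year_rate(0.3)), 0.3,
               tolerance = 1e-12)
  expect_error(rescale_five_year_rate(1.2), "\\[0, 1\\]")
  expect_error(compound_yearly_rate(-0.1), "\\[0, 1\\]")

  grid <- seq(0, 0.999, length.out = 1e4)
  expect_lt(max(abs(compound_yearly_rate(rescale_five_year_rate(grid)) - grid)),
            1e-12)
  ## strictly increasing
  expect_true(all(diff(rescale_five_year_rate(grid)) > 0))
})
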