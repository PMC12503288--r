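#' Covariate partition scheme
#'
#' Bin edges used to partition the calibration data: origin population size
#' (bins `P1..P4`, right-closed), GDP-per-capita ratio origin/destination
#' (bins `g1..g4`, left-closed) and relative diaspora size (bins `d1..d5`,
#' left-closed).  The defaults are the scheme the model is calibrated with;
#' edges are configurable but bins must stay disjoint and cover the domain.
#'
#' @param population_edges Increasing numeric vector of population bin
#'   boundaries, first element 0, last `Inf`.  Intervals are right-closed:
#'   the first bin is `[e1, e2]`, subsequent bins `(ek, ek+1]`.
#' @param gdp_ratio_edges Increasing boundaries for the GDPc ratio bins,
#'   first `-Inf`, last `Inf`; intervals left-closed `[ek, ek+1)`.
#' @param diaspora_edges Increasing boundaries for the relative diaspora
#'   bins, same closure convention as `gdp_ratio_edges`.
#' @return An object of class `partition_scheme`.
#' @examples
#' sch <- partition_scheme()
#' population_label(5e5, sch)   # "P1"
#' gdp_ratio_label(0.05, sch)   # "g1"
#' diaspora_label(0.2, sch)     # "d5"
#' @export
partition_scheme <- function(population_edges = c(0, 1e6, 1e7, 1e8, Inf),
                             gdp_ratio_edges = c(-Inf, 1e-1, 1, 1e1, Inf),
                             diaspora_edges = c(-Inf, 1e-7, 1e-5, 1e-3, 0.1, Inf)) {
  check_edges <- function(e, what) {
    if (length(e) < 3 || anyNA(e) || any(diff(e) <= 0))
      stop(what, " must be strictly increasing with at least 2 bins", call. = FALSE)
  }
  check_edges(population_edges, "population_edges")
  check_edges(gdp_ratio_edges, "gdp_ratio_edges")
  check_edges(diaspora_edges, "diaspora_edges")
  if (population_edges[1] != 0 || !is.infinite(population_edges[length(population_edges)]))
    stop("population_edges must start at 0 and end at Inf", call. = FALSE)
  structure(list(population_edges = population_edges,
                 gdp_ratio_edges = gdp_ratio_edges,
                 diaspora_edges = diaspora_edges),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("Partition scheme\n")
  cat("  population (right-closed):", paste(format(x$population_edges), collapse = " | "), "\n")
  cat("  gdp ratio  (left-closed): ", paste(format(x$gdp_ratio_edges), collapse = " | "), "\n")
  cat("  diaspora   (left-closed): ", paste(format(x$diaspora_edges), collapse = " | "), "\n")
  invisible(x)
}

n_bins <- function(edges) length(edges) - 1L

bin_labels <- function(prefix, edges) paste0(prefix, seq_len(n_bins(edges)))

## right-closed lookup: x in (e_k, e_{k+1}], first bin [e_1, e_2]
.bin_right_closed <- function(x, edges) {
  inner <- edges[-c(1L, length(edges))]
  idx <- rep(1L, length(x))
  for (b in inner) idx <- idx + (x > b)
  idx
}

## left-closed lookup: x in [e_k, e_{k+1})
.bin_left_closed <- function(x, edges) {
  inner <- edges[-c(1L, length(edges))]
  idx <- rep(1L, length(x))
  for (b in inner) idx <- idx + (x >= b)
  idx
}

#' Population-size bin of a country
#'
#' @param P Native population size(s) in persons, nonnegative.
#' @param scheme A [partition_scheme()].
#' @return Character vector of bin labels (`"P1"`..`"P4"` at the defaults).
#'   Boundary values belong to the lower bin (right-closed intervals), so
#'   `P = 1e6` is `"P1"`.
#' @export
population_label <- function(P, scheme = partition_scheme()) {
  if (anyNA(P) || any(P < 0)) stop("population must be nonnegative", call. = FALSE)
  bin_labels("P", scheme$population_edges)[.bin_right_closed(P, scheme$population_edges)]
}

#' GDP-per-capita ratio bin
#'
#' @param g Ratio(s) of origin to destination GDP per capita, positive.
#' @inheritParams population_label
#' @return Character vector of labels (`"g1"`..`"g4"` at the defaults).
#'   Boundary values belong to the upper bin (left-closed), so `g = 1` is
#'   `"g3"`.
#' @export
gdp_ratio_label <- function(g, scheme = partition_scheme()) {
  if (anyNA(g) || any(g <= 0)) stop("gdp ratio must be positive", call. = FALSE)
  bin_labels("g", scheme$gdp_ratio_edges)[.bin_left_closed(g, scheme$gdp_ratio_edges)]
}

#' Relative diaspora-size bin
#'
#' @param d Relative migrant population size(s), nonnegative (existing stock
#'   in the destination divided by the origin population).
#' @inheritParams population_label
#' @return Character vector of labels (`"d1"`..`"d5"` at the defaults);
#'   `d = 0` falls in `"d1"`.
#' @export
diaspora_label <- function(d, scheme = partition_scheme()) {
  if (anyNA(d) || any(d < 0)) stop("diaspora size must be nonnegative", call. = FALSE)
  bin_labels("d", scheme$diaspora_edges)[.bin_left_closed(d, scheme$diaspora_edges)]
}

#' Convert a 5-year migration rate to a yearly rate
#'
#' Uses the compounding relation `m1 = 1 - (1 - m5)^(1/5)`, which assumes a
#' homogeneous rate within the 5-year window.  The transform is monotone and
#' maps `[0, 1]` onto itself.
#'
#' @param m5 Rate(s) per 5-year period, in `[0, 1]`.
#' @return Yearly rate(s) in `[0, 1]`.
#' @seealso [compound_yearly_rate()] for the inverse.
#' @export
rescale_five_year_rate <- function(m5) {
  if (anyNA(m5) || any(m5 < 0 | m5 > 1)) stop("5-year rate must lie in [0, 1]", call. = FALSE)
  1 - (1 - m5)^(1 / 5)
}

#' Compound a yearly migration rate over a 5-year period
#'
#' Inverse of [rescale_five_year_rate()]: `m5 = 1 - (1 - m1)^5`.
#'
#' @param m1 Rate(s) per year, in `[0, 1]`.
#' @return Rate(s) per 5-year period, in `[0, 1]`.
#' @export
compound_yearly_rate <- function(m1) {
  if (anyNA(m1) || any(m1 < 0 | m1 > 1)) stop("yearly rate must lie in [0, 1]", call. = FALSE)
  1 - (1 - m1)^5
}
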