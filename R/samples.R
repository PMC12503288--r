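## Construction of labeled calibration samples from bilateral flow tables.
##
## Flow tables are long data frames of 5-year totals:
##   emigration: origin, destination, period_start, period_end, flow
##   return:     residence, origin, period_start, period_end, flow
## Stocks are long data frames: residence, origin, year, stock.
## All rates are measured with respect to the population at the period
## start and converted to yearly rates before binning.

stocks_matrix <- function(stocks, year, countries) {
  rows <- stocks[stocks$year == year, , drop = FALSE]
  D <- matrix(0, length(countries), length(countries),
              dimnames = list(countries, countries))
  if (nrow(rows)) {
    i <- match(rows$residence, countries)
    j <- match(rows$origin, countries)
    keep <- !is.na(i) & !is.na(j)
    D[cbind(i[keep], j[keep])] <- rows$stock[keep]
  }
  D
}

#' Build per-population-bin emigration rate samples
#'
#' For each (origin, period) the total 5-year outflow is divided by the
#' origin's native population at the period start, converted to a yearly
#' rate with [rescale_five_year_rate()], and assigned to the origin's
#' population bin for that period.  Records with zero origin population, or
#' with an (unphysical) 5-year rate above 1, are skipped with a warning.
#'
#' @param flows Emigration flow table (columns `origin`, `destination`,
#'   `period_start`, `period_end`, `flow`).
#' @param panel A [country_panel()] covering the period-start years.
#' @param scheme A [partition_scheme()].
#' @return Named list of [labeled_samples()], one per population bin
#'   (possibly `n = 0` for uncovered bins).
#' @export
build_emigration_rate_samples <- function(flows, panel, scheme = partition_scheme()) {
  labs <- bin_labels("P", scheme$population_edges)
  out <- stats::setNames(lapply(labs, function(l) labeled_samples(numeric(), l)), labs)
  if (!nrow(flows)) return(out)
  tot <- stats::aggregate(flow ~ origin + period_start, data = flows, FUN = sum)
  skipped <- 0L
  vals <- vector("list", length(labs)); names(vals) <- labs
  for (r in seq_len(nrow(tot))) {
    P <- panel$population[panel$country_id == tot$origin[r] &
                            panel$year == tot$period_start[r]]
    if (!length(P) || is.na(P) || P <= 0) { skipped <- skipped + 1L; next }
    rate5 <- tot$flow[r] / P
    if (rate5 > 1) { skipped <- skipped + 1L; next }
    lab <- population_label(P, scheme)
    vals[[lab]] <- c(vals[[lab]], rescale_five_year_rate(rate5))
  }
  if (skipped)
    warning(skipped, " origin-period record(s) skipped (zero population or rate > 1)",
            call. = FALSE)
  for (l in labs) out[[l]] <- labeled_samples(vals[[l]], l)
  out
}

#' Build destination-share samples per (GDPc-ratio, diaspora) cell
#'
#' Each bilateral share `m_ij = M_ij / M_i` (flows over a period, origins
#' with positive total outflow) is labeled by the GDPc ratio bin of
#' `g_i / g_j` and by the diaspora bin of the relative migrant population
#' connecting origin to destination at the period start.  With
#' `diaspora_mode = "bilateral"` (default) the covariate is
#' `d_ij = D[j, i] / P_i`, the origin's existing stock in the destination
#' relative to the origin population; `"origin_total"` uses the origin's
#' worldwide stock `sum_j D[j, i] / P_i` for all destinations.
#'
#' @inheritParams build_emigration_rate_samples
#' @param stocks Long stock table (`residence`, `origin`, `year`, `stock`)
#'   covering the period-start years.
#' @param diaspora_mode `"bilateral"` or `"origin_total"`.
#' @return Named list of [labeled_samples()] keyed `"g:d"` (e.g.
#'   `"g2:d3"`), covering every cell of the scheme.
#' @export
build_share_samples <- function(flows, stocks, panel, scheme = partition_scheme(),
                                diaspora_mode = c("bilateral", "origin_total")) {
  diaspora_mode <- match.arg(diaspora_mode)
  glabs <- bin_labels("g", scheme$gdp_ratio_edges)
  dlabs <- bin_labels("d", scheme$diaspora_edges)
  cells <- as.vector(outer(glabs, dlabs, paste, sep = ":"))
  vals <- stats::setNames(vector("list", length(cells)), cells)
  skipped <- 0L
  if (nrow(flows)) {
    countries <- panel_countries(panel)
    for (ps in sort(unique(flows$period_start))) {
      sub <- flows[flows$period_start == ps, , drop = FALSE]
      pan <- panel[panel$year == ps, , drop = FALSE]
      gd <- stats::setNames(pan$gdpc, pan$country_id)
      pop <- stats::setNames(pan$population, pan$country_id)
      D <- stocks_matrix(stocks, ps, countries)
      tot <- tapply(sub$flow, sub$origin, sum)
      for (r in seq_len(nrow(sub))) {
        o <- sub$origin[r]; dst <- sub$destination[r]
        Mi <- tot[[o]]
        if (is.na(Mi) || Mi <= 0) next
        if (is.na(gd[o]) || is.na(gd[dst]) || !o %in% names(gd) || !dst %in% names(gd)) {
          skipped <- skipped + 1L; next
        }
        if (is.na(pop[o]) || pop[o] <= 0) { skipped <- skipped + 1L; next }
        dcov <- if (diaspora_mode == "bilateral") D[dst, o] / pop[o]
                else sum(D[, o]) / pop[o]
        cell <- paste(gdp_ratio_label(gd[[o]] / gd[[dst]], scheme),
                      diaspora_label(dcov, scheme), sep = ":")
        vals[[cell]] <- c(vals[[cell]], sub$flow[r] / Mi)
      }
    }
  }
  if (skipped)
    warning(skipped, " share record(s) skipped (missing GDPc or population)",
            call. = FALSE)
  out <- vals
  for (cl in cells) out[[cl]] <- labeled_samples(if (is.null(vals[[cl]])) numeric() else vals[[cl]], cl)
  out
}

#' Build the pooled return-rate sample
#'
#' 5-year return rates `R_ij / D_ij` are computed per (residence, origin)
#' corridor, records with a rate above 100% are discarded (as are records
#' with return flow but no stock), and the remainder is converted to yearly
#' rates.  Return rates are pooled into a single unpartitioned sample; their
#' empirical distribution is tight around its median, so partitioning buys
#' little.
#'
#' @param return_flows Return flow table (columns `residence`, `origin`,
#'   `period_start`, `period_end`, `flow`).
#' @param stocks Long stock table covering the period-start years.
#' @return A [labeled_samples()] with label `"return"`; attribute
#'   `"n_discarded"` counts the removed records.
#' @export
build_return_rate_samples <- function(return_flows, stocks) {
  vals <- numeric(); discarded <- 0L
  if (nrow(return_flows)) {
    countries <- sort(unique(c(return_flows$residence, return_flows$origin,
                               stocks$residence, stocks$origin)))
    for (ps in sort(unique(return_flows$period_start))) {
      sub <- return_flows[return_flows$period_start == ps, , drop = FALSE]
      D <- stocks_matrix(stocks, ps, countries)
      Dij <- D[cbind(match(sub$residence, countries), match(sub$origin, countries))]
      rate5 <- ifelse(Dij > 0, sub$flow / Dij, ifelse(sub$flow > 0, Inf, 0))
      drop <- rate5 > 1
      discarded <- discarded + sum(drop)
      vals <- c(vals, rescale_five_year_rate(rate5[!drop]))
    }
  }
  out <- labeled_samples(vals, "return")
  attr(out, "n_discarded") <- discarded
  out
}
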