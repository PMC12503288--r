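#' Read a country panel CSV, filling gaps
#'
#' Reads a CSV with columns `country_id, year, population,
#' natural_change_rate, birth_rate, death_rate, gdpc, region, income_group`
#' (GDP per capita may instead be supplied as the precedence chain
#' `gdpc_ppp`, `gdpc_mer`, `gdpc_usd`, merged in that order).  Missing
#' populations are filled by linear interpolation strictly within each
#' country's observed span (no extrapolation); GDPc still missing after the
#' precedence merge is filled from the country's closest available year.
#' Every filled cell is flagged in the logical columns
#' `population_interpolated` / `gdpc_filled`.  Countries with no population
#' data at all are dropped with a warning.
#'
#' @param path CSV file path.
#' @return A [country_panel()] with the two provenance flag columns.
#' @export
read_country_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("country_id", "year")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("panel file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  ## GDPc precedence chain: PPP, then MER, then USD
  if (!"gdpc" %in% names(df)) df$gdpc <- NA_real_
  for (col in c("gdpc_ppp", "gdpc_mer", "gdpc_usd")) {
    if (col %in% names(df)) {
      take <- is.na(df$gdpc) & !is.na(df[[col]])
      df$gdpc[take] <- df[[col]][take]
      df[[col]] <- NULL
    }
  }

  df$population_interpolated <- FALSE
  df$gdpc_filled <- FALSE
  out <- NULL
  dropped <- character()
  for (cid in unique(df$country_id)) {
    sub <- df[df$country_id == cid, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    obs <- !is.na(sub$population)
    if (!any(obs)) { dropped <- c(dropped, cid); next }
    if (any(!obs)) {
      span <- range(sub$year[obs])
      fill <- !obs & sub$year >= span[1] & sub$year <= span[2]
      if (any(fill)) {
        sub$population[fill] <- stats::approx(sub$year[obs], sub$population[obs],
                                              xout = sub$year[fill])$y
        sub$population_interpolated[fill] <- TRUE
      }
    }
    gobs <- !is.na(sub$gdpc)
    if (any(gobs) && any(!gobs)) {
      for (r in which(!gobs)) {
        nearest <- which.min(abs(sub$year[gobs] - sub$year[r]))
        sub$gdpc[r] <- sub$gdpc[gobs][nearest]
        sub$gdpc_filled[r] <- TRUE
      }
    }
    out <- rbind(out, sub)
  }
  if (length(dropped))
    warning("dropped countries with no population data: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (is.null(out)) stop("no usable countries in ", path, call. = FALSE)
  out <- out[!is.na(out$population), , drop = FALSE]
  country_panel(out)
}

#' Read bilateral flow and stock tables
#'
#' `read_flows` expects columns `origin, destination, period_start,
#' period_end, flow` (or `residence, origin, ...` for return flows, set
#' `kind = "return"`); `read_stocks` expects `residence, origin, year,
#' stock`.  Negative entries, nonzero diagonals and duplicate keys are
#' errors; an empty file yields an empty table.
#'
#' @param path CSV file path.
#' @param kind `"emigration"` or `"return"` (controls the expected id
#'   columns).
#' @return A validated data frame.
#' @export
read_flows <- function(path, kind = c("emigration", "return")) {
  kind <- match.arg(kind)
  idc <- if (kind == "emigration") c("origin", "destination") else c("residence", "origin")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c(idc, "period_start", "period_end", "flow")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("flow file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(df)) return(df)
  if (any(is.na(df$flow) | df$flow < 0)) stop("negative or missing flows in ", path, call. = FALSE)
  if (any(df[[idc[1]]] == df[[idc[2]]] & df$flow != 0))
    stop("nonzero diagonal flow entries in ", path, call. = FALSE)
  if (anyDuplicated(df[c(idc, "period_start")]))
    stop("duplicate (", paste(idc, collapse = ","), ",period) rows in ", path, call. = FALSE)
  df
}

#' @rdname read_flows
#' @export
read_stocks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("residence", "origin", "year", "stock")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("stock file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(df)) return(df)
  if (any(is.na(df$stock) | df$stock < 0)) stop("negative or missing stocks in ", path, call. = FALSE)
  if (any(df$residence == df$origin & df$stock != 0))
    stop("nonzero diagonal stock entries in ", path, call. = FALSE)
  if (anyDuplicated(df[c("residence", "origin", "year")]))
    stop("duplicate (residence,origin,year) rows in ", path, call. = FALSE)
  df
}

#' Write / read an ensemble summary as tidy CSV
#'
#' The tidy layout is `series, year, stat, value` with stats `median`,
#' `q25`, `q75`, `q2.5`, `q97.5`.
#'
#' @param summary An `ensemble_summary` or its tidy `summary` data frame.
#' @param path CSV file path.
#' @export
write_summary <- function(summary, path) {
  df <- if (inherits(summary, "ensemble_summary")) summary$summary else summary
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Aggregate ensemble stocks to regions or income groups
#'
#' Sums per-country stock series within groups along the chosen axis
#' (country of origin or of residence) separately for every ensemble
#' sample, then extracts the median and 50%/95% intervals.  Quantiles are
#' not additive, so aggregating before summarising is the only correct
#' order.
#'
#' @param ens An `ensemble_summary` from [run_ensemble()].
#' @param mapping Data frame with column `country_id` plus the grouping
#'   column; every simulated country must be mapped.
#' @param axis `"origin"` or `"destination"` (residence side).
#' @param grouping Name of the grouping column in `mapping` (e.g.
#'   `"region"` or `"income_group"`).
#' @return Tidy data frame `series, year, stat, value` with one series per
#'   group, named `<axis>:<group>`.
#' @export
aggregate_series <- function(ens, mapping, axis = c("origin", "destination"),
                             grouping = "region") {
  axis <- match.arg(axis)
  if (!all(c("country_id", grouping) %in% names(mapping)))
    stop("mapping needs columns country_id and ", grouping, call. = FALSE)
  grp <- stats::setNames(as.character(mapping[[grouping]]),
                         as.character(mapping$country_id))
  unmapped <- setdiff(ens$countries, names(grp))
  if (length(unmapped))
    stop("unmapped countries: ", paste(unmapped, collapse = ", "), call. = FALSE)
  arr <- if (axis == "origin") ens$samples$origin_stock else ens$samples$residence_stock
  out <- NULL
  for (g in sort(unique(grp[ens$countries]))) {
    members <- ens$countries[grp[ens$countries] == g]
    sub <- arr[members, , , drop = FALSE]
    tot <- apply(sub, c(2, 3), sum)      # [year, sample]
    out <- rbind(out, summarise_samples(tot, paste(axis, g, sep = ":"), ens$years))
  }
  out
}

#' Compare model summaries with reference stocks
#'
#' Joins a tidy model summary with observed reference values and reports,
#' per series and year, the absolute error (model median minus observed),
#' the relative error (absolute error over observed; `NA` where the
#' observation is zero) and indicators for the observation lying inside the
#' 50% and 95% prediction bands.  Rows are ordered so that series rank by
#' absolute error magnitude at their final common year.
#'
#' @param summary An `ensemble_summary` or tidy summary data frame.
#' @param reference Data frame with columns `series`, `year`, `observed`.
#' @return A data frame with columns `series`, `year`, `observed`,
#'   `median`, `q25`, `q75`, `q2.5`, `q97.5`, `abs_error`, `rel_error`,
#'   `in_50`, `in_95`.
#' @export
compare_to_reference <- function(summary, reference) {
  df <- if (inherits(summary, "ensemble_summary")) summary$summary else summary
  wide <- stats::reshape(df, idvar = c("series", "year"), timevar = "stat",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  cmp <- merge(reference, wide, by = c("series", "year"))
  if (!nrow(cmp)) stop("no overlapping (series, year) pairs", call. = FALSE)
  cmp$abs_error <- cmp$median - cmp$observed
  cmp$rel_error <- ifelse(cmp$observed != 0, cmp$abs_error / cmp$observed, NA_real_)
  cmp$in_50 <- cmp$observed >= cmp$q25 & cmp$observed <= cmp$q75
  cmp$in_95 <- cmp$observed >= cmp$q2.5 & cmp$observed <= cmp$q97.5
  ## rank series by |abs error| at their final year
  fin <- do.call(rbind, lapply(split(cmp, cmp$series), function(s) {
    s[which.max(s$year), c("series", "abs_error")]
  }))
  rank_order <- fin$series[order(-abs(fin$abs_error))]
  cmp <- cmp[order(match(cmp$series, rank_order), cmp$year), , drop = FALSE]
  rownames(cmp) <- NULL
  cmp
}
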