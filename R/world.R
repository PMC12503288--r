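#' Country panel of demographic and economic covariates
#'
#' Validates and classes a per-country, per-year table with columns
#' `country_id`, `year`, `population`, `natural_change_rate`, `birth_rate`,
#' `death_rate`, `gdpc`, `region`, `income_group`.  The natural change rate
#' may be negative; birth and death rates are stored as nonnegative
#' magnitudes.
#'
#' @param df A data frame with the columns above.
#' @return The data frame with class `country_panel` prepended.
#' @export
country_panel <- function(df) {
  req <- c("country_id", "year", "population", "natural_change_rate",
           "birth_rate", "death_rate", "gdpc", "region", "income_group")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("country panel missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(df$population) || any(df$population < 0))
    stop("population must be nonnegative", call. = FALSE)
  if (anyNA(df$gdpc) || any(df$gdpc <= 0))
    stop("gdpc must be positive", call. = FALSE)
  if (any(df$birth_rate < 0) || any(df$death_rate < 0))
    stop("birth and death rates must be nonnegative", call. = FALSE)
  if (anyDuplicated(df[c("country_id", "year")]))
    stop("duplicate (country_id, year) rows in panel", call. = FALSE)
  df$country_id <- as.character(df$country_id)
  class(df) <- unique(c("country_panel", class(df)))
  df
}

panel_countries <- function(panel) sort(unique(panel$country_id))

## Fast per-year lookup: named vectors aligned to `countries`.
panel_year <- function(panel, year, countries) {
  rows <- panel[panel$year == year, , drop = FALSE]
  if (!nrow(rows)) stop("panel does not cover year ", year, call. = FALSE)
  idx <- match(countries, rows$country_id)
  if (anyNA(idx))
    stop("panel year ", year, " missing countries: ",
         paste(countries[is.na(idx)], collapse = ", "), call. = FALSE)
  list(population = stats::setNames(rows$population[idx], countries),
       c = stats::setNames(rows$natural_change_rate[idx], countries),
       c_birth = stats::setNames(rows$birth_rate[idx], countries),
       c_death = stats::setNames(rows$death_rate[idx], countries),
       gdpc = stats::setNames(rows$gdpc[idx], countries))
}

#' World state: native populations and migrant stock matrix at one year
#'
#' @param year Integer calendar year.
#' @param P Named nonnegative vector of native population sizes, one entry
#'   per country.
#' @param D Nonnegative migrant-stock matrix indexed `[residence, origin]`
#'   with zero diagonal, `dimnames` matching `names(P)`.  The arrival-time
#'   dimension of the stock is aggregated out: return and birth flows in
#'   this model depend only on the current stock, so the aggregation is
#'   exact.
#' @return A `world_state` object.
#' @export
world_state <- function(year, P, D) {
  if (is.null(names(P))) stop("P must be a named vector", call. = FALSE)
  countries <- names(P)
  if (!is.matrix(D) || !identical(dim(D), c(length(P), length(P))))
    stop("D must be a square matrix matching P", call. = FALSE)
  if (is.null(dimnames(D))) dimnames(D) <- list(countries, countries)
  if (!identical(rownames(D), countries) || !identical(colnames(D), countries))
    stop("dimnames of D must match names of P", call. = FALSE)
  if (anyNA(P) || any(P < 0) || anyNA(D) || any(D < 0))
    stop("populations and stocks must be nonnegative", call. = FALSE)
  if (any(diag(D) != 0)) stop("migrant stock matrix must have zero diagonal", call. = FALSE)
  structure(list(year = as.integer(year), P = P, D = D), class = "world_state")
}

#' @export
print.world_state <- function(x, ...) {
  cat(sprintf("<world_state %d: %d countries, total P = %.4g, total D = %.4g>\n",
              x$year, length(x$P), sum(x$P), sum(x$D)))
  invisible(x)
}

#' Bilateral flow matrices for one simulation year
#'
#' @param M Emigration flows `[origin, destination]`.
#' @param R Return flows `[residence, origin]`.
#' @param B Birth flows `[residence, origin]` (births to migrant
#'   populations, entering the native population of the residence country).
#' @return A `flow_matrices` object.
#' @export
flow_matrices <- function(M, R, B) {
  for (nm in c("M", "R", "B")) {
    m <- get(nm)
    if (anyNA(m) || any(m < 0)) stop(nm, " must be nonnegative", call. = FALSE)
    if (any(diag(m) != 0)) stop(nm, " must have zero diagonal", call. = FALSE)
  }
  structure(list(M = M, R = R, B = B), class = "flow_matrices")
}

#' Labeled sample set for calibration
#'
#' @param values Numeric observations in `[0, 1]` (rates or shares).
#' @param label Partition label the sample belongs to (a P-bin, a
#'   `"g:d"` cell, or `"return"`).
#' @return A `labeled_samples` object with fields `values`, `label`, `n`.
#' @export
labeled_samples <- function(values, label) {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0 | values > 1))
    stop("sample values must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, label = label, n = length(values)),
            class = "labeled_samples")
}

sample_values <- function(samples) {
  if (inherits(samples, "labeled_samples")) samples$values else as.numeric(samples)
}

#' @export
print.labeled_samples <- function(x, ...) {
  cat(sprintf("<labeled_samples '%s': n = %d, median = %.4g>\n",
              x$label, x$n, if (x$n) stats::median(x$values) else NA_real_))
  invisible(x)
}
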