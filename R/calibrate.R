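#' Assemble a flow distribution set
#'
#' Container for the calibrated sampling distributions: one emigration-rate
#' fit per population bin, one destination-share fit per populated
#' `(g, d)` cell, and one pooled return-rate fit.  Cells without a fit carry
#' an explicit fallback pointer resolved by [share_fit_for()].
#'
#' @param emigration Named list of `migsim_fit`, one per population bin.
#' @param shares Named list keyed `"g:d"`; entries are `migsim_fit` or
#'   `migsim_empty_fit`.
#' @param return_rate A `migsim_fit` for the pooled return rate.
#' @param pools Named list of pooled share fits backing the fallbacks
#'   (keys like `"pool_d:d3"` and `"pool_all"`).
#' @param fallback Named character vector mapping empty cells to pool keys.
#' @param provenance List of calibration metadata (sample counts, scheme
#'   edges, options).
#' @return A `flow_distribution_set`.
#' @export
flow_distribution_set <- function(emigration, shares, return_rate,
                                  pools = list(), fallback = character(),
                                  provenance = list()) {
  if (!length(emigration) || !all(vapply(emigration, inherits, logical(1), "migsim_fit")))
    stop("every population bin needs an emigration fit", call. = FALSE)
  if (!inherits(return_rate, "migsim_fit"))
    stop("return_rate fit is required", call. = FALSE)
  empty <- names(shares)[vapply(shares, is_empty_fit, logical(1))]
  noptr <- setdiff(empty, names(fallback))
  if (length(noptr))
    stop("empty share cells without fallback pointer: ",
         paste(noptr, collapse = ", "), call. = FALSE)
  structure(list(emigration = emigration, shares = shares,
                 return_rate = return_rate, pools = pools,
                 fallback = fallback, provenance = provenance),
            class = "flow_distribution_set")
}

#' @export
print.flow_distribution_set <- function(x, ...) {
  fitted <- sum(!vapply(x$shares, is_empty_fit, logical(1)))
  cat(sprintf(paste0("<flow_distribution_set: %d emigration bins, ",
                     "%d/%d share cells fitted (%d pooled fallbacks), return fit n = %d>\n"),
              length(x$emigration), fitted, length(x$shares),
              length(x$fallback), x$return_rate$n_fit))
  invisible(x)
}

#' Resolve the share distribution for a (g, d) cell
#'
#' Returns the cell's own fit when present; otherwise follows the fallback
#' pointer to the fit pooled over all GDPc-ratio bins at the same diaspora
#' bin, or the globally pooled fit.  The diaspora covariate dominates the
#' share distributions, so pooling over the ratio bins is the mildest
#' possible substitution.
#'
#' @param dists A [flow_distribution_set()].
#' @param g_label,d_label Bin labels, e.g. `"g2"`, `"d4"`.
#' @return A `migsim_fit`.
#' @export
share_fit_for <- function(dists, g_label, d_label) {
  key <- paste(g_label, d_label, sep = ":")
  fit <- dists$shares[[key]]
  if (is.null(fit)) stop("unknown share cell: ", key, call. = FALSE)
  if (!is_empty_fit(fit)) return(fit)
  pool <- dists$pools[[dists$fallback[[key]]]]
  if (is.null(pool) || is_empty_fit(pool))
    stop("no usable fallback for share cell ", key, call. = FALSE)
  pool
}

#' Calibrate the full flow distribution set from bilateral data
#'
#' Builds the labeled rate/share samples, fits the Jones--Faddy skew-t to
#' the emigration rates of each population bin, the Weibull-maximum to each
#' sufficiently populated destination-share cell, and the Student t to the
#' pooled return rates.  With `exploratory = TRUE` each component instead
#' keeps the family ranked best by histogram SSE via [rank_families()].
#'
#' @param flows Emigration flow table (see
#'   [build_emigration_rate_samples()]).
#' @param return_flows Return flow table (see
#'   [build_return_rate_samples()]).
#' @param stocks Long stock table covering the period-start years.
#' @param panel A [country_panel()].
#' @param scheme A [partition_scheme()].
#' @param min_n Minimum observations for a share-cell fit; thinner cells
#'   fall back to pooled fits.
#' @param bins Histogram bins for the SSE score.
#' @param diaspora_mode Passed to [build_share_samples()].
#' @param exploratory Rank candidate families instead of using the fixed
#'   per-component families.
#' @return A [flow_distribution_set()].  Any empty population bin is an
#'   error: the model cannot sample emigration without it.
#' @export
calibrate_model <- function(flows, return_flows, stocks, panel,
                            scheme = partition_scheme(), min_n = 30,
                            bins = 100,
                            diaspora_mode = c("bilateral", "origin_total"),
                            exploratory = FALSE) {
  diaspora_mode <- match.arg(diaspora_mode)
  emi_samples <- build_emigration_rate_samples(flows, panel, scheme)
  empty_bins <- names(emi_samples)[vapply(emi_samples, function(s) s$n == 0, logical(1))]
  if (length(empty_bins))
    stop("no emigration-rate observations in population bin(s): ",
         paste(empty_bins, collapse = ", "), call. = FALSE)

  pick <- function(samples, family) {
    if (exploratory) rank_families(samples, min_n = min_n, bins = bins)[[1]]
    else fit_distribution(samples, family, min_n = min_n, bins = bins)
  }

  emigration <- lapply(emi_samples, function(s) {
    ## emigration bins must always yield a usable fit, however thin
    f <- pick(s, "jones_faddy_skew_t")
    if (is_empty_fit(f)) f <- fit_distribution(s, "jones_faddy_skew_t", min_n = 4, bins = bins)
    if (is_empty_fit(f))
      stop("population bin ", s$label, " too thin to calibrate (n = ", s$n, ")",
           call. = FALSE)
    f
  })

  share_samples <- build_share_samples(flows, stocks, panel, scheme, diaspora_mode)
  shares <- lapply(share_samples, function(s) {
    if (s$n < min_n) empty_fit(sprintf("%d observations < min_n = %d", s$n, min_n))
    else pick(s, "weibull_max")
  })

  ## pooled fits backing the fallback chain
  dlabs <- bin_labels("d", scheme$diaspora_edges)
  pools <- list()
  for (dl in dlabs) {
    pooled <- unlist(lapply(share_samples[grepl(paste0(":", dl, "$"), names(share_samples))],
                            function(s) s$values))
    pools[[paste0("pool_d:", dl)]] <-
      if (length(pooled) >= min_n)
        pick(labeled_samples(pooled, paste0("pool_d:", dl)), "weibull_max")
      else empty_fit("pooled d-bin too thin")
  }
  ## the global pool is the last-resort fallback; fit it whenever any share
  ## data exists at all
  all_shares <- unlist(lapply(share_samples, function(s) s$values))
  pools[["pool_all"]] <-
    if (length(all_shares) >= 4)
      fit_distribution(labeled_samples(all_shares, "pool_all"), "weibull_max",
                       min_n = 4, bins = bins)
    else empty_fit("no share data at all")

  fallback <- character()
  for (key in names(shares)) {
    if (!is_empty_fit(shares[[key]])) next
    dl <- sub("^.*:", "", key)
    pk <- paste0("pool_d:", dl)
    if (is_empty_fit(pools[[pk]])) pk <- "pool_all"
    if (is_empty_fit(pools[[pk]]))
      stop("no share data to back fallback for cell ", key, call. = FALSE)
    fallback[key] <- pk
  }

  ret_samples <- build_return_rate_samples(return_flows, stocks)
  ret <- pick(ret_samples, "student_t")
  if (is_empty_fit(ret))
    ret <- fit_distribution(ret_samples, "student_t", min_n = 4, bins = bins)
  if (is_empty_fit(ret))
    stop("too few return-rate observations to calibrate (n = ", ret_samples$n, ")",
         call. = FALSE)

  flow_distribution_set(
    emigration = emigration, shares = shares, return_rate = ret,
    pools = pools, fallback = fallback,
    provenance = list(
      n_emigration = vapply(emi_samples, function(s) s$n, integer(1)),
      n_shares = vapply(share_samples, function(s) s$n, integer(1)),
      n_return = ret_samples$n,
      n_return_discarded = attr(ret_samples, "n_discarded"),
      scheme = unclass(scheme),
      options = list(min_n = min_n, bins = bins, diaspora_mode = diaspora_mode,
                     exploratory = exploratory)))
}

## ---------------------------------------------------------------------------
## JSON serialisation

fit_to_list <- function(fit) {
  if (is_empty_fit(fit)) list(empty = TRUE, reason = fit$reason)
  else list(family = fit$family, params = as.list(fit$params), sse = fit$sse,
            loglik = fit$loglik, n_fit = fit$n_fit, convergence = fit$convergence)
}

fit_from_list <- function(x) {
  if (isTRUE(x$empty)) return(empty_fit(x$reason))
  structure(list(family = x$family, params = unlist(x$params), sse = x$sse,
                 loglik = x$loglik, n_fit = as.integer(x$n_fit),
                 convergence = as.integer(x$convergence)),
            class = "migsim_fit")
}

#' Write / read a flow distribution set as JSON
#'
#' @param dists A [flow_distribution_set()].
#' @param path File path.
#' @return `read_distribution_set` returns the restored
#'   [flow_distribution_set()]; `write_distribution_set` returns `path`
#'   invisibly.
#' @export
write_distribution_set <- function(dists, path) {
  obj <- list(emigration = lapply(dists$emigration, fit_to_list),
              shares = lapply(dists$shares, fit_to_list),
              return_rate = fit_to_list(dists$return_rate),
              pools = lapply(dists$pools, fit_to_list),
              fallback = as.list(dists$fallback),
              provenance = dists$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_distribution_set
#' @export
read_distribution_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  flow_distribution_set(
    emigration = lapply(obj$emigration, fit_from_list),
    shares = lapply(obj$shares, fit_from_list),
    return_rate = fit_from_list(obj$return_rate),
    pools = lapply(obj$pools, fit_from_list),
    fallback = unlist(lapply(obj$fallback, as.character)) %||% character(),
    provenance = obj$provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
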