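## Small fixture builders shared across tests.

tiny_panel <- function(ids, years, population, c = 0, c_birth = 0, c_death = 0,
                       gdpc = 1e4) {
  n <- length(ids)
  grid <- expand.grid(country_id = ids, year = years, stringsAsFactors = FALSE)
  country_panel(data.frame(
    grid,
    population = rep(population, length(years)),
    natural_change_rate = rep(rep_len(c, n), length(years)),
    birth_rate = rep(rep_len(c_birth, n), length(years)),
    death_rate = rep(rep_len(c_death, n), length(years)),
    gdpc = rep(rep_len(gdpc, n), length(years)),
    region = "R1", income_group = "mid"))
}

tiny_state <- function(ids, P, D = NULL) {
  if (is.null(D)) D <- matrix(0, length(ids), length(ids),
                              dimnames = list(ids, ids))
  world_state(1990L, stats::setNames(P, ids), D)
}

## distribution set with no mass on [0, 1]: every truncated draw clamps to
## exactly zero, giving a flow-free world
null_dists <- function(scheme = partition_scheme()) {
  zero <- structure(list(family = "normal", params = c(mu = -1, sigma = 1e-6),
                         sse = NA_real_, loglik = NA_real_, n_fit = 0L,
                         convergence = 0L), class = "migsim_fit")
  plabs <- paste0("P", seq_len(length(scheme$population_edges) - 1))
  glabs <- paste0("g", seq_len(length(scheme$gdp_ratio_edges) - 1))
  dlabs <- paste0("d", seq_len(length(scheme$diaspora_edges) - 1))
  shares <- list()
  for (gl in glabs) for (dl in dlabs) shares[[paste(gl, dl, sep = ":")]] <- zero
  flow_distribution_set(
    emigration = stats::setNames(rep(list(zero), length(plabs)), plabs),
    shares = shares, return_rate = zero)
}
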