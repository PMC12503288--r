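---
title: "A stochastic evolution model of international migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic evolution model of international migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migsim)
```

## The model

`migsim` treats international migration as a stochastic process wrapped in
deterministic demographic accounting.  Each country $i$ carries a native
population $P_i(t)$ and hosts migrant stocks $D_{ik}(t)$, indexed by
residence $i$ and country of birth $k$.  Three flows connect them:
emigration $M_{il}$ out of native populations, return migration $R_{ik}$
from stocks back to origins, and births $B_{ik}$ from migrant stocks into
the native population of the residence country.  Transit migration (stock
to stock in a third country) is excluded; its global volume is an order of
magnitude below emigration and return.

Per simulated year the balance equations are

$$P_i(t+1) = \Big(P_i(t) - \sum_l M_{il}(t)\Big)\,(1 + c_i(t))
  + \sum_l R_{li}(t) + \sum_l B_{il}(t),$$

$$D_{ik}(t+1) = D_{ik}(t)\,(1 - c^\dagger_k(t)) - R_{ik}(t) + M_{ki}(t),$$

where $c_i$ is the natural change rate and $c^\dagger_k$ the death rate of
the *origin* country (migrant vital rates are assumed equal to those of
the country of birth).  Immigration inflows are not rescaled by
within-year births and deaths; the flow estimates the model is calibrated
on already contain natural changes.  A death rate is stored as a
nonnegative magnitude and applied as a survival factor $(1-c^\dagger)$ — a
positive death rate must shrink a stock.  All flows of a year are drawn
from the state at $t$ and applied simultaneously; there is no intra-year
sequencing.

The stock's arrival-time dimension is aggregated out: because return and
birth flows depend only on the current stock (below), summing over arrival
cohorts is exact, and initial stocks may be treated as if created at the
start year.

### Flow sampling

The complexity of migration is confined to three calibrated probability
distributions:

* **Emigration rates.**  Yearly rates $\tilde M$ are drawn from a
  Jones–Faddy skew-t whose parameters $(\mu, \sigma, a, b)$ depend on the
  origin's population bin
  $P1 = [0, 10^6],\; P2 = (10^6, 10^7],\; P3 = (10^7, 10^8],\;
  P4 = (10^8, \infty)$ — a step-function approximation in $P$-space.
  Partitioning by orders of magnitude keeps each bin statistically
  populated while separating the smallest from the largest countries.
* **Destination shares.**  For each ordered pair a raw share is drawn from
  a Weibull-maximum (reversed Weibull) distribution whose parameters
  depend on the cell of a two-way partition: the GDP-per-capita ratio
  $g_{ij} = g_i / g_j$ in bins
  $(-\infty,0.1), [0.1,1), [1,10), [10,\infty)$ and the relative diaspora
  size in bins split at $10^{-7}, 10^{-5}, 10^{-3}, 0.1$.  Raw shares do
  not sum to one; the vector is uniformly renormalized every draw.
  Bilateral flows are then $M_{ij} = P_i \cdot \tilde M \cdot m_{ij}$, so
  total outflow can never exceed the native population.
* **Return rates.**  A single unpartitioned Student-t: empirical return
  rates concentrate tightly around their median, so partitioning buys
  little.  $R_{ik} = D_{ik} \cdot r$ with one independent draw per
  (residence, origin) pair per year.

Birth flows are deterministic: $B_{ik} = D_{ik} \cdot c^*_k$ with the
origin country's birth rate $c^*_k$.

The population bins are right-closed as printed above (a population of
exactly $10^6$ is P1); the ratio and diaspora bins are left-closed (a
ratio of exactly 1 is g3).  The diaspora covariate is implemented
bilaterally, $d_{ij} = D_{ji} / P_i$ — the origin's existing stock in a
destination relative to the origin population — because an origin-level
covariate could not differentiate destinations, which is the covariate's
entire role.  A config switch (`diaspora_mode = "origin_total"`) provides
the origin-level alternative reading.

### Truncation and the deterministic mode

Fitted families are unbounded, preserving their heavy tails, and are
truncated to $[0,1]$ only at sampling time: draws are rejected and redrawn
(up to 1,000 vectorised rounds, then clamped).  A distribution with no
numerical mass on $[0,1]$ short-circuits to its clamped median.  The
deterministic model variant replaces every draw by the median of the
truncated distribution, computed through the untruncated quantile
function; it consumes no random numbers and is reproducible without a
seed.  For right-skewed emigration distributions the deterministic run
systematically undershoots the stochastic ensemble median of accumulated
stocks — the mean of draws exceeds the substituted median — which is why
the stochastic formulation is the primary mode.

### Calibration

Calibration consumes three tables: bilateral 5-year emigration flows,
bilateral 5-year return flows, and stock snapshots at period starts,
together with a country panel.  Per origin-period the total outflow over
the origin population at the period start gives a 5-year rate, converted
to a yearly rate by $m_{1y} = 1 - (1 - m_{5y})^{1/5}$ (homogeneity within
the window assumed) and assigned to the origin's population bin.  Shares
$M_{ij}/M_i$ are labeled by their $(g, d)$ cell.  5-year return rates
$R_{ij}/D_{ij}$ above 100% are discarded (they are data artefacts; in the
published flow estimates they are below 0.1% of records), and zero-stock
records with positive return flow are discarded and counted.

Parameters are estimated by maximum likelihood (Nelder–Mead on an
unconstrained reparameterisation — log scale for positive parameters,
log-offset above the sample maximum for the Weibull-max location — with a
deterministic ladder of perturbed restarts).  Families are compared by the
sum of squared errors between the fitted density and the histogram density
of the sample, evaluated at the centres of 100 equal-width bins spanning
the sample range.  MLE is the estimation loss and SSE only the ranking
score: the SSE mirrors the visual-fit comparisons the family choice is
based on, while MLE is stable and standard.  The fixed production families
are skew-t (rates), Weibull-max (shares) and Student-t (returns);
`exploratory = TRUE` instead keeps the SSE-best of the candidate set
(which also contains normal and logistic baselines).

Share cells with fewer than `min_n = 30` observations stay empty and carry
a fallback pointer to the fit pooled over all GDPc-ratio bins at the same
diaspora bin (the diaspora covariate dominates the share distributions;
the ratio has only minor influence), then to the globally pooled fit.  An
empty population bin aborts calibration — the model cannot sample
emigration without it.

### Ensembles

`run_ensemble()` draws `n_samples` independent trajectories.  Sample $k$
is seeded by a fixed function of (master seed, $k$), so ensembles are
reproducible, independent of execution order, and nested across sizes —
the convergence diagnostic exploits the nesting by computing medians over
prefixes of one maximal ensemble.  Summaries report the per-year median
and the central 50% and 95% intervals; aggregates over regions or income
groups are summed per sample *before* quantile extraction, since quantiles
are not additive.

## The synthetic world

Real calibrations use published bilateral flow estimates, UN population
prospects, migrant stock matrices and GDP panels.  The package ships a
synthetic-world generator so that every stage — calibration, sampling,
evolution, reporting — is testable offline against a known ground truth.
The generator's defaults define the study conditions and are deliberately
fixed:

* 40 countries assigned round-robin to the four population bins,
  log-uniform within each bin (so every bin is covered by construction);
  log-uniform GDP per capita over 300–100,000; uniform yearly birth rates
  0.8–3.5% and death rates 0.4–2%, with natural change their difference —
  roughly the ranges national statistics spanned in recent decades.
* Ground-truth distributions mirroring the calibrated shapes: right-skewed
  skew-t rates ($a = 3$, $b = 2$, $\sigma \approx$ median/4) with medians
  narrowing from 0.006 (P1) to 0.001 (P4) per year; Weibull-max share
  distributions whose medians climb four orders of magnitude
  ($10^{-5}$ to $0.3$) across the diaspora bins but vary only ±10% across
  the ratio bins; a tight Student-t return rate centred at 0.004/yr.
* An initial stock matrix built for realism, not just coverage.  A naive
  i.i.d. log-uniform matrix produces unphysical worlds — island states
  "hosting" several times their own population, native populations growing
  10%/yr from migrant births, and share renormalization amplifying
  mid-tier corridors twenty-fold for origins without any dominant
  corridor.  The generator therefore (i) weights corridor stocks by host
  size (gravity structure: diasporas concentrate in large destinations),
  (ii) gives every origin up to three anchor corridors (15/10/5% of its
  population) hosted by comparably sized or larger countries, so raw share
  sums are of order one, and (iii) caps total hosted stock at 20% of the
  residence population and total diaspora at 50% of the origin population.

`generate_flow_history()` then simulates forward with the package's own
samplers, aggregates yearly flows into 5-year tables and snapshots stocks
at period boundaries — exactly the dialects the calibration reads — which
closes the generate → calibrate → simulate loop.

### What the closed loop does and does not show

Calibrating on a generated history recovers the per-bin emigration-rate
medians to within roughly 5–15%.  The residual is not estimation noise
alone; it decomposes into three systematic, model-faithful effects:
within-period population growth enters the flow/population-at-period-start
measurement (about $+2(1+g)\%$ for growth rate $g$); converting 5-year
aggregates of a right-skewed yearly process shifts the median toward the
mean (about +2%); and fitting the skew-t to 5-year-averaged samples is a
mild misspecification.  These are consequences of the one-year/five-year
rate-conversion problem that the measurement conventions share with real
calibrations, so the closed loop quantifies them rather than hiding them;
the thinnest bin (P1, ~50–60 observations) can exceed a 10% deviation for
some generator seeds.  Return-rate medians recover with a similar upward
offset, because 5-year return flows include returns of migrants who
arrived within the window while the denominator is the initial stock.

The synthetic world omits features of real data the model must face in
production: historical shocks and policy changes, regionally correlated
flows, measurement error in the flow estimates, and age/sex structure.
Passing the closed loop therefore validates the machinery and its
statistical conventions, not the model's fidelity to any historical
record.

## Numerical choices

* Interval closures follow the printed partitions exactly; boundary grids
  in the tests pin them.
* Rejection-based truncation (not inverse-CDF) keeps the fitted tail shape
  on the valid support; the 1,000-round cap is effectively never reached
  for calibrated distributions.
* Negative populations or stocks after a step (possible when mortality
  plus a large return draw overdraw a stock) are clamped to zero and
  counted; in the conservation regime (all natural rates zero) clamping
  provably cannot occur and the tests assert the count is zero.
* Optimizer restarts use a fixed perturbation ladder, so calibration is
  bit-reproducible for identical inputs — there is no hidden randomness.
* Desk-scale defaults (ensembles of 400–1,600 members, worlds of 12–40
  countries, horizons of 10–30 years) are the package's chosen test and
  demonstration sizes; production analyses match the published setup with
  ensembles of $10^5$ over 192 countries by raising `n_samples`.

## Known limitations

* Draws are independent across corridors and years; there is no
  correlation structure or memory beyond what the stock matrix carries.
* One return-rate distribution serves all corridors.
* No destination-capacity term: a persistently attractive corridor into a
  small host can accumulate stocks that outgrow the host, since nothing
  in the share mechanism saturates.
* The deterministic mode is a diagnostic companion, not a calibrated
  projection tool: with skewed inputs it is biased low by construction.
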