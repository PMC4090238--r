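---
title: "Modelling forest-pest dispersal risk from camper travel networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling forest-pest dispersal risk from camper travel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campnet)
```

## The problem

Campers moving untreated firewood are a recognised long-distance dispersal
pathway for bark- and wood-boring insects. Unlike wind- or flight-driven
spread, this pathway runs along a network of specific origin–destination
routes whose strength is the number of trips travelled, not their length.
`campnet` builds that network from reservation-style trip records and
scores, for every ordered pair of map cells, the relative risk that camper
travel carries a pest from one to the other. The outputs are rankings:
which destinations a pest at a given origin is most likely to reach
(forward analysis), which origins most plausibly supplied a pest found at a
given destination (reverse analysis), and which external cells pose the
greatest risk to a whole state or province.

## From trip records to a travel matrix

Three preprocessing steps take raw records to the sparse travel matrix
**M**:

* **Seasonal filter.** Pest transfer matters most when adult borers are
  emerging, so only trips whose visit date falls in a late-spring/early-
  summer window — at *both* the origin and the destination — are kept. The
  window is 10 weeks long by default, inclusive of its start date and
  exclusive of the end (start + 70 days), so windows compose without
  double-counting. The true window start varies geographically with
  climate; since that estimation needs external climate surfaces, the
  default `season_model()` uses a single configurable start date
  everywhere and exposes a `start_fun(lon, lat)` hook for per-location
  starts supplied by the user.
* **Grid aggregation.** Points are projected with a spherical Lambert
  azimuthal equal-area projection centred on the data extent (the package
  implements the closed-form spherical version; no external projection
  library is required) and binned into 15 km square cells, the resolution
  at which a continental reservation data set stays computationally
  tractable. Cell ids are row-major integers from the grid's lower-left
  corner, so the mapping is deterministic and invertible to cell centres.
  Same-cell trips are discarded — the diagonal of **M** is defined as zero.
* **Low-frequency filter.** Origin–destination pairs with three or fewer
  trips over the study period are dropped (`min_trips = 4`). The package
  applies this at raw point-pair resolution *before* aggregation by
  default (`filter_level = "pair"`), which is what makes the aggregation
  of a very large file tractable; `filter_level = "cell"` applies it to
  aggregated cell pairs instead. The two readings differ only in how much
  sparse, low-volume travel survives pooling.

Finally, every forward segment (i, j) gains a return segment (j, i) with
weight 0.15 m<sub>ij</sub>, added to any observed reverse travel. The 15%
reflects survey evidence on campers bringing unused firewood home; beyond
literal return trips it gives the aggregated network a secondary-
transmission channel (campground to campground, community to community).
Return weights are computed from the input weights only — no cascading —
and stay fractional, since they feed probabilities rather than counts. The
package adds returns after the low-frequency filter: return segments are a
model construct, not observed data, so they should neither rescue nor be
culled by a data-cleaning rule.

## The transition model and the simulated risk

**M** is scaled linearly into transition values p<sub>ij</sub> =
λ<sub>t</sub> m<sub>ij</sub>. The only structural requirement on
λ<sub>t</sub> is that every row of the resulting matrix sums below 1; the
package uses λ<sub>t</sub> = *safety* / (maximum row sum of **M**), with
*safety* = 0.9 by default. This choice maximises contrast between rows
(larger transition values preserve more signal in finite simulations)
while guaranteeing the constraint; *safety* is exposed for sensitivity
analysis, and relative rankings are insensitive to it because every
p<sub>ij</sub> scales by the same factor. The per-row remainder is the
termination probability p<sub>i term</sub> = 1 − Σ<sub>j</sub>
p<sub>ij</sub>; rows with no outgoing travel get p<sub>i term</sub> = 1
and never act as origins, though they remain reachable destinations.

Risk is estimated by simulation: from each origin cell, `estimate_phi()`
runs M independent walks (`sims_per_origin`); at each node the walk either
steps to a neighbour with its transition probability or terminates. A walk
contributes one count to M<sub>ij</sub> for every distinct cell j it
visits — intermediate or final, so multi-destination itineraries are
represented — and φ<sub>ij</sub> = M<sub>ij</sub> / M. Counting visits as
indicators (not multiplicities) is what keeps φ<sub>ij</sub> in [0, 1];
the origin itself is never counted, so φ<sub>ii</sub> is absent. We read
the simulation budget as *per origin*, which is the reading under which
φ<sub>ij</sub> = M<sub>ij</sub> / M is a proportion of walks from i.

Numerical and implementation choices:

* The walk engine is compiled (Rcpp) with a self-contained
  xoshiro256++ generator. Each origin's walks use a substream derived from
  (seed, origin id), so results are reproducible and independent of the
  order origins are processed in — including under future parallelism.
* A hard cap of 10,000 steps per walk guards against misconfigured inputs;
  with row sums ≤ 0.9 the expected walk length is at most 10, so the cap
  is unreachable in practice. Cap hits are counted and reported in the
  result's metadata.
* `analytic_visit_probability()` computes the exact hitting probability
  h(k) = p<sub>k,target</sub> + Σ<sub>l≠target</sub> p<sub>kl</sub> h(l)
  by one sparse LU solve per target. Because row sums are strictly below
  1, I − Q is strictly diagonally dominant and the system is never
  singular. This oracle is used throughout the tests to validate the
  simulated φ̂ at binomial-error resolution.

## Jurisdiction summaries

A jurisdiction is a named set of cells, given explicitly or derived from a
boundary polygon by testing cell centres (each border cell therefore
belongs to exactly one jurisdiction — the deterministic raster
convention). `jurisdiction_origin_risk()` sums φ<sub>ij</sub> over all
member destination cells j for every external origin cell i; it is exactly
the external-origin sum of the member cells' reverse profiles, and the
test suite asserts that identity. `classify_risk()` labels cells
"moderate-high" where the summed risk strictly exceeds 0.0001 and "low"
otherwise; the strict inequality follows the printed form of the cutoff.
Maps display the raw summed φ values, not a per-jurisdiction rescaling, so
maps for different jurisdictions computed from one risk matrix share a
single frame of reference and are directly comparable.

## The synthetic generator

Real reservation data are not redistributable, so the package generates
synthetic trip sets with the features of the real ones that the model is
sensitive to:

* **Landscape.** Population centres follow a clustered (Thomas-like)
  process — uniform parents, Gaussian offspring with ~80 km spread — with
  lognormal trip-generation weights. Campgrounds are a mixture: 65% placed
  within ~50 km of the population clusters (assigned round-robin so every
  cluster has local options, as real communities do), 35% uniform remote
  destinations; popularity weights are lognormal with sdlog 1.5, so a
  handful of destinations dominate visitation (max/median ratio well above
  10 at the default 200 campgrounds).
* **Distance kernel.** Destinations are chosen with probability
  proportional to popularity × kernel(distance), distances great-circle.
  The kernel family is lognormal, the family reported to fit reservation
  trip distances well. Its two parameters are solved numerically, before
  any sampling, so that the *marginal* trip-distance distribution meets
  the two published quantiles — P(D ≤ 100 km) = 0.5 and P(D > 500 km) =
  0.1. Solving against the marginal matters: over a discrete campground
  set the realised distances are tilted away from the kernel by geometry,
  so calibrating the kernel's own quantiles would miss both targets. The
  marginal is computed in closed form from the centre–campground distance
  matrix, making calibration deterministic; a profile solve (root in
  meanlog for the near quantile, grid in sdlog for the tail) seeds a
  joint tolerance-weighted least-squares polish. For some landscape
  geometries the fitted sdlog grows very large — the lognormal's
  power-law-decay limit, a recognised gravity-kernel form — so
  destination weights are evaluated in log space to keep that limit
  numerically exact.
* **Fixtures.** `make_fixture()` emits small self-contained bundles
  (trips CSV, grid JSON, jurisdiction list) engineered to reproduce the
  two qualitative archetypes of state-level origin-risk maps: a localized
  pattern with risk mass concentrated in cells adjacent to the target
  region, and a distant-hub pattern where the top-ranked origins form a
  far-away urban cluster, plus a mixed form. Bundles are byte-identical
  given a seed.

What the generator does *not* emulate: road-network routing (distances are
straight-line), multi-night itinerary correlation in the raw records, trip
party sizes (each record is one trip), and the geographic covariance of
season timing. Passing tests therefore demonstrate that the pipeline's
algebra, simulation, and summaries are correct under realistic marginal
structure — not that any particular real-world map is reproduced.

## Problem sizes used by the tests

The suite validates the simulation against the analytic oracle on 20
random sparse networks of 8–40 nodes at 100,000 walks per origin,
requiring agreement within four binomial standard errors for at least 99%
of pairs; kernel calibration is checked on a 100,000-trip synthetic set;
fixture scenarios run end-to-end at 2,000 walks per origin. These sizes
give sub-percent Monte Carlo resolution while keeping the whole suite
around a minute of compute.

## Limitations

* φ is a relative, ordinal score. Converting it into an absolute
  introduction probability would require the unknown fraction of trips
  carrying infested wood, and is deliberately out of scope.
* The 0.15 return fraction rests on thin evidence (a single state-level
  survey); results involving return-dominated paths deserve caution.
* The seasonal filter's single-start default is a simplification; users
  with climate-derived start dates should supply them via `start_fun`.
* Aggregation to 15 km cells merges distinct communities and campgrounds;
  within-cell structure is invisible to the model.
* The low-frequency filter removes genuine but rare long-distance events;
  it bounds the tail the model can represent.
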