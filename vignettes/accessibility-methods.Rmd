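---
title: "Floating catchment and gravity models for community care accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floating catchment and gravity models for community care accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accessfca)
```

## The problem

At sub-district scale in a dense Chinese city, elderly residents reach
community care facilities on foot. Planning where to add facilities or
beds requires a per-community measure of how much service is actually
reachable, not just how much exists inside administrative boundaries.
`accessfca` computes such measures for a region consisting of a demand
layer (communities with elderly populations, here people over 70) and a
supply layer (facility points with bed counts), then classifies, ranks and
summarizes the results into planning priorities.

All coordinates are planar meters in a projected system; distances are
straight lines. At a walking scale of a few hundred meters the road
network is dense and the straight-line approximation is the standard
simplification. Demand is located at the community's geometric centroid
(computed by the shoelace formula when a polygon is supplied) — a
stand-in for the unknown residential center of the elderly population,
and a known limitation of analyses at this scale.

## The models

Write $D_k$ for the elderly population of community $k$, $S_j$ for the
beds of facility $j$, and $d_{kj}$ for their separation in meters.

**Two-step floating catchment area (2SFCA).** Step one floats a catchment
of radius $d_0$ over each facility and computes its supply–demand ratio

$$R_j = \frac{S_j}{\sum_{k:\,d_{kj} \le d_0} D_k},$$

in beds per person. Step two floats the same catchment over each community
and sums the reachable ratios:

$$A_i = \sum_{j:\,d_{ij} \le d_0} R_j.$$

The catchment boundary is inclusive. Because the search floats rather than
following administrative boundaries, facility use across community borders
is captured automatically.

**Potential (gravity) model.** The classical potential replaces the hard
catchment with power-law distance decay controlled by a friction
coefficient $\beta$:

$$A_i = \sum_{j=1}^{n} \frac{M_j}{d_{ij}^{\beta}},$$

with facility mass $M_j$ taken as the bed count — beds are the sole
supply measure in this analysis. Note the plain potential has no demand
term, so its scale is not beds per person.

**Two-step gravity variant.** The description of the potential approach as
*two* searches with a distance-attenuated supply–demand ratio corresponds
to a gravity-weighted 2SFCA:

$$R_j = \frac{S_j}{\sum_k D_k\, w(d_{kj})}, \qquad
  A_i = \sum_j R_j\, w(d_{ij}), \qquad w(d) = \max(d, d_{\min})^{-\beta}.$$

This is the default meaning of `model = "potential"` in
`run_accessibility()`, because it keeps beds-per-person units and matches
the two-search procedure; the plain form is available as
`variant = "plain"`. Both are implemented through one kernel abstraction
(`kernel_indicator()`, `kernel_power()`): 2SFCA is the indicator kernel,
the gravity models are power kernels. That single code path gives a free
cross-model consistency check — substituting the indicator kernel into the
gravity machinery must reproduce 2SFCA exactly, and the tests assert it
does.

## Parameters

* `d0` (meters): the walking catchment. Defaults used in the drivers are
  500 and 600 m, bracketing the acceptable walking range reported for
  elderly pedestrians (survey work puts single trips mostly between 500
  and 800 m, shorter when destinations are discretionary; the straight-line
  radius must undercut the true walked distance).
* `beta` (dimensionless): friction coefficient of the power kernel,
  default 1. Values of 1–2 are conventional; at this spatial scale
  $\beta = 2$ spreads the scores so widely that maps become unreadable,
  which is why 1 is the working default.
* `min_distance` (meters, default 1): floor applied to distances before
  exponentiation. Without it a facility coincident with a community
  centroid makes the power weight undefined. One meter is far below any
  real centroid–facility separation, so the floor is inert except in the
  degenerate case it guards.
* `threshold` (beds per person, default 0.035): the policy benchmark of
  35 beds per 1000 elderly from China's 13th Five-Year Plan, used to count
  communities whose reachable supply may meet demand.

## Degenerate inputs and numerical choices

A facility whose catchment contains no positive demand has an undefined
ratio; it is assigned $R_j = 0$ with a warning naming the facility.
Treating unreachable supply as unusable (rather than erroring, or letting
the ratio blow up) preserves the conservation identity below in its
natural form and flags the facility for planner attention. Communities
with zero population still receive scores — they contribute nothing to any
denominator but remain map units (campus- or park-dominated tracts are the
real-world example).

Conservation is the central invariant: summing population-weighted scores
returns exactly the beds of every facility whose (weighted) catchment
contains positive demand,
$\sum_i D_i A_i = \sum_{j\,\text{served}} S_j$, for the indicator and any
power kernel. The suite verifies it to near machine precision on hundreds
of random regions, alongside homogeneity (scores scale linearly in beds,
inversely in population) and agreement with naive triple-loop reference
implementations to 1e-10.

A consequence worth stating: power kernels are strictly positive, so under
either gravity formulation every community with any supplied bed in the
region has a strictly positive score. An exactly zero potential-model
score can therefore only be a display or rounding artifact in a report,
never a model output; this package reports raw values and deliberately
does not guess a display cutoff.

## Classification and prioritization

`equal_interval_levels()` bins scores into $k$ equal-width intervals from
minimum to maximum (six levels for 2SFCA maps, five for the gravity map in
the drivers); a degenerate all-equal vector maps to level 1. The phrase
"averaged" sometimes attached to such map legends is read here as
describing symbology, not a transform; levels are computed on raw scores.

`percentile_bands()` ranks communities by descending score and cuts at
cumulative fractions (default 10% / 27% / 45%, remainder 55%), using
ceiling cutoffs and a deterministic tie-break (score descending, then id
ascending) so permuting the input never changes an assignment. Zero-score
communities are always placed in the bottom band: the design question is
whether a zero score can ride rank arithmetic into a favorable band when
most of a run's scores vanish, and the answer must be no, because bands
feed the priority logic where zeros specifically mark deprivation.

`priority_classes()` applies the planning rules in order: analyst-supplied
exclusions are `not_considered` (exclusion is a qualitative judgment about
who lives there and is never inferred from scores); zero accessibility in
every run is `highest` priority; a top-decile band in any run is
`not_considered`; combined bands 2/3/4 map to `very_low`/`low`/`high`.
The band-to-class mapping is an argument, because the narrative this
reconstruction follows states the two extreme rules explicitly but not the
middle of the scale; the default encodes "worse accessibility, higher
priority" monotonically.

## The synthetic generator

`generate_region()` emulates the structure of the motivating study area:
49 communities and 32 facilities on a 4 km square (a four-sub-district
scale), elderly populations uniform on 200–2000 persons, bed counts
uniform on 10–80. Uniform attribute distributions are the
least-assumption choice in the absence of any published distributional
information; both ranges and sizes are config fields. With these defaults
total beds over total population lands near 0.027, and essentially every
draw falls in 0.001–0.05 beds per person, the order of magnitude of
reported mean accessibility values (0.002–0.011). Facilities are placed
uniformly, or with a configurable fraction dropped within 300 m of
community centroids (`"clustered"`) — 300 m sits below both walking radii,
so clustering visibly raises catchment overlap and lowers the zero-score
fraction, a seeded Monte-Carlo property the tests check. Community
polygons are small squares centered on the demand points: real community
boundaries are unavailable and only centroids enter the models, so the
polygons exist to exercise the centroid code path honestly.

What the generator does *not* emulate: real street-block geometry,
spatially correlated population density, the size-frequency distribution
of facilities, or the specific communities of any real district. Passing
tests on synthetic regions therefore demonstrate the correctness of the
computations and the stated invariants, not agreement with any published
per-community value — those would require the undeposited administrative
records.

Problem sizes in the test-suite and acceptance runs — batches of 200
regions of 10×6 units for conservation, regions up to 50×50 for oracle
equivalence, 400 draws for the ratio bound — were chosen as the smallest
sizes at which the Monte-Carlo properties are stable.

## Worked example

```{r example}
reg <- line_fixture() # 3 communities on a line, facilities of 10 and 35 beds
ratios <- supply_demand_ratios(reg, d0 = 600)
ratios                # 10/200 and 35/200: each catchment holds 200 persons
scores <- accessibility_scores(reg, ratios, d0 = 600)
scores                # middle community reaches both facilities
sum(reg$demand$population * scores) # conservation: all 45 beds accounted for
summarize_run(scores, populations = reg$demand$population, ids = reg$demand$id)
```

## Limitations

Straight-line distances ignore barriers (rail lines, arterial roads);
centroid demand points misplace skewed populations; the 2SFCA ignores
distance inside the catchment (the enhanced-2SFCA family addresses this
and is out of scope here); $\beta$ is fixed rather than calibrated from
observed flows. The package computes and reports — siting new facilities
(e.g. at the geographic center of a deprived cluster) remains an analyst
decision.
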