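---
title: "Methods: health-risk based network representativeness in aqrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: health-risk based network representativeness in aqrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Regulatory air-quality networks report concentrations at a handful of
fixed-site monitors (FSMs). Whether those readings stand for the *health
risk* experienced by a city's population depends on three heterogeneous
layers at once: the spatial structure of each pollutant, the differing
toxicity of the pollutants, and where people actually live. `aqrep`
evaluates a network through all three.

Concentrations are transformed into additive excess hospital-admission
risks with an exponential concentration-response,
$\%AR_{p,j,t} = (e^{\beta_p C_{p,j,t}} - 1) \times 100$, per grid cell $j$
and hour $t$. The default slopes $\beta_p$ (per µg/m³:
PM2.5 $2.180567\times10^{-4}$, PM10 $2.821751\times10^{-4}$,
NO2 $4.462559\times10^{-4}$, O3 $5.116328\times10^{-4}$) are the all-age
Hong Kong hospital-admission coefficients used by air-quality health-index
practice; they are configuration, not constants, since risk slopes are
city- and study-specific. Because $\beta C \ll 1$ at ambient levels the
transform is nearly linear, which is what makes risks *additive* across
pollutants: the combined risk sums the NO2 and O3 terms with the larger of
the two PM fractions (the fractions nest, so adding both would double-count
mass).

Representativeness of a station for a cell is the *similarity frequency*
(SF): the fraction of hours at which the cell's %AR differs from the
pseudo-station's by no more than 20% (relative). A cell's network
representativeness $R$ is its best SF against any station, and the
population-health network representation index of a domain $d$ is
$PHNI_{p,d} = \sum_{i\in d} R_{p,i}\,pop_i / \sum_{i\in d} pop_i$. SF > 0.9
defines "well-represented" for area/population tallies. All of these are
computed independently per period (annual and the four seasons), i.e. SF is
recomputed on each period's hours rather than averaged from annual maps —
seasonal pollution regimes differ too much for the annual map to stand in.

## Conventions and numerical choices

- **Grid.** Regular, projected, planar; cells are half-open rectangles so
  every point has exactly one owner, with a point on a shared edge owned by
  the cell whose lower/left boundary it lies on. Indexing is 1-based with
  row 1 at the grid's minimum y. Cell size defaults to 45 m × 48 m
  (2160 m² per cell). No reprojection is attempted — CRS identifiers are
  only checked for equality.
- **Rasterization.** Dispersion models emit dynamic point meshes, denser
  near sources; each cell takes the arithmetic mean of its points per hour.
  Empty cells are missing, not interpolated; an optional nearest-cell fill
  exists but is off by default because any fill invents structure the model
  did not produce.
- **Population resampling.** Each fine cell is assigned to the nearest
  coarse-cell centre and the coarse count is divided equally among its fine
  children. A plain nearest-neighbour value copy would multiply the city
  total by the area ratio of the two grids; equal division conserves the
  total to floating tolerance (tested at 1e-6 relative).
- **Gas units.** NO2 and O3 arrive in ppb from most models; conversion uses
  $\mu g/m^3 = ppb \cdot M / V_m$ anchored to the conventional
  $V_m = 24.45$ L/mol at 25 °C and 1013.25 hPa and scaled by the ideal gas
  law for other configured conditions.
- **SF details the headline definition leaves open.** The relative
  difference is taken against the *station* series — the station is the
  object under evaluation; a symmetric max-denominator variant is available
  behind `reference = "max"`. Hours missing in either series are excluded
  from numerator and denominator, and SF is undefined below 75% joint
  coverage (configurable) rather than silently computed from a sliver of
  data. A reference value below $\varepsilon = 10^{-9}$ (zero concentration
  gives exactly zero %AR) degenerates the relative criterion, so there a
  timestep counts as similar only if the two values agree within
  $\varepsilon$. The station's own cell is SF = 1 by definition.
- **Bands.** low [0, 0.5), medium [0.5, 0.7), medium_high [0.7, 0.9],
  high (0.9, 1]: "well-represented" requires *strictly* more than 0.9, and
  the bands partition [0, 1] with deterministic edges.
- **PHNI.** The denominator sums population over the same domain as the
  numerator, which is what keeps district PHNI within [0, 1]. Cells whose
  $R$ is undefined (no model coverage) are excluded from both sums: missing
  data should not read as bad representation. District membership is by
  cell-centroid containment (even-odd rule; `mgcv::in.out` does the
  point-in-polygon work) — fractional-area weighting is out of scope.
- **Verification statistics.** The index of agreement is implemented in the
  standard Willmott form
  $1 - \sum(P_i-O_i)^2 / \sum(|P_i-\bar O| + |O_i-\bar O|)^2$. A variant
  replacing $|P_i-\bar O|$ with $|P_i+\bar O|$ — a form that circulates in
  print but is not bounded the way the index is meant to be — is available
  behind `denominator = "printed"` for audit only. Constant observations
  make IOA undefined and are reported as NA with a warning.

## The synthetic scenario generator

Real inputs at this resolution (street-scale model output, gridded
population) are proprietary, so the generator produces scenarios carrying
the statistical structure the method's behaviour depends on, with every
draw governed by one explicit seed:

- a **regional background** per pollutant: spatially homogeneous, AR(1) in
  time (persistence 0.9 by default, stationary sd 15% of the mean), around
  seasonal mean levels (PM 32.2/19.2 µg/m³, NO2 20.5 ppb, O3 30.4 ppb
  annually, peaking in autumn/winter for PM and NO2 and in autumn for O3 —
  the monsoon-style seasonality of a subtropical coastal city). Seasonality
  is emulated by switching the background mean per month block; there is no
  real meteorology.
- **traffic-like local sources**: exponential plumes
  $S\,e^{-d/L}$ around line or point sources with a diurnal modulation in
  [0.3, 1]; defaults are two line sources with peak 20 ppb NO2 and
  $L = 200$ m.
- an **Ox-conserving gas pair**: an hourly total-oxidant level shared by
  every cell; NO2 takes its seasonal share plus plumes and
  $O_3 = Ox - NO_2$ clipped at 0. Where clipping does not bite, NO2 + O3 is
  spatially *exactly* constant per hour; strong plumes can drive O3 to zero
  near the source (the real titration saturation seen at roadside sites),
  which is why the conservation scan in the tests uses moderate plume
  strengths and, for the default strength, asserts exact conservation on
  the unclipped hours. The default 20 ppb peak was chosen so that
  $(1-r)\,Ox \approx 30$ ppb headroom makes clipping rare.
- **PM** as a mix of regional and local: 65% (PM10) and 40% (PM2.5)
  regional by default, the remainder following the source-plume geometry.
  `pmScale` multiplies both PM levels; the mechanism demonstrations use
  0.6 so that PM contributes under 15% of the combined risk in a winter
  month, keeping the NO2/O3 anticorrelation the dominant term.
- a **clustered population**: a mixture of Gaussian clusters (default five,
  sd 150 m) scaled to a fixed total (default 1e5 persons for the desk-scale
  domain), strictly positive everywhere so no district is accidentally
  empty.
- default **stations** by type: a general station mid-domain, roadside
  stations on the line sources, a background station in the far corner —
  mirroring how real networks site them.

What the generator does *not* emulate: dispersion physics, chemistry beyond
the Ox budget, meteorology, terrain, or any real city's geography. Passing
tests on these scenarios show that the *pipeline arithmetic and the
mechanism* (anticorrelated gases under conserved Ox make combined risk
uniformly representable) are correct — not that any particular real network
achieves any particular PHNI.

## Verification strategy and problem sizes

Every pipeline quantity is checked two ways: against hand-computed analytic
cases, and against `bruteForcePHNI()`, a deliberately naive scalar-loop
implementation of the whole chain (conversion, %AR, SF counting, network
max, weighted mean) sharing no code with the vectorized path; the suite
requires agreement to 1e-12 on 20 × 20 × 500 h scenarios over ten seeds.
The mechanism demonstration runs at 30 × 30 cells × 720 h with one general
station and four quadrant districts — large enough for plumes, titration
and clustered population to interact, small enough to run in seconds.
District assignment is cross-checked against an independently written
ray-casting loop.

## Known limitations

- Only short-term (hospital-admission) risk: no chronic coefficients exist
  in the configuration, and none should be inferred from these outputs.
- SF treats the station series as error-free; monitor noise or low-cost
  sensor drift would need an error term in the similarity criterion.
- Nearest-centre population resampling is not dasymetric: population is
  spread uniformly within each coarse cell's footprint.
- The combined-risk uniformity result is a property of VOC-limited,
  Ox-conserving regimes; in NOx-limited cities the mechanism, and hence
  high combined-risk PHNI, need not hold.
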