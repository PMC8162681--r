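# aqrep — population-health based representativeness of air quality monitoring networks

Fixed-site air quality monitors (FSMs) are sparse, while urban pollution and
population are both strongly heterogeneous. `aqrep` answers the question a
network operator or exposure epidemiologist actually cares about: **how well
does the monitoring network represent the short-term health risk of the
population it serves**, rather than how much area it covers for any single
pollutant.

The package implements the full chain for PM10, PM2.5, NO2 and O3:

1. **Risk transform.** Hourly concentrations C (µg/m³) on a fine raster
   become additive excess hospital-admission risks per cell *j* and hour *t*:

   %AR<sub>p,j,t</sub> = (e^(β<sub>p</sub>·C<sub>p,j,t</sub>) − 1) × 100,

   with all-age admission slopes β per µg/m³ (defaults give 0.022%, 0.028%,
   0.045% and 0.051% per µg/m³ for PM2.5, PM10, NO2 and O3). The combined
   risk adds the NO2 and O3 terms to the larger of the two PM fractions:
   %AR<sub>total</sub> = %AR<sub>NO2</sub> + %AR<sub>O3</sub> +
   max(%AR<sub>PM2.5</sub>, %AR<sub>PM10</sub>).

2. **Similarity frequency (SF).** Each cell's %AR series is compared with the
   series at every *pseudo-station* (the grid cell containing an FSM); SF is
   the fraction of hours at which the cell differs from the station by at
   most 20% (relative). SF > 0.9 marks a *well-represented* cell; per-station
   represented area (km²) and population are tallied at that cutoff.

3. **Network index (PHNI).** Per cell the network representativeness R is the
   best SF against any station; the population-health network representation
   index of a domain *d* is the population-weighted mean

   PHNI<sub>p,d</sub> = Σ<sub>i∈d</sub> R<sub>p,i</sub>·pop<sub>i</sub> /
   Σ<sub>i∈d</sub> pop<sub>i</sub> ∈ [0, 1],

   evaluated annually and per season (spring Mar–May, summer Jun–Aug, autumn
   Sep–Nov, winter Dec–Feb) and per district (cells assigned by centroid
   containment in district polygons).

Supporting modules rasterize irregular dispersion-model point meshes (per-cell
arithmetic mean), locate stations on the grid, resample coarse population
rasters conservatively (nearest-centre assignment, counts split equally among
child cells), and compute the Willmott index of agreement and RMSE for model
verification. A seeded synthetic scenario generator produces complete,
realistic inputs — including an Ox-conserving NO2/O3 pair in which titration
makes the two gases anticorrelated while their combined risk stays spatially
near-uniform — so the whole pipeline is reproducible without proprietary
model output or population data.

## Worked example

```r
library(aqrep)

cfg  <- ScenarioConfig(seed = 2021, pmScale = 0.6,
                       stationCounts = c(general = 1, roadside = 1))
scen <- generateScenario(cfg)          # 30 x 30 cells x 720 h, 2 stations
res  <- evaluateScenario(scen, quantities = c("PM10", "NO2", "O3", "total"),
                         periods = "annual")
do.call(rbind, lapply(res, function(r) r$phniTable[r$phniTable$domain == "all", ]))
#>  pollutant domain period      phni population
#>       PM10    all annual 0.8734151      1e+05
#>        NO2    all annual 0.9459262      1e+05
#>         O3    all annual 0.7455398      1e+05
#>      total    all annual 1.0000000      1e+05
res$NO2$stationSummary
#>  station_id pollutant period area_km2 population
#>         GE1       NO2 annual   1.1664   68606.95
#>         RO1       NO2 annual   1.0368   58094.32
```

Reading: individual pollutants are imperfectly represented (O3 worst here —
its plume-driven titration makes it heterogeneous away from the stations; the
NO2-dedicated roadside station helps NO2), yet the **combined** risk reaches
PHNI = 1.0 because NO2 and O3 anticorrelate under a conserved total oxidant,
so their summed risk is nearly uniform in space. The station summary shows
each station's well-represented area (SF > 0.9) and the population living in
it.

A thin command-line wrapper (`inst/cli/aqrep.R`) exposes the same pipeline as
`simulate`, `rasterize`, `evaluate` and `verify` subcommands over YAML
configuration and plain-text (CSV/GeoJSON) inputs and reports.

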