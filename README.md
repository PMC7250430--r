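# ventgrowth

Growth phenotyping of microbial isolates across a salinity × pH ×
temperature factorial design, from raw microplate optical-density readings
to environmental-response groups.

The package was built for assays like those used on fungi isolated from
shallow hydrothermal vent sediments: each organism is grown in microtitre
wells over every combination of salinity (e.g. 0 ‰ and 30 ‰), pH (1–9) and
temperature (15–45 °C), with replicate wells and uninoculated controls, and
absorbance at 630 nm is read daily for a month. `ventgrowth` turns those
readings into replicate-level growth rates, factorial statistics and a
three-way phenotype classification, and ships a synthetic plate simulator
with known ground truth so the whole chain is testable without instrument
data.

## The model and statistics

Each blank-subtracted well series is fitted with the four-parameter
Richards (generalized logistic) curve

y(x) = a · [1 + (d − 1) e^(−k (x − x_c))]^(1/(1−d)), d ≠ 1,

with upper asymptote *a* (OD), rate constant *k* (1/day), shape *d* and
inflection time *x_c* (days); `d = 2` recovers the ordinary logistic. The
per-well summary statistic is the **normalized average growth rate**

r = k / (2 (d + 1)) (1/day),

recorded as 0 for wells called no-growth (peak OD below 0.05 or a
non-sigmoid trace). Replicate-level rates then enter, separately per
salinity:

1. Shapiro–Wilk normality and Brown–Forsythe variance-homogeneity screens;
2. an **aligned rank transform (ART)** two-way ANOVA for pH, temperature
   and their interaction (growth rates are typically non-normal and
   heteroscedastic, so ranks are used after aligning away non-focal
   effects);
3. per-level **Kruskal–Wallis** tests with **Dunn's** pairwise post hocs
   and compact letter displays (levels share a letter iff not significantly
   different).

Finally each organism's growth presence/absence profile is classified as
**temperature_tolerant** (growth at 45 °C), **wide_range** (growth at 37 °C
in both salinities, at pH 3, and in both salinities) or
**salinity_dependent_temperature_sensitive** (everything else).

## Worked example

Fit one noisy synthetic well and run the full pipeline on a small simulated
two-organism plate:

```r
library(ventgrowth)

x <- 0:29
y <- richards(x, a = 0.8, k = 0.5, d = 3, xc = 12)
set.seed(7)
fit <- richards_fit(x, pmax(y + rnorm(30, 0, 0.01), 0))
fit
#> Richards growth-curve fit (30 points)
#>       a       k       d      xc
#>  0.8040  0.4496  2.6184 11.5303
#> rate: 0.06213 1/day   R2: 0.9991   growth: TRUE

cfg <- run_config(
  out_dir = file.path(tempdir(), "demo"), seed = 42,
  design = plate_design(salinities = c(0, 30), phs = c(1, 3, 7),
                        temperatures = c(25, 37, 45), replicates = 4,
                        organisms = c("isolate_A", "isolate_B"), days = 30))
res <- run_pipeline(cfg)
#> simulate: 216 wells x 30 days written
#> fit: 144 wells, 116 converged, 80 growth calls
#> stats: 4 strata analysed, 6 factor levels dropped as no-growth
#> classify: 2 organism(s) labelled
```

The fitted parameters sit close to the simulation truth (a = 0.8, k = 0.5,
d = 3, xc = 12) and the rate 0.062/day close to the true k/(2(d+1)) =
0.0625/day. In the pipeline run, the six dropped factor levels are the pH 1
rows (nothing grows there) and the 45 °C rows of the non-thermotolerant
organism; the report ends with the group tally — the simulator's default
truth makes the first organism thermotolerant:

```
Group counts:
  wide_range: 1
  salinity_dependent_temperature_sensitive: 0
  temperature_tolerant: 1
```

The packaged reference profiles of ten vent isolates classify as

```r
counts <- group_counts(classify_rate_table(vent_fungi_growth())$group)
#> wide_range: 4, salinity_dependent_temperature_sensitive: 5, temperature_tolerant: 1
```

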