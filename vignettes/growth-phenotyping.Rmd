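---
title: "Growth phenotyping across salinity, pH and temperature: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth phenotyping across salinity, pH and temperature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventgrowth)
```

`ventgrowth` analyses factorial microplate growth assays: every organism is
cultured over a full salinity × pH × temperature cross with replicate wells
and uninoculated controls, optical density at 630 nm is read daily, and the
question is which abiotic conditions permit growth, how fast growth is
where it occurs, and what kind of environmental-response phenotype each
organism has. This vignette is the package's account of the methods: the
model, the statistical chain, the simulator, and the judgement calls.

## The growth model

A well's blank-subtracted OD series is summarised by the four-parameter
Richards (generalized logistic) curve

$$y(x) = a\,\bigl[1 + (d-1)\,e^{-k(x - x_c)}\bigr]^{1/(1-d)}, \qquad d \ne 1,$$

with upper asymptote $a$ (OD units), rate constant $k$ (1/day), shape $d$
(dimensionless) and inflection time $x_c$ (days). At $d = 2$ this is the
ordinary logistic; as $d \to 1^+$ it approaches the Gompertz limit. Only
the sigmoid branch $d > 1$ is admitted: the same algebra with $0 < d < 1$
describes decay, which cannot arise in a growth assay, and $d = 1$ is a
singularity. The per-well summary statistic is the normalized average
growth rate

$$r = \frac{k}{2\,(d+1)} \quad (1/\text{day}),$$

strictly increasing in $k$ and decreasing in $d$, so it orders wells the
way a biologist would order their curves. Replicate wells are fitted
individually — eight replicate rates per treatment feed the statistics —
rather than fitting one curve to the replicate mean, because the
between-replicate spread is exactly what the rank tests need.

### Fitting

`richards_fit()` minimises the residual sum of squares by bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`). Starting values are data-driven:
$a_0$ is the running-median-smoothed maximum, $x_{c,0}$ the first half-max
crossing, $k_0$ the early-phase log-linear slope, $d_0 = 2$; two coarse
fallback starts guard against a bad first guess and the best converged
solution by RSS is kept. Bounds — $a \in (0, 2\max y]$, $k \in (0, 10]$,
$d \in (1, 20]$, $x_c \in [\min x - 5, \max x + 5]$ — keep the solver on
the sigmoid branch and away from the $d \to 1$ singularity. Solver
tolerances are tight (`ftol = ptol = 1e-12`) so noiseless synthetic wells
are recovered to relative error below $10^{-4}$, which the test suite
asserts.

### The growth call

Instruments report no explicit "no growth" state, so the package uses a
deterministic rule with two configurable thresholds: a well is growing iff
its peak blank-subtracted OD is at least `threshold_od = 0.05` absorbance
(boundary inclusive) *and* the fit converged with $R^2 \ge$
`threshold_r2 = 0.7`. The OD gate rejects flat noise traces; the $R^2$ gate
rejects erratic traces that happen to cross the OD gate. If the solver
fails outright the call falls back to the OD gate alone, so an obviously
growing well is never discarded for numerical reasons; such wells keep
`fit_ok = FALSE` and a rate of 0, and the pipeline log counts them so the
exclusion is auditable. No-growth wells are recorded with rate 0 and kept
in the rate table — absence of growth is data, not a missing value.
Defaults were chosen once against the simulator's noise scale (peak OD of
real growth here is an order of magnitude above 0.05) and are exposed as
arguments, not retuned per dataset.

## Blank subtraction

One set of uninoculated control wells per treatment is shared by all
organisms; the control signal subtracted from an inoculated well is the
per-day mean of its treatment's controls. Per-day (rather than
time-averaged) subtraction was adopted because control absorbance can
drift; the choice is visible in `blank_subtract()` and is an assumption,
not a measurement. Negative blank-subtracted values are retained: clamping
at zero would bias the early, noise-dominated part of every trace upward.
Blank subtraction is linear, so subtracting then averaging replicates
equals averaging then subtracting — a property the tests check.

## The statistical chain

Growth rates from microplate assays are generally non-normal with
heteroscedastic residuals, so the factorial analysis is rank-based
throughout. Statistics are computed separately per (organism, salinity)
stratum — freshwater and seawater data are never pooled — and within a
stratum the two factors are pH and temperature.

**Screening.** Shapiro–Wilk (`stats::shapiro.test`) and Brown–Forsythe
(Levene on deviations from group medians, `car::leveneTest`) are reported
per stratum. They justify the rank-based chain; they do not gate it.

**Level pruning.** A pH or temperature level with no growing well anywhere
in the stratum (pH 1 universally; 45 °C for non-thermotolerant organisms)
carries no rate information and is dropped before the factorial analysis.
Within retained levels, no-growth replicates stay in as rate 0 so the
design stays fully crossed and balanced. Dropping whole levels rather than
individual cells is deliberate: the aligned rank transform needs every cell
of the cross non-empty. If pruning leaves a factor with a single level the
two-way ANOVA is skipped with a notice and only the one-way chain runs.

**Aligned rank transform.** For each effect $E \in \{A, B, A{\times}B\}$
the response is aligned by keeping only $E$'s estimated contribution plus
the cell residual: main effects are estimated as marginal means minus the
grand mean, the interaction as cell mean minus both marginal means plus the
grand mean. Aligned values are mid-ranked and a standard two-way fixed
effects ANOVA is run on each rank column, reading off only the focal
effect's $F$ and $p$. The defining identity — every non-focal effect
re-estimated from an aligned column is zero — is asserted to $10^{-9}$ on
every input before ranking, and a Monte-Carlo test (4×4 null layout, 8
replicates per cell, 2000 tables) confirms the interaction test holds its
nominal 5% size within ±2 percentage points.

**Post hoc.** Where the factorial structure warrants level-wise
comparisons, each retained level of one factor conditions a Kruskal–Wallis
test (`stats::kruskal.test`, tie-corrected) across the other factor,
followed by Dunn's pairwise $z$ tests on mean ranks with tie-corrected
pooled variance. The default multiplicity adjustment is `none`, matching
the plain Dunn procedure; Bonferroni and Holm are available
(`adjustment=`). Significance at $\alpha = 0.05$ is summarised as a
compact letter display built by insert-and-absorb, which guarantees two
levels share a letter iff they are not significantly different; the test
suite verifies this equivalence exhaustively for all significance patterns
up to four levels, and checks Kruskal–Wallis and Dunn against brute-force
rank computations on small instances.

## Response-group classification

Each organism's profile — growth presence/absence per (salinity, pH,
temperature), where a condition counts as growing when at least half its
replicates were called growing — is assigned one of three labels by ordered
clauses (`response_rules()`):

1. **temperature_tolerant** — growth at 45 °C under any salinity and pH.
   This clause dominates because thermotolerance alone defines the group.
2. **wide_range** — growth at 37 °C in *both* salinities, growth at pH 3
   somewhere, and growth in both salinities.
3. **salinity_dependent_temperature_sensitive** — everything else.

The both-salinities requirement in clause 2 is the package's design
choice on a genuinely open point: several vent isolates grow at 37 °C in
seawater only, and their warm growth is a salinity-dependent trait, not
evidence of a wide range. Requiring warm growth in both salinities is what
cleanly separates the two groups across the packaged ten-isolate reference
profiles (4 wide-range, 5 salinity-dependent/temperature-sensitive, 1
temperature-tolerant); relaxing it (`wide_temp_both_salinities = FALSE`)
moves seawater-only warm growers into the wide-range group. Classification
uses presence/absence only, not rate magnitudes — the groups describe
growth *ranges*. Every profile receives exactly one label, and adding a
growth condition can never demote a thermotolerant organism.

The packaged table `vent_fungi_growth()` encodes the growth occurrence of
ten vent-sediment fungal isolates over the full 2 × 5 × 4 condition grid.
It is an encoding of reported growth ranges, not raw plate data; where a
description hedged ("growth generally occurred at…"), the encoding keeps
the explicit statements and resolves the hedges conservatively, which does
not affect any clause input.

## The simulator

`simulate_plate()` exists so every downstream stage has ground truth. It
emulates: a full factorial well enumeration (the default design's
2 × 5 × 4 × 8 layout gives 320 inoculated wells per organism); daily
readings on an integer day grid 0…29 (month-long assay, day-0 reading
included); Richards-shaped growth with per-cell true parameters; additive
Gaussian measurement noise truncated at zero (default sd 0.01 OD — the
instruments give no noise model, so this is a free parameter documented
here); a control-well baseline (default 0.05 OD); and the assay's
qualitative structure — no growth at pH 1, 45 °C growth restricted to one
designated thermotolerant organism. Seeding is per-well: a master seed is
folded with a hash of the well id, so simulating a subset of a design
reproduces exactly the per-well traces of the full design.

It does **not** emulate: evaporation or edge effects, optical saturation,
well-position systematics, condensation artefacts, lag-phase irregularity,
or death phases. Passing tests therefore demonstrate that the estimator
and statistics recover truth under the stated noise model — not that any
real plate is free of these artefacts. `simulate_rate_table()` skips the
curve level entirely and generates balanced two-factor rate tables with
known (centred) effects for validating the ART chain.

## Numerical choices and problem sizes

Ties are mid-ranked everywhere, with tie corrections in both the
Kruskal–Wallis statistic and the Dunn variance; a fully tied sample is
reported as no separation ($H = 0$, $p = 1$) rather than an error, and a
within-groups-constant sample makes Brown–Forsythe warn and report
non-rejection. Letter assignment orders groups by their first member with
levels sorted ascending, so output is deterministic. CSV output renders
numerics at full double precision (`%.17g`), making write→read a true
identity, which the round-trip tests rely on.

The validation suite's problem sizes are chosen to give tight Monte-Carlo
error at desk scale: 2000 null tables for the interaction size check
(standard error ≈ 0.5 percentage points), 100 seeds × 8 replicates for
noisy rate recovery (observed bias well under the 10% band), 30-day grids
for noiseless recovery. The pipeline tests run a reduced 2 × 3 × 3 × 3
design purely to exercise the plumbing quickly; the statistical checks do
not depend on it.

## Known limitations

- The Richards fit assumes a single sigmoid phase; diauxic or declining
  cultures will fit poorly and be caught (if at all) by the $R^2$ gate.
- The growth/no-growth rule is threshold-based; organisms with peak OD
  near `threshold_od` will flip calls between replicates, which the
  at-least-half-replicates profile rule absorbs but does not eliminate.
- ART's alignment uses unweighted marginal means and is exact only for
  balanced strata; pruning keeps strata balanced, but externally supplied
  unbalanced tables are the user's responsibility.
- Dunn $p$-values are normal approximations; at very small group sizes the
  letters should be read qualitatively.
- The classifier's clauses are an operationalization of verbal group
  definitions; they are configurable precisely because other assays may
  draw the wide-range boundary differently.
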