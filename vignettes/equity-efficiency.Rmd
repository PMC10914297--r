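---
title: "Measuring equity and efficiency of regional health-resource allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring equity and efficiency of regional health-resource allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrequity)
```

## The problem

Provincial health administrations allocate primary-care resources — beds,
health technicians, licensed (assistant) physicians, registered nurses —
across regions that differ enormously in population and in geographic size.
Two questions recur in health-services research on such panels:

1. **Equity** — how evenly are resources distributed, relative to the people
   they serve (population base) and relative to the territory they must
   cover (geography base)?
2. **Efficiency** — how well do the allocated resources convert into service
   utilisation (outpatient consultations, hospital admissions)?

`hrequity` implements the standard toolkit for both questions on a long
panel with one row per region and year, plus a synthetic-data generator so
the whole pipeline can be exercised and validated without access to any
yearbook.

## Equity: Lorenz curves and Gini coefficients

For a chosen resource and allocation base, regions are ranked in ascending
order of resource per unit of base; plotting cumulative base share $X$
against cumulative resource share $Y$ gives the Lorenz polyline from (0,0)
to (1,1). The Gini coefficient is twice the area between the polyline and
the diagonal, computed by the trapezoid rule

$$G = 2\left[0.5 - \tfrac{1}{2}\sum_{i=1}^{n}(X_i - X_{i-1})(Y_i + Y_{i-1})\right],
\qquad X_0 = Y_0 = 0,$$

with $n$ the number of regions. This is algebraically identical to the
base-share-weighted mean-absolute-difference definition
$G = \sum_{i,j} w_i w_j |r_i - r_j| / (2\mu)$ over per-base rates $r$, which
the test suite uses as an independent oracle. Conventional bands label the
result: below 0.2 absolute equity, 0.2–0.3 relatively fair, 0.3–0.4
basically reasonable, 0.5+ a wide gap, 0.6+ a dangerous state of high
inequality (boundaries left-closed).

One construction detail is genuinely open: under the geography base, regions
could conceivably be ranked by per-capita rate instead of per-km² rate. We
rank by the rate of the *active* base. Ranking a geography-base curve by
per-capita rates can produce a non-convex polyline whose trapezoid sum goes
negative; ranking by the active base is the standard Lorenz construction,
guarantees $Y_i \le X_i$ (convexity), and makes $G \ge 0$ by construction.

Each year is treated as an independent cross-section, matching the
year-by-year layout of published equity tables.

## Equity: density indices HRDI and W

A per-capita view understates scarcity in vast sparse regions; a per-km²
view understates it in dense ones. The health resource density index
combines both as a geometric mean:

$$\mathrm{HRDI} = \sqrt{\frac{\text{resource}}{\text{population}/1000}\times
\frac{\text{resource}}{\text{area km}^2}}.$$

The geometric mean is the unit-coherent reading (its units are resources per
$\sqrt{1000\,\text{persons}\cdot\text{km}^2}$, and it is homogeneous of
degree 1 in the count); the bare product of the two densities is available
behind `method = "product"` for sensitivity analysis.

The standardised index $W = \mathrm{HRDI}_\text{region} /
\mathrm{HRDI}_\text{standard}$ compares each region with a province
standard. Two constructions of the standard are plausible and both are
implemented: the **aggregate** standard (total resources, total population,
total area of the province; the default) and the unweighted **mean** of the
regional HRDIs. The aggregate is the default because it is the only
construction under which a region shaped exactly like the province — the
natural reading of "the provincial average level" — scores exactly $W = 1$;
this identity is asserted in the tests. Reports conventionally call out
regions with every $W < 1$ (persistently below the provincial level) and
every $W > 1.8$ (persistently far above it); `w_table()` flags both sets.

## Efficiency: input-oriented DEA

Each decision-making unit (DMU) — a year of province totals, or a region
within one year — converts $m = 4$ inputs into $s = 2$ outputs. The radial
input-oriented envelopment program for DMU 0 is

$$\min\ \theta \quad \text{s.t.}\quad \sum_j \lambda_j x_{ij} \le \theta
x_{i0},\ \ \sum_j \lambda_j y_{rj} \ge y_{r0},\ \ \lambda \ge 0,$$

with no further constraint under constant returns to scale (CRS, the CCR
model; its optimum is **overall efficiency**), with $\sum_j\lambda_j = 1$
under variable returns (VRS, the BCC model; **technical efficiency**), and
with $\sum_j\lambda_j \le 1$ under non-increasing returns (NIRS). **Scale
efficiency** is the CRS/VRS ratio, and returns to scale are classified by
the standard NIRS comparison: constant when CRS = VRS, otherwise decreasing
when NIRS = VRS and increasing when not.

Design choices:

* **Two-phase, epsilon-free slacks.** After the radial phase, a second LP
  maximises the total remaining input excess and output shortfall at fixed
  $\theta^*$. This avoids the arbitrary non-Archimedean $\varepsilon$ of the
  single-LP formulation. Internally the slack variables are eliminated
  (they are affine in $\lambda$), shrinking the phase-2 LP to $n$ variables.
* **Slack source.** Published year-level tables in this literature can show
  technical efficiency of exactly 1 alongside non-zero slack
  ("relaxation"), which is only consistent with slacks taken from the CRS
  model; CRS phase-2 slacks are therefore the reported default, with
  `slack_from = "vrs"` as a switch.
* **Conditioning.** Every input and output column is rescaled to mean 1
  before solving (radial scores are units-invariant — a tested property)
  and slacks are rescaled back, keeping the LP well conditioned when
  consultation counts in the $10^5$–$10^8$ range meet bed counts in the
  $10^2$–$10^5$ range.
* **Solver.** The envelopment problems are tiny (at most a few dozen
  variables and about ten rows), so the package ships a dense two-phase
  primal simplex with Bland's anti-cycling rule, exact on these sizes to
  about $10^{-12}$. Its optima are checked in the tests against a
  closed form (1×1 CRS), against exhaustive vertex enumeration on small
  instances, and against hand-solved frontier examples.
* **Tolerances.** Efficiency ties and the "slack is zero" test use
  `tol = 1e-6`, with slack comparisons scaled by each column's mean;
  LP solvers legitimately return 0.999999… for an efficient unit.
  Degenerate alternative optima in $\lambda$ and individual slacks are
  accepted as solver-dependent; only $\theta$, slack totals and the
  zero/non-zero pattern are treated as reproducible.
* **DMU schemes.** `run_dea()` exposes both the year-as-DMU scheme on
  province totals (5 DMUs, the province-by-year table) and the
  region-as-DMU scheme within each year (one cross-section per year, the
  per-region table). A third conceivable scheme — each region's five years
  as five DMUs — is deliberately not the per-region default: with 6
  dimensions and 5 DMUs nearly every unit would be trivially efficient.

## The synthetic generator

`generate_panel()` emulates the statistical shape of a provincial panel:
near-uniform per-capita resource rates (population-base Gini well below
0.3) together with heavy-tailed per-km² densities (geography-base Gini
above 0.6), populations spanning roughly $2\times10^5$–$1.6\times10^7$ with
areas 1.5–150 thousand km², and utilisation that follows resources with
multiplicative lognormal noise. The calibration targets are stated as the
quantity the analysis actually measures: the *region-level, base-weighted*
Gini.

That last point drove the main design decision. The closed form
$G = 2\Phi(\sigma/\sqrt 2) - 1$ links a lognormal dispersion to the Gini of
an *unweighted continuum* of rates; drawing 21 iid rates and weighting them
by heavy-tailed base shares misses the target badly (by ~0.05 on the
population base and by more than 0.2 on the geography base in our
experiments — one region can carry half the weight). The generator therefore
*discretises* the lognormal at the region level: regions are laid out in
random order along the cumulative base-share axis, each receives the
conditional mean of the mean-1 lognormal over its own share interval, and
$\sigma$ is then solved by root-finding so the weighted Gini of the
resulting panel equals the target essentially exactly (the closed form
provides the starting point, exposed as `sigma_for_target_gini()`). Areas
are built the same way from a calibrated density profile (area =
count/density), which automatically makes sparse regions large — the
density–area anticorrelation real provinces show. With
`resource_jitter_sd = 0` the targets are recovered to machine precision;
the default small jitter (0.05) decorrelates the four resources at a cost
of roughly ±0.01 in the realised Gini.

Default magnitudes are chosen to be realistic for township-level primary
care: mean rates per 1000 population of 1.5 beds, 1.4 technicians, 0.55
physicians and 0.5 nurses; about 1300 consultations per technician and 25
admissions per bed per year (≈60–70% occupancy at a one-to-two-week stay);
3% annual growth applied uniformly, which keeps the cross-sectional Gini
structure constant across years, as observed in real five-year panels.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring regions, within-region (sub-prefecture) heterogeneity,
resource-specific equity profiles (all four resources share one regional
profile up to jitter), demand-side drivers of utilisation, and shocks such
as an epidemic year. Passing recovery tests therefore demonstrates that the
estimators measure what they claim on data with the assumed structure — not
that real yearbook data satisfy those assumptions.

`generate_dea_set()` plants known efficiencies: frontier DMUs are placed on
a single constant-returns ray and each DMU's inputs are inflated by
$1/\theta^*$, which makes the measured CRS efficiency equal the planted
value exactly — the basis of the solver-recovery tests. A Cobb–Douglas
technology with a returns parameter exercises the variable-returns side.

## Worked example

```{r example}
panel <- generate_panel(seed = 1)
gini_table(panel)[1:4, ]
head(w_table(panel), 4)
fit <- run_dea(panel, "years_as_dmus_on_totals")
fit
```

## Degenerate inputs and edge cases

* An all-zero resource column gives a degenerate Lorenz curve; the error
  names the condition rather than returning NaN shares.
* Ties in per-base rates keep input order; the Gini is provably unaffected
  by tie order (asserted in the tests).
* A tiny negative trapezoid sum (floating cancellation, within $10^{-12}$)
  is clipped to $G = 0$.
* A single-DMU DEA problem is trivially efficient ($\theta = 1$,
  $\lambda = 1$).
* Incomplete panels (a missing region-year) are refused by the DEA stage;
  equity tables only require the years they are asked for.

## Problem sizes

The shipped test-suite and acceptance runs use 21 regions × 5 years (the
typical size of a provincial panel), 50-seed replications for recovery
medians, 200 random instances for the Gini oracle comparison and 100 for
the DEA closed-form comparison; brute-force vertex-enumeration checks run
on instances up to 4 DMUs × 2 inputs × 2 outputs, where exhaustive
enumeration is exact and fast.

## Limitations

Quality of care, case mix, demand and financial inputs are outside the data
model; the DEA scores are relative to the observed frontier (adding a DMU
can only lower, never raise, others' scores — also a tested property); and
Gini coefficients at 21 regions are cross-sectional descriptions, not
inferential estimates with sampling error.
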