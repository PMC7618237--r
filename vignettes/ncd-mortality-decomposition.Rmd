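---
title: "Methods: lifetable probabilities of NCD death and their cause-age decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetable probabilities of NCD death and their cause-age decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncdbench)
```

# The measure

The pipeline's primary outcome is the unconditional probability of dying
from a set of non-communicable disease (NCD) causes between two exact
ages, in the absence of competing causes of death. It is built from an
abridged lifetable restricted to the causes of interest: for an age band
of width $n$ years with cause-set death rate $m$ (deaths per
person-year) and separation factor $a_x$ (average years lived within the
band by those who die in it),

$$ {}_nq_x = \frac{n\,m}{1 + (n - a_x)\,m}, $$

and the probability of dying between exact ages $x_1$ and $x_2$ is

$$ q = 1 - \prod_{b} \left(1 - {}_nq_b\right) $$

over the bands tiling $[x_1, x_2)$. Because only the cause-set rates
enter, the measure is independent of the population age structure and of
mortality from all other causes — two countries with identical NCD rate
schedules get identical values regardless of how much infectious or
injury mortality they carry. The conversion formula is the standard
abridged-lifetable form; for $m \to 0$ it agrees with the constant-hazard
alternative $1 - e^{-nm}$ to first order (the suite checks
$|{}_nq_x - (1 - e^{-nm})| \le (nm)^2$ at small $m$), and for finite $m$
it stays strictly below 1, so no clamping is needed.

## Grids and defaults

The default grid has 17 bands — $[0,1)$, $[1,5)$, then 5-year bands
through $[75,80)$ — covering exactly $[0,80)$, matching the
birth-to-age-80 primary outcome. The SDG target 3.4 variant uses eight
5-year bands on $[30,70)$ and only the cause groups tagged as part of
the SDG superset (cancers, cardiovascular diseases, chronic respiratory
diseases, diabetes).

The separation factor defaults to the band midpoint $a_x = n/2$
everywhere, including infancy. The usual all-cause infant skew
($a_0 \approx 0.1$) reflects the concentration of neonatal deaths, which
is not clearly applicable to NCD-only schedules dominated by congenital
conditions spread across the first year; $a_x$ is per-band configuration
rather than a constant, so a user with better information can override
it. Mortality above age 80 is ignored by construction: the measure is
deliberately insensitive to old-age mortality differences.

Probabilities are stored at full precision; one-decimal
percentage-point rounding is a display concern only and never feeds the
classification or benchmark logic.

# Cause groups

All NCD deaths are partitioned into 20 mutually exclusive, collectively
exhaustive groups: 16 named leading causes or aetiologically related
groups, plus exactly four residuals (other circulatory diseases, other
malignant neoplasms, other neuropsychiatric conditions, other NCDs).
The 16-vs-residual split depends on the upstream cause list, so the map
ships as editable YAML with only the structural constraints (20 groups,
4 residuals, disjoint codes) enforced. The default map's member codes
are synthetic placeholders; `read_cause_map()` accepts a real
assignment. Detailed codes are aggregated by summing deaths before
rates are formed, which conserves total deaths within each age stratum
exactly.

# Change, classification, and benchmarks

Change over a period is the difference between the probabilities in the
final and first year, in percentage points — endpoint years only, with
no linearity assumption in between. Comparing the 2010–19 change
$\Delta_2$ with the 2001–10 change $\Delta_1$ yields seven categories:
larger decline, reversal of an increase, and smaller increase count as
improvement; smaller decline, reversal of a decline, and larger increase
as deterioration. Boundary conventions (exact ties, zero first-period
change) are fixed and documented in `classify_decadal()`: ties are
`unchanged_pace` (neutral), $\Delta_1 = 0$ classifies by the sign of
$\Delta_2$ as a larger decline/increase, and $\Delta_2 = 0$ with a
nonzero $\Delta_1$ is a smaller decline/increase. A property test sweeps
random and boundary pairs to confirm the partition is total and
single-valued.

Regional summary statistics follow fixed conventions: the regional mean
decline is the unweighted mean of $-\Delta$ over *all* countries in the
region (increases enter negatively), the share of world population in
declining countries weights by sex-specific population, within-region
dispersion is the sample standard deviation ($n-1$), and the level–change
association is the plain Pearson correlation.

The regional benchmark is the eligible country (high-quality data,
member of the decomposition set) with the most negative change over
2010–19, per sex; regions with two or fewer eligible countries return no
benchmark. Ties — measure-zero in practice — break first on the larger
starting level (the harder starting point) and then alphabetically, so
selection is deterministic. Whether "largest reduction" is absolute or
relative is ambiguous in principle; absolute percentage points are used,
consistent with how all magnitudes are reported.

Countries enter the cause-decomposition subset if they have high-quality
data and population above a floor (default 2 million, both sexes,
configurable), are explicitly overridden as high-quality, or are added
for regional representation (medium-quality countries among the five
most populous of their region, and each region's most populous country
regardless of quality). Overridden countries are selected outright —
the floor applies only to the high-quality arm.

# The Horiuchi decomposition

Attribution of a change to causes and ages treats the probability (times
100, so results are in percentage points) as a functional
$f(x)$ of the full band-by-group rate vector, and integrates partial
effects along the linear path from $x_1$ (rates in the first year) to
$x_2$ (rates in the second), discretized into $N$ equal steps with all
other covariates held at the step midpoint. Key properties, all tested:

* contributions plus the reported residual equal the target change
  exactly, by construction of the residual;
* a covariate with zero change contributes exactly zero (bitwise — it is
  never perturbed);
* if only one covariate changes, the step sum telescopes and its
  contribution equals the whole difference exactly, for any $N$;
* on linear functionals the decomposition is exact for any $N$;
* the residual decays at order $N^{-2}$, verified empirically across
  $N \in \{10, 100, 1000\}$, and contributions at large $N$ match
  numerically integrated line integrals of central-difference gradients.

$N$ defaults to 100: with the measured $N^{-2}$ decay the residual is
then orders of magnitude below the 0.1 pp at which contributions are
read, at modest cost. The residual is always reported, never
redistributed across cells — redistribution would hide convergence
failures. Zero-valued rates pose no issue under linear interpolation.

Decadal-difference and benchmark-gap decompositions are cellwise
*differences of two within-period decompositions*, not direct
decompositions along a single path between the difference endpoints.
This matches the quantity being explained (a difference in changes),
preserves exact additivity to $\Delta_2 - \Delta_1$ (or to the gap), and
keeps the within-period results reusable. A single-path alternative
would also satisfy additivity and differs at the order of the residual;
the differencing construction is the fixed, documented choice.
Computation always runs on the full age grid; pooling display columns
(for example 0–4) is a reporting option only.

# Uncertainty

The default uncertainty mechanism is Poisson resampling: each replicate
surface draws deaths\* ~ Poisson(observed deaths) independently per cell
and recomputes rates. The 95% uncertainty interval of any statistic is
the 2.5th–97.5th percentile across replicates under the
linear-interpolation percentile rule (`quantile()` type 7), which
depends only on the order statistics and is bit-reproducible given the
seed; the point estimate is the statistic on the central surface. An
interval excludes zero when it lies strictly on one side of it.
Externally produced draws (for example, upstream estimation draws) can
be supplied through the same interface, which isolates the choice of
draw mechanism from everything downstream. Calibration is checked by
simulation: on a known-rate scenario, observed counts are drawn from
the truth, intervals built by resampling the observed counts, and
empirical coverage of the truth is required to land in 92–98% over 500
replications. Interval widths are checked to shrink as exposure grows.

# The synthetic generator

The generator emulates the statistical structure the analysis assumes of
its inputs, with known ground truth:

* **Age gradient.** Band all-NCD rates follow a Gompertz curve
  $\alpha\,e^{\beta\,\mathrm{age}}$ with a lognormal country effect on
  $\alpha$. Defaults $\alpha = 4\times 10^{-5}$ per person-year at age 0
  (SD 0.3 on the log scale) and $\beta = 0.085$ per year of age give
  birth-to-80 all-NCD probabilities spanning roughly 0.15–0.7 across
  simulated countries with a mean near 0.38 — the range national
  populations actually occupy — and a male multiplier of 1.3 reproduces
  the usual male excess.
* **Cause composition.** Fixed age-shape profiles allocate each band's
  rate across the 20 groups: circulatory and dementia weights rise with
  age, site-specific cancers are humped in late-middle age, alcohol and
  cirrhosis concentrate in working ages, sex-specific cancers are zeroed
  for the other sex, and a congenital-type component of the other-NCD
  residual concentrates in infancy so the $[0,1)$ band and residual
  groups are exercised. Weights are non-negative and sum to one within
  each band.
* **Trends.** Each cause group carries a log-linear annual trend that
  differs between 2001–10 and 2010–19, with country effects
  (SD 0.008/yr). The default means encode the slowdown structure the
  analysis is designed to detect: circulatory causes decline faster in
  the first period than the second, dementia and pancreatic and liver
  cancer drift upward, lung cancer declines faster in the second period.
  Under these defaults nearly every simulated country declines over
  2010–19 and registers a decadal deterioration; the spread of national
  trajectories in real data is wider than the default country-effect SD
  produces, which is a deliberate simplification, not a claim about the
  world.
* **Exposure and counts.** Person-years come from a lognormally sized
  population (mean 20 million) spread over an exponentially declining
  pyramid (2% per year of age); when counts are requested, deaths are
  Poisson. With rates-only output the surface is exact and endpoint
  changes are deterministic.

Two constructed scenarios plant recoverable truths. The improvement
scenario solves, per country, for uniform rate-scale factors at the
period endpoints such that $(\Delta_1, \Delta_2)$ lands in a prescribed
category with at least 0.5 pp of boundary clearance (the exact-tie
`unchanged_pace` category is planted as bitwise-identical year blocks,
i.e. exactly zero change in both periods, since a nonlinear solve cannot
hit an exact tie). The benchmark scenario gives one country per region a
uniformly steeper second-period decline across all causes, so it must
emerge as the regional benchmark and every other country must lag it in
every cause column of the gap decomposition.

What the generator does **not** emulate: real cause-of-death coding
practices and their errors, non-log-linear trends, migration and cohort
effects, within-band age-structure shifts, correlated cause trends, and
the estimation uncertainty of upstream modelled mortality (its Poisson
noise is pure count sampling). Passing the pipeline's tests therefore
demonstrates correctness of the computations under the stated model, not
robustness to the full messiness of observed registration data.

# Problem sizes and numerics

The default simulated world is 24 countries (8 regions of 3) over
2001–2019 — about 310,000 surface cells — which the full pipeline
processes in seconds. The test suite uses 1000 random surfaces for the
lifetable oracle (agreement required at $10^{-12}$ relative), 50 seeded
replications for benchmark recovery and for decadal sign recovery
(margins of at least 0.2 pp must match the planted slope-change sign in
at least 95% of cells), and 500 replications at 200 draws for interval
calibration. Root-finding in the improvement scenario uses `uniroot()`
at tolerance $10^{-14}$ on the log scale. Degenerate inputs fail loudly:
missing surface cells, unmapped cause codes, negative counts,
misaligned age ranges, empty cause sets and rate/count inconsistencies
are all hard errors rather than silent repairs.

# Known limitations

* The measure ignores mortality above 80 and morbidity entirely.
* The abridged conversion assumes deaths within a band are described by
  a single separation factor; with 5-year bands and the midpoint default
  the error is second-order in $nm$ but not zero.
* Decadal and benchmark decompositions inherit the residuals of their
  two constituent decompositions; both residuals are reported.
* Poisson resampling understates uncertainty wherever the input rates
  are themselves modelled estimates rather than complete registration
  counts; supplying upstream draws through the draw-set interface is the
  remedy.
* The seven-category classification reads exact ties literally; with
  full-precision inputs ties essentially never occur, but classifying
  externally rounded deltas can produce `unchanged_pace` labels that
  full-precision data would not.
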