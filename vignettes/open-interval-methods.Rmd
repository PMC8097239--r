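---
title: "Methods: modelling the open birth interval distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the open birth interval distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The quantity being modelled

The *open birth interval* is the time elapsed since a woman's most recent
live birth, observed at a survey interview. Unlike closed intervals (between
two successive births) it is defined for every mother at every interview,
is cheap to collect (a single question), and responds quickly to fertility
change: any fall in births must, on average, thin out the short intervals
first. Tabulated across married women of reproductive age, the distribution
of women by open-interval year follows a strikingly regular descending
curve, and the package's central model summarises that curve with two
parameters:

$$y = a \, x^{-b}, \qquad x = 1, \dots, 20,$$

where $x$ is the interval year, $y$ the share of women in that year, $a$
the starting level of the curve, and $b$ the magnitude of its downward
slope. Because the shares must total 100%, a curve that starts high must
also fall steeply, so $a$ and $b$ are strongly coupled across populations.

## Tabulation rules

`tabulate_distribution()` implements the inclusion rules exactly:

* eligible women are currently married, aged 15–49, and either currently
  pregnant or mothers of at least one child born within the last 20 years;
* currently pregnant women are assigned to interval year 1 regardless of
  parity or of the date of their last birth — they are about to restart the
  clock and resemble the first-year group;
* interval year $k$ covers months $[12(k-1), 12k)$ since the last birth;
  months $\ge 240$ fall beyond the 20th year and are excluded, with
  percentages renormalised over years 1–20 (the exclusion count is
  reported). Non-pregnant nulliparous women have no open interval and are
  excluded from the denominator, but the simulator emits them so that
  either denominator convention can be formed.

All date arithmetic uses century-month codes (CMC, months since January
1900), the DHS convention, so intervals are exact integers.

## Curve fitting and model comparison

`fit_power()` estimates $(a, b)$ by ordinary least squares on
$(\ln x, \ln y)$ — the spreadsheet-trendline convention, chosen for
transparency and reproducibility over weighted or likelihood-based
alternatives, which would require the microdata counts that published
tables do not carry. Zero bins cannot enter a log fit; they are dropped and
counted in a diagnostics field. Three comparators (exponential
$y = a e^{cx}$, logarithmic $y = c + d\ln x$, quadratic polynomial) are fit
the same way, and `compare_models()` ranks all four by $R^2$ computed as
$1 - SS_{res}/SS_{tot}$ *on the original proportion scale* for every
family, so that families fitted in different spaces remain comparable; the
in-space $R^2$ is reported alongside. The quadratic is the minimal
nonlinear polynomial; ties in $R^2$ go to the family with fewer parameters.

The level parameter is reported in proportion units
($a_{\%} = 100\,a$); the slope is scale-invariant. Fits require at least
three (polynomial: four) positive bins.

## The country panel and its cleaning rules

The packaged 75-survey panel carries $(a, b, \mathrm{TFR}, \mathrm{GFR},
R^2)$ for the latest survey per country. Slopes are printed in accounting
convention (parentheses = negative) and are negated on load. Three rows —
Benin 2017-18, Guinea 2018, Haiti 2016-17 — print a slope magnitude below
0.2 next to a level above 0.4, which contradicts the level–slope coupling
visible in all 72 other rows; these are treated as decimal-shift misprints,
multiplied by 10 before negation, and flagged (`b_corrected`). The
correction can be disabled (`b_correction = FALSE`). With it, the
level–slope correlation over the panel is $r = -0.979$; without it,
$-0.793$.

Recomputed from the panel, the slope–fertility correlations exceed 0.91 in
magnitude ($b$–TFR $-0.925$, $b$–GFR $-0.915$) but the level–fertility
correlations are 0.886 (TFR) and 0.871 (GFR). The panel's $R^2$ column is
carried as metadata only: it cannot be re-derived without the underlying
microdata.

A note on conventions: sources in this literature often print signed
quantities labelled "R²". `pearson()` therefore returns both the signed
product-moment $r$ and $r^2$, and the association tables carry both.

## The microsimulator

`simulate_survey()` generates survey-style microdata from a monthly-step
model of one woman at a time:

* **Age at interview** is drawn uniformly over 15–49 — the cross-section of
  a stationary population with constant annual cohorts. Each history is
  then simulated forward from exact age 15 under time-invariant rates, so
  the sample approximates the stable state in which the open-interval curve
  is well defined. Under time-invariant rates the census date is arbitrary:
  translating it leaves the tabulated distribution unchanged, which the
  test suite checks exactly.
* **Exposure** begins at marriage (age drawn from a discretised normal over
  15–35) and is scaled by an optional spousal-absence factor.
* **Conception** is Bernoulli per exposed month at probability
  `monthly_fecundability` (default 0.20; natural-fertility populations are
  typically 0.15–0.25), reduced proportionally by
  `contraceptive_effectiveness` once a contracepting woman (probability
  `contraceptive_prevalence`) has reached her desired parity (drawn from a
  truncated Poisson over 0–12). Imperfect effectiveness produces unplanned
  births; this is what generates the long right tail of the distribution.
* **Gestation** lasts 9 months; a birth is followed by
  `postpartum_infecundable_months` of lactational infecundability
  (5–20 months across observed regimes).
* **Sterility** onset is a per-month hazard, piecewise constant over
  5-year age groups and rising steeply after 35. The default hazards give
  roughly 10% of women permanently sterile by 25, 40% by 40, and 85% by 49;
  they deliberately sit above purely clinical sterility estimates because
  they also proxy the age-decline of fecundability, which the model does
  not represent separately.
* **Determinism**: each woman's random stream is derived from the master
  seed by counter, so the same seed is byte-reproducible and enlarging the
  cohort extends rather than reshuffles it.

Two qualitative presets bracket the observed range — a high-fertility
regime (early marriage, desired parity ~8.5, 20 months postpartum
infecundability, 8% contraceptive prevalence; simulated TFR ≈ 7.8) and a
transitional regime (marriage ~23, desired parity ~1.9, 94% prevalence;
TFR ≈ 2.7). `fertility_regime_grid()` interpolates between a still-lower
regime (TFR ≈ 1.5) and the high regime. Fertility responds concavely to
the interpolated parameters — postpartum infecundability and sterility cap
the high end — so the interpolation coordinate is warped through fixed
knots chosen to space regimes approximately evenly in expected TFR;
without the warp the top regimes are indistinguishable in TFR and rank
statistics over the panel become unstable.

**What the simulator does and does not emulate.** It reproduces the
features the analysis depends on: the descending interval curve, the rise
of mean age with interval length, the dominance of low parities in long
intervals under transitional fertility, the coupling of the fitted level
and slope, and the negative fertility–interval relation. It omits female
and spousal mortality (a monthly exposure factor stands in for absence),
union dissolution, abortion, multiple births, heterogeneous fecundability,
and all period/cohort change within a woman's lifetime (fertility decline
is emulated by comparing separately simulated regimes, a cohort-free
approximation). Passing property tests on simulated data therefore
demonstrates internal consistency of the method under stated assumptions,
not agreement with any particular country's survey.

**Fertility measures.** `compute_tfr()`/`compute_gfr()` use the
conventional DHS-style design: births and woman-months of exposure in the
36 months before interview, age-specific rates over 5-year groups 15–49
(GFR denominator 15–44), computed over all women rather than only the
married, since TFR and GFR are population rates. Under time-invariant
rates the period TFR equals completed cohort fertility; the tests verify
the two agree within 5% using an independent event-count oracle (women
simulated straight to age 49).

## Renewal theory

In a stationary renewal process with closed-interval survivor function
$S$ and mean $\mu$, the open interval is the backward recurrence time with
density $f_B(t) = S(t)/\mu$; in particular $f_B(0) = 1/\mu$ and
$E[B] = E[X^2]/(2\mu)$. `backward_recurrence_from_closed()` applies this
identity on a uniform monthly grid (configurable step, capped at 360
months, matching CMC resolution); `closed_from_open()` inverts it
($\hat\mu = 1/f_B(0)$, $\hat S = \hat\mu f_B$, density by central
differences), refusing inputs whose density rises with duration, which
contradicts stationarity. Integration uses the trapezoid rule throughout,
for which the grid-point density convention is second-order accurate;
distributions with jumps (a degenerate interval) are supplied through the
survivor-function constructor, and a finer grid step recovers the closed
form to within 1%.

The event-driven check (`validate_against_simulation()`) simulates an
actual renewal sequence, places inspection times uniformly after a burn-in
of 200 events, and compares the sampled backward times with $S(t)/\mu$ by
Kolmogorov–Smirnov distance — an independent route to the same quantity,
since the simulator never evaluates the identity. Real populations are not
stationary, which is why casting an observed open-interval distribution to
a duration density requires an explicit `assume_stationary = TRUE`.

## Numerical and design choices

* Interval year from months: $\lfloor m/12 \rfloor + 1$; month 239 is the
  last included, month 240 the first excluded.
* The printed 6+ parity column is coded as parity 6 when reconstructing
  means from published rows; rows with no 6+ mass reconstruct exactly, rows
  with 6+ mass are necessarily underestimated.
* Composition shares in empty interval bins are flagged `NA`, never 0/0.
* Survey mid-year from labels: "2017-18" parses to 2017.5.
* Trend slopes use all of a country's surveys in one OLS fit; two-point
  first-vs-last differencing is available as a sensitivity variant.
* No survey weights in this version; the schema reserves the column.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to keep Monte
Carlo noise well below the tolerances they assert: cohorts of 1,500–20,000
simulated women, 12 regimes of 2,000 women for the cross-regime panel, 200
replicates of 10,000 multinomial draws for slope recovery, and 50,000
inspection times for the renewal identity (KS noise ≈ 0.006 against a 0.02
bound).

## Known limitations

* The power fit is unweighted least squares in log space; sparse tail bins
  get disproportionate influence, which matters below ~2,000 eligible
  women.
* The level–fertility correlations recomputed from the packaged panel
  (0.87–0.89) sit below the slope–fertility ones (0.92+); analyses relying
  on a single fitted parameter should prefer the slope.
* The simulator's stationarity makes it unsuitable for studying period
  shocks (war, policy shifts) except by comparing separately simulated
  regimes.
* Renewal inversion amplifies noise at $t = 0$: $\hat\mu$ depends entirely
  on the estimated density at zero, so smoothed or binned open-interval
  data need careful boundary treatment before inversion.
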