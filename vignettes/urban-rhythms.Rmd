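---
title: "Inferring urban circadian rhythms from calling activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring urban circadian rhythms from calling activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanrhythm)
library(data.table)
```

## The model

A city's aggregate calling activity is treated as a daily point process.
For city $c$ and day $d$, $P_{all}(t,d)$ is the probability of an outgoing
call at time-of-day $t$. Empirically this distribution is bimodal — a
morning period peaking near noon, an evening period peaking near 20:00 —
separated by an afternoon trough near 16:00 and a near-null overnight
region around 04:00. The overnight minimum motivates the *activity day*:
analysis days run 04:00 → 03:59, encoded here as *extended hours* in
$[4, 28)$ so that no window of interest ever wraps.

The phase of the rhythm is carried by two order statistics per user-day:
the first call in the morning window $[5, 16)$ and the last call in the
night window $[17, 28)$ (both 11 h long), giving distributions $P_F$ and
$P_L$ whose means $t_F$ and $t_L$ mark the onset and termination of urban
activity. Three comparisons are built on top:

1. **Longitudinal synchronization.** Within a latitudinal band, the delay
   of city $c$ behind a reference is estimated as the shift $n\Delta$
   ($-5 \le n \le 8$, $\Delta = 5$ min) minimizing
   $D_{KL}\!\left(P_{ref} \,\|\, P_c(t + n\Delta)\right)$, averaged per
   weekday across the year. Sun-entrained cities should exhibit delays of
   $4$ min per degree of longitude (Earth's rotation rate), which is what
   the synthetic-recovery tests assert.
2. **Seasonal entrainment.** The band-averaged curves $\bar t_L(d)$,
   $\bar t_F(d)$ (cities first collapsed by their transit delays) are
   compared against the clock-time solar-midnight curve of the band's
   reference location, including its DST discontinuities and its interior
   extrema.
3. **Cohort rest period.** Per age-bin, gender and weekday:
   $T_{LCA} = (t_F + 24) - t_L$ (last call of night $w$ to first call of
   the following morning) and the mid-sleep proxy
   $t_{mid} = (t_L + t_F - 24)/2$, with $t_L > 24$ encoding calls past
   civil midnight so the formula needs no case-splitting.

## Key parameters

| Parameter | Default | Why |
|---|---|---|
| activity-day boundary | 04:00 | overnight activity minimum |
| morning / night windows | $[5,16)$, $[17,28)$ | 11 h each; exclude the boundary hours 04–05 and 16–17 |
| histogram bin width | 5 min | equals the grid step $\Delta$, so candidate shifts are whole-bin moves |
| shift grid | $n \in [-5, 8]$, $\Delta = 5$ min | spans $-25$…$+40$ min, covering transit delays inside a ~11°-wide band |
| KL smoothing | pseudocount $\alpha = 0.5$/bin | empty bins would make $D_{KL}$ infinite; applied identically to both arguments |
| rise/set zenith | 90.833° | civil standard (refraction + solar radius) |
| DST calendar | days 84–301, +1 h, base UTC+1 | EU rules for 2007; fully configurable since real CDR geographies are masked |
| residence rule | < 15, < 15, < 30 km, strict | MAC-tower/centre, postal/centre, MAC-tower/postal conjunction |
| city population cut | > 100,000, strict | study-population definition |
| age bins | 2-year bins over 18–80 | resolution vs cohort size trade-off; the shell pipeline's default config coarsens to 10-year bins to suit its smaller synthetic populations |

Numerical conventions worth stating: KL divergence is evaluated in the
direction $D_{KL}(\text{reference} \,\|\, \text{shifted candidate})$; grid
ties break toward the smallest $|n|$, then negative $n$ (determinism);
mass shifted past a window edge is dropped and the remainder renormalized
(windows are wide relative to ≤ 40-min shifts, and a circular shift would
be wrong — the night window is not periodic); weekday spreads use the
population (n-denominator) standard deviation; $t_F$/$t_L$ are arithmetic
means of raw event times in extended-hour coordinates (no circular mean is
needed because the windows never wrap), while `mean_time()` on a binned
distribution is kept for bin-level checks; empty distributions and
sub-threshold cohorts are flagged/suppressed, not silently zeroed.

## The solar module

Declination and the equation of time come from the Spencer Fourier series
(NOAA-style, ±0.5 min class accuracy) — minutes matter here, seconds do
not. Transit is $12 - \mathrm{EoT}/60 - \lambda/15$ plus the zone and DST
offsets; rise/set invert the hour-angle formula
$\cos H = (\cos z - \sin\varphi \sin\delta)/(\cos\varphi \cos\delta)$ at
$z = 90.833^\circ$. Solar midnight is defined as the sunset → next-sunrise
midpoint, computed in standard time with the day's DST offset applied
afterwards, so the curve is smooth within each DST regime; the identity
solar midnight $=$ transit $+ 12$ h (within a minute) is kept as a test
property rather than as the definition. Masked geographies are handled by
resolving *relative* longitudes against a configurable reference meridian;
solar quantities depend only on the resolved meridian, which a test
asserts. The test suite cross-checks the whole ephemeris against an
independent implementation of the NOAA solar-position spreadsheet
(Meeus-based Julian-century polynomials) to within ±2 min across 2007 at
the study latitudes 37–43°N.

For 2007 EU clock rules the solar-midnight curve has interior minima near
days 133–135 and 305–307 and an interior maximum near day 209 (equation-of-
time extrema, cut by the DST changeovers at days 84/301). These are the
turning points the band-averaged $\bar t_L$ curve is compared against.

## The synthetic generator

Real CDR datasets are NDA-protected, so all tests run on generated data
with known truth. Each (city, day, cohort) block draws an inhomogeneous
Poisson process by thinning from

$$\lambda(t) = k\left[\,w_m\,\phi_{[4,28)}(t; 12 + \varphi, 1.3) +
  w_e\,\phi_{[4,28)}(t; 20 + \varphi, 1.5) + f\,\right]$$

with truncated-Gaussian bumps (an activity day is an interval, not a
circle, so von Mises shapes are not used), a floor $f$ at 1% of the peak
rate (the "near-null" overnight region), and $k$ scaled so each user
makes 3 calls/day in expectation. The common phase
$\varphi = \varphi_{lon} + a\,\mathrm{smdev}(d) + \varphi_{wd} + \varphi_{coh}$
combines the city's transit delay (4 min/deg, the quantity the alignment
stage must recover), a seasonal term coupling to the solar-midnight
deviation from its annual mean (default amplitude $a = 0.3$, which keeps
the annual $\bar t_L$ swing under one hour while the sunset swing is
~3 h), weekday offsets (Fri +30, Sat +45 min), and cohort offsets
(defaults: a 30-min young-vs-old gap and a 12-min female-vs-male gap).

Bump widths are 1.3 h (morning) and 1.5 h (evening). The widths control
how sharp the first/last-call distributions are; substantially wider bumps
yield flat, nearly featureless order-statistic distributions whose KL
profile has no usable minimum — unlike real calling data, whose first- and
last-call distributions are sharp with well-defined maxima. The chosen
widths reproduce that sharpness and place the afternoon trough of
$P_{all}$ between 15:00 and 17:00.

What the generator deliberately does **not** emulate: social-network
structure between callers (callee ids are uniform), burstiness and
heavy-tailed inter-event times, holidays and festivities, within-cohort
chronotype heterogeneity, and population differences between cities.
Passing recovery tests therefore demonstrate that the *pipeline* measures
injected phases correctly under realistic sampling noise — not that real
cities behave like the generator.

One reproducibility note: RNG substreams are derived per
(city, day, cohort) block rather than per user, so generation can be
vectorized across users; the contract that matters — the same seed yields
a byte-identical dataset — is tested directly.

## Known systematics

Order statistics over fixed windows compress injected phase differences
slightly: shifting an intensity by $\varphi$ shifts the *distribution of
the last call* by a little less than $\varphi$, because window edges and
the unshifted uniform floor do not move. At the default settings the
compression is below 10% (≈ 2–3 min on a 30-min offset), visible in the
recovery tests' tolerances (one 5-min grid step for alignment, 5 min for
cohort offsets). The same effect exists in any windowed analysis of real
CDRs.

## Problem sizes

The shipped tests use a 5-city band × 1,000 users × 8 weeks for shift
recovery, 2 × 2,000 users × 52 weeks of one weekday (plus the following
mornings) for cohort recovery, and 2 cities × 600 users on Mon–Thu days
for the seasonal-coupling check; the full suite runs in about half a
minute on one CPU. Larger populations tighten the stochastic recoveries
as $1/\sqrt{n}$; the defaults already put sampling error well below the
5-min grid resolution.

## Limitations

- Calling activity is a proxy: $t_{mid}$ is the midpoint of *calling*
  inactivity and its interpretation as mid-sleep is exactly that, an
  interpretation.
- The ephemeris is minute-accurate, not second-accurate, and has no polar
  handling (|lat| < 60°).
- Only outgoing calls are used; texts, data sessions and incoming calls
  are out of scope.
- The KL estimator is discrete: resolution is one grid step, and delays
  outside $[-25, 40]$ min saturate the grid.
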