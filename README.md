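# urbanrhythm

Population-level circadian rhythms of cities, inferred from mobile-phone
call detail records (CDRs).

People in a city start and stop calling on a strikingly regular daily
schedule. `urbanrhythm` turns a year of raw call records into the phase of
that schedule and compares it against astronomical cues: does a city's
calling activity follow the clock on the wall, or the sun? The package is
aimed at computational social scientists and chronobiologists working with
operator CDR dumps (which are typically NDA-protected), so it ships a
synthetic CDR generator with known ground truth that stands in for real
data in every test.

## What it computes

For each city and each *activity day* (04:00 → 03:59 next calendar day,
cut at the overnight activity minimum):

- **Daily calling distributions.** P_all(t, d), the probability of an
  outgoing call at time-of-day *t*; P_F(t, d) from each user's *first*
  call in the 11-h morning window [05:00, 16:00); P_L(t, d) from each
  user's *last* call in the 11-h night window [17:00, 04:00).
- **KL shift alignment.** The delay of city *c* behind a reference city is
  the shift n·Δ (−5 ≤ n ≤ 8, Δ = 5 min) minimizing the Kullback–Leibler
  divergence D_KL(P_ref ‖ P_c(t + nΔ)) = Σᵢ Pᵢ log(Pᵢ/Qᵢ), averaged per
  weekday over the year. For sun-entrained cities this delay equals the
  sun-transit delay, 4 min per degree of longitude.
- **Solar cues.** A built-in low-precision ephemeris (Spencer series for
  declination and the equation of time; zenith 90.833° for rise/set) gives
  sun transit, sunrise/sunset and solar midnight in zone clock time,
  including DST handling, so the annual drift of calling phases can be
  compared with the solar-midnight curve.
- **Cohort rest metrics.** Per age-bin × gender × weekday: mean last-call
  time t_L, next-morning mean first-call time t_F, the low-calling-activity
  period T_LCA = (t_F + 24) − t_L, and the mid-sleep proxy
  t_mid = (t_L + t_F − 24)/2.

## Worked example

Generate a synthetic latitudinal band (five cities at relative longitudes
−7.8°, −4.7°, −3.7°, 0°, +3°, i.e. injected transit delays +31.2, +18.8,
+14.8, 0, −12 min), run the pipeline, and recover the delays from the
last-call distributions:

```r
library(urbanrhythm)
library(data.table)

cfg <- generator_config(seed = 42, users_per_city = 1000)
ds  <- generate_dataset(cfg, days = 1:56)          # eight weeks

ad  <- assign_activity_day(ds$records$start)
hom <- filter_study_population(ds$subscribers, ds$cities)
calls <- data.table(caller_id = ds$records$caller_id, day = ad$day,
                    extended_hour = ad$extended_hour,
                    city = hom$city[match(ds$records$caller_id, hom$id)])

rep <- band_alignment_report(calls, ds$cities, "ref")
rep[which == "last", .(mean_shift_min = round(mean(mean_shift_min), 1)),
    by = .(city, expected_transit_delay_min)][
    order(-expected_transit_delay_min)]
#>      city expected_transit_delay_min mean_shift_min
#> 1:  west1                       31.2           30.7
#> 2:  west2                       18.8           17.5
#> 3:  west3                       14.8           13.6
#> 4:    ref                        0.0            0.0
#> 5:  east1                      -12.0          -11.6
```

Every recovered shift sits within one 5-min grid step of the injected
sun-transit delay: the westernmost city's calling activity lags the
reference by about half an hour, exactly as the sun does. The ephemeris
side is a one-liner:

```r
solar_ephemeris(42, 0, days = c(21, 172))
#>   day declination_deg eot_min sunrise_h transit_h sunset_h solar_midnight_h
#> 1  21          -20.09  -10.60      7.37     12.18    16.98            24.17
#> 2 172           23.45   -1.33      5.40     13.02    20.64            25.02
```

(January 21 vs the June solstice at 42°N: the ~3.7-h sunset difference and
the ~50-min annual swing of clock-time solar midnight, before DST.)

A five-command shell pipeline (`generate`, `distributions`, `align`,
`solar`, `cohorts`) is available via `run_pipeline()` or the thin wrapper
in `inst/cli/urbanrhythm.R`; see the vignette in `vignettes/`.

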