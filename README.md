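# diurnalmusic

Music listening shifts with the clock: at population scale, the audio
content people stream divides the day into recurring blocks — morning,
afternoon, evening, night and late night/early morning — that follow the
same cyclic order every day and stretch or shift at the weekend.
`diurnalmusic` is an R package for chronobiologists and computational
social scientists who want to detect and quantify that structure from
streaming-event logs, and to relate it to human activity patterns,
playlist-level classification and single-track preference.

The pipeline, in the field's standard notation:

* **Hour-of-week aggregation.** Events are filtered (listened to most of
  the track, ≤ 1 seek operation, intact date/hour), indexed by
  `h = 24·weekday + hour + 1` ∈ 1..168 (hour 1 = Monday 00:00), and each
  audio feature's event-weighted mean and s.d. are computed per hour.
* **Subdivision discovery.** Hourly means are standardized,
  `z = (x − u)/s`, and k-means is scanned over k = 2..24; k is selected by
  an automated elbow rule (maximum perpendicular distance to the chord of
  the min-max-scaled inertia curve). The fitted model reports modal onset
  hours with circular s.d., a cyclic-order consistency check, and centroid
  profiles relative to the weekly grand mean.
* **Diversity analysis.** Hourly feature s.d.s are z-normalized and
  collapsed to a 24-hour variability series; time-use diaries are rounded
  to hours, forward-filled and stripped of sleep/missing codes, and each
  hour's activity-diversity index is the median of the 49 descending
  differences among its top-50 activity proportions (range [−1, 0], 0 =
  most diverse). The two series are compared by Pearson correlation
  (df = 22).
* **Classification.** A feed-forward network (6 remapped features → 64,
  128, 64, 32 sigmoid units → 5-way softmax; Adam, class weights
  `N/(K·n_c)`, dropout 0.30, proximal L1 0.01, early stopping on
  validation accuracy) classifies tracks; playlists get the argmax of the
  mean track probabilities. Agreement uses the circular error
  `min(|res − pred|, 5 − |res − pred|)` ∈ {0, 1, 2}.
* **Preference statistics.** Per participant and subdivision, the mean
  rating of the subdivision's own tracks at its rating slot minus the mean
  rating of the other subdivisions' tracks at that slot; one-sample
  t-tests against zero with Bonferroni correction (×5, capped at 1) and
  95% confidence intervals.

Every input can be simulated by the package's synthetic module (track
catalogs, event logs, activity diaries, ratings) with ground-truth labels,
so each stage is testable by parameter recovery.

## Worked example

Simulate a week of listening under the five-regime schedule, recover the
subdivisions, and compute preference statistics from a synthetic survey:

```r
library(diurnalmusic)

profiles <- regime_profiles("diurnal5")
schedule <- weekly_schedule("diurnal5")
catalog  <- generate_track_catalog(5000, profiles, seed = 1)
events   <- generate_streaming_events(catalog, schedule, 2e5,
                                      invalid_frac = 0.1, seed = 2)
hourly   <- aggregate_hourly(filter_events(events), catalog)
z        <- zscore_hourly(hourly)
curve    <- kmeans_scan(z$scaled, k_range = 2:24, seed = 3)
(k <- select_k_elbow(curve))
#> [1] 5
model <- fit_subdivisions(z$scaled, z$scaler, k, seed = 4)
tidy(model)
#> # A tibble: 5 × 7
#>   subdivision cluster n_hours n_occurrences mode_onset onset_sd mode_offset
#>   <chr>         <int>   <int>         <int>      <dbl>    <dbl>       <dbl>
#> 1 morning           1      42             7          6    0              11
#> 2 afternoon         2      56             7         12    0              19
#> 3 evening           3      30             7         20    0              22
#> 4 night             4      28             7         23    2.07            3
#> 5 late_night        5      12             7          4    0.452          5
```

The elbow rule recovers the planted k = 5; mode onsets land exactly on the
planted 06/12/20/23/04 pattern, the weekend-shifted night onsets produce
the large circular spread (s.d. 2.07 h), and `glance(model)` confirms the
subdivisions occur in the same cyclic order all week
(`cyclic_order_ok = TRUE`). `autoplot(model)` draws the relative centroid
heat map; `plot_weekly_features(z$scaled, model = model)` shows the
trajectories behind it.

A synthetic preference survey with planted effects (176 participants,
rating noise s.d. 20):

```r
effects <- c(morning = 4.34, afternoon = -4.38, evening = 0.34,
             night = -4.64, late_night = 10.92)
ratings <- generate_ratings(176, effects = effects, noise_sd = 20, seed = 5)
prefs   <- ttest_vs_zero(preference_differences(exclude_participants(ratings)))
tidy(prefs)
#> # A tibble: 5 × 9
#>   subdivision   mean    sd     n      t    df        p conf_low conf_high
#> 1 morning      5.07   13.5   176  4.98    175 7.70e- 6     3.06      7.08
#> 2 afternoon   -4.64   13.5   176 -4.57    175 4.68e- 5    -6.65     -2.64
#> 3 evening     -0.432  12.4   176 -0.462   175 1   e+ 0    -2.28      1.41
#> 4 night       -4.63   12.9   176 -4.77    175 1.95e- 5    -6.54     -2.71
#> 5 late_night  10.9    12.5   176 11.5     175 1.52e-22     9.01     12.7
```

Each planted effect falls inside its 95% confidence interval; `p` is the
Bonferroni-corrected two-sided p-value (capped at 1, as for the null
evening effect). `autoplot(prefs)` draws the interval plot.

`run_pipeline(pipeline_config(seed = 1), dir = "out")` executes all stages
end to end and writes CSV/JSON artifacts plus a manifest of seeds and file
hashes; rerunning the same configuration reproduces the hashes exactly.

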