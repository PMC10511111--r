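# freerun

Free-running circadian period analysis of insect locomotor activity.

Chronobiology labs measure how fast an animal's internal clock runs by
entraining it to a light–dark (LD) cycle, releasing it into constant darkness
(DD), and extracting the *free-running period* τ of its locomotor activity.
Treatment groups (e.g. RNAi knockdowns of a candidate clock gene) are then
compared against controls — but only animals with a single, stable,
statistically significant rhythm should contribute a τ. `freerun` implements
that entire workflow for the two common recording modalities:

* **beam-break monitors** — tab-delimited files of per-channel counts per time
  bin (the standard DAM/LAM dialect), and
* **timed arena images** — grayscale frames of animals in Petri dishes taken
  every few minutes, converted to activity events by the classic "body shift
  greater than 1 cm between consecutive frames" scoring rule after automated
  tracking against an ROI label mask.

## The analysis in brief

The DD portion of each record is scanned with the classical **normalized
Lomb–Scargle periodogram**

P_N(ω) = 1/(2σ̂²) · [ (Σ (xᵢ−x̄) cos ω(tᵢ−θ))² / Σ cos²ω(tᵢ−θ)
                    + (Σ (xᵢ−x̄) sin ω(tᵢ−θ))² / Σ sin²ω(tᵢ−θ) ],

whose single-frequency null distribution is Exponential(1), so a peak of
power z scanned over M independent frequencies has p-value 1 − (1 − e^(−z))^M.
Each animal is called

* **strong** — exactly one distinct significant non-harmonic peak, power
  PN ≥ 20, and a sliding-window period range ≤ 1 h (τ is reported, refined by
  parabolic interpolation),
* **complex** — more than one distinct component, or an unstable period,
* **arrhythmic** — no significant peak, or primary power below the PN floor.

Cohort statistics follow the field's conventions: mean ± SEM of τ over
strongly rhythmic animals, one-way ANOVA with **Dunnett's many-to-one post
hoc** (family-wise p from the equicorrelated multivariate-t, seeded
quasi-Monte-Carlo), and the unpaired two-tailed Student t-test for single
comparisons.

A first-class **synthetic-data generator** (Poisson activity with a
von-Mises-shaped daily profile; 2-D dish trajectories; rendered frame stacks
with ground truth) makes every stage verifiable end to end. See the methods
vignette (`vignettes/freerun-methods.Rmd`) for the model, parameter defaults
and design rationale.

## Worked example

Simulate one knockdown-like animal (intrinsic period 28.63 h, 5 days LD 18:6
then 10 days DD, 5-minute bins) and analyze it:

```r
library(freerun)
spec <- sim_spec(tau_hours = 28.63, entrain_days = 5, dd_days = 10,
                 light_hours = 18, dark_hours = 6, seed = 42)
rec  <- simulate_activity_record(spec)
analyze_record(rec)
#> # A tibble: 1 × 7
#>   animal_id classification tau_hours primary_power primary_p n_components stability_range_h
#>   <chr>     <chr>              <dbl>         <dbl>     <dbl>        <int>             <dbl>
#> 1 sim       strong              28.6          983.         0            1             0.400
```

The record is strongly rhythmic with τ̂ = 28.61 h (generative value 28.63),
a primary power far above both the significance threshold and the PN ≥ 20
floor, one rhythmic component, and a window-to-window period range of 0.4 h.
`autoplot(lomb_scargle(segment_dd(rec)))` draws the periodogram and
`autoplot(build_actogram(rec))` the double-plotted actogram.

A full cohort run — simulate, analyze, summarize, test — from one config:

```r
cfg <- list(
  mode = "synthetic", seed = 1,
  schedule = list(entrain_days = 5, light_hours = 18, dark_hours = 6, dd_days = 10),
  cohort = list(n_per_group = 10, groups = list(
    control   = list(tau_hours = 24),
    knockdown = list(tau_hours = 28.63)
  )),
  stats = list(control = "control", method = "dunnett")
)
run_pipeline(cfg, "run1")
report_run("run1")
#> # A tibble: 2 × 7
#>   group         n pct_strong pct_complex pct_arrhythmic mean_tau sem_tau
#>   <chr>     <int>      <dbl>       <dbl>          <dbl> <chr>    <chr>
#> 1 control      10        100           0              0 24.0101  0.0031
#> 2 knockdown    10        100           0              0 28.6281  0.0046
```

All 20 animals are strongly rhythmic; the knockdown group's mean τ is slowed
by 4.6 h, and `run1/stats.csv` holds the Dunnett comparison
(`knockdown vs control`, mean difference 4.62 h, adjusted p ≈ 0). Rerunning
with the same config and seed reproduces every output byte for byte.

For real monitor data, replace the simulation with
`read_monitor_file(path, channel_ids, schedule)`; for image data, use
`read_frames()` + `read_roi_mask()` + `track_positions()` +
`events_from_track()`, then `analyze_cohort()` and the statistics functions
on the resulting τ table.

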