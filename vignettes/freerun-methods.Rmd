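---
title: "Methods: free-running period estimation and rhythmicity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-running period estimation and rhythmicity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freerun)
```

# The problem

Insects entrained to a light–dark (LD) cycle and then released into constant
darkness (DD) express their endogenous circadian rhythm: locomotor activity
recurs with the animal's *free-running period* τ, typically near but not equal
to 24 h. Experiments that manipulate a candidate clock gene compare the τ of
treated animals against controls, but only animals whose rhythm is clean
enough to yield a trustworthy τ should enter that comparison. This package
implements the full chain from raw recordings to cohort statistics:

1. **Input** — beam-break monitor files (one count per channel per time bin)
   or timed grayscale images of animals in Petri dishes, converted to activity
   events by a displacement rule.
2. **Rhythm analysis** — normalized Lomb–Scargle periodogram on the DD
   portion, peak significance, τ estimation, period-stability analysis, and a
   three-way call: *strong* (one clear stable significant period), *complex*
   (multiple components or an unstable period), *arrhythmic* (no significant
   period, or power below the PN floor).
3. **Statistics** — per-group mean ± SEM of τ over strongly rhythmic animals,
   one-way ANOVA with Dunnett's many-to-one post hoc against the control, and
   the unpaired two-tailed Student t-test for single comparisons.
4. **Synthetic data** — a seeded generator of activity records, Petri-dish
   trajectories and rendered frame stacks with known ground truth, so every
   stage is testable without animals.

# The periodogram and its calibration

For samples $x_i$ at times $t_i$ (hours), the normalized Lomb–Scargle power at
angular frequency $\omega$ is

$$
P_N(\omega) = \frac{1}{2\hat\sigma^2}\left[
  \frac{\left(\sum_i (x_i-\bar x)\cos\omega(t_i-\theta)\right)^2}
       {\sum_i \cos^2\omega(t_i-\theta)} +
  \frac{\left(\sum_i (x_i-\bar x)\sin\omega(t_i-\theta)\right)^2}
       {\sum_i \sin^2\omega(t_i-\theta)}\right],
$$

with $\tan(2\omega\theta) = \sum_i \sin 2\omega t_i / \sum_i \cos 2\omega t_i$
and $\hat\sigma^2$ the sample variance. This is the classical normalization
under which a single frequency's power is exponentially distributed for white
noise, so the "PN" scale matches the convention of the standard actogram
software in this field, including its widely used floor of PN ≥ 20 for calling
an animal rhythmic. Unevenly sampled series are handled natively, which is why
missing bins are simply excluded rather than imputed.

**Scan grid.** Periods 16–35 h, wide enough to bracket every circadian τ
reported in insect knockdown work (about 19–29 h), on a frequency grid
oversampled 4× relative to the natural spacing $1/\mathrm{span}$. A 10-day DD
record gives a grid step of about 0.6–0.9 h near circadian periods; sub-grid
accuracy comes from interpolation (below).

**Significance.** The p-value of a peak of power $z$ scanned over $M$
independent frequencies is $1-(1-e^{-z})^M$, inverted to the threshold
$z_\alpha = -\ln(1-(1-\alpha)^{1/M})$ at $\alpha = 0.01$. The choice of $M$
matters. Counting only the natural Fourier spacings in the scan band
(`m_convention = "natural"`) calibrates the test *only* when the maximum is
taken at those natural frequencies; taking the maximum over the 4×-oversampled
grid against that threshold inflates the family-wise false-positive rate to
2–3.5% in simulation. The default therefore counts every scanned grid
frequency (`m_convention = "scanned"`, the conservative Horne–Baliunas-style
count used by standard periodogram software), which holds the empirical rate
of pure-noise records with any significant peak at or below the nominal 1%
(about 0.5–1% in the test suite's 2000-replicate calibrations).

**τ estimation.** The primary peak's period is refined by parabolic
interpolation of log-power through the peak grid point and its two
neighbours. On noiseless sinusoids this recovers the period to about a
quarter of one percent of the grid step; on the strong-phenotype simulations
below the median absolute error is well under 0.15 h. A peak sitting at the
grid boundary is returned uninterpolated with a warning.

# What counts as "one clear peak"

The published class definitions are qualitative, so the package fixes an
explicit rule. A significant local maximum other than the primary counts as a
*distinct component* only if:

* it is **non-harmonic**: its period differs from the primary's period,
  half-period and double period by more than 0.5 h (`harmonic_tol_h`), and
* its power is at least **10% of the primary's** (`min_rel_power`).

The second condition exists because a finite rectangular observation window
leaks power into sidelobes at about 5% of the main peak; once the primary
power is large (high-amplitude rhythms easily reach PN of several hundred)
those sidelobes cross any fixed significance threshold, and without the
relative-power guard essentially every strongly rhythmic animal would be
called complex. Ten percent sits comfortably above the first sidelobe (≈4.7%)
and far below a genuine second component of comparable amplitude; both
tolerances are exposed as arguments.

**Stability.** τ is re-estimated in sliding windows (5 d long, stepped 1 d;
only windows with a significant peak contribute), and the range max−min of the
window estimates is the stability diagnostic: a range above 1 h
(`stability_tol_h`) sends an otherwise clean record to *complex*. Stationary
noiseless signals never trip this rule, which is how the default was fixed.
The window scans use a finer grid (oversample 8) than the main scan because a
5-day window's natural grid step near circadian periods exceeds the tolerance
itself. Records too short for two windows are flagged `low_coverage` with a
range of 0.

**Classification.** *Arrhythmic* if the primary power is below the PN floor
(20) or its p-value is ≥ α; otherwise *strong* iff there is exactly one
distinct component and the stability range is within tolerance; otherwise
*complex*. The floor is applied uniformly to both input pathways (monitor
counts and image-derived events); whether the original analyses applied it to
both species is not documented, so it is a single configurable parameter.

# The synthetic-data generator

The generator defines the study conditions the tests and the acceptance
script run under; it is deliberately simple and fully documented rather than
biomechanically realistic.

**Activity records.** Counts per bin are Poisson with rate
$\lambda(t) = b + a\,e^{\kappa\cos\theta(t)}/I_0(\kappa)$: a von-Mises-shaped,
unimodal daily profile (actograms of real animals show one consolidated
activity bout; no published functional form exists, so unimodality with
adjustable sharpness κ is the minimal choice). The $I_0$ normalization makes
the circular mean of the modulation exactly 1, so the mean rate is $b+a$ for
every phenotype — a closed form the tests check the empirical mean against.
The phase is locked to the 24-h light cycle during entrainment (peak at
lights-off for nocturnal animals) and advances with period τ in DD,
continuously across the transition. Complex phenotypes either sum two
components (τ and τ₂ at least 1.5 h apart by default, each with amplitude
$a/2$) or let the instantaneous period drift at 0.3 h/day; arrhythmic records
use the constant phase-averaged rate. Defaults for the monitor-style cohorts
(5 d LD 18:6 + 10 d DD for the bug protocol, 4 d LD 16:8 + 10 d DD for the
cockroach protocol, 5-min bins, baseline 1 and amplitude 5 events/bin, κ = 2)
reflect the published protocols and give a signal-to-noise ratio at which
recovery is reliable but not trivial.

**Trajectories.** One position per 5-min frame inside a 9-cm dish. Each step
is "active" with probability $\min(1, \lambda(t))$, with the same rate model
read on a per-frame probability scale (baseline 0.05, amplitude 0.6, κ = 2 by
default: near-certain activity at the nocturnal peak, rare movement at the
trough). Active steps have exponential length with mean 2.5 cm, resting steps
mean 0.2 cm — fixture parameters chosen so the 1-cm scoring threshold cleanly
separates the regimes ($P(\text{step}>1\,\mathrm{cm})$ is 0.67 active vs
0.0067 resting), not claims about real cockroach locomotion. Steps reflect at
the dish wall. Events are scored exactly as in the assay: displacement
**strictly greater than** 1 cm between consecutive located positions; pairs
with an unlocated endpoint become missing bins, never zeros.

**Frames.** Rendered stacks place a dark disc per dish on a bright background
with Gaussian pixel noise (0–255 scale); the matching label mask and
ground-truth positions are returned. The tracker (median background over a
≤200-frame subsample; threshold at max(4 robust SDs, absolute floor 10);
largest connected component, ties to the lower label; intensity-weighted
centroid) recovers positions to well under half a pixel and ≥95% of
ground-truth suprathreshold steps at noise SD 5.

**Seeding.** Every animal's seed derives from the master seed by a
counter-based scheme keyed on (stream name, index)
(`derive_animal_seed()`), so cohorts are bit-reproducible and stable under
insertion of animals, and pipeline stages consume independent streams.

# Statistics

Group summaries are mean ± SEM (SD with the $n-1$ denominator over
$\sqrt n$), computed over strongly rhythmic animals only — complex and
arrhythmic animals have no meaningful single τ. The two-sample comparison is
Student's pooled-variance t (the published degrees of freedom,
$n_1+n_2-2$, identify the pooled rather than Welch form), two-tailed. The
many-to-one comparison is Dunnett's test: $t_i$ statistics share the ANOVA
within-group mean square, and the family-wise adjusted p is the tail
probability of the maximum absolute component of an equicorrelated
multivariate t with correlations
$\rho_{ij} = \sqrt{n_i n_j}/\sqrt{(n_i+n_c)(n_j+n_c)}$, evaluated by seeded
quasi-Monte-Carlo integration (≥10⁵ integrand evaluations; the integration
error is reported alongside each p). The test suite checks this against an
independent implementation and verifies family-wise error calibration under a
null simulation.

# Numerical and degenerate-input choices

* Missing data are represented as absent bins throughout; a zero count is
  data. Image-derived records with more than 20% missing bins carry a QC flag.
* A constant series has no periodogram (zero variance) and is classified
  arrhythmic directly.
* Zero pooled variance in the t-test: equal means give t = 0, p = 1; unequal
  means are an error. A degenerate ANOVA (zero within-group variance) is
  flagged, with F = ∞ when means differ.
* DD day windows: the default `"label"` convention reads `c(1, 7)` as "DD
  days 1–7" = [0, 7) days after DD onset, matching how such windows are
  labelled on figures; `"offset"` reads `c(a, b)` as [a, b) days.
* Ties in peak detection resolve to the highest power; equal-size blobs in
  tracking resolve to the lower component label.

# Problem sizes used in validation

The shipped test suite and the acceptance script rerun the full pipeline at
the sizes a desk check of this design calls for: recovery cohorts of 30
monitor-style animals per period (10 d DD, 2880 five-minute bins each) and 25
trajectory animals; significance calibration on 2000 pure-noise records;
Dunnett null calibration on 1500 three-group replicates. These sizes give
Monte-Carlo standard errors comfortably below the decision tolerances while
keeping a complete run in tens of seconds.

# Limitations

* The generator's unimodal von-Mises profile omits features of real records:
  crepuscular (bimodal) activity, bout microstructure, transient after-effects
  of entrainment, inter-individual amplitude heterogeneity, and
  temperature effects. Passing recovery tests therefore demonstrate correctness
  of the analysis chain under the stated statistical model, not performance on
  every real-world waveform.
* One animal per dish is assumed; identity maintenance with multiple animals
  per ROI is out of scope, as are video-rate tracking and posture analysis.
* Alternative periodogram normalizations and other rhythm statistics
  (chi-square periodogram, autocorrelation, wavelets) are intentionally not
  provided; the analysis mirrors one widely used convention exactly.

# A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- list(
  mode = "synthetic", seed = 1,
  schedule = list(entrain_days = 5, light_hours = 18, dark_hours = 6, dd_days = 10),
  cohort = list(n_per_group = 10, groups = list(
    control = list(tau_hours = 24),
    knockdown = list(tau_hours = 28.63)
  )),
  stats = list(control = "control", method = "dunnett")
)
run_pipeline(cfg, "run1")
report_run("run1")
```
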