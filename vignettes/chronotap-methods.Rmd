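---
title: "Methods: rhythm and sleep-window analysis of tappigraphy and actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm and sleep-window analysis of tappigraphy and actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotap)
```

This vignette documents the models, conventions and numerical choices behind
the package, in the spirit of a methods section a maintainer can audit. It
states no empirical results beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Data model and time conventions

All internal times are numeric seconds since the Unix epoch. A per-subject
UTC offset converts to local clock time; every "hour of day" or "day of
week" in the package means *local* clock time, and hour bins are half-open
`[h, h + 1)` aligned to the local clock (an event exactly on a boundary
belongs to the later bin). Weekdays are indexed 0 = Monday … 6 = Sunday.

Three containers carry the data between stages: `event_stream` (timestamped
smartphone events from a closed six-kind vocabulary), `wearable_series`
(uniform epochs of acceleration or activity counts plus lux), and
`binned_series` (contiguous uniform bins of one parameter). Downstream
modules consume only these types; nothing re-reads raw files. Missing bins
are `NA` for the latency parameters — speed is undefined where nothing
happened — but 0 for counts, where absence of touches is itself signal.

## Tappigraphy parameters

An inter-touch interval is kept only if it is at most `max_gap_s` (default
30 s): longer gaps separate usage sessions and say nothing about tapping
speed. Tapping speed (TS) is the 25th percentile of the kept intervals per
bin, with the linear-interpolation (type-7) percentile definition fixed so
exact tests are possible; bins with fewer than `min_intervals = 5` intervals
are missing. Unlocking (US) and app-locating (ALS) episodes pair each
completion with the most recent opener, discard episodes with an intervening
`screen_off` or longer than `max_duration_s = 60` s, and aggregate per bin
by the median — chosen for robustness to the heavy right tail of
naturalistic latencies; the within-bin aggregator for these two parameters
is a package choice, not an external prescription. Every interval or
episode is assigned to the bin of its completing event, which makes the
assignment unambiguous.

## Spectral analysis

`lomb_scargle()` implements the classical normalized periodogram with the
time-offset τ, evaluated on a uniform frequency grid with spacing
`1/(oversampling × span)` (oversampling 4) covering periods from
`min_period_h = 3` h — twice the default bin width, below which hourly bins
carry no information — to half the record length. Missing bins are simply
excluded, which is the entire point of using an unevenly-sampled spectral
estimator on gappy behavioral data. With the sample-variance normalization
the power at any frequency of a white-noise series is approximately
Exp(1)-distributed with mean 1, which gives the zero-amplitude reference
used at the cohort level: per period, a one-sample t-test of subject powers
against 1, with Benjamini–Hochberg FDR at `q = 0.05` across the frequency
grid (applied across frequencies within one parameter; applying it across
parameters too would be a caller-side variant). The estimator is exactly
equivalent to a least-squares sinusoid fit on the mean-centred values at
each period — the test suite holds the two routes together at `1e-8`.

Band-limited peaks use a diurnal band of 16–32 h and an infradian band of
5–9 days; exact power ties resolve toward 24 h in the diurnal band (band
centre elsewhere). Peak periods are tested against 24 h at a family-wise
α of 0.0083 (six parameter families). A zero-variance peak sample is
guarded: all peaks at 24 h gives t = 0, p = 1; all peaks equal but away
from 24 h is reported as p = 0. The 90-min question is the same pipeline at
`bin_width = 900` s with a 1–3 h band.

## Cosinor and circular statistics

The fixed-period cosinor is the linear model `x = M + β cos ωt + γ sin ωt`
with amplitude `A = √(β² + γ²)` and acrophase `atan2(γ, β)/ω mod 24`; the
zero-amplitude test is the exact F-test of `β = γ = 0` on (2, n − 3)
degrees of freedom. Latency parameters are negated before fitting, so the
acrophase of every parameter uniformly means *time of best performance* —
one convention instead of a 12-hour ambiguity. Subjects whose individual
fit is not significant at α = 0.05 are excluded from acrophase samples, and
the excluded fraction is itself reported (it measures how often no 24-h
rhythm is detectable for a parameter).

Watson–Williams uses the textbook F with the `K = 1 + 3/(8κ̂)` correction,
κ̂ from the Fisher approximation to the von Mises ML estimate; a warning is
issued when the weighted mean resultant length falls below 0.45, where the
approximation degrades. Circular correlation is the
Jammalamadaka–SenGupta coefficient with its asymptotic normal p-value.
Both have brute-force transcriptions in the test suite as independent
oracles. The model-free peak is the argmax (argmin for latencies) of the
mean clock-hour profile; the peak-versus-off-peak comparison uses the raw
values of the 1-h clock bins containing the acrophase and bathyphase —
closer to the data than fitted values, and stated as such.

## Actigraphy and sleep windows

Acceleration converts to counts as `gain × Σ max(0, |a| − 1 g)` per epoch, a
stated approximation of proprietary device-side counting; series that
already carry counts pass through unchanged. Cole–Kripke scoring uses the
published one-minute-epoch weights (106, 54, 58, 76, 230, 74, 67) with
scale 0.001 and threshold 1 as defaults; all three are configuration because
calibration is device-dependent and no single parameterization is canonical
across actigraphs. Webster-style rescoring rules are deliberately not
applied. Consolidation drops sleep bouts under 20 min, merges bouts
separated by less than 60 min of wake, and keeps the longest merged bout per
noon-to-noon local day; these defaults yield one consolidated nocturnal
period per day on the synthetic data and are the package's own choice where
no consolidation rule is externally fixed.

The sleep-tethered windows are *pre-bed* `[onset − 1 h, onset)`, *bed*
`[onset, offset)` and *rise* `[offset, offset + 1 h)`. Latency episodes are
pooled over all nights per window; the per-subject summary is the median
(TS: the pooled-interval 25th percentile, the windowed analogue of the
per-bin TS construct, with a median variant available). A subject enters a
parameter's comparison only with at least `min_episodes = 3` in *every*
window (complete case). The comparison is a one-way repeated-measures
ANOVA over the three windows plus the three paired t-tests, computed from
balanced-design sums of squares so degenerate inputs have defined answers
(identical windows give F = 0, p = 1 rather than 0/0). The
weekday/weekend split repeats everything on nights with onset on
Fri/Sat/Sun versus Mon–Thu and flags concordance when the sign pattern of
the three paired contrasts matches.

## The synthetic world

The generator's defaults state the emulated conditions: 21-day recordings;
touches from an inhomogeneous Poisson process at 60/h (waking mean) with an
80% diurnal modulation peaking mid-afternoon (15 h) and a 20% weekly
modulation peaking midweek; sleep from 23:30 to 07:30 with 30-min jitter
and a 60-min weekend delay; latency baselines 300/2000/1200 ms (TS/US/ALS)
with lognormal noise (σ = 0.3) and 10% diurnal modulation slowest near
04:00; a 20% in-bed penalty on US (5% TS, 0% ALS) and a 10% post-wake
inertia penalty decaying with a 45-min constant, consistent with the
30–90-min window in which sleep inertia is usually described; wake activity
counts with mean 50/min (gamma), sleep counts near zero (exponential, mean
0.5), day/night lux of 500/1.

Two reconciliations are worth recording. First, touch *counts* follow the
Poisson process exactly (so closed-form count checks hold), while
inter-touch *gaps* within a session are re-drawn from the TS latency model —
counts are preserved, and TS acquires the stated modulation structure; a
pure Poisson process would pin TS to the intensity and leave it
unmodulatable. Second, latency multipliers combine multiplicatively on the
lognormal location, so a penalty of 0.2 means exactly a 1.2× mean ratio
regardless of σ, and penalties read as percentage slowing.

What a green test does establish: the pipeline recovers injected periods,
acrophases, sleep times and window effects from data with this structure.
What it does not: realism of app content, bursty non-Poisson touch
clustering beyond the session mechanism, posture, naps beyond a single main
sleep period, device-specific count calibration, or missing-not-at-random
wear gaps. Cohort-level numbers from the recorded study population are
only reproducible from the deposited recordings themselves (dataverse
dataset 10.34894/6CIGDY), which are not bundled; the corresponding
acceptance check runs the reproduction when those CSVs are supplied locally
and fails otherwise.

## Numerical and degenerate-input choices

- Constant series: undefined normalized power (error) in `lomb_scargle()`;
  amplitude 0 with p = 1 in `fit_cosinor()`.
- A perfect cosinor fit (residual sum of squares at rounding level) reports
  p = 0 rather than an unstable F ratio.
- The acrophase clock bin in `peak_vs_offpeak()` is selected with a `1e-9`
  tolerance so an acrophase of exactly 16 h lands in `[16, 17)` despite
  floating-point wrap.
- Zero-resultant circular groups and zero circular variance are errors, not
  NaNs.
- Per-subject seeds derive linearly from the master seed modulo 2³¹, so a
  cohort is reproducible subject-by-subject.
- Cohort periodograms must share a grid; `lomb_scargle(span_h =)` fixes the
  grid-defining record length (e.g. the nominal 21 days) because observed
  spans differ by a bin depending on when the first and last touch fell.

## Known limitations

Actigraphy-defined "sleep" includes still-but-awake time, so in-bed phone
use is visible by construction; the package deliberately reports
performance in that obscure period rather than reclassifying it. The
Watson–Williams test assumes von Mises-like concentration, which excluded
low-concentration acrophase samples can violate (hence the warning). The
repeated-measures ANOVA is the classical univariate form without sphericity
correction — with three levels and the paired follow-ups reported
alongside, this is a transparency trade-off, not an oversight.
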