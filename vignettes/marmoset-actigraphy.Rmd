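---
title: "Methods: actigraphy, sleep and circadian analysis in the marmoset model of parkinsonism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actigraphy, sleep and circadian analysis in the marmoset model of parkinsonism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marmact)
```

## The measurement model

A collar accelerometer integrates a marmoset's omnidirectional movement
into one non-negative activity count per fixed epoch.  The package
assumes strictly uniform sampling: gaps must be represented by the
explicit missing-mask of an `epoch_series`, never by dropped rows.
Operations that are undefined on incomplete data (the circadian indices)
refuse masked epochs; descriptive summaries ignore them with a message.
Counts are kept as non-negative reals because vendor firmwares differ on
scaling; every analysis in the package is either scale-free or reported
in counts, so the absolute calibration never matters.

Recording days run from 09:00 to 09:00, matching the usual deployment
protocol in which the device is fitted in the morning and collects a
whole day from 09:00.  All clock arithmetic is naive local time at
minute resolution; there is no time-zone or daylight-saving handling,
which is adequate for housed animals and bounded recording spans.

## Sleep scoring

The nocturnal analysis window is fixed at 19:00–06:30 (11.5 h) for every
subject.  Holding the window fixed rather than detecting per-night sleep
onset standardises the period analysed across animals with different
settling behaviour; settling activity after 19:00 then legitimately
counts against sleep quality.

An epoch is *immobile* when its count is strictly below the immobility
threshold (default 1 count/epoch — healthy animals show essentially zero
counts during sleep, so any appreciable count marks movement; the
threshold is a parameter).  Wake/sleep defaults to a straight relabelling
of mobile/immobile, the simplest defensible rule; a smoothing policy
(centered weighted moving sum of raw counts, default kernel
`c(1,2,4,2,1)/10`, against a wake threshold) is available but off by
default because it trades single-epoch arousal sensitivity for robustness
to movement artefacts, and the right trade-off is study-specific.

Eight metrics summarise a night, computed from one labelling so the
identities among them hold exactly: % awake (identical whether computed
from epochs or bouts, since bouts partition the window), wake-bout count,
mean sleep-bout length (min), fragmentation index, immobile-phase count,
mean immobility length (min), total moving time (min) and mean activity
(counts/epoch).  The fragmentation index is the actiwatch-software
composite — % of window epochs mobile plus % of immobile bouts no longer
than one minute — exposed as a replaceable function (`fi_fun`) because the
vendor constant is a convention, not a measurement.

## Nonparametric circadian indices

On hourly-binned complete days, with `x_i` the chronological hourly
sequence, `x̄_h` the mean of clock-hour `h` across days, `N` hourly
samples and `p = 24`:

$$IS = \frac{N\sum_h (\bar x_h - \bar x)^2}{p\sum_i (x_i - \bar x)^2},
\qquad
IV = \frac{N\sum_{i\ge 2}(x_i - x_{i-1})^2}{(N-1)\sum_i (x_i-\bar x)^2}.$$

IS is 1 exactly when the daily profile repeats; IV is ≈ 2 for white
noise, exactly 4 in the limit of a strictly alternating sequence, and
`2(1 − cos(2π/24)) ≈ 0.068` for a pure 24-h cosine sampled hourly.  A
constant series makes both ratios 0/0; the package raises an error rather
than silently returning a value.  Both indices are invariant under
positive rescaling of counts.  IS and IV are computed once on the pooled
record (not per day): the successive-difference statistic needs the
overnight transitions between days, and pooling is also the convention of
the analysis software these indices come from.

L5 and M10 scan every window of 5 or 10 h at a configurable onset step
(default 60 min, consistent with published onset tables at hourly
resolution), wrapping across the day boundary; ties are broken toward the
earliest onset after the day start, making results deterministic.  Window
means are reported in counts per hour.  L5, M10, amplitude (M10 − L5) and
relative amplitude `(M10 − L5)/(M10 + L5)` are computed per day, then
summarised mean ± SD.  Onsets are averaged linearly as minutes since the
day start, not circularly: with a 09:00 boundary both extreme windows sit
far from the boundary, where the linear mean is exact.  This is a
documented limitation for day boundaries placed inside either window.

## Activity profiles and the dose response

Activity onset is the first clock time after the day's main quiescent
period (the longest sub-threshold run, treating the day as circular) at
which the raw count reaches `threshold_frac` (default 0.2) of the peak
smoothed activity while the smoothed activity holds that level for the
sustain period (default 10 min).  Requiring the raw count prevents the
centered smoother (default 10 min) from back-dating the onset into the
quiescent side; anchoring to the main quiescent run makes the estimate
independent of the arbitrary 09:00 segment start.  An all-zero day has no
onset and errors.

Peak detection smooths the mean 24-h profile circularly and keeps local
maxima rising at least 10 % of the profile range above its minimum — the
floor suppresses noise peaks when resolving the healthy biphasic pattern
(peaks near 10:00 and 16:00).  A flat profile has no peaks; a monotone
one at most one (at the wrap point).

`dose_response()` uses the 2.5 h pre-dose window (the dosing protocol
records from 09:00 and doses at 11:30) for a baseline mean and SD.  The
response onset is the first post-dose epoch whose raw count exceeds
`mean + k·SD` (k = 2) while the smoothed series holds that threshold for
the sustain period (5 min); the response ends when that stops being true;
the peak is the argmax of the smoothed series within the response; AUC
integrates smoothed activity above the baseline mean over the response.
The search is limited to 6 h post-dose so the evening activity peak and
the next morning cannot masquerade as drug responses on long recordings.
All latencies are relative to the dose, so the analysis is
translation-equivariant.  A vehicle day, which never crosses threshold,
returns `response = FALSE` rather than zeros.

## Behaviour scoring

The rating scale sums items scored 0–3.  The published item list names
"posture" twice and splits arm tremor and gross motor skills by side,
which would overshoot the printed scale maximum of 57; the shipped
`pdrs57` registry removes the duplicate and merges each bilateral pair,
giving 19 items × 3 = 57.  Consistency with the printed maximum is the
only hard constraint available, so the registry is plain data and
alternative compositions are drop-in.  The motor subscale excludes
apathy, vocalization, drooling and startle response.

ORTBD sessions are event logs, one row per reach.  The ten summary
variables follow their operational definitions; two need conventions:
*awkward reach* is a reach with the hand farthest from a lateral opening
(left hand to a right opening and vice versa, in the animal's frame;
front openings are never awkward), and *perseverative response* is a
reach to the side that was open on the previous trial but is closed on
the current one, so the first trial contributes no opportunity.  Rates
are reported over the session (days pooled); `execution ≤ correct` holds
by construction.  Tremor frequency is count/duration per observation
window, reported mean ± SD — the input is manual oscillation counts, as
video playback scoring is a human protocol.

## The synthetic generator

`simulate_activity()` draws from an explicit model of healthy marmoset
rest–activity structure:

* **Daytime** (06:45–19:00): a deterministic expectation built from a
  50 counts/epoch plateau plus Gaussian feeding-related modes at 10:00
  (height 180, width 90 min) and 16:00 (height 140, width 75 min), with
  10-min linear ramps at the window edges.  The abrupt morning rise is
  what makes a sharp detectable onset; the mode positions encode the
  biphasic pattern.
* **Count noise**: gamma-mixed Poisson with variance `λ(1 + φ)`,
  dispersion φ = 5 by default — accelerometer counts are overdispersed
  relative to Poisson.  φ = 0 is the deterministic noiseless limit used
  by exactness tests; small positive φ approaches pure Poisson.
* **Night**: an alternating renewal process of sleep and wake bouts with
  geometric lengths (≈ 25 arousals/night, wake bouts ≈ 2 min, implying
  ≈ 26-min sleep bouts; a mean sleep-bout length can be set directly).
  Sleep epochs have zero counts.  Wake-bout intensity follows a nocturnal
  template with strong settling restlessness until ≈ 21:45 and pre-dawn
  restlessness from ≈ 03:45 around a quiet core.  The sharply bounded
  shoulders give each night a well-defined least-active period (baseline
  onset ≈ 22:00, matching healthy animals); an earlier, smoothly-curved
  template made the L5 onset noise-dominated and irrecoverable, which is
  a property of valley-finding statistics, not of the analysis code.
* **Lesion effects** are orthogonal transformations: daytime amplitude
  scale; arousal-rate multiplier and sleep-bout scale (both act on the
  mean sleep-bout length); M10 delay (translates the whole diurnal
  waveform); L5 advance (translates the nocturnal template only); and an
  optional hyperactive mode adding intermittent high-intensity daytime
  bursts.  Because phase shifts translate deterministic components only,
  each effect is individually recoverable by its analysis stage.
* **Dose days** add a pulse `(multiplier − 1) × (pre-dose mean expected
  activity)` shaped as a half-cosine rise from 30 min post-dose, a
  Gaussian peak (σ = 15 min) at 70 min, a sustained plateau at 0.7 of
  the peak, and a half-cosine fall ending 270 min post-dose — the
  peak-then-sustained-elevation time course of an oral dopaminergic
  dose.  A multiplier of 1 produces a vehicle day bit-identical to the
  undosed day under the same seed.  The default multiplier (40) makes
  the response unambiguous against the lesioned daytime baseline, as
  dosed-animal actograms show.

The generator emulates the *structure* the analyses assume — it does not
model individual animals, dopamine pharmacokinetics, seasonal or housing
effects, device saturation, or missing data.  Passing recovery tests
therefore demonstrates that each analysis stage correctly inverts its
documented generative feature at realistic noise levels, not that the
pipeline is validated against real recordings.

ORTBD sessions draw the open side uniformly, reach outcomes as Bernoulli
successes (so execution % recovers the success probability), and
failed-reach types (perseveration toward the previous open side, barrier
touches, open-side misses) from configured probabilities; latencies are
log-normal.  PDRS assessments draw each item Binomial(3, p) with p set so
the expected total hits the preset (0 healthy, 43 acute, 29 chronic).
Tremor windows draw a per-window frequency `N(f, jitter)` and round
`f × duration` to a count.

All generators restore the caller's RNG state and are pure functions of
(configuration, seed).

## Validation problem sizes

The shipped tests exercise: exhaustive-enumeration equivalence for the
extreme-window scan on 200 random days plus minute-resolution days at
15/30/60-min steps; literal-formula oracles for IS/IV to 1e-12; lesion
parameter recovery on 10-day records (daytime ratio within 0.05 of 0.5,
wake-bout ratio in (2, 4), sleep-bout ratio within 15 %, both phase
shifts within one 60-min onset bin); geometric sleep-bout recovery over
50 nights; dose recovery (peak within 10 min of 70, duration within 20 %
of 240 min, vehicle negative); 600-trial ORTBD recovery within three
binomial standard errors; and 400-draw PDRS preset means within 2 points.
These sizes keep the whole suite under a minute on one core while leaving
every stochastic tolerance at least three standard errors wide under its
fixed seed.

## Known limitations

Linear (non-circular) onset averaging; no missing-data imputation (masked
epochs are refused or skipped, never filled); sleep scoring is
single-channel actigraphy — it cannot see quiet wakefulness, so % awake
is a lower bound relative to EEG; the fragmentation-index constants are a
vendor convention; the PDRS item merge is one defensible reading of an
inconsistent published list; and the simulator's count scale is
arbitrary, so only scale-free or ratio quantities should be compared
against real devices.
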