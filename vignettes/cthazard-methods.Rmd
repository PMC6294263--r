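---
title: "Hazard scoring for calcium-transient screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard scoring for calcium-transient screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneously beating hiPSC-derived cardiomyocyte monolayers, loaded with a
calcium-sensitive dye and imaged well-by-well on a kinetic plate reader,
give a medium-throughput functional readout of drug-induced cardiac
electrophysiological liabilities. Each well yields a fluorescence time
series of periodic calcium transients. Three beating parameters summarize a
recording: the transient duration at 90% of decay (CTD90, a surrogate for
action-potential and QT duration), the beat rate (BR, transients per
minute), and the transient amplitude (Amp, peak minus minimum signal).
Three abnormal phenotypes carry additional information: beating arrest,
fibrillation-like activity (sustained small, rapid transients), and
EAD-like events (extra calcium spikes during or directly after a
transient), the last being a specific surrogate for torsadogenic risk.

`cthazard` turns these raw traces into a concentration-dependent cardiac
hazard label (no / low / high / very high; green / yellow / red / black)
per compound, through four stages: feature extraction, vehicle-referenced
effect normalization with quality control, tolerance-interval-derived
cutoffs, and a weighted scoring matrix.

## Feature extraction

Beats are detected as local maxima whose prominence exceeds both half of
the robust trace amplitude and a noise floor, with a refractory period.
Prominence is computed against the deeper of the two minima separating a
candidate from its neighbouring candidates, after pruning noise-scale
candidates that would otherwise fragment a genuine peak's prominence.
The trace noise scale is estimated from a low quantile of successive
differences, which samples the quiescent inter-beat segments rather than
the decay slopes.

CTD90 is measured per beat from an upstroke reference — the time the
signal rises through 10% of the beat amplitude — to the first post-peak
crossing of `local_baseline + 0.1 * amplitude`, with linear interpolation
between samples for sub-sample accuracy at the instrument's 66.7 Hz
sampling rate. The upstroke reference is our choice: the field's
definitions fix only the decay endpoint, and a rise-threshold start is the
standard convention for transient-duration metrics. A beat whose decay
never reaches the 90% level before the next upstroke has no defined CTD90
and is excluded from the well median rather than truncated.

Well parameters are medians over all beats in a one-minute analysis
window; we use the final 60 s of each recording phase (the window position
is not specified by the assay description, and the final minute is the
farthest from any compound-addition transient). Beat rate is the beat
count in that window. Beat stop is a 30-minute call with a strict
threshold: fewer than 5 beats/min. A well silent at 15 minutes but beating
at 30 minutes is not a beat stop; the 15-minute recording is used only to
observe EADs and fibrillation-like events.

EAD-like events are counted as secondary maxima between a beat's peak and
the next upstroke, before the decay completes, with prominence above 15%
of the host beat's amplitude (configurable; manual review is the
historical practice, so automation needs an explicit rule).
Fibrillation-like activity is called when a sustained segment (>= 20 s)
shows a transient rate at least 3 times the well's baseline rate at
amplitudes at most 0.3 times baseline; within each scanned window the
candidate transients are detected against the local signal range on a
lightly smoothed copy, so the small rapid transients are seen even though
they fall below the primary beat threshold. A flat (arrested) trace has no
transients and is never called fibrillation.

## Effect normalization and quality control

Each parameter's effect is the percent change at 30 minutes versus the
well's own baseline,

$$\Delta\% = 100 \cdot \frac{x_{30\mathrm{min}} - x_{\mathrm{baseline}}}{x_{\mathrm{baseline}}},$$

and the plate-level net effect subtracts the same plate's vehicle median,

$$\Delta\Delta\% = \Delta\%_{\mathrm{drug}} - \Delta\%_{\mathrm{vehicle}}.$$

Treatments are aggregated as medians over included, still-beating wells
(typically 4–8 wells per plate-treatment; counts outside that range warn).
Stopped wells contribute to the beat-stop incidence but not to parameter
medians — arrest is its own scored parameter, and treating it as a -100%
rate change would double-count it. The vehicle reference is the median
over all included vehicle wells of the plate.

Well QC excludes wells with no baseline beating, wells annotated as
non-synchronous (a property the integrated-well signal cannot itself
reveal; the simulator can inject the annotation), and wells with baseline
BR below 30 or above 90 beats/min. We read "lower than 30 or higher than
90" strictly, so 30 and 90 themselves pass. Plate QC fails a plate when
more than 10% of wells violate the beating/BR rules, or when a present
positive control misses its sensitivity criterion: dofetilide 3 nM must
reach at least +15 net percent CTD90 prolongation, isoprenaline 0.1 uM at
least +30 net percent BR increase, and nimodipine 0.1 uM at most -10 net
percent CTD90. QC-failed plates are reported and never scored.

## Tolerance intervals and cutoffs

Cutoffs between the no-effect, mild and strong zones are anchored in
nonparametric tolerance intervals computed with the classical Wilks
order-statistic construction: the two-sided interval is simply
`(min, max)` of the sample, and the population mass it covers follows a
`Beta(n-1, 2)` law whatever the underlying distribution. The achieved
confidence of covering at least a proportion $p$ is
$1 - I_p(n-1, 2)$, and the package reports it alongside the interval;
samples too small for the requested confidence (fewer than 46 for 90%
coverage at 95% confidence) are flagged rather than rejected, so pilot
plates remain analyzable with a warning.

Zone derivation per parameter and direction:

* no-effect bound: the vehicle tolerance interval re-centred at zero
  (both bounds minus the vehicle TI midpoint) — the most direct reading of
  "corrected for vehicle offset";
* strong anchor: the outer bound of the relevant control drug's tolerance
  interval, minus the same vehicle midpoint;
* mild/strong boundary: placed strictly between the no-effect bound and
  the strong anchor, by default at their midpoint. The original cutoff
  placement came from an iterative expert optimization that is not
  reproducible from published information; the midpoint default is an
  explicit, overridable rule standing in for it.

A control whose corrected bound falls inside the no-effect zone is too
weak to define a strong cutoff and raises an error.

## The scoring matrix

Each parameter's net effect earns weighted points by zone and direction;
boundaries belong to the milder zone, a deliberately conservative
tie-break (fewer false positives). Defaults: CTD90 mild 1 / strong 3
points, BR and Amp mild 1 / strong 2. Beat-stop incidence is scored in
three zones — up to 50% of wells (1 point; incidences up to one half occur
with relatively cardiac-safe sodium blockers), more than 50% but not all
(2), and exactly 100% (4) — and any fibrillation incidence adds 4 points.
The total maps to labels: 0 = no, 1–2 = low, >= 3 high; so 100% beat stop
alone reaches high hazard even though a fully arrested study has no
parameter effects at all. Any EAD incidence overrides the label to very
high hazard, and that override is the *only* route to very high — a score
alone never reaches it. All weights, zones and label ranges are
configuration (YAML, validated on read), and the shipped defaults were
produced by running the cutoff derivation on a packaged synthetic
calibration study (`data-raw/default-matrix.R`: one vehicle arm plus four
directional control arms of 100 wells each at seed 20181211); they are
this package's defaults, not published reference values.

## The plate simulator

The simulator exists so every stage is testable without laboratory data.
A well's transient is a sum of per-beat kernels — a logistic upstroke
(time constant 8 ms by default, normalized to reach the peak exactly)
followed by a single-exponential decay — on a constant baseline with
additive Gaussian noise. This shape matches the qualitative morphology of
well-integrated calcium transients and gives a closed-form implied CTD90,
`5.2511 * tau_up + ln(10) * tau_decay`, which feature extraction must
recover on noise-free traces.

Baseline heterogeneity follows truncated normal distributions (BR mean 60,
sd 12, truncated to 20–110 beats/min; CTD90 mean 500 ms, sd 80 ms):
baseline histograms of such assays are approximately Gaussian, but no
published parameters exist, so these are the package's chosen study
conditions. Vehicle drift between baseline and the post phases is a
normal perturbation with sd 3 percentage points per parameter — "low
variability" made concrete. Drug effects follow monotone hyperbolic
concentration-effect curves per parameter, and event probabilities
(EAD, fibrillation, arrest) the same form. EADs are synthesized as
secondary kernels of 20–60% of the beat amplitude injected during the
decay phase; fibrillation replaces the final segment with transients at
3.5x the native rate and 0.25x amplitude; arrest flattens the trace after
10 s. Each well consumes its own substream drawn from the master seed, so
datasets are bit-reproducible and independent of iteration order.

What the simulator does *not* emulate: dye/optics kinetics,
photobleaching, batch-to-batch maturity differences, non-synchronous
beating (only its annotation), and drifting cell health. Passing tests
therefore demonstrate the correctness and calibration of the analysis
chain under the stated noise model, not instrument-level robustness.

## Numerical choices and simulation sizes

* Sampling at 66.7 Hz (15 ms) with linear interpolation at both CTD90
  crossings; recovery is verified to 1.5 sample periods against a
  continuous-time oracle on a 31-point grid spanning 30–90 beats/min and
  200–800 ms CTD90 (combinations with CTD90 above 85% of the period are
  excluded as unresolvable overlapping beats).
* Tolerance-interval calibration is checked over 10,000 simulated normal
  samples of n = 100; the minimum-n values are verified by an independent
  closed-form scan and a 100,000-replicate Monte-Carlo.
* The null false-positive study uses 50 seeded 96-well vehicle-only
  plates (8 reference wells + 11 null pseudo-compounds of 8 wells each);
  concentration-monotonicity uses 100 seeded 32-well plates of a strong
  prolonger at 4 log-spaced concentrations spanning the model's dynamic
  range (EC50/10 to 10x EC50), the usual dose-spacing practice — adjacent
  doses on a response plateau would differ by less than plate-to-plate
  noise and say nothing about monotonicity. Recordings are simulated at 75 s
  per phase (the 60 s analysis window plus margin), and the 15-minute
  observation phase is omitted where only 30-minute endpoints are
  evaluated.
* Degenerate inputs: zero-noise traces (the noise floor collapses to
  machine epsilon, which is harmless because noise-free local maxima only
  occur at true peaks), constant traces (no candidates, no beats, never
  fibrillation), and all-stopped treatments (incidence-only scoring) are
  all exercised in the test suite.

## Known limitations

* Beat detection assumes a well-integrated (single-ROI) signal; it cannot
  distinguish non-synchronous beating from rate changes, which is why
  that exclusion is accepted as an upstream annotation.
* The mild/strong boundary placement is a convention, not an estimate;
  sites adopting the package should re-derive cutoffs from their own
  vehicle and control data (`derive_cutoffs()`, `calibrate_scoring_matrix()`)
  and revisit them periodically.
* Very fast, very long transients (CTD90 approaching the beat period)
  bias CTD90 downward because the decay never returns to baseline; the
  effect is consistent between baseline and treatment and largely cancels
  in the percent effects, but absolute CTD90 values at extreme rates
  should be interpreted with care.
* EAD counting at the 15% prominence threshold recovers large injected
  spikes reliably but misses a fraction of spikes near the threshold;
  well-level flags (any EAD) are the robust quantity, and they drive the
  very-high override.
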