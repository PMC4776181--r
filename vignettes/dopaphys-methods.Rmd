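---
title: "Methods: burst, synaptic and pharmacological analysis of dopaminergic recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst, synaptic and pharmacological analysis of dopaminergic recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopaphys)
```

dopaphys implements the quantitative core of a disinhibition study on
midbrain dopaminergic neurons: how regularly or burstily a cell fires, how
its rate responds to GABAergic and glutamatergic drugs, how strong and how
fast its inhibitory synaptic inputs are, and whether two treatment cohorts
differ on any of these measures. This vignette records the models, the
tunable parameters, and the design decisions behind each stage, plus what
the synthetic-data validation does and does not establish.

## Burst detection and firing statistics

Dopamine cells in vivo alternate between pacemaker-like tonic firing and
bursts. We use the classical two-threshold ISI criterion: scanning
interspike intervals left to right, a burst **opens** at the first ISI
strictly below 80 ms (both spikes of the onset pair belong to the burst),
**extends** while each following ISI is at most 160 ms, and **terminates**
at the first ISI strictly above 160 ms. The 80–160 ms band therefore
continues a burst but can never start one; the tie-breaks (exactly 80 ms
does not open, exactly 160 ms continues) follow directly from reading the
onset condition as "< 80" and the termination condition as "> 160". A lone
spike is never a burst (minimum size 2).

Derived statistics per unit: mean rate `n/T` over the half-open epoch
`[0, T)`; SWB, the percentage of spikes inside bursts; burst frequency in
bursts/s (the unit is stated explicitly in all outputs because conventions
vary); mean burst duration (first-to-last spike, `NA` when there are no
bursts); and the ISI coefficient of variation.

**CV of ISIs.** ISIs are histogrammed at a 10 ms bin width (tunable), and a
Gaussian `A exp(-(x-μ)²/2σ²)` is fitted to the bin counts by
Levenberg–Marquardt least squares (initialized at the sample mean/sd,
parameter tolerance 1e-8); `CV = 100 σ/μ` percent. The Gaussian model is
meaningful only for unimodal, pacemaker-like ISI distributions. When the
fit fails to converge, or yields μ ≤ 0, the implementation falls back to
the sample sd/mean and flags `fallback_used` — bursty trains, whose ISI
distributions are bimodal, routinely and intentionally take this path.
Fewer than 10 ISIs is an error rather than a guess.

**Unit inclusion.** Dopaminergic units are broad-spiked. In vivo, a unit is
kept when its *median* per-spike duration (onset to negative trough) is at
least 1.1 ms — the median summarizes per-spike measurements into the
per-unit decision the criterion implies. In vitro, individual spikes
shorter than 2 ms are removed before any statistic and the unit is kept.

## Drug-response quantification

Rates are binned on a 20 s grid anchored at the start of the baseline
window (60 s immediately before application, by default), so the
normalization target is exact: each bin is expressed as
`100 · rate / mean(baseline rate)`, and the baseline bins average exactly
100%. The response summary is the mean of the normalized bins strictly
inside the application window, minus 100. Partial onset/offset bins outside
the window are excluded deliberately: including them would dilute the
response by an amount that depends on the bin phase. A unit with a silent
baseline has no defined percent change and is excluded with an error
(condition class `dopaphys_zero_baseline`) rather than imputed.
Superfusion analyses return rate and CV inside an analysis window, each as
a percentage of its own baseline value; the windowed CV is the sample
statistic, since a histogram fit is not stable on a 1–2 minute window.

## Miniature synaptic event detection

The detector operationalizes threshold-based mini detection on explicit,
testable rules:

* **Pre-smoothing** (`smooth_ms`, default 0.6 ms boxcar). An 8 pA threshold
  over σ ≈ 2 pA noise is only a 4σ test per sample; at 5–10 kHz, raw
  thresholding would fire ~0.16 times/s on noise alone. Averaging ~3
  samples makes the test ≈ 7σ while biasing a τ_rise ≈ 1.5 ms event peak by
  ~0.1%.
* **Baseline**: trailing median over 50 ms, frozen at its pre-crossing
  value for all per-event measurements, so an event cannot drag its own
  reference down.
* **Threshold crossing**: baseline-subtracted inward deflection ≥ 8 pA for
  at least `min_above_ms` (0.4 ms), with a 5 ms onset refractory period.
  A candidate must additionally rise by ≥ 8 pA above its own local (5 ms)
  pre-run level; this rejects noise flickers riding on the decay tail of
  the previous event, which sit far from the 50 ms baseline but are not new
  events, while a genuine overlapping event (a real ≥ 8 pA rise) still
  passes.
* **Onset** is the last sample below 10% of the peak before the crossing;
  **amplitude** is baseline-to-peak.
* **Double peaks**: an event is flagged when a second rise registers before
  the current has decayed to 50% of its peak — either a dip-and-rebound of
  at least the threshold, or, for merged events whose summed rise is
  monotone, a second prominent hump in the smoothed rising-phase slope
  (prominence at least the threshold and half the maximum slope).

Flagged events still count toward the event *frequency* — an overlapping
event is a real synaptic event — but are excluded from amplitude pooling
and from kinetics averaging, mirroring the convention that events are
*selected* to reject double peaks before averaging. Cell-level kinetics
require more than 50 clean events and are measured by default on the
onset-aligned average waveform of clean events whose averaging window
(2 ms before to 50 ms after onset) contains no other detected event;
`kinetics = "per_event"` averages per-event fits instead, and on
homogeneous synthetic events the two agree.

**Decay fit span.** The decay τ comes from a single-exponential
least-squares fit initialized at `t_half/ln 2`. The fit starts where the
decay has fallen to 50% of the peak and ends at 10% (or the next event).
Starting at the exact peak is tempting but wrong for difference-of-
exponentials events: the residual rise component flattens the early decay,
and on a noiseless τ_rise 1.5 / τ_decay 7 ms event a fit from the peak
returns τ ≈ 8.15 ms (+16%). From the 50% point the bias is ~0.5% at
τ_decay 7 ms and ~2% at 5 ms, which the noiseless-recovery tests pin down.

## Evoked and intrinsic currents

Inward currents are stored as negative samples; all reported amplitudes are
positive magnitudes with the sign convention stated in the function docs.

* **Agonist-evoked peak**: maximum baseline-subtracted inward deflection
  after the stimulus mark, read from a 10 ms-smoothed trace. Smoothing
  matters: evoked currents develop over hundreds of ms, so the peak is
  unaffected, but the maximum of tens of thousands of raw noisy samples is
  biased upward by several σ, which would systematically inflate small
  (e.g. blocked) responses and distort blockade percentages.
* **Blockade**: `100 · blocked peak / control peak` for a same-cell pair.
* **AHP tail**: peak outward current after the pulse-end mark (fast
  component) and trapezoidal charge transfer in pA·ms from pulse end until
  the 5 ms-smoothed tail first returns to baseline (slow component). On an
  exponential tail `A e^{-t/τ}` the charge converges to `A·τ`, which the
  tests check at 5, 10 and 50 kHz.
* **Sag current (I_h)**: the activation develops with τ on the order of
  100–200 ms, so a plain "steady state minus current at 20 ms" difference
  misses both the sag already active at 20 ms and any part not yet
  expressed at step end — on synthetic sags it under-reads by 15–25%.
  The default estimate therefore fits `I(t) = I∞ + B e^{-(t-t_on)/τ}` to
  the post-transient step current (from 20 ms after onset) and reports the
  full amplitude `|B|` referenced to step onset; the plain difference
  remains available as `method = "difference"` and as the fallback when the
  fit fails.
* **Passive properties**: the seal-test capacitive transient is fitted with
  a single exponential and extrapolated to the step onset, giving
  `Rs = ΔV/I_peak`, `Rm = ΔV/I_ss − Rs`, `Cm = τ (Rs+Rm)/(Rs·Rm)` — the
  standard single-compartment estimates, exact on an ideal RC trace.

## Synthetic data: what it emulates

The generator exists so that every stage can be validated against ground
truth; its defaults are the study conditions.

**Spike trains.** Three renewal-type models: `pacemaker_gaussian`
(truncated-normal ISIs, default sd 5% of the mean ISI, 2 ms absolute
refractory floor), `poisson_refractory` (exponential ISIs on a refractory
floor), and `two_state_burst`, which alternates burst packets (sizes
uniform on 2–8, intra-packet ISIs truncated-normal 40 ± 15 ms below 80 ms)
with singleton spikes separated by inter-event gaps above 160 ms. The
packet probability is solved from the target in-burst spike fraction, and
the gap mean from the target rate. Three corrections keep the generator
calibrated rather than approximately right: truncated-normal means are
adjusted so the *realized* mean equals the configured value; the renewal
process starts from a warm-up period (or a uniform phase on the first
interval) so counting begins in equilibrium — without this, mean rates
carry a small O(1/T) startup deficit that a 3-standard-error calibration
test detects; and packets cut to a single spike at an epoch edge are
relabelled as non-burst, because a lone spike is not a burst. Ground truth
is defined by generator packets, *not* by the 80/160 detector, so
detector-vs-truth agreement is a measured quantity, not an identity; the
construction (intra < 80 ms, gaps > 160 ms) makes agreement exact, and the
tests assert exactly that. Optional between-unit rate heterogeneity
(`unit_rate_sd`) emulates cell-to-cell variability; cohort regimes derive
it from printed SEM × √n.

**Traces.** mIPSCs arrive as a Poisson process; each event adds a
difference-of-exponentials waveform, peak-normalized so the drawn amplitude
is the true baseline-to-peak value (rise and decay are independently
parameterized, matching how kinetics are reported). Gaussian noise is
additive. Protocol traces (agonist plateau, AHP tail, sag step, seal test)
are deterministic with analytic truth attached. Cohort regimes in
`default_regimes()` use the published group values where printed (rates
4.8/5.1 Hz, in-burst fractions 0.31/0.67, evoked peaks 825/491 pA, AHP
662/727 pA and 10773/8978 pA·ms, sag 425/437 pA, Rs/Rm/Cm, mini kinetics);
per-cell SDs are back-computed as SEM × √n. Values nowhere printed were
chosen once as realistic for GABAergic minis on dopamine cells — amplitude
regimes 30 vs 24 pA (sd 5), frequencies 2.0 vs 1.4 Hz, AHP tail τ set to
charge/peak (16.3/12.3 ms), sag τ 150 ms — and are not tuned thereafter.

**What passing tests do not show.** Synthetic traces have stationary
Gaussian noise, stationary baselines and exactly biexponential events; real
recordings drift, contain series-resistance and dendritic-filtering
distortions, and mix event shapes. Recovery of generator parameters
therefore demonstrates correctness of the analysis logic, not robustness to
every pathology of real data. Likewise the renewal spike-train models have
no slow rate modulation; QC thresholds are exercised, but real
spike-sorting quality is out of scope (the pipeline starts at spike times).

## Statistics

Group comparisons use the Mann–Whitney U test (exact when the combined
sample is ≤ 20 without ties, otherwise the tie-corrected normal
approximation with continuity correction), the two-sample
Kolmogorov–Smirnov test on pooled per-cell amplitude subsamples (exactly
100 per cell, seeded), and one-way ANOVA for multi-group CV designs. The
post-hoc procedure after ANOVA is a genuine open choice; we default to
Holm-adjusted pairwise Mann–Whitney tests because they are
distribution-free and consistent with the primary two-group test, and the
choice is a function argument, not a constant. Cells are the unit of
analysis (no animal-level clustering), with animal counts carried in
summary rows for transparency only. Type-I error calibration of both tests
is asserted at α = 0.05 within [0.04, 0.06] under 10,000-rep null
simulations in the acceptance suite.

## Pipeline, determinism and problem sizes

`run_pipeline()` writes a manifest first, then per-stage CSVs and a report
directory; every random draw derives from the single master seed, and the
provenance log records the seed, config hash and package version but no
wall-clock quantities, so identical config + seed yields bit-identical
output directories (asserted by hashing every file). The test suite runs
the cohort-discrimination, CV-recovery, drug-calibration and mini-recovery
checks at 100 seeds each, the burst-detector oracle over all 4^7 ISI
sequences on a four-letter ISI alphabet, and the pipeline determinism check
at scale 0.15; `scripts/acceptance.R` runs the full study sizes. These
sizes are the package's validation design: large enough for stable medians
and rejection-rate estimates, small enough to run routinely.

## Known limitations

* The mini detector is a threshold detector; very small events (< 8 pA)
  are invisible by design, and amplitude estimates carry a ~+1 pA
  max-of-noise bias at σ = 2 pA.
* The Gaussian-fit CV is undefined for strongly bursty trains except
  through the documented sample-statistic fallback.
* Charge transfer truncates at the first smoothed return to baseline; with
  heavy noise this can clip a small fraction (< 1%) of the true tail.
* No vendor acquisition formats (ABF/Igor) and no NWB export; plain CSV
  with JSON sidecars keeps fixtures diffable.
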