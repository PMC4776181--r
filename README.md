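# dopaphys

Analysis pipeline for electrophysiological recordings from midbrain
dopaminergic neurons: burst structure of extracellular spike trains,
baseline-normalized drug responses, miniature inhibitory postsynaptic
currents (mIPSCs), evoked and intrinsic currents, and the nonparametric
group statistics used to compare treatment cohorts. It is written for
studies of the tonic-to-burst shift in nigral dopamine cell firing and the
GABAergic disinhibition that can drive it.

Because raw recordings for such studies are rarely deposited, the package
ships a first-class synthetic-data generator with known ground truth
(packet-structured bursty spike trains, Poisson trains of biexponential
synaptic events in noise, step/tail protocol traces), so every analysis
stage is validated end to end against quantities that are true by
construction.

## What it computes

**Spike trains.** Bursts are detected with the Grace–Bunney criterion: a
burst opens at an interspike interval (ISI) < 80 ms and terminates at an
ISI > 160 ms; intervals in `[80, 160]` ms extend an open burst but cannot
open one. Per-unit statistics: mean rate `n/T` (Hz), **SWB** (percentage of
spikes within bursts), burst frequency (Hz), mean burst duration, and the
ISI coefficient of variation `CV = 100 · σ/μ` (%) taken from a least-squares
Gaussian fit to the ISI histogram (sample statistics as a documented
fallback for non-unimodal trains). Unit inclusion follows spike-waveform
duration: in vivo units need a median onset-to-trough duration ≥ 1.1 ms;
in vitro, individual spikes < 2 ms are dropped.

**Pharmacology.** Firing rates are binned at 20 s, normalized so the mean of
the 60 s pre-application baseline is exactly 100%, and summarized as the
mean percent change during the application window; superfusion responses
report rate and CV each normalized to its own baseline.

**Patch clamp.** mIPSCs are detected at an 8 pA baseline-to-peak threshold
against a trailing-median baseline; per-event and averaged-waveform
kinetics give the 10–90% rise time and a single-exponential decay τ.
Evoked measures: agonist-evoked peak inward current, percent remaining
under blockade, afterhyperpolarization tail peak and charge transfer
(pA·ms), the hyperpolarization-activated sag current I_h, and passive
membrane properties (Rs, Rm, Cm) from a seal-test transient.

**Statistics.** Mann–Whitney U (exact for small samples),
Kolmogorov–Smirnov on pooled per-cell amplitude samples, one-way ANOVA with
Holm-adjusted pairwise rank tests, and mean ± SEM report tables.

## Worked example

```r
library(dopaphys)

cfg <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.67,
                        epoch_duration = 120, seed = 3)
train  <- simulate_spike_train(cfg)
bursts <- detect_bursts(train)
burst_stats(train, bursts)
#> # A tibble: 1 x 12
#>   unit_id group   condition setting n_spikes n_bursts mean_rate_hz
#>   <chr>   <chr>   <chr>     <chr>      <int>    <int>        <dbl>
#> 1 u001    control baseline  in_vivo      578       85         4.82
#> # swb_percent 65.1, burst_frequency_hz 0.708, mean_burst_duration_s 0.139,
#> # cv_isi_percent 85.2 (sample-statistic fallback for this bursty train)
```

The detector reports that 65.1% of this unit's spikes sit inside bursts —
identical to the generator's ground-truth label fraction (the packet
construction makes every true burst detectable) — at a mean rate of
4.82 Hz over the 2-minute epoch. A whole two-cohort study runs with

```r
res <- run_pipeline(pipeline_config(seed = 1), "run1")
res$report$summary       # mean ± SEM per measure, group and stage
res$report$comparisons   # Mann-Whitney tests between cohorts
```

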