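# emgcmc

Analysis pipeline for at-home EMG-biofeedback studies of wrist motor
control after stroke — for researchers who need to quantify whether
training changed *muscle individuation* (can the participant activate
wrist extensors without co-activating flexors?) and *corticomuscular
coupling* (which hemisphere drives the muscles, and how strongly?), and to
relate those physiological measures to clinical outcomes.

## What it computes

**Extensor ratio (ER).** During a tracking task (12 trials of a 4 s hold at
15% of maximal grasp, 6 s rest), surface EMG from four forearm muscles is
band-passed 15–450 Hz, rectified and normalized to the recorded maximum
grasp. Muscle individuation per trial is

    ER = EMG_ext / (EMG_ext + EMG_flex)

averaged over the last 3 s of each hold: 1 = pure extension, 0 = pure
flexion, 0.5 = balanced co-activation.

**Corticomuscular coherence (CMC).** Welch magnitude-squared coherence
(128 ms Hann windows, 75% overlap) between preprocessed sensorimotor EEG
(5–100 Hz, bad channels removed, common-average referenced, z-scored) and
z-scored Hilbert envelopes of the task muscles, restricted to hold epochs,
with the analytic confidence level `1 − 0.05^(1/(L−1))`. Beta-band
(12–30 Hz) bins are Fisher-transformed (`atanh(sqrt(coh))`), scaled to
normal scores and combined with Stouffer's method per hemisphere, giving
the laterality index

    Laterality = (Coh_ipsi − Coh_contra) / (Coh_ipsi + Coh_contra)

**Group statistics.** Paired pre/post t-tests per measure, Pearson
correlation matrices between motor-control changes and Stroke Impact Scale
domains with Benjamini–Hochberg adjustment per matrix, SIS domain scoring,
and peak-CMC vs FMA correlations.

**Synthetic ground truth.** Generators for EMG sessions, coupled EEG/EMG
with programmable per-hemisphere coupling gains, artifact injection, and
paired clinical tables with programmable effect sizes and cross-measure
correlations — every analysis stage can be verified against recoverable
parameters.

## Worked example

```r
library(emgcmc)

# A session whose ground truth is ER = 0.45 / (0.45 + 0.15) = 0.75
cfg  <- synth_signal_config(seed = 3, extensor_level = 0.45, flexor_level = 0.15)
sess <- generate_emg_session(cfg)
map  <- synth_channel_map(cfg)
er   <- er_pipeline(sess$recording, sess$schedule, map, sess$calibration)
er
#> <er_result> task: extension, mean ER = 0.736 over 12 trials
#>   channels: extensor=ECRL, flexor=FCR

# Coupled EEG/EMG with 4x stronger ipsilesional coupling
ccfg <- synth_signal_config(seed = 5, n_trials = 6,
                            ipsilesional_gain = 2, contralesional_gain = 0.5)
co   <- generate_coupled_eeg_emg(ccfg)
cmc  <- cmc_pipeline(co$eeg, co$emg, map, co$schedule)
cmc
#> <cmc_result> task: extension
#>   ipsilesional  (C3): stouffer z = 89.80, peak 0.867 @ 23.4375 Hz
#>   contralesional(C4): stouffer z = 9.73, peak 0.037 @ 23.4375 Hz
#>   laterality = 0.804

# Group statistics on a synthetic 9-participant battery
tab <- generate_clinical_table(synth_clinical_config(seed = 1))
rep <- group_report(tab)
head(rep$paired_tests[, c("measure", "n", "t", "p", "mean_diff")], 3)
#>            measure n         t          p   mean_diff
#> 1 active_extension 9  3.969177 0.00412368 12.67495703
#> 2   active_flexion 9  3.108524 0.01447778  8.89284797
#> 3     er_extension 9 -1.322888 0.22243396 -0.05592188
```

The mean ER lands within ±0.05 of the programmed 0.75; the laterality is
positive because the ipsilesional gain dominates; and the group table
reproduces the analysis layout of a pre/post battery (t, p, mean change per
measure) on data with known effect sizes.

A command-line front end (`inst/cli/emgcmc.R`) exposes `simulate`, `er`,
`cmc`, `stats` and `report` subcommands over the same functions;
`run_pipeline()` orchestrates simulate → ER → CMC → stats end to end and
writes a checksummed run manifest.

See `vignettes/methods.Rmd` for the models, parameter choices and design
rationale.

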