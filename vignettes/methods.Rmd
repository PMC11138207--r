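---
title: "Muscle individuation and corticomuscular coherence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle individuation and corticomuscular coherence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgcmc)
```

# Scope

`emgcmc` implements the quantitative analysis used in EMG-biofeedback
rehabilitation studies of wrist motor control after stroke: a muscle
individuation statistic computed from surface EMG during an amplitude
tracking task, corticomuscular coherence (CMC) between sensorimotor EEG and
EMG envelopes, a hemispheric laterality index, and the pre/post group
statistics that tie these physiological measures to clinical outcomes.
Because patient recordings in this area are rarely deposited, the package
ships a synthetic generator whose ground-truth parameters are recoverable by
every analysis stage; the test suite is built on that closed loop.

# The recording protocol being modeled

The assessed task is quasi-isometric wrist extension (and separately
flexion) with the impaired hand: 12 trials of a 4 s hold at 15% of a
prerecorded maximal gross grasp, each followed by 6 s of rest.  Surface EMG
is recorded from four forearm muscles — extensor carpi radialis longus,
extensor carpi ulnaris, flexor carpi radialis, flexor carpi ulnaris — at a
nominal 2148 Hz.  EEG is recorded at 500 Hz from a lateral sensorimotor
subset of the 10–10 montage.  All streams are aligned by their start times
and linearly interpolated onto a common 1 kHz grid for offline analysis.
Linear interpolation was chosen over sinc or spline schemes because it is
exactly reproducible, artifact-free at block edges, and adequate for
content below 100 Hz (the resampling tests bound the relative RMS error of
sub-100 Hz sinusoids under 2148→1000 Hz resampling at 2%).

A note on the montage: published montage lists for this protocol are
sometimes ambiguous (one label duplicated in print); `channel_map()`
therefore accepts any lateral 10–10 subset rather than hard-coding a list,
and classifies electrodes by the odd/even terminal digit convention
(odd = left hemisphere).

# Extensor ratio

Muscle individuation is summarized by the extensor ratio

$$\mathrm{ER} = \frac{\mathrm{EMG}_{ext}}{\mathrm{EMG}_{ext} + \mathrm{EMG}_{flex}},$$

where the numerator and denominator are mean rectified, normalized EMG
amplitudes over the last 3 s of each hold.  ER = 1 means pure extensor
recruitment, 0 pure flexor recruitment, 0.5 balanced co-activation.  The
statistic is scale invariant, so any common gain (electrode impedance,
amplifier setting) cancels.

Processing chain (`preprocess_emg()`): zero-phase Butterworth band-pass
15–450 Hz, full-wave rectification, division by the maximum-grasp
reference.  Two realization choices deserve comment:

* **Filter realization.**  Band edges are implemented as a cascade of a
  4th-order low-pass and a 4th-order high-pass section, each run
  forward–backward (`signal::filtfilt`).  A single 8-pole band-pass with a
  450 Hz edge at a 1 kHz rate is numerically fragile in double precision;
  the cascade is stable and keeps 4th-order behavior at each edge.
* **Normalization reference** (`compute_max_grasp()`): the 95th percentile
  of the 250 ms moving-average rectified calibration signal, maximized over
  calibration repeats.  The percentile makes the reference robust to
  isolated spikes (a single-sample artifact 100× the baseline moves it by
  less than 10%), which a plain maximum would not be.

Which channel represents a muscle group is decided the same way the online
feedback channel is chosen: the group channel with the largest hold/rest
RMS ratio (`select_feedback_channel()`), with ties broken by channel-map
order.  Averaging the two channels of a group instead is exposed via
`er_pipeline(average_group = TRUE)`, since published descriptions do not
always pin this down; the SNR-selected channel is the default because it
mirrors the feedback rule exactly.

The screening rule for study eligibility (`screening_test()`) requires the
hold-window mean to reach 30% of maximum on **all** 10 screening trials,
threshold inclusive — the strictest reading of "hold 30% for 10 trials".
The real-time game control signal (`control_signal()`) is the same ratio
regularized by a small ε so that rest maps to 0.5 and the signal is
continuous in both inputs.

# Corticomuscular coherence

CMC is the magnitude-squared coherence between a sensorimotor EEG channel
and the z-scored Hilbert envelope of a muscle's EMG.  The chain is:

1. **EEG** (`preprocess_eeg()`): zero-phase 5–100 Hz band-pass; bad-channel
   removal; common-average re-reference over retained channels; per-channel
   z-score.  Bad channels are flagged by a robust kurtosis rule
   (`detect_bad_channels()`): excess kurtosis z-scored across channels with
   the median/MAD, flagged above z = 5, plus flatlines.  The robust center
   matters: with ~10 channels, one extreme spike-train channel inflates a
   plain standard deviation enough to hide itself.  The false-positive rate
   on clean Gaussian montages is under 5% (tested over 100 seeds).
   Detection reads the *unfiltered* signals (flatlines and spikes are
   raw-signal properties; zero-phase filtering smears a constant channel
   with edge transients that defeat any flatline threshold), while removal
   happens after filtering so the operational order is unchanged.
2. **EMG** (`emg_for_cmc()`): 15–450 Hz band-pass, magnitude of the
   analytic signal (FFT construction, zero-padded to a fast composite
   length), z-score.  The envelope (modulus) rather than the real part of
   the analytic signal is used, consistent with z-scoring a one-sided
   amplitude quantity.
3. **Coherence** (`compute_coherence()`): Welch estimate with 128 ms Hann
   windows and 75% overlap (window 128 samples, hop 32 at 1 kHz), segments
   mean-detrended.  Coherence is computed on concatenated hold epochs only:
   CMC is defined during contraction, and rest periods would dilute it.

## The confidence level and the segment count

Each profile carries the analytic confidence level
$1 - \alpha^{1/(L-1)}$, the $(1-\alpha)$ quantile of coherence between
independent signals estimated from $L$ independent segments.  With
overlapping windows, what to use for $L$ is a genuine choice.  The package
default is the variance-equivalent ("effective") number of independent
segments of the overlapped Welch average,

$$L_{\mathrm{eff}} = \frac{K}{1 + 2\sum_m (1 - m/K)\, c_m^2},$$

with $K$ the overlapped segment count and $c_m$ the normalized window
overlap correlation at lag $m$ hops.  This choice is empirically
calibrated: on independent noise, the fraction of bins exceeding the
confidence level is ~5%, as the formula intends.  The two plausible
alternatives are both biased in coverage — counting raw overlapped segments
(`"raw"`) makes the level anti-conservative, and counting disjoint windows
(`floor(N/W)`, `"disjoint"`) makes it conservative by roughly a factor
of two in $L$ (measured coverage ~0.1% instead of 5%).  All three rules are
available through `segment_rule=`.

## Beta-band summary and laterality

In-band (12–30 Hz) coherence bins are variance-stabilized with the Fisher
transform $\operatorname{atanh}(\sqrt{C_f})$, scaled by $\sqrt{2L}$ to an
approximate standard-normal score, and combined over the $K$ in-band bins
with Stouffer's method, $\sum_f z_f / \sqrt{K}$ (`beta_band_summary()`).
With a 128-sample window at 1 kHz the in-band bins are 15.625 and
23.4375 Hz.  A hemisphere's summary pools the in-band bins of both task
muscles into one Stouffer combination — one number per hemisphere is needed
by the laterality index, and pooling bins is the most direct reading of
"combined with Stouffer's method" (summarizing per muscle and averaging is
the alternative; the pooled version weights both muscles equally and is the
package's fixed choice).  Peak CMC is the maximum raw in-band coherence;
frequency ties break to the lowest frequency for determinism.

The laterality index is

$$\mathrm{Laterality} = \frac{\mathrm{Coh}_{ipsi} - \mathrm{Coh}_{contra}}
 {\mathrm{Coh}_{ipsi} + \mathrm{Coh}_{contra}},$$

on the per-hemisphere Stouffer summaries: +1 means exclusively ipsilesional
coupling, −1 exclusively contralesional.  It is antisymmetric under
hemisphere exchange and bounded in [−1, 1] for nonnegative summaries (both
properties are tested over randomized inputs).  If C3 or C4 was removed as
a bad channel, a fixed same-hemisphere fallback order is used
(C3 → CP1, FC1, CP5, FC5; C4 → CP2, FC2, CP6, FC6), nearest sensorimotor
neighbors first.

# The synthetic generator

The generator exists to make every stage falsifiable, not to be a
biophysical simulator.

**EMG sessions** (`generate_emg_session()`): each channel is band-limited
(20–450 Hz) Gaussian noise whose amplitude envelope is the programmed group
level during holds and a small baseline at rest, scaled by a per-channel
electrode gain, plus gain-independent white sensor noise (2 µV RMS).
Because the 15–450 Hz analysis filter passes the 20–450 Hz carrier
essentially unchanged and normalization cancels channel gains, the
recovered ER equals `extensor_level / (extensor_level + flexor_level)` up
to estimation noise; the suite requires recovery within ±0.05 of the
programmed ratio across 20 seeds of the full 12-trial protocol.  The
sensor-noise floor also makes the hold/rest SNR proportional to the
electrode gain, so the feedback-channel selector can be tested against the
programmed gains.

**Coupled EEG/EMG** (`generate_coupled_eeg_emg()`): a narrowband Gaussian
beta source (default 20 Hz center, 2 Hz bandwidth — a pure sine would make
neighboring-bin coherence estimates degenerate) is injected into the EEG
with a per-hemisphere gain and amplitude-modulates the task muscles' EMG
envelope.  The source's scalp expression is focal: weight 1 at the
hemisphere's motor electrode, 0.3 at its neighbors.  This focality is load
bearing — a source expressed uniformly over a hemisphere is symmetrized by
common-average re-referencing (the montage mean contains half of it, and
subtracting that mean gives both hemispheres equal-magnitude expressions),
which would null the laterality index by construction regardless of the
gains.  Expected beta coherence for a hemisphere with gain $g$ is
approximately $g^2/(g^2 + \sigma_n^2)$ times an EMG-side attenuation
factor; this closed form is approximate (envelope extraction and CAR
leakage both perturb it), so tests assert monotonicity in $g$, the sign of
the laterality, and null coverage rather than exact equality.

**Clinical tables** (`generate_clinical_table()`): paired pre/post scores
for the full assessment battery (active ROM, ER, SIS subscales, FMA,
ARAT).  Defaults are the published group statistics of a nine-participant
cohort: pre mean/SD per measure, mean paired difference equal to the
reported post–pre change, and difference SDs back-computed from the
reported group t statistics ($sd_d = \bar d \sqrt{n} / t$).  Change scores
can be correlated across measures (default: ER-extension change with the
SIS Participation and Strength changes at r = 0.72/0.77, plus 0.6 between
the two SIS changes to keep the matrix positive definite).  Bounded
instruments are truncated to their score ranges, so extreme draws shrink
slightly toward the bounds.  What the generator does **not** model: floor
and ceiling effects beyond truncation, item-level SIS structure,
non-normal score distributions, and missing data — so passing tests say
the pipeline recovers its own generative parameters, not that real
clinical data meet these distributional assumptions.

All generators are pure functions of their configuration (including the
seed), which the determinism tests assert bit-exactly.

# Group statistics

Paired pre/post tests use `stats::t.test(paired = TRUE)`; correlations use
`stats::cor.test`; BH adjustment uses `stats::p.adjust(method = "BH")`.
The package wraps rather than reimplements them, but the test suite pins
their behavior against independent oracles: the paired-t formula evaluated
directly, numerical quadrature of the t density (agreement to 1e-6 over
df 1–30, |t| ≤ 10), and a brute-force step-up implementation of BH checked
on all subsets of a six-value grid.  Under null simulations at n = 9 both
tests show 5% ± 2% type-I error.

SIS domain scores use the instrument's standard transformation
((mean item − 1)/4 × 100, `sis_domains()`): Impairment is the normalized
Strength subscale, Function the unweighted mean of normalized ADL and Hand
Function (the simplest reading of "combined"), Participation the
normalized Participation subscale.

The BH family question deserves a note.  `correlation_matrix()` adjusts
within one declared family — by default all cells of one motor-measure ×
SIS-domain matrix at one timepoint — and records the family in its output.
Published correlation tables in this literature are not always
reconstructible from printed r values under any single family convention
(back-computing raw p from r at n = 9 matches some printed cells and not
others), so the package makes its family explicit rather than guessing,
and the group-level paired tests are left unadjusted, each domain being
treated as an independent hypothesis.

Group-level degrees of freedom in the worked examples: with n = 9
participants, paired tests have df = 8 and correlations df = 7; recomputed
two-sided p-values reproduce printed values to 3 decimals whenever the
printed statistic carries enough precision (statistics printed to 2
decimals limit agreement to ~0.003).

# Numerical and design choices, collected

* Linear interpolation for resampling; streams truncated to their
  overlapping interval before interpolation.
* CSV + YAML sidecar is the lossless recording format; EDF (16-bit,
  single data record) is supported for interchange, with quantization
  bounded by half a digital step of each channel's physical range.
* Cascaded 4th-order zero-phase Butterworth sections instead of one 8-pole
  band-pass (stability).
* Robust (median/MAD) kurtosis z for bad channels; flatline threshold at
  SD < 1e-8.
* `L_eff` overlap correction for the coherence confidence level
  (coverage-calibrated); alternatives exposed.
* Stouffer pooling across the two task muscles per hemisphere; peak ties
  to the lowest frequency.
* Coherence restricted to concatenated hold epochs.
* Screening threshold inclusive (≥), all trials must pass.
* Complete-case handling per test in `group_report()`, with the n used
  reported per row and absent measures listed rather than dropped.

## Problem sizes used by the test suite

Monte-Carlo checks run at sizes chosen to make their bounds sharp but the
suite practical on one CPU: the ER-recovery and laterality-sign checks use
the full 12-trial protocol and 6-trial sessions respectively (20 and 40
seeds); coherence-coverage and gain-monotonicity checks use 4–6-trial
sessions; statistical calibration uses 1000 null replicates at n = 9.

# Known limitations

* The coherence confidence level is asymptotic in L; for very short
  segments (L < ~10) its coverage is approximate.
* The generator's expected-coherence formula is documentation, not a
  calibration target; only monotonicity and signs are guaranteed.
* EDF support is deliberately minimal (16-bit, one data record, no
  annotations); it is an interchange convenience, not a full EDF+
  implementation.
* `group_report()` assumes one row per participant × measure; repeated
  sessions per timepoint must be aggregated upstream.
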