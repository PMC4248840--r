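---
title: "Methods: synthetic EEG workload studies and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic EEG workload studies and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`workloadbci` studies a binary operator-workload monitor: a classifier
that labels 30 s EEG epochs as *high* or *low* task demand and whose
performance is tracked as a function of the time gap between training
and test data. This vignette documents the generative model, the
estimation and training choices, the places where the design was
genuinely open and what was decided, and the limits of what the
synthetic studies can show.

## The signal model

Each channel is a sum of three parts, all in microvolts:

1. **Background**: Gaussian noise with power spectral density
   proportional to $1/f^{k}$, shaped exactly in the frequency domain
   (the scaling is clamped below 0.5 Hz so the variance stays finite,
   and the DC bin is removed) and rescaled to a target RMS. Defaults:
   $k = 1.5$, a typical resting-EEG slope, and 31 µV RMS. The RMS
   default is calibrated to the noise-correlation regime the package is
   meant to exercise: with 15 µV RMS of added white noise the expected
   clean-vs-noisy correlation is
   $1/\sqrt{1 + 15^2/31^2} \approx 0.90$, the region where
   noise-corrupted traces are still comparable to what dry-electrode
   validation studies report.
2. **Oscillatory components**: white noise passed through a 4th-order
   zero-phase Butterworth band-pass, normalized to unit RMS, and
   multiplied by a per-sample RMS envelope. This is the simplest
   generator whose band RMS can be set exactly. The envelope encodes
   the workload signature: inside high-workload blocks the component
   RMS is multiplied by its *workload gain*; across transition blocks
   the envelope interpolates linearly (transitions are discarded by the
   feature extractor anyway, the interpolation only avoids
   discontinuities). Defaults: a frontal-weighted theta component
   (5.5 Hz centre, 3 Hz bandwidth, 8 µV, gain 1.6) and a
   posterior-weighted alpha component (9.5 Hz centre, 5 Hz bandwidth,
   10 µV, gain 0.7) — increased theta and suppressed alpha under load,
   the standard direction of the effect. The magnitudes are chosen so
   that same-session separation is strong; they are deliberately *not*
   fit to any recorded data set.
3. **Blinks** (optional): Poisson-timed Gaussian-shaped pulses
   (~200 ms, default 0.2 Hz rate, 150 µV) carried on EOG channels at
   10× the weight of EEG channels — a crude but testable ocular
   topography.

Channel topography is a fixed channels × components weight matrix; the
default weights the theta component frontally and the alpha component
posteriorly, with small residual weights on the EOG channels. The
configured component RMS is the source RMS at unit mixing weight, so
power *ratios* between workload states are the same on every channel.

**Drift.** Component RMS multipliers follow a cumulative log-normal
walk: a step of SD `session_drift_sd` (default 0.15) between sessions of
a day and SD `day_drift_sd` (default 0.3) between days, per subject and
component. The variance of the accumulated log-multiplier grows with
the number of steps, so spectral statistics wander further apart at
longer separations and cross-session accuracy decays with scale — the
phenomenon the temporal protocols are designed to measure. Zero drift
reproduces a stationary study exactly. The default step sizes were
chosen once as "visible degradation over a week without destroying
within-day transfer"; there is no recorded-data estimate behind them.

**Schedule.** The default study is 8 subjects × 5 days × 3 sessions per
day, 15 min sessions at 256 Hz with 21 channels, each session holding
one 5 min high and one 5 min low block separated by at least 60 s of
transition. Nominal session spacing is 30 min within a day and 1 day
between days; these offsets only order the sessions and scale the gap
axis.

## Feature extraction

Band powers per 30 s epoch (7680 samples), advanced every 5 s, computed
only within contiguous high/low blocks so no epoch straddles a block
boundary. The transform length is 1024 samples, which does not divide
the epoch evenly in time — the epoch is split into seven consecutive
non-overlapping 1024-sample segments (remainder discarded) and their
magnitude-squared spectra averaged. A rectangular window with no
detrending is used. Averaged one-sided bin powers are summed over the
seven bands with half-open `[low, high)` edges and the Nyquist bin
assigned to the last band, so the bands exactly partition total power
(tested to 1e-9 relative). Features are absolute band powers; the
z-normalization absorbs overall scale. Normalization statistics are
always computed from training rows only — the prospective protocols
would otherwise leak future information through the feature scaling.

EOG channels are retained as feature channels: 19 + 2 channels × 7
bands = 147 features, which is the arithmetic the classifier input
width is built on.

## Classifier

A multilayer perceptron with five hidden layers of 10 tanh units each, a
2-unit softmax output and cross-entropy loss, trained by Møller's scaled
conjugate gradient. "Five hidden layers" is taken literally; a
five-*unit* single hidden layer — the other plausible reading — is
expressible as `net_config(hidden_layers = 5)`. Hidden activation,
output layer and loss are unstated in the tradition this follows; tanh +
softmax + cross-entropy is the standard pairing for SCG classification
training.

Per restart (10 by default) a class-stratified random half of the
training vectors is used for weight updates and the other half for
early stopping (training stops after 6 accepted steps without
validation-loss improvement; the weights with the best validation loss
are kept). The restart with the best validation loss wins. Weight
initialization is Gaussian with SD $1/\sqrt{\text{fan-in}}$. Everything
is driven by derived seeds, so a `(features, config)` pair fully
determines the returned network. Exact output ties in the argmax go to
"high", matching the ensemble's tie rule.

## Noise injection and the ensemble

Testing-with-noise only: networks are always trained on clean features.
Each of the 10 ensemble members adds an independent white Gaussian
stream (SD = the configured RMS, per channel and sample — white at the
recording's Nyquist bandwidth) to the raw recording, re-extracts
features and classifies; per-epoch majority vote breaks ties toward
"high". Noise is added to all 21 channels, EOG included, since EOG
channels feed the feature vector. Member seeds derive from the master
seed, the member index and the session identity.

The correlation study uses one designated channel (default the first
channel); which channel the original analysis used is unknowable from
the text, and for the stationary synthetic background all channels are
statistically equivalent.

## Protocols and statistics

*Same-session*: first 20 epochs (125 s) of each class block train the
network; an 11-epoch (80 s) window slides in 1-epoch (5 s) steps through
each class's remaining epochs. The step size is the finest consistent
choice; the windows are evaluated per class stream and pooled by time
gap (gap = end of test window − end of that class's training data).
*Cross-session*: minutes = first→second session of a day, hours =
first→last session of a day, days = very first session→every later
session, all subject-specific and strictly prospective, re-using the
same-session training segments and testing on every epoch of the test
session. *Leave-one-out*: per subject, train on all other sessions,
test on the held-out one — the non-causal average benchmark. Overall
figures always average per-session accuracies first, then per subject,
then across subjects.

The chance-level resampler replaces the classifier with a fair coin
(p = 0.5 per epoch regardless of class balance, as a deliberate
definition of "chance") and analyzes it identically; 1000 runs on the
default study structure give a mean of 50.0%. The paired-run statistics
are the all-successes probability $p^n$ and the exact Clopper–Pearson
lower bound, computed from the beta quantile and equal to
$(\alpha/2)^{1/n}$ when all $n$ runs succeed. The repeated-measures
ANOVA that sometimes accompanies such comparisons is out of scope; the
binomial analysis is the implemented significance machinery.

## Problem sizes

The shipped tests run on reduced studies chosen to exercise every code
path at desk scale: sessions with 200 s workload blocks (35 epochs per
class: 20 training + 15 test), one-subject 2-day × 3-session studies
for the drift properties (10 replicates), and a 2-subject × 2-day × 3-
session end-to-end run with the 0/5/10/20 µV noise sweep. The
chance-level and binomial results use the full default 120-session
structure, which costs almost nothing because no signal needs to be
generated for them.

## Limitations

- The generator emulates *spectral statistics*, not physiology: no
  cortical sources, no volume conduction, no EMG, no electrode
  drift/pops, and only blink-type artifacts. Passing tests demonstrate
  the pipeline's correctness and its qualitative temporal behaviour,
  not performance on recorded EEG; the headline accuracies of real
  competition data are not reproducible from simulation and are not
  claimed.
- The synthetic background has much lower high-frequency power and
  epoch-to-epoch band-power variability than real recordings (which
  carry EMG and instrumentation noise). Consequently injected test-time
  noise shifts the upper-band features by many training-set standard
  deviations and degrades accuracy at noise levels real data tolerated;
  the noise sweep in the pipeline documents this honestly rather than
  reproducing a stochastic-resonance enhancement, which at these
  magnitudes (< 1% on real data) is below what a desk-scale synthetic
  study can resolve.
- Drift is a log-normal random walk on component amplitudes only;
  real nonstationarity also moves peak frequencies, topographies and
  artifact statistics.
- The EDF writer quantizes to 16 bits over each channel's observed
  range (relative error ≤ range/65535); the internal container is
  lossless and preferred for round-tripping synthetic studies.
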