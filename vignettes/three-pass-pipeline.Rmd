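---
title: "The three-pass EEG event classification pipeline: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The three-pass EEG event classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegevents)
```

This vignette documents the science and the engineering decisions inside
`eegevents`: the models each pass implements, the parameters that matter
and their defaults, what the synthetic data generator does and does not
emulate, and the choices made where the design was genuinely open. It
states no empirical number that the test suite or `scripts/acceptance.R`
does not itself compute.

## Problem setting

Clinical EEG records are annotated per channel with six event classes:
three of clinical interest — SPSW (spike and/or sharp waves), PLED
(periodic lateralized epileptiform discharges, repeating at 0.5–3 s
intervals over one hemisphere), GPED (generalized periodic epileptiform
discharges, bilaterally symmetric) — and three that model non-pathological
signal: EYEM (eye movement transients, frontal), ARTF (non-cerebral
artifact) and BCKG (everything else). The classes are heavily imbalanced:
background dominates, spikes are rare. The scoring unit is the 1 s epoch,
fixed pipeline-wide; signals are canonicalized to 250 Hz and the standard
22-channel temporal-central-parasagittal (TCP) bipolar montage.

## Pass 1: cepstral features and GMM-HMM decoding

**Features.** Each channel is cut into 0.2 s analysis windows every 0.1 s
(`frame_step`), Hamming-tapered and transformed with a 64-point FFT. A bank
of 24 triangular filters, linearly spaced over 0–125 Hz with 50% overlap,
pools the power spectrum; an orthonormal DCT-II of the log filter outputs
yields cepstral coefficients, of which coefficients 1–7 are kept (the
zeroth is discarded in favor of an explicit energy term). Two energy
features complete the nine absolute features: the log total energy
`E_f` and the differential energy `E_d`, the max-minus-min of `E_f` over a
centered 0.9 s (9-frame) window — a transient detector by construction.
Regression deltas with half-window 9 and delta-deltas with half-window 3
are appended; the `E_d` delta-delta is dropped, giving 9 + 9 + 8 = 26
dimensions per frame.

Open parameter choices here (filter count 24, FFT size 64, Hamming taper,
band 0–125 Hz) are conventional spectral-analysis values; all are exposed
in `feature_config()`. Numerical choices: logs are floored at `1e-10` so
silent frames stay finite; delta edges replicate boundary values; the `E_d`
window is clipped at record edges; the final analysis window is zero-padded
so the frame count is exactly `duration / frame_step`. The energy sum runs
over the filter-bank outputs by default (`energy_from = "filterbank"`),
with a config switch to raw FFT bins — the two conventions differ only by
the filter-bank's overlap gain. There is no pre-emphasis: EEG has no
speech-like spectral tilt convention.

**Models.** One left-to-right HMM per class, three emitting states with
self-loops (the state count is configurable; 10 frames per epoch supports
3 well), each state an 8-component diagonal-covariance Gaussian mixture.
Training is channel-independent: every annotated 1 s epoch on every channel
is pooled by its class (an epoch overlapping several labels on a channel
takes the label covering the majority of it). Initialization is a flat
start from the global mean/variance with a small deterministic per-state
stagger; mixtures grow by binary splitting (1→2→4→8, means perturbed
±0.2 sd) with a few Baum-Welch iterations per stage; variances are floored
at `1e-3` of the global per-dimension variance. The forward-backward
recursions are scaled per frame; the scaled per-row emission rescaling
keeps 26-dimensional log-densities inside floating-point range.

**Decoding.** Each 1 s epoch of each channel is scored by all six models'
forward log-likelihoods, converted to a posterior by log-sum-exp
normalization with a flat class prior. A flat prior is deliberate: the
empirical class prior is so skewed that applying it would drown the rare
classes, and the later passes are the designed place for contextual
correction. Decoding is per-epoch (forced choice) rather than
whole-channel Viterbi segmentation; `viterbi()` is provided and
oracle-tested but the epoch grid is the interface between passes.

## Pass 2: spatial and temporal context via stacked denoising autoencoders

The 6 scores × 22 channels of one epoch form a 132-dimensional supervector
(channel-major order). A global PCA (fit on the training corpus) reduces
it to 20 dimensions for the 6-way classifier and 13 for the two binary
detectors; outputs are min-max scaled to [0, 1] using training bounds
(clipped at apply time) so that sigmoid reconstruction with a
cross-entropy loss is well-posed. The binary branch additionally averages
each three consecutive reduced vectors (sliding window, edges clipped).
Temporal context comes from stacking a centered window of consecutive
epoch vectors — 3 epochs for the binary detectors (13 × 3 = 39 inputs), 41
for the 6-way network (20 × 41 = 820 inputs) — with boundary epochs
replicated at record edges.

Each network is a stack of tied-weight denoising autoencoder layers
(sigmoid nonlinearities) pre-trained greedily and unsupervised: inputs are
corrupted by masking-to-zero noise at level 0.3 per layer, and each layer
minimizes the reconstruction cross-entropy of the clean input by plain
minibatch SGD. Masking noise is the classic corruption type for this
architecture; only the level is a stated constant. Fine-tuning appends a
softmax head and trains the whole encoder end-to-end on the negative
log-likelihood. The epoch-level training label is a clinical-priority vote
across channels: SPSW > PLED > GPED > EYEM > ARTF > BCKG, i.e. an epoch
counts as the most clinically significant thing seen on any channel. Rare
classes (SPSW, EYEM) are augmented in the fine-tuning sets by convex
interpolation between same-class nearest neighbors plus Gaussian jitter at
0.05 of the class standard deviation.

The *enhancer* merges the three outputs. The 6-way posterior initializes
the result; if a binary detector is confident (posterior > 0.5) while the
6-way classifier assigns its block — {SPSW, PLED, GPED} for the
epileptiform detector, {EYEM} for the eye-movement detector — no more than
half of the total mass, the block is rescaled to carry exactly the
detector's mass, preserving internal ratios (an all-zero block splits
equally), and the complement is rescaled to the remainder. Agreement is
defined on block mass rather than on the argmax so that the override
arithmetic is well-defined for ties and near-uniform posteriors.

Two training profiles ship in `pipeline_config()`. The `"full"` profile
uses the full-scale architecture and schedules (hidden layers 100/100/100
for the detectors and 800/500/300 for the 6-way network; pre-training at
learning rate 0.5 for 150–200 epochs with batch 300; fine-tuning at
0.1–0.2 for 100–800 epochs with batch 100), sized for a large annotated
corpus. The `"test"` profile is this package's scaled-down configuration
for the synthetic corpus the suite trains on (hidden 40/40 and 100/60,
pre-training at 0.05 for 15 epochs, fine-tuning at 0.1 for 300–600 epochs,
batch 50); the smaller learning rates reflect that plain SGD on the
820-input network is unstable at this data scale with the full-scale rates.
The examples, tests and acceptance script use the test profile with a
50-record, 60 s corpus — problem sizes chosen so the whole pipeline trains
in minutes on one CPU while leaving each pass something real to learn.

## Pass 3: iterative bigram-grammar smoothing

The packaged 6 × 6 bigram table encodes clinical context: PLED runs are
long (self-transition 0.90), grouped spikes are periodic discharges rather
than SPSW (P(PLED→SPSW) = 0), background transitions are permissive. Two
rows (ARTF, BCKG) sum to 1.02 due to rounding; they are stored verbatim, with
a `renormalize` flag at load. A count-based estimator
(`estimate_bigram_grammar()`) is provided as a utility, but the packaged
table is the operating default.

Each iteration recomputes: the file prior
`P_gprior = (Σ_i P_i + ε·M)/(L + M)` over the L epoch posteriors; left and
right context distributions as exponentially decayed sums
`Σ_{i=1..N} exp(−iλ) P_{k±i}` over N = 10 neighbors per side (out-of-range
neighbors are skipped — no phantom context is invented), blended with the
file prior at weight α and normalized; and the per-epoch update: class c is
re-weighted by `[Σ_i LPP(i)·Prob(i,c)]·[Σ_j RPP(j)·Prob(c,j)]` raised to
the grammar exponent, then renormalized. Defaults: ε = 0.1, M = 1,
λ = 0.2, α = 0.1, γ = 1, up to 20 iterations, stopping when the argmax
labels are stable between iterations.

The grammar exponent is implemented as γ/n at iteration n (annealed
influence), switchable to γ·n via `grammar_config(anneal = FALSE)`. The
annealed form is the package's interpretation: a growing exponent would
amplify the grammar factor geometrically across iterations and work
against the stated label-convergence behavior, while annealing makes later
iterations refine rather than overwrite. The context sums in the update
are read as sums over the six classes (LPP/RPP are class distributions),
and all normalization constants are normalize-to-unit-sum. The file prior
uses the current iteration's posteriors rather than the original pass-2
outputs, so the prior sharpens as the file's labeling stabilizes.

## The synthetic corpus generator

`generate_record()` emulates the statistical structure the pipeline
assumes, not EEG biophysics: 1/f background noise (15 µV RMS at
`noise_level = 1`) on all 22 montage channels, plus stylized events placed
on whole epochs — biphasic 20–70 ms transients at ~120 µV on 1–4 focal
channels (SPSW); periodic discharge trains with inter-discharge intervals
drawn from 0.5–3 s, lateralized to one hemisphere's derivations with a
sharp 70 ms waveform (PLED) or on all channels with a blunter 200 ms
waveform (GPED); 0.3–0.5 s half-sine deflections at ±150 µV on the four
frontal derivations (EYEM); and broadband noise bursts on a random channel
subset (ARTF). Amplitudes were fixed once at physiologically plausible
ratios to background. A record never contains both PLED and GPED, and
`generate_corpus()` assigns the periodic kind per record by deterministic
stratification so small corpora realize both in proportion to the mix.

Two class-mix profiles exist: `"easy"` (moderate imbalance, 45% background
epochs, high SNR — the testing default) and `"hard"` (clinical-style
imbalance with <1% SPSW and ~64% background, doubled noise). Annotations
are epoch-aligned and cover every channel (explicit BCKG rows fill the
gaps), which makes reference labels exact.

What passing tests on this corpus shows: that every stage computes what it
claims, end to end, and that the architecture's division of labor works —
per-channel decoding is sensitive but false-alarm-prone, spatial context
separates lateralized from generalized discharges, and grammar smoothing
removes isolated label noise. What it does not show: performance on real
EEG, where waveform morphology, artifacts and annotation ambiguity are far
richer than the generator's stylized events.

## Numerical and interface conventions

Time intervals are half-open `[start, stop)` seconds; annotation channel
indices are 0-based in the CSV dialect (matching the on-disk format) and
converted at use sites. Resampling is Fourier-domain (spectrum truncation
or zero-extension), which is zero-phase, delay-free and applies an ideal
anti-alias low-pass; records below 250 Hz are upsampled with a warning.
The EDF writer chooses per-channel physical min/max headers to cover the
data, bounding quantization error at one least-significant bit of a 16-bit
scale, and zero-pads to whole-second data records. The TCP montage pair
list (22 derivations over the 10/20 electrode set) ships as the packaged
default and can be overridden by a YAML pair list. All stochastic stages
(corpus generation, weight initialization, corruption, minibatch order,
augmentation) derive their seeds from a single pipeline seed; identical
seeds give bit-identical corpora, bundles and decodings.

Scoring follows the field's conventions: event-based scoring counts each
(channel, epoch) pair, epoch-based scoring counts epochs after the same
priority vote used in training. Because this application area commonly
reports a false-alarm-style quantity under the name "specificity", the
2-way scores expose both `false_alarm_rate` (% of background units called
target) and `specificity_conventional` (100 minus that), explicitly named.
DET curves sweep a penalty subtracted from the target score (`score − p >
0.5` decides target), and the zero-penalty point reproduces the
forced-choice 2-way operating point by construction.

## Known limitations

- Pass-1 posteriors use a flat class prior; applications needing
  calibrated probabilities under clinical priors should re-weight.
- The SdA optimizer is plain minibatch SGD by design; it requires the
  profile-appropriate learning rates and is sensitive to scale.
- The grammar's monotone-smoothing behavior is an aggregate property: on
  individual adversarial sequences a stronger grammar weight can flip
  epochs away from their local context majority, because the packaged
  table encodes asymmetric clinical biases, not pure smoothing.
- Channel-dependent HMMs, full covariances, learned grammars and recurrent
  architectures are out of scope.
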