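---
title: "Evaluating reconstructed speech waveforms: metrics, models, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reconstructed speech waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavescore)
library(dplyr)
```

## The problem

Speech brain-computer interfaces that reconstruct audio waveforms from
intracranial recordings are evaluated, across the literature, with an
inconsistent mix of objective metrics — correlation coefficients computed
over different window lengths, occasionally STOI or mel cepstral
distortion — which makes results from different studies incomparable.
Correlation-based measures ignore absolute spectral level; distance-based
measures punish level offsets that listeners barely notice. wavescore
implements a standardized evaluation pipeline around that observation: a
fixed feature substrate, the individual metrics with their known failure
modes made explicit, and predictive models that map the objective metrics
to a perceptual target (the mean opinion score, MOS), validated by grouped
cross-validation.

## The feature substrate

All objective metrics operate on mel-frequency cepstral coefficients
(MFCCs) of whole utterances, silent periods included — a reconstruction
that produces spurious noise during silence should pay for it. Defaults,
recorded in every metric record via `feature_config()`:

* sample rate 16 kHz (speech-band standard; inputs are resampled on load),
* 25 ms Hann frames, 10 ms hop, 40 mel bands, 13 cepstral coefficients,
* log mel energies floored 80 dB below the loudest band of the utterance
  (an absolute fallback guards all-zero input).

The dynamic-range floor deserves a note: with an absolute floor, the log
energies of near-silent bands are dominated by the recording noise floor,
and cepstral distances between two recordings with different noise floors
explode into values that carry no perceptual information. The relative
floor bounds the usable dynamic range at 80 dB, keeps the cepstra
covariant under global gain (a scaled waveform changes only c0), and turns
digitally silent stretches into constant frames, which the segment metric
then skips by its constant-segment rule.

## The metrics

**CC** (`cc_full()`): Pearson correlation between the flattened MFCC
matrices of reference and reconstruction. One number per utterance; its
value depends strongly on how much audio is pooled, which
`cc_window_sensitivity()` quantifies by splitting a pair into windows of
several lengths. When the two signals share coarse energy structure
(bursts and pauses) but not fine structure, mean CC rises with window
length — the inflation that makes CC values from studies with different
window conventions incomparable.

**STOI variant** (`stoi_mfcc()`): the mean over consecutive,
non-overlapping short-time segments (default 30 frames ≈ 300 ms) of the
Pearson correlation between the flattened reference and reconstruction
sub-matrices. Segments where either side is constant are skipped and
counted rather than scored 0, so silence does not inject arbitrary values
into the mean; trailing frames that do not fill a segment are dropped.
With a single segment spanning all frames the score reduces exactly to
`cc_full()` on the same matrices. Correlations are computed on the
flattened segment (all coefficients jointly); a per-coefficient variant
was considered and rejected as the default because the definition used
here writes one correlation per segment.

**MCD** (`mcd()`): `(10/ln 10) · sqrt(2) ·` mean over frames of the
Euclidean distance between cepstral vectors, in dB, excluding the energy
coefficient c0 by default (conventional; configurable and recorded).
MCD is zero iff the compared coefficients are identical, symmetric in its
arguments, and strictly sensitive to constant spectral offsets that leave
the segment correlations untouched — the two metrics dissociate, which is
the package's central diagnostic.

**Complexity** (`normalized_entropy()`): the Shannon entropy of the whole
time–frequency magnitude matrix, treated as one discrete distribution and
normalized by `log(cell count)` to `[0, 1]`. Natural logarithms are used;
the normalized ratio is base-invariant. The measure is invariant to
global amplitude scaling. Narrowband single-burst utterances score low;
broadband multi-syllable material scores high. The normalization is a
package choice: only on a `[0, 1]` scale is a fixed threshold such as 0.7
meaningful across recordings.

## Predicted MOS

The subjective target is the MOS: the flat arithmetic mean of all integer
1–5 ratings a trial received, over raters and repetitions
(`mos_scores()`). Panel consistency is summarized by Cronbach's alpha
with raters as items (`cronbach_alpha()`); repetitions are averaged
within rater first, since alpha is defined over raters-as-items, and
variances use the unbiased n−1 estimator.

Three predictors map the objective metrics to MOS:

* **Piecewise linear scorer** (`piecewise_scorer()`): two linear models in
  (MCD feature, STOI), gated by the normalized entropy of the reference at
  threshold 0.7. The default coefficients are the published ones — low
  regime `0.101 + 0.544·MCD + 0.089·STOI`, high regime
  `0.921 − 0.892·MCD + 0.223·STOI`. Entropy exactly at the threshold uses
  the high regime (the published form leaves equality undefined; ties go
  up). `fit_piecewise()` refits both regimes by ordinary least squares and
  requires at least 3 samples per regime.
* **SVR** (`fit_scorer(kind = "svr_rbf")`): RBF-kernel support-vector
  regression, cost 1, kernel width from the inverse feature-variance
  heuristic.
* **Random forest** (`fit_scorer(kind = "random_forest")`): 500 trees,
  unrestricted depth.

The trainable models take only STOI and MCD as inputs — entropy gates the
piecewise baseline but is not a regression feature. Because MCD is
unbounded and in dB while the published piecewise coefficients only make
sense on a bounded, unitless input, raw MCD is min–max normalized over
the training pool; the affine map is stored with every fitted model and
applied identically at prediction time. The default scorer evaluates its
linear form literally on whatever `mcd_feature` it is given, so the
published coefficients are reproduced exactly rather than re-derived
(their original normalization is not stated anywhere we could verify).
Scores from the published coefficients are treated as normalized quality;
refitted models are on whatever scale their training MOS was.

## Cross-validation

`cross_validate()` implements leave-one-dataset-out (LODO; one fold per
dataset label) and leave-one-trial-out (LOTO). Per fold the model — and
the MCD min–max map — are fitted on the training rows only. All
out-of-sample predictions are aggregated first and R² / MAE computed once
on the aggregate; fold-averaged metrics are a different quantity in
general and are deliberately not reported. R² is the standard coefficient
of determination about the aggregate truth mean and can be negative out
of sample. Folds on which the piecewise model cannot be fitted (an
entropy regime falls under 3 training samples) are flagged, skipped with
a warning, and excluded from the aggregate rather than imputed. Fold
iteration order is sorted by group label for reproducibility, and every
stochastic fit derives its seed from the report seed and fold index.

## The synthetic benchmark

No public corpus pairs reconstructed BCI audio with released ratings, so
the package ships a generator whose defaults emulate the shape of the
published multi-dataset pool: 10 datasets of 4–19 trials, utterance
durations averaging 1.3–3.4 s per dataset, and a simulated panel of 14
raters × 3 repetitions.

`synth_utterance()` produces two material classes. *Simple*: one harmonic
burst (f0 100–250 Hz, 2–3 formant resonances, steep source rolloff) under
a single bell envelope — a stylized monosyllabic word. *Complex*: 2–6
bursts with distinct formant patterns mixed with broadband
fricative-like noise, separated by pauses. Per-utterance heterogeneity
(rolloff, burst width, breathiness) is deliberate: complexity forms two
overlapping distributions rather than two points, with complex material
higher on average — so an entropy gate at a fixed 0.7 is right for most
but not all trials, as a trial-and-error threshold on real data would be.
A −60 dB noise floor underlies every utterance; silence is never
digitally zero.

`degrade()` applies three mechanisms, each mapped onto a documented
failure mode:

* additive white noise (`noise_sd`) — the generic quality axis;
* a time-invariant spectral tilt (`spectral_offset_db`, ±offset/2 dB
  across the band) — adds a near-constant vector to every frame's
  cepstrum, inflating MCD while leaving segment correlations ≈ 1. A flat
  gain would move only c0, which the default MCD excludes, so the tilt is
  the minimal spectral-domain offset that the energy-excluded cepstra can
  see;
* `envelope_only` — replaces all fine structure with noise shaped by the
  utterance's long-term average spectrum (~100 Hz smoothing) and
  modulated by its short-time energy envelope (20 ms by default;
  configurable down to burst-level coarseness). On simple material this
  "bad but plausible" reconstruction keeps segment correlations above
  0.9 while being audibly wrong.

`make_benchmark()` draws a latent quality `q ∈ [0.05, 0.95]` per trial
and maps it monotonically to degradation strength (white noise at
`0.08 (1 − q)`; this scale is the range over which the segment score and
MCD respond monotonically to quality on this material — beyond it both
saturate and the benchmark would carry no quality signal). The first
dataset is an extreme envelope-only family at low quality — its noise is
kept low, `0.02 (1 − q)`, precisely so its segment correlations stay
deceptively high while its MOS is poor. The last dataset is an 8 dB tilt
family at high quality (high MCD, high MOS). Milder versions of both
pathologies occur throughout, sampled conditionally on material kind
(envelope substitution with probability `0.5 (1 − q)` on simple
material, tilts uniform on 0–5 dB on complex material), so a
cross-validation training fold always contains the feature-space
directions the extreme families occupy — without them, a held-out
pathological dataset would be a pure extrapolation problem no model
could solve. Ratings come from a latent-score model: trial latent
`1 + 4q`, per-rater bias (sd `rater_sd/2`), per-rating noise (sd
`rater_sd`, default 0.3), rounded and clipped to 1–5. All randomness
descends from one master seed through named substreams.

On this benchmark the entropy-gated linear baseline generalizes poorly
across datasets (its aggregate out-of-sample R² is often near or below
zero — its two fixed-gate linear surfaces cannot represent the
high-correlation/high-distortion pocket the envelope family occupies),
while the random forest remains positive; the model-comparison test
asserts exactly this ordering over repeated benchmark regenerations, not
any absolute R² value, which on synthetic material is not comparable to
values reported on real recordings.

What the generator does *not* emulate: real vocoder artifacts, temporal
misalignment between reference and reconstruction, rater fatigue or bias
drift, and the acoustic diversity of actual speech corpora. Passing
tests on this benchmark therefore demonstrates that the pipeline
measures what it claims on controlled material with known ground truth —
not that any particular model generalizes to a specific real dataset.

## Problem sizes and numerical choices

The test suite runs the model comparison on 10 regenerations of the
default 79-trial benchmark, the window-inflation check on 20 seeds of a
12 s utterance, the dissociation fixtures on 20 seeds each, and the
piecewise parameter-recovery simulation on 100 seeds of 200 samples per
regime — sizes chosen so the full suite completes in minutes on one CPU
while keeping the statistical checks well-powered. Degenerate inputs
follow explicit contracts: constant sequences have no correlation
(error), all-zero spectrograms no entropy (error), constant truth no R²
(error), min–max transforms of constant pools map everything to 0.5.
Correlation ties in regime gating go to the high-entropy regime. The
resampler uses `signal::resample` with the exact rational rate ratio.

## Known limitations

The STOI variant here is the MFCC segment-correlation form, not the
canonical third-octave-band STOI with clipping; an external STOI can be
substituted upstream, but every documented property in this package
refers to the variant. No time alignment beyond truncation/padding is
performed (dynamic time warping is out of scope), so systematically
delayed reconstructions are penalized by all metrics. MCD values on
synthetic material are larger than the 4–8 dB typical of vocoded natural
speech because the synthetic dynamic range is wider; the min–max feature
map absorbs the scale for modeling, but absolute synthetic MCDs should
not be compared against published values on real speech.
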