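---
title: "Detecting focal sources in atrial fibrillation electrograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting focal sources in atrial fibrillation electrograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastegm)
```

## The problem

During atrial fibrillation (AF), localized focal sources may drive the
arrhythmia from sites outside the pulmonary veins. At the epicenter of a
focal source the unipolar electrogram (EGM) shows a characteristic
footprint: a sustained train of periodic, purely negative **QS complexes**,
reflecting centrifugal spread of activation away from the recording site. A
recording site showing this footprint over a full 5-s acquisition is called
a **FaST site** (Focal Source and Trigger), and is a candidate ablation
target beyond pulmonary-vein isolation.

`fastegm` implements the full analysis chain on paired 5-s unipolar/bipolar
recordings sampled at 1,000 Hz:

1. a **rule-based hierarchical detector** (`classify_fast()`): bipolar
   spectral periodicity, graph-search annotation of the periodic activation
   train, and unipolar R/S morphology classification at the annotated
   onsets;
2. a **1-D residual convolutional classifier** (`train_model()`,
   `predict()`) that maps the raw (downsampled, scaled) unipolar trace to a
   FaST probability, with classic baselines (`fit_baseline()`);
3. **Grad-CAM importance traces** (`gradcam_trace()`) that visualize which
   parts of the 5-s trace the classifier relied on;
4. an **evaluation harness** (`roc_auc()`, `operating_points()`,
   `cross_validate()`, `cohen_kappa()`) with patient-level splits;
5. a **synthetic record generator** (`synth_record()`, `synth_cohort()`)
   with complete ground truth, so every stage can be tested end to end
   without access to clinical recordings.

## The rule-based FaST algorithm

A site is FaST when both of the following hold over the 5-s recording.

**Sustained bipolar periodicity.** The bipolar trace is band-pass filtered
40–250 Hz, rectified, then band-pass filtered 0.5–20 Hz (all zero-phase,
4th-order Butterworth applied forward–backward; the band-pass is realized
as a high-pass/low-pass cascade because a direct high-order design at a
normalized corner of 0.001 is numerically ill-conditioned). The spectrum of
this envelope is searched over the physiologic atrial cycle-length (CL)
window 100–250 ms (4–10 Hz). Periodicity is declared when the peak bin,
together with one adjacent bin on each side (5-s records give 0.2 Hz
resolution), carries at least 10% of the total envelope power over
0.5–20 Hz. The periodicity CL is the inverse of the peak frequency.

Because the rectified envelope of a pulse train carries strong harmonics of
the true rate, the implementation applies a standard **harmonic guard**: if
the subharmonic at f/2 or f/3 of the in-window peak holds at least half the
peak's neighborhood power (`subharmonic_ratio = 0.5`), the subharmonic is
taken as the activation rate. This both recovers trains whose second
harmonic happens to out-power the fundamental (e.g. CL ≈ 220 ms) and
rejects slow trains (e.g. CL 500 ms) whose 4 Hz harmonic falls inside the
window while the true rate lies outside it.

**Periodic activation train.** Candidate activations are local maxima of
the band1-filtered bipolar trace exceeding 0.05 mV with a maximum slew rate
above 0.014 mV/ms within ±10 ms, separated by a 50 ms refractory period
(below half the minimum CL, so fractionated deflections are not double
counted). A dynamic program then finds the longest chain of candidates
whose consecutive intervals lie strictly within CL ± 25%, breaking ties by
minimal total cost (sum of |interval − CL|) and then by earliest start.
This reconstruction honors the published objective — the greatest number of
consecutive candidate activations at the extracted CL with the lowest total
deviation — and is verified in the test suite against exhaustive
enumeration over all increasing subsequences for candidate sets up to size
12. The train is **sustained** when the chain covers at least 90% of the
expected beats (duration / CL).

**Unipolar QS morphology.** Chain times are transposed onto the unipolar
trace. In a window of −20 to +80 ms around each onset, R is the maximum
positive and S the maximum negative deviation from a baseline taken as the
median of the 10 ms preceding the window. A complex is QS when
R/S < 0.1. Before measurement the trace is smoothed with a 7-ms moving
average so that broadband noise maxima are not mistaken for R waves;
complexes whose S amplitude falls below the 0.05 mV noise floor are flagged
indeterminate and excluded from the QS fraction (counting them as non-QS
would penalize genuinely low-amplitude QS trains near the PV ostium). The
site is FaST when it is periodic, sustained, and more than 90% of
determinate complexes are QS.

All times are in ms from record start; sample index 0 corresponds to
t = 0 ms.

## The deep classifier

The classifier consumes the raw unipolar trace downsampled to 200 Hz by
Fourier truncation (`resample_fft()`) and min-max scaled to [0, 1]
(length 1000 for a 5-s record). The network is the standard 18-weighted-
layer 1-D residual topology: a kernel-7 stride-2 stem with max-pooling,
four stages of two residual blocks (each block two kernel-3 convolutions
with batch normalization, a ReLU and an identity or projection shortcut;
the first block of stages 2–4 halves time resolution and doubles channels),
global average pooling, dropout (rate 0.2) and one fully connected logistic
output. Descriptions of this architecture sometimes count its pieces as
"four residual blocks" (the stages) and sometimes as "five convolutional
blocks" (stem plus stages); the topology shipped here is the standard one
under either count. Weights are He-initialized; training minimizes binary
cross-entropy with Adam under either a reduce-on-plateau schedule (factor
0.5, patience 3, on validation AUC) or cosine annealing, and returns the
epoch checkpoint with the best validation AUC. A grid-search utility
(`grid_search_cnn()`) ranks batch size (32/64/128), initial learning rate
(1e-2/1e-3/1e-4) and schedule by patient-level cross-validated AUC; the
packaged defaults (batch 64, learning rate 1e-3, plateau schedule) sit in
the middle of that grid.

The forward and backward passes are implemented directly in R on top of
BLAS matrix products (im2col convolutions), with analytic gradients for
every layer; the test suite verifies them against central finite
differences to relative error below 1e-8. This keeps the package
dependency-free and the experiments fully reproducible: with fixed seeds,
two training runs produce bit-identical histories.

Four stochastic augmentations are available during training, each applied
independently with a configurable probability (default 0.5): a constant
baseline shift drawn from N(0, 0.1); i.i.d. Gaussian noise (sd 0.05);
cropping, which zeroes a contiguous 5–15% segment; and resampling, which
deletes a 5–15% segment and Fourier-stretches the remainder back to the
original length (slowing the waveform by the deleted fraction). Magnitudes
are package defaults — the augmentation mechanisms are established, their
clinical magnitudes are not published. Scaling is re-applied after
augmentation so the network always sees [0, 1] inputs (otherwise a baseline
shift would be undone exactly by the scaler).

Classic baselines operate on the same length-1000 vectors:
ridge-penalized logistic regression (`glmnet`; the ridge keeps the model
defined when features outnumber records), polynomial-kernel SVM of degree 3
or 10 (`e1071`), and k-nearest-neighbours with k = 10 or 50 (`class`).

## Grad-CAM importance traces

`gradcam_trace()` probes a convolutional layer of the network (default
`stage3.block0`, the first block of the third stage): channel weights are
the time-averaged gradients of the output logit with respect to that
layer's activation map, the trace is the rectified weighted sum of the
maps, linearly interpolated to the input length and max-normalized (the
pre-normalization peak is kept as `cam_max` so absolute importance can be
compared across records). A guided variant multiplying by a
guided-backpropagation saliency is available behind a flag; the plain
variant is the default output. Peaks are local maxima above 0.5 of the
normalized trace with 50 ms minimum separation, and `peak_alignment()`
quantifies their distance to ground-truth complex onsets.

Which tensor inside a residual block counts as "the convolutional layer"
is a genuine design choice, and the capture points behave differently: a
bare block id probes the block's **first convolution** (its
post-normalization ReLU activation), whose importance peaks sit slightly
*before* the complex onset, in the region where an R wave would have been;
the suffix `.out` probes the post-residual block output, whose peaks sit
30–50 ms *after* the onset at the recovery upstroke; `.conv2` probes the
second convolution. The first convolution is the default because it is the
block's convolutional feature map proper (the block output is a sum
junction) and because it aligns most closely with the complexes
themselves. On synthetic records the trace is strongly class-
discriminative under any capture point: near zero on periodic RS trains
and on ventricular far-field-only records, active at QS complexes.
Cubic-spline interpolation of the coarse activation grid was evaluated as
an alternative to linear interpolation and did not improve alignment, so
the simpler linear scheme is kept.

Which *network layer* best tracks the complexes also varies from one
trained model to another (different training runs distribute the same
discriminative evidence across depths differently). The interpretability
analysis therefore begins with a layer-identification step,
`select_gradcam_layer()`: a probe sample of ten QS-train records is run
through Grad-CAM at each candidate layer (the four blocks of stages 2 and
3 by default) and the layer whose peaks best track the true complex onsets
— pooled fraction of peaks within a quarter cycle length — is kept for the
full analysis on a disjoint evaluation sample.

## The synthetic generator

Because the clinical recordings behind the method are not publicly
available, the package generates labelled records that emulate the
documented morphologies: sustained periodic QS trains at CL 100–250 ms
(typical, low-amplitude, and broad/slurred variants — the FaST classes);
periodic RS trains; rS trains with small r waves (R/S 0.15–0.3, above the
0.1 cut-off but visually QS-like); records switching from RS to QS at
1.4 s (QS fraction 0.72, below the 90% criterion); non-sustained QS trains
(activity covering 40–70% of the record); fractionated activity; and
aperiodic activity. Default cohort prevalence of the FaST classes is 9.2%.

Waveshapes are stylized: QS is an inverted raised-cosine dip (width
30–50 ms, amplitude 0.5–2 mV; low-amplitude variant 0.2–0.35 mV; slurred
variant 60–90 ms wide), RS/rS prepend a half-sine R lobe with an exact
amplitude ratio, fractionated complexes are three jittered biphasic
sub-deflections within 60 ms, and ventricular far-field complexes (present
in 30% of records) are 120-ms-wide low-slew biphasic waves at CL
600–1,000 ms added to the unipolar trace. The bipolar companion is a sharp
derivative-of-Gaussian kernel (σ = 2 ms) at each activation time with
amplitude 0.3–1.5 mV, so candidate-detection thresholds are exercised
independently of unipolar morphology. Activation jitter is Gaussian
(sd 3 ms, truncated at ±10 ms); unipolar noise sd is 0.015 mV with
0.05 mV, 0.25 Hz baseline wander. Records are assigned to synthetic
patients in blocks of 50 with a per-patient amplitude scale in [0.8, 1.3],
enabling patient-level cross-validation. These ranges are package defaults
chosen for qualitative realism — published figures do not quantify clinical
amplitudes or widths — and they are *not* clinical claims.

What the generator does **not** emulate: biophysical propagation,
electrode geometry, contact artifacts, non-stationary cycle lengths, or
the full ambiguity of borderline clinical EGMs. Passing tests on synthetic
cohorts therefore demonstrate internal correctness and the qualitative
orderings of the method (deep model above raw-sample baselines, rule-based
detector consistent with ground truth), not clinical performance.

## Numerical choices and degenerate inputs

* Fourier resampling keeps all bins below the smaller Nyquist and splits or
  folds the shared Nyquist bin, so round trips preserve band-limited energy
  to better than 1%.
* Min-max scaling maps constant signals to 0.5 everywhere (declared
  convention, keeps the classifier input well-defined).
* An all-zero envelope yields `is_periodic = FALSE` with power fraction 0
  rather than an error; an empty candidate set yields an empty chain.
* Chain-search ties are broken by (length, cost, lexicographically earliest
  time sequence), making the result unique and oracle-comparable. The
  interval tolerance is strict (< 25% of CL), so an interval at exactly the
  boundary does not extend a chain.
* Batch-norm running variance uses the unbiased correction; evaluation mode
  is exactly deterministic.
* Records shorter than 2 s are rejected; morphology windows at record edges
  are clipped to the available samples.

## Experiment sizes

The packaged experiments are sized for a single CPU: the
generator/detector agreement suite uses cohorts of 120–500 records; the
learning experiment trains the quarter-channel network for 5 epochs on a
2,000-record cohort at prevalence 0.10 (patient-level 75/25 split),
reaching held-out AUC above 0.95 in a few minutes and exceeding the
logistic baseline on the same split; the interpretability experiment probes
50 QS-train records. These sizes are package choices balancing statistical
resolution against runtime.

## Known limitations

* The spectral periodicity criterion inherits the harmonic ambiguity of
  dominant-frequency analysis; the harmonic guard resolves the common
  cases but a pathological spectrum can still mislead it.
* Unipolar morphology is measured on raw amplitude deviations; overlapping
  ventricular far-field waves can masquerade as R waves and turn a true QS
  train into a non-QS call. This mirrors the documented clinical confound
  and accounts for most residual generator/detector disagreement (about
  1–2% of default cohorts).
* Grad-CAM localization is limited by the probed layer's time resolution
  (80 ms at stage 3 for a 5-s input), and different capture points within
  a block carry systematic offsets of opposite sign relative to the
  complex onset; alignment statistics should be read with both effects in
  mind.
* The exact cost-matrix construction of the original graph search is not
  published in the main text; the dynamic program here honors the stated
  objective but is a reconstruction, flagged as such.
* Whether the ">90% QS" criterion counts beats, seconds or annotated
  complexes is not published; this implementation counts determinate
  annotated complexes.
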