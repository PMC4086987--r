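---
title: "Detecting bundle branch block beats with a heterogeneous one-vs-one ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bundle branch block beats with a heterogeneous one-vs-one ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbensemble)
```

## The classification problem and its protocol

Bundle branch block changes ventricular depolarisation: LBBB widens the
QRS into a broad, often notched complex with a discordant T wave; RBBB
adds a late secondary R deflection (the rSR' pattern). Both must be told
apart from normal sinus beats, whose morphology itself varies widely
between individuals. The package therefore evaluates everything
*inter-patient*: classifiers are fitted on one set of patients and tested
on a disjoint set, which is the only protocol whose numbers say anything
about unseen patients. For real data this is the canonical 22/22 record
division of the 48-record two-lead Holter corpus (four paced records
excluded), shipped as an editable YAML file
(`inst/extdata/mitdb_split.yaml`) rather than hard-coded.

## Preprocessing

Beats are cut from the annotated R peak: 100 samples before and 100 after
(0.278 s per side at 360 Hz, so the R wave sits at offset 100 of a
200-sample window). Each lead of each beat is z-normalized independently
with the population (divide-by-N) standard deviation, making every lead
exactly mean 0 / SD 1 and removing amplitude calibration differences
between devices and patients. No filtering or denoising is ever applied:
filters distort exactly the morphology the classifiers rely on. The RR
interval attached to a beat is the gap to the *preceding* studied R peak,
in seconds, unscaled; the first beat of a record copies the following
interval so the RR vector stays index-aligned with the beats. Beats whose
window would cross the record boundary are edge-padded by replicating the
boundary sample (configurable to skip-and-log instead); a flatline
segment, which cannot be normalized, is always skipped and logged.

Three choices here were genuinely open and are worth stating. Leads are
normalized separately (not jointly) so each lead individually satisfies
the stated zero-mean/unit-SD property. RR enters in seconds rather than
z-scored; since every morphology coordinate is O(1) after normalization
and RR is O(1) in seconds, the scales are already commensurate. And RR
intervals are computed over the studied-beat stream (NORM/LBBB/RBBB only),
matching the beat sequence that is actually classified; computing them
over all annotations (ectopics included) is a one-line change in
`make_beats()` if a user wants it.

## ICA features

For the two classifiers that use transform features, each lead gets its
own basis of 100 independent components, fitted on a designated subset of
training beats: from every training record containing a class, the first
10 NORM, 100 LBBB and 80 RBBB beats in temporal order — 620 beats on the
canonical division (180 + 200 + 240). Taking the *first* k beats per
record is a deterministic reading of a selection the protocol leaves
unspecified; a seeded random selection is available. When the per-record
quotas are infeasible (small synthetic cohorts), `train_ensemble()` falls
back to balanced per-class quotas taken round-robin over records.

FastICA is implemented in the package (no installed R package provides
it): PCA whitening to the target dimension, then fixed-point iteration
with the tanh contrast, extracting components one by one by deflation
with Gram–Schmidt re-orthogonalisation. Defaults: 1000 iterations
maximum, convergence tolerance 1e-6 on the direction cosine (a loose
tolerance can freeze a component mid-rotation on small sample sizes, so
the default is strict; the cost is a handful of extra iterations), seeded
random initialisation. One-by-one extraction was chosen over symmetric
(parallel) estimation because the components are then produced in order
of extraction; that matches how the basis is described and used. When a
component fails to converge within the iteration budget the fit keeps the
last iterate and warns — the behaviour of the field's standard FastICA
implementations — because late components of whitened beat matrices sit
in near-Gaussian residual directions where the fixed point wanders
without harming the basis; `on_no_convergence = "error"` makes this
strict.

A new beat is projected with the cached Moore–Penrose pseudo-inverse of
the 100×200 component matrix: the feature vector is the least-squares
coefficient vector of the segment in the component row space. This makes
projection linear, maps a component row to a standard basis vector, and
is invariant to how the unmixing was scaled.

## The three classifiers and the vote

*NORM vs LBBB* uses the minimum-distance classifier on morphology + RR
(401 dimensions for two leads). NORM and LBBB overlap heavily and LBBB is
far from Gaussian; comparing Euclidean distances to the two class
centroids is deliberately insensitive to boundary beats.

*NORM vs RBBB* uses the weighted linear discriminant on ICA + RR (201
dimensions). The pooled scatter matrix is the class-weighted sum of outer
products with **no** per-class normalisation — the weights (w₁, w₂)
absorb scale, and with equal priors the prediction is provably invariant
to multiplying both weights by a constant (this is property-tested).
Posteriors are a softmax over the two linear discriminants, computed with
a max-subtraction guard so extreme discriminant values cannot overflow.
If the scatter matrix is singular (possible only in tiny synthetic fits,
never at protocol scale) a logged ridge of `1e-6 · trace(Σ)/d` is added;
setting `ridge_eps = 0` turns the fallback into an error.

*LBBB vs RBBB* uses a linear SVM on ICA + RR. The solver is libsvm's
linear-kernel C-SVC via `e1071` (an L2-regularised hinge-loss linear
classifier); the fitted hyperplane is extracted so prediction is an
explicit, auditable sign test, and the stored orientation is calibrated
against the solver's own predictions so "positive decision value" always
means the first class label. Per-class penalty weights are supported for
the weighted-SVM comparison experiments.

All ties — equal centroid distances, a 0.5/0.5 posterior, a decision
value of exactly zero — resolve to NORM when NORM is one of the pair, by
the same prevalence argument as the vote tie-break below.

The final label is the majority over the three votes. Exactly one
ambiguous pattern exists (all three labels once); it is assigned to NORM,
the class that outnumbers the others roughly tenfold. The full 8-row vote
table is asserted in the tests by exhaustive enumeration, and the
per-beat vote triple is always retained in prediction output so
per-classifier breakdowns can be audited after the fact.

## Parameter selection

Both tunable classifiers are tuned by stratified 10-fold cross-validation
on the training split, beat-level, seeded. Per setting, the ten held-out
confusion matrices are **summed** and metrics are computed from the sum —
never averaged over folds, because with ~10:1 imbalance a fold-wise mean
of sensitivities weights a fold with two minority beats as heavily as one
with twenty (the suite demonstrates the difference on rigged folds). The
discriminant grid is w₁ ∈ {0.01, …, 0.10} × w₂ ∈ {0.4, 0.5, 0.6} (30
pairs), selected by max RBBB sensitivity, then max RBBB positive
predictive value, then grid order — the last rule is ours, needed to make
selection fully deterministic. The SVM grid is C ∈ {0.001, 0.01, 0.1, 1,
10, 100}, selected by max mean sensitivity, ties to the smallest C. The
centroid classifier has no parameters and is excluded from
cross-validation. The ICA basis is fitted once on the full designated
subset, not refitted inside each fold: the basis is unsupervised and
shared, and refitting per fold would multiply runtime tenfold for no
change in the selection on any data we generated (a strict per-fold mode
would be the conservative alternative; the single-basis choice is the
package default and the one the evaluation numbers reflect).

Beat-level folding mixes beats of the same patient across folds; that is
acceptable *inside* the training split (the test split is still
patient-disjoint), and record-level folding of 2 LBBB records cannot make
10 folds. This is stated rather than hidden: cross-validated numbers are
optimistic relative to inter-patient numbers, which is exactly why final
evaluation only ever uses the held-out split.

## The synthetic generator

The generator exists so the entire pipeline — file reading included — is
testable without any database download. A beat is a sum of Gaussian
bumps (center, width, amplitude) per class and lead: NORM a narrow
central QRS with upright T, LBBB a widened notched complex with
discordant T, RBBB a late secondary deflection. These are controllable
class geometries echoing the qualitative morphology of the real classes,
*not* physiological ECG models. A "virtual patient" is a fixed random
perturbation of the class template (bump amplitudes ±12%, centers ±1.5
samples) shared by all of that patient's beats; training and testing
splits draw disjoint patients, so generalisation across the split is
genuinely inter-patient-like. Per beat, a multiplicative amplitude jitter
(SD 0.10) and additive Gaussian noise (SD 0.10 against bump amplitudes of
O(1)) are applied before z-normalization. RR intervals are class-dependent
normals (NORM 0.80 ± 0.05 s, LBBB 0.92 ± 0.06 s, RBBB 0.70 ± 0.05 s,
truncated at 0.2 s), keeping the RR feature informative but not
class-determining. Default sizes are 1000/100/100 beats per split over
10/2/3 virtual patients — the ~10:1 imbalance and the record structure of
the real corpus at a size that keeps the full pipeline (both
cross-validation grids included) at a few seconds.

What passing on this generator shows: every computational step —
segmentation, normalization, basis fitting, projection, the three fits,
the vote, the selection rules, the metric algebra — is correct and
deterministic under seed, and the pipeline separates classes whose
geometry supports separation, across unseen virtual patients. What it
does not show: performance on real ECG, where noise is structured
(baseline wander, electrode artefacts), morphology drifts within a
record, and the NORM class is vastly more heterogeneous. The generator's
defaults are deliberately separable; real-data numbers are produced only
by running `run_reproduce()` against an actual WFDB directory.

## Numerical and I/O choices

- 0-based sample indexing everywhere, matching the annotation format.
- Report tables round half-up to one decimal in percent; raw fractions
  are always retained in the machine-readable outputs.
- Metrics with a zero denominator (a class absent from a record) are
  `NA`, rendered `"-"` in reports — never silently 0 or 100.
- The WFDB reader implemented here covers the MIT dialect used by
  two-lead Holter records: text headers, 12-bit packed (format 212) and
  16-bit signals, and the standard annotation byte format including
  long-interval SKIP and AUX pseudo-annotations. It is not a general
  WFDB implementation (no multi-segment records, no EDF), and records at
  other sampling rates are rejected rather than resampled.
- Models and ICA bases serialize to versioned JSON (metadata plus full
  precision arrays) and round-trip exactly; runs write a manifest with
  every seed so any output can be regenerated.

## Known limitations

Single-lead configurations (`lead_config = "A"` or `"B"`) use the halved
feature sizes (201 morphology, 101 ICA) by construction. The weighted-SVM
variant used in comparison experiments reconstructs its weight grid
({1, 2, 5, 10} on the minority class crossed with the C grid) rather than
taking it from a published source, since none is given. FastICA
convergence warnings on late components are expected on low-rank or
heavily whitened data and are safe to ignore unless components are
interpreted individually. Finally, the package classifies the three
studied beat types only; applying it to a full Holter record first
requires upstream identification of sinus-origin beats.
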