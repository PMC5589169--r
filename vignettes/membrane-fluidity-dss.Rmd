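---
title: "Membrane fluidity mapping and pattern classification: methods"
author: "rbcfluidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane fluidity mapping and pattern classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcfluidity)
```

## The measurement model

Laurdan is an environment-sensitive membrane dye whose emission spectrum
shifts with lipid packing: tightly packed (gel, ordered) membrane emits
mostly in a blue window (400--460 nm), loosely packed (liquid-crystalline,
fluid) membrane mostly in a green window (470--530 nm). Recording both
windows simultaneously gives, per pixel, the generalized polarization

$$GP = \frac{I_{400\text{--}460} - G\,I_{470\text{--}530}}
            {I_{400\text{--}460} + G\,I_{470\text{--}530}},$$

a normalized ratio in $[-1, +1]$: $-1$ is fully fluid, $+1$ fully ordered.
Because it is ratiometric, GP is independent of excitation intensity and
probe concentration. $G$ is the instrument calibration constant for the
relative detection efficiency of the two bands; it must come from a
calibration measurement, so the package treats it as a configuration
parameter with default 1.

In red blood cells the dye labels only the plasma membrane (there are no
interior organelles), so the GP map reads out membrane order directly. In
type 1 diabetes, glycation and oxidative damage fluidify the membrane and
nucleate fluid domains of roughly 0.5--1 µm; their number and size grow
with disease stage. The package quantifies this two ways: scalar summaries
of the GP map (mean, variance, fixed-edge histograms over $[-1,1]$), and a
texture-based classifier operating on the raw channel images.

### Preprocessing choices

- **Background**: the acquisition background is estimated as the mean of
  the pixels below the image's global Otsu threshold (the dark, cell-free
  class) and subtracted with clamping at zero. A measured value can be
  supplied instead. A constant image returns 0.
- **Debris removal**: segmentation thresholds the summed two-channel
  intensity (Otsu) and drops 8-connected components smaller than
  `min_area_px` (default 100 px = 4 µm² at the 200 nm pitch, far below an
  RBC footprint of ~150 µm² projected).
- **Degenerate ratios**: pixels whose denominator $I_b + G I_g$ does not
  exceed `denom_tol` (default 1e-9 on the background-subtracted scale) are
  removed from the validity mask rather than divided; off-mask values are
  `NA`, never silently zero.
- **Histograms**: 100 bins with fixed edges over $[-1,1]$, so histograms
  are comparable across patients.

## The synthetic cohort

No public image data accompany this problem, so the package ships a
seeded simulator whose defaults *are* the study conditions used in every
validation run; they are declared settings, not measured values.

Each cell is an annular footprint (membrane-dominated signal) of outer
radius 3.5 µm and inner radius 2.5 µm, placed centrally with jitter in a
256 × 256 px frame at 200 nm/pixel. The baseline GP texture is low-pass
filtered white noise (correlation length 1 µm) rescaled to SD 0.05 around
a per-group base level of 0.45 / 0.40 / 0.33 for G0 / G1 / G2 — values
chosen once to reproduce the qualitative ordering of the disease stages
(controls most ordered, complicated diabetes most fluid). Fluid domains
are a Poisson process over the membrane: expected counts 0 / 40 / 120 per
cell with diameters uniform in 500--1000 nm, each lowering GP by 0.25
inside its disc; overlaps stack and the field is clamped to $[-1,1]$.
These strongly separated parameters emulate the regime in which the
original three-class system was reported to be perfectly accurate, and
make the group mean GP strictly decreasing and the within-cell GP
variance strictly increasing with stage — the package's qualitative
reproduction of the observed histogram shift-plus-widening.

Rendering inverts the GP formula: per membrane pixel the total
($G$-weighted) signal is the photon budget $S$ (default 2000), split as
$I_b = S(1+GP)/2$ and $I_g = S(1-GP)/(2G)$, with independent Poisson
noise per channel; off-membrane pixels receive a background level
(default 100 photons). A noiseless render followed by GP mapping
reproduces the field exactly, which the tests exploit as an algebraic
round-trip oracle.

Covariates are Gaussian per group: HbA1c 5.2 ± 0.3 (G0), 7.9 ± 0.9 (G1),
8.1 ± 0.9 (G2) — controls well separated, diabetic groups heavily
overlapping, emulating a matched-metabolic-control design; cholesterol
and LDL means non-decreasing with stage; disease duration truncated below
15 years for G1 and above for G2; diabetics receive MDI or CSII therapy
(50/50) with per-therapy insulin doses, and CSII shifts the membrane
baseline GP by −0.03 (the simulator's handle on the observed higher
fluidity under pump therapy). A patient-level random GP offset (SD 0.01)
induces the within-group patient scatter that makes leave-one-person-out
evaluation meaningful.

What the simulator does **not** model: optical point-spread functions,
discocyte 3-D geometry, hemoglobin autofluorescence, z-correlation
between fields (the default 10 images per patient are independent
fields), and any realistic relationship between covariates and membrane
texture beyond the declared offsets. Passing tests therefore demonstrate
the pipeline's correctness and its behavior under the declared
conditions, not clinical performance on real cohorts.

## Texture descriptors

Per channel and image the descriptor vector concatenates:

- **First-order** (6): mean, population variance, skewness, excess
  kurtosis, gray-histogram energy and entropy (64 bins over the observed
  range; constant regions are defined to have skewness/kurtosis 0,
  entropy 0, energy 1).
- **GLCM** (5): the image is quantized to 32 equal-width levels over the
  masked range; symmetric, normalized co-occurrence matrices at the four
  unit offsets are averaged into contrast, correlation, energy,
  homogeneity and entropy. Correlation of a degenerate matrix is 0.
- **RICLBP** (666): 8-neighbor LBP codes (ties use $\ge$, so codes are
  shift-invariant and a constant image is the all-ones pattern), mapped
  to the 36 rotation-invariant representatives (minimum over circular
  bit-shifts); the descriptor is the normalized joint histogram of
  unordered code pairs at displacement 2 px pooled over the four
  directions. With the 90°-step rotation group realized as bit-shifts,
  the descriptor is *exactly* invariant to quarter-turn rotations of a
  square frame, which the tests assert bit-for-bit.

Features are computed full-frame by default (`mask_mode = "full"`), with
a masked-to-cells mode available. They are computed on the raw channel
intensities — the GP map itself feeds only the scalar baseline and the
descriptive statistics — so the two channels remain separate information
sources for the classifier.

## The decision-support system

Each channel has its own pipeline, fitted on training patients only:
per-feature standardization (the descriptor families have incommensurate
scales), PCA retaining the smallest number of components that reach 99%
of the training variance (refitted in every fold, so the count may vary
by fold), and a one-vs-one linear SVM (C = 1). Per-image labels are
aggregated per patient by majority over the z-stack; a tied stack
majority is resolved by the weighted sum of both channels' vote
fractions, so the other channel's evidence settles it. The two channel
decisions are then fused by weighted voting.

The voting weights are each channel's held-in accuracy under an internal
3-fold split of the training patients (round-robin within class in list
order — deterministic, no RNG anywhere in the classifier). The weights
use *image-level* accuracy rather than patient-level: patient-level
accuracies saturate at 1.0 for both channels on separable cohorts, which
reduces the fusion of two disagreeing channels to an arbitrary
tie-break; image-level accuracy is finer-grained, so the vote almost
never ties and the fusion follows the channel that is genuinely more
reliable. Remaining exact ties go to the heavier channel's vote, then to
the lower class index.

Evaluation is leave-one-person-out: every fold refits standardizer, PCA,
SVM and weights from scratch on the remaining patients. Isolation is
structural — the training list simply never contains the held-out
patient — and a fold callback exposes the training ids so the tests can
assert it for every fold.

Two scalar baselines use the same LOPO protocol with a Gaussian
class-conditional Bayes classifier (class priors = training frequencies,
SD floored at 1e-6, posterior ties to the lower class index): one on
HbA1c, one on the patient's mean GP. Under matched metabolic control the
HbA1c baseline cannot separate G1 from G2, while mean GP and the DSS
can — the qualitative ranking DSS ≥ mean-GP > HbA1c that the acceptance
suite asserts over five cohort seeds at the full cohort size (26
patients, 10 image pairs, 256 px). The full size matters: with fewer
patients or images the SVM's generalization noise in the 677-dimensional
standardized space dominates, and the comparison measures small-sample
variance rather than the methods' ordering.

Metrics come from the 3 × 3 confusion matrix with rows = predicted and
columns = true: accuracy is the trace over the total; per-class precision
is the diagonal entry over its row sum, recall over its column sum, F1
their harmonic mean; zero-denominator ratios are reported as 0 and
flagged.

## Descriptive statistics

The cohort-level analyses are deliberately plain: pairwise two-sided
Welch t-tests per group (no multiplicity correction, flagged at 0.05 and
0.001), normalization of GP and HbA1c to their control-group means,
coefficients of variation (sample SD over |mean|), OLS regressions of the
normalized quantities on disease duration and of mean GP on cholesterol
and LDL per group (slope sign and $R^2$ only — no causal reading), and a
therapy-separation report: the fraction of MDI and CSII patients on their
expected sides of a line in the (insulin dose, GP) plane. The line is a
reporting device, not a classifier; when not supplied it defaults to the
horizontal midline between the two therapy groups' mean GP. Note that
under the strongly separated class parameters the group effect on mean GP
dwarfs the therapy offset, so the separation is only informative in a
matched-fluidity regime (similar class baselines), which is how the tests
exercise it.

## Numerical and validation choices

- Validation sizes (chosen once as the package's own validation design):
  the reference-classification check runs the full 26-patient cohort;
  the ranking check uses five cohort seeds at full size; Poisson
  cluster-count calibration uses 400 replicate fields at 64 px; the
  qualitative stage-ordering check uses 30 cells per group at default
  frame size.
- Determinism: cohorts derive per-patient sub-seeds from the master seed
  (kept below $2^{31}$); the classifier stack contains no randomness, so
  identical inputs give identical reports.
- GP maps are stored as two-page 32-bit float TIFFs holding
  $(GP+1)/2$ and the validity mask (the TIFF writer clamps values outside
  $[0,1]$); the reader inverts the transform. Channel images are 16-bit
  TIFFs on the photon-count scale, lossless up to 65535 counts.
- Known limitations: the simulator's class separation is far stronger
  than any real cohort's; per-fold PCA counts vary (the retained-variance
  contract, not a fixed component count, is the invariant); the
  full-frame feature mode dilutes membrane texture with background, which
  is why the classifier needs the full training scale; and the scalar
  mean-GP baseline is essentially perfect under these conditions, so the
  DSS's advantage manifests only against HbA1c, not against mean GP.
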