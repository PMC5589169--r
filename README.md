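# rbcfluidity

Quantifies red-blood-cell (RBC) plasma-membrane fluidity from two-channel
Laurdan fluorescence microscopy and classifies patients into healthy
(G0), type-1-diabetic without complications (G1) and with complications
(G2) groups from the spatial *pattern* of membrane phase separation —
not just its mean level.

## Who this is for

Groups analyzing ratiometric membrane-order imaging (Laurdan, di-4-ANEPPDHQ
and similar probes) who want a tested, reproducible pipeline from raw
two-channel TIFFs to per-pixel generalized-polarization (GP) maps,
texture descriptors, and a leave-one-person-out-evaluated classifier,
plus a fully synthetic cohort generator so every stage can be validated
without patient data.

## The model

Per pixel, with blue band $I_b$ (400–460 nm), green band $I_g$
(470–530 nm) and instrument calibration factor $G$:

$$GP = \frac{I_b - G\,I_g}{I_b + G\,I_g} \in [-1, +1]$$

$-1$ = liquid-crystalline (fluid), $+1$ = gel (ordered); being a
normalized ratio, GP is independent of excitation intensity and probe
concentration. In diabetes, glycation and oxidation fluidify the RBC
membrane and nucleate 0.5–1 µm fluid domains whose number grows with
disease stage; the mean GP falls and the GP distribution widens.

The decision-support system (DSS) classifies the phase-separation
pattern: per emission channel, each image yields 677 texture descriptors
(first-order moments, gray-level co-occurrence statistics, and a
rotation-invariant co-occurrence local-binary-pattern histogram); each
channel pipeline standardizes, projects onto the principal components
covering 99% of the training variance, and classifies each image with a
linear SVM; per-channel patient labels are the majority over the z-stack
and the two channels are fused by weighted voting. Evaluation is
leave-one-person-out (LOPO) with every component refitted per fold.
Gaussian Bayes classifiers on scalar HbA1c and on mean GP serve as
baselines.

## Worked example

```r
library(rbcfluidity)

# a reduced synthetic cohort: 4 patients per group, 6 image pairs each
cfg <- cohort_config(n_per_group = c(4, 4, 4), images_per_patient = 6,
                     image_size_px = 192, seed = 7)
cohort <- simulate_cohort(cfg)

# GP map of one image pair (a G2 patient: diabetes with complications)
z <- cohort$patients[[9]]$stack[[1]]
blue  <- subtract_background(z$blue,  estimate_background(z$blue))
green <- subtract_background(z$green, estimate_background(z$green))
mask  <- segment_cells(blue, green)
gp    <- compute_gp_map(blue, green, g = 1, mask = mask)
gp
#> <gp_map> 192 x 192 px, 473 valid px, mean GP -0.2983
gp_summary(gp)$variance_gp
#> [1] 0.1452791

# full analysis: features -> DSS LOPO -> baselines -> statistics
res <- run_analyze(cohort, tempfile("results"), write_images = FALSE)
res$metrics$dss
#> <metrics_report> n = 12, accuracy = 0.917
#>          true
#> predicted G0 G1 G2
#>        G0  4  0  0
#>        G1  0  4  1
#>        G2  0  0  3
#>           G0    G1    G2
#> precision  1 0.800 1.000
#> recall     1 1.000 0.750
#> f1         1 0.889 0.857
```

The G2 membrane's mean GP (−0.30) sits far below the healthy baseline
(~0.45): overlapping fluid domains (~120 per cell, each lowering GP by
0.25) pull the mean down and inflate the pixel variance (0.145 against
0.0025 for a domain-free control). The reduced 12-patient LOPO run
misclassifies one G2 patient — per fold the SVM sees only 66 training
images; at the package's reference size (26 patients, 10 image pairs of
256 px) the DSS is perfect and the three-method comparison gives
DSS = 1.00, mean-GP baseline = 1.00, HbA1c baseline ≈ 0.6 (HbA1c cannot
separate the two diabetic groups when they are matched for metabolic
control).

A command-line wrapper over the same functions lives at
`inst/cli/rbcfluid.R`:

```sh
Rscript inst/cli/rbcfluid.R all --config inst/extdata/default_cohort_config.yaml --out run1
```

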