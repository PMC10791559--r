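---
title: "Quantification methods for sodium-channel redistribution in cardiomyocytes"
author: "myoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for sodium-channel redistribution in cardiomyocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

## Scope

Persistent activation of protein kinase A redistributes the cardiac sodium
channel NaV1.5 from intracellular compartments to the peripheral membrane and
intercalated discs (ICDs) of ventricular myocytes. Demonstrating that
redistribution quantitatively requires a chain of measurements spanning
high-resolution immunofluorescence, live-cell photobleaching, cell-attached
patch clamp and immunoblot densitometry. This package implements that chain
as reusable, tested R functions, and pairs every statistic with a synthetic
phantom generator whose ground truth is known exactly, so that each stage can
be validated by recovery rather than by eye.

## Image-based statistics

### Pixel content and degrees of enrichment

All expression surrogates derive from the *pixel content* of a region $R$ on
a single analysis plane:

$$\mathrm{PC}(R) = (\overline{I}_R - b)\,\cdot\,\mathrm{area}(R)$$

where $\overline{I}_R$ is the mean intensity over $R$ and $b$ a background
level. The *degree of enrichment* of a subregion (the 1-µm lateral rim, or
the ICD area demarcated by an nCadherin marker) is

$$E(R) \;=\; \frac{100\,\mathrm{PC}(R)/\mathrm{PC}(\mathrm{cell})}
                 {100\,\mathrm{area}(R)/\mathrm{area}(\mathrm{cell})},$$

so $E = 1$ means a uniform distribution and $E > 1$ concentration in the
region. `lateralEnrichment()` and `icdEnrichment()` compute both percentages
and their ratio; the analysis plane is a caller choice, conventionally the
central z-plane with the clearest contour (`selectCentralPlane()` picks the
plane of maximal cell cross-section).

Two conventions had to be fixed where the original workflow leaves them
open. First, the background source: we take the mean over an explicit
cell-free ROI (`estimateBackground()` refuses masks that touch the cell) and
record the value in every result. Second, background-subtracted region means
can be slightly negative in dim regions; the raw pixel content keeps its
sign, and only the *percentage* field is clipped at zero, so downstream
ratios remain well defined while no information is silently discarded.

The rim itself is defined by an exact Euclidean distance transform in
physical units: a cell pixel belongs to the rim when its center lies within
`widthUm` of the nearest outside-cell pixel center. This reproduces a
hand-drawn "1 µm from the contour" band but is reproducible and testable
against a brute-force distance computation.

### Cluster parameters

Surface and en-face ICD views are segmented with `segmentClusters()`:
signals outside the ROI are cleared, pixels at or above a threshold form
foreground, and 8-connected components of at least `minSizePx` pixels become
clusters. Three parameters summarize a field (`clusterStats()`): density
(% of ROI area occupied), average cluster size (µm²) and mean
immunofluorescence intensity over cluster pixels (reported raw and
background-subtracted).

Numerical choices:

* **Threshold rule.** The source workflow does not state its ImageJ
  settings, so quantitative agreement with its published cluster numbers is
  not claimable; the default here is Otsu computed *within the ROI*, with
  `mean + k sd` and fixed-value alternatives. Whatever rule runs, the
  applied threshold is recorded in the `ClusterSet`. A contrast-free ROI
  yields zero clusters rather than an all-foreground degeneracy.
* **Connectivity.** 8-connected, the ImageJ default for particle analysis;
  the labeling is implemented in the package because the available library
  primitive is 4-connected, and is tested against a flood-fill oracle.
* **Minimum size.** 4 pixels by default (2 for PLA puncta), suppressing
  single-pixel noise at 50-nm pitch.

En-face ICD analysis (`icdClusterProfile()`) reslices the stack into YZ
planes at caller-given x positions, segments the ICD-marker channel with one
*stack-global* Otsu threshold (a per-plane threshold would hallucinate an
ROI out of dim cell-body signal on planes without a disc), fills holes,
keeps components above an area floor as the ICD ROI, and then runs the
cluster statistics on the target channel inside that ROI. Positions without
marker signal produce missing rows, not errors, matching how planes beyond
the disc are handled in practice.

One ambiguity is deliberately surfaced rather than resolved: the
"myocyte central area" used for microtubule occupancy is described both as
interfibrillar and as "within 1 µm from cell contour". `occupancyPct()`
therefore takes an explicit region argument — rim, interior (cell minus
rim) or whole cell — and the choice travels with the result.

### Thresholded Pearson colocalization

`thresholdedPCC()` computes the Pearson correlation twice: over all masked
pixels and over the pixels above the Costes automatic thresholds.
`costesThresholds()` fits the orthogonal (total least squares) regression
$b = s\,a + c$ — orthogonal because both channels carry symmetric noise —
and bisects for the threshold $T_a$ at which the correlation of the pixels
*below* the line ($a < T_a$, $b < s T_a + c$) first becomes non-positive;
$T_b = s T_a + c$. Bisection stops at 0.5 intensity units or 200 iterations.
A non-positive slope means the search is undefined; the result is flagged
and the thresholded coefficient reported missing rather than fabricated.

The above-threshold pixel set is a convention, not a law: the default
`"either"` (a pixel qualifies when either channel exceeds its threshold)
preserves genuine anti-correlation between well-resolved structures while
excluding background-dominated pixels; `"both"` and `"all"` are available
and the convention used is recorded in the result.

### PLA puncta density and expression correction

`plaDensity()` collapses the PLA channel by maximum-intensity z-projection,
segments puncta within the cellular contour and reports the percentage of
cellular area occupied. Because comparison across treatment groups is the
point, the threshold should be one rule per batch — `pooledOtsuThreshold()`
computes a single Otsu value over the pooled in-mask histogram of a whole
batch — never a per-image adaptation. `correctedPlaDensity()` divides each
cell's density by the product of its normalized expression pixel contents,
$d_\mathrm{corr} = d / \big((\mathrm{pc}_1/\overline{\mathrm{pc}}_1)\,
(\mathrm{pc}_2/\overline{\mathrm{pc}}_2)\big)$, which removes trivial
density increases caused by higher expression of either partner and is
invariant to cohort-wide rescaling of the expression channels.

## FRAP kinetics

The acquisition protocol is 25 baseline scans at 0.5-s intervals, a bleach
of two ROIs (cell center, cell end) to below 30% of baseline, and 275
recovery scans; two further ROIs provide the in-cell reference and the
cell-free background. Analysis (`analyzeFrap()`) proceeds:

1. subtract the background ROI's mean level from all traces;
2. correct acquisition bleaching by the reference:
   $F'(t) = F(t)\,\overline{F}^\mathrm{ref}_\mathrm{pre} / F^\mathrm{ref}(t)$;
3. normalize to the bleach span using the single scans bracketing the bleach
   (scan 25 → 1, scan 26 → 0). A pre-bleach-mean variant exists but is off
   by default to match the stated convention;
4. fit the saturating biexponential
   $N(t) = A_1(1 - e^{-t/\tau_1}) + A_2(1 - e^{-t/\tau_2})$, anchored at
   $N(0) = 0$.

The functional form is a design decision: "two-exponential" could include an
offset, but anchoring at zero makes the plateau $A_1 + A_2$ the mobile
fraction and $1 - (A_1{+}A_2)$ the immobile fraction, which is the quantity
of biological interest. Constraints are $A_i \ge 0$ and
$0.1\,\mathrm{s} \le \tau \le 10^4\,\mathrm{s}$, components ordered
$\tau_1 < \tau_2$; the optimizer is Levenberg–Marquardt (`minpack.lm`) with
at least five seeded starts and the lowest residual sum of squares winning,
which in practice removes dependence on initialization. A fitted plateau
above 1 is physically suspect and is logged, not clipped. The headline
statistic, percent recovery two minutes after the bleach, is evaluated on
the fitted curve to suppress scan noise (the raw-trace value is also
reported). For the reference truth $A_1{=}0.3, \tau_1{=}5$ s,
$A_2{=}0.4, \tau_2{=}60$ s the closed form gives
$100\,[0.3(1-e^{-24}) + 0.4(1-e^{-2})] = 64.6\%$, which the fit reproduces
to machine precision on noiseless traces. No diffusion-model interpretation
of the time constants is attempted.

## Ensemble sodium currents

Cell-attached families (4–12 protocol repeats) are averaged per voltage and
time point (`ensembleAverage()`), baseline-subtracted using the 5 ms before
the test pulse, and blanked for the first 0.3 ms of the pulse where residual
capacitive transient lives (both windows configurable). `peakIna()` takes
the most negative current per voltage and the largest magnitude across the
ladder as the maximal peak; all-outward families report zero amplitude with
a warning rather than a spurious peak. `fitInactivation()` fits
$I(t) = I_p e^{-(t-t_0)/\tau} + c$ from 0.5 ms after the peak to the window
end: the short delay keeps the tail of the activation phase from biasing
$\tau$ (on the simulator's kinetics the bias drops from ~4% to ~0.1%), and
the offset $c$ absorbs residual leak. Voltages are expressed as membrane
potentials; the acquisition's pipette-voltage ladder (+100 → −75 mV in −5 mV
steps from a +120 mV holding) maps to membrane test voltages −100 → +75 mV
against a zeroed resting potential, with the maximal peak designed at
−35 mV as observed under zeroed-potential conditions.

## Densitometry

Three ratio schemes (`ratioPkaCon()`, `coipDegree()`, `surfaceDegree()`)
operate on long-format band tables, always pairing lanes *within* an
experiment to cancel blot-to-blot variation: the PKA:CON ratio of band
intensities; the degree of coimmunoprecipitation ([+]IP/WCL) and its
PKA:CON ratio; and the degree of surface biotinylation (biotinylated/WCL)
and its PKA:CON ratio. Loading conventions matter: WCL lanes are loaded at
1:20 of the pulldown-equivalent material, so raw degrees overstate absolute
recovery twenty-fold; ratios are reported raw (like-for-like comparison)
with an `absolute` flag applying the factor. Coomassie-blue correction is
an explicit flag, never automatic, because the trigger for "if necessary"
in the source protocol is unstated. Excluded experiments (missing lanes,
zero denominators) are retained in the output with a reason — exclusions
are never silent. Summaries are mean ± SE across experiments with a
one-sample t test against 1 for convenience.

## The phantom generator

Phantoms exist so that every statistic above can be checked by ground-truth
recovery. `makeMyocyteStack()` builds a two-channel z-stack:

* **Geometry.** A stadium-shaped (rounded-end) footprint — defaults
  120 × 25 µm with 12 µm height, conventional for adult rat ventricular
  myocytes, all configurable — extruded over z inside a frame with 2 µm of
  cell-free margin. Transverse ICD bands of `icdDepthUm` sit at both ends;
  the 1-µm rim follows the distance transform. Interior planes carry a
  sarcomeric striation pattern of ~2 µm period; the top surface plane
  carries randomly placed, non-overlapping cluster disks on a smooth base
  (striations are interior structure and do not appear on the surface
  view).
* **Exact enrichment.** Rim and ICD pixels are intensity-weighted by
  factors solved from a 2 × 2 linear system over the actual rasterized
  pattern, so that the *measured* degrees of enrichment of the noiseless
  image equal the requested factors exactly, not merely approximately.
  Requests incompatible with the geometry (enrichment × area fraction ≥ 1)
  are rejected.
* **Optics.** A separable anisotropic Gaussian PSF, FWHM 100 nm lateral /
  300 nm axial at the whole-cell pixel geometry (100-nm XY, 300-nm z) and
  isotropic 50-nm geometry for cluster views; $\sigma =$ FWHM/2.3548,
  kernels truncated at 4σ, convolution in floating point before noise.
  No detector-array model is attempted: only the resulting pixel geometry
  and blur matter downstream.
* **Noise.** Poisson–Gaussian, the standard CCD approximation:
  $\mathrm{Pois}(\lambda I)/\lambda + \mathcal{N}(0, \sigma_r)$. The
  variance of a uniform region is $I/\lambda + \sigma_r^2$, which the test
  suite verifies to 10% on ≥10⁴ pixels. The signal-to-noise ratio of a
  region of intensity $I$ is approximately $\sqrt{\lambda I}$, so
  `photonScale = 100` gives SNR 10 at unit intensity.
* **Determinism.** Identical spec and seed give bit-identical voxels; the
  generators use an isolated RNG state and do not disturb the caller's.

`makeFrapDataset()`, `makeInaDataset()` and `makeBandTable()` provide the
matching FRAP traces (biexponential recovery over a monoexponential
acquisition-bleach, four ROIs), Hodgkin–Huxley-style inward current
families ($I = g\,m_\infty^3(V)\,(1-e^{-t/\tau_a})^3 e^{-t/\tau_i}(V-E)$,
Boltzmann activation, Gaussian sweep noise, no stochastic gating), and
log-normal-noise band tables for the three densitometry schemes.

What the phantoms do *not* emulate — and hence what passing tests do not
show about real data: out-of-focus haze and depth-dependent aberrations,
antibody labeling stochasticity, cell-to-cell morphological variability
beyond the configured dimensions, bleaching during z-acquisition, seal
instability and capacitive artifacts in patch recordings, and any true
biological coupling between the channels. Recovery tests certify the
*estimators*, not the biology.

## Problem sizes and test design

The validation suite runs phantoms at reduced cell sizes chosen as a
package design decision to keep full-suite runs convenient while leaving
every geometric relation intact: whole-cell enrichment phantoms at
30 × 12 µm (100-nm pixels, three cell z-planes), cluster-mode phantoms at
20 × 10 µm (50-nm pixels, density 5%, radius 0.25 µm), FRAP Monte Carlo
with 200 traces at noise SD 0.02, current recovery over 100 seeded
single-voltage families at 1% peak noise plus full-ladder peak
identification, and an end-to-end cohort of 10 + 10 cells with a designed
two-fold enrichment difference. All tolerances asserted in the tests
(exact recovery at ≤10⁻⁶ relative without optics; ±10% enrichment at
SNR 10; ±15% cluster parameters under PSF + noise; τ₂ median error <10%
and mobile fraction <5% in FRAP; τ inactivation median error <2%;
densitometry means within 2% at CV 0.1 over large replicate counts) were
fixed from the study conditions before the phantoms were tuned to pass
anything, and the acceptance script recomputes the same quantities from
scratch at run time.

## Known limitations

* Cluster parameters depend on the threshold rule; absolute agreement with
  any particular ImageJ configuration is not claimed, only internal
  consistency and ground-truth recovery.
* En-face ICD cluster sizes inherit axial PSF elongation, as any
  YZ-reconstruction does; comparisons should be within one imaging
  configuration.
* The Costes bisection assumes an approximately monotone below-threshold
  correlation in the threshold, which holds for two-population images but
  can be noisy for pathological intensity distributions; the exhaustive
  scan used as a test oracle is available for diagnosis.
* `runPipeline()` orchestrates phantom cohorts end to end; applying the
  measurement stages to real acquisitions means calling the module
  functions directly on imported stacks (`readImageStack()`,
  `readFrapTable()`, `readSweepTable()`), since whole-cell segmentation
  from raw fluorescence is out of scope — contours are inputs.
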