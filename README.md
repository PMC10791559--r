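# myoquant

Quantification of sodium-channel redistribution in cardiomyocytes: subcellular
enrichment, cluster analysis, colocalization, PLA, FRAP kinetics, ensemble
currents and immunoblot densitometry — with ground-truth phantom generators.

## The problem

Persistent protein kinase A (PKA) activation redistributes the cardiac sodium
channel NaV1.5 from intracellular stores to the peripheral membrane and
intercalated discs (ICDs) of ventricular myocytes, raising sodium current
without changing total protein. Detecting that redistribution quantitatively
requires a heterogeneous measurement chain — high-resolution
immunofluorescence geometry, photobleaching kinetics, cell-attached patch
clamp and blot densitometry — each with its own conventions and pitfalls.
`myoquant` packages that chain for imaging scientists and cardiac
electrophysiologists as tested R functions, and ships synthetic phantom
generators with exact ground truth so every estimator can be validated by
recovery instead of inspection.

## The statistics at its core

- **Pixel content** of a region *R*: `PC(R) = (mean(I over R) − b) · area(R)`,
  the expression surrogate.
- **Degree of enrichment** of a subregion (1-µm lateral rim from the cell
  contour, or the nCadherin-demarcated ICD area):
  `E = (% pixel content in R) / (% cell area in R)`; 1 = uniform. The rim is
  an exact Euclidean distance transform in physical units.
- **Cluster parameters** inside an ROI after thresholding (Otsu within the
  ROI by default) and 8-connected labeling: density (% of ROI area), average
  size (µm²), mean in-cluster intensity (raw and background-subtracted).
- **Thresholded Pearson correlation** (Costes): orthogonal regression
  `b = s·a + c`, bisection for the threshold where the below-line pixel
  correlation first becomes non-positive, PCC over the above-threshold set.
- **PLA density** `= % cellular area occupied by puncta` after maximum z
  projection, with expression correction
  `d / ((pc1/mean1)(pc2/mean2))`.
- **FRAP recovery** `N(t) = A1(1−e^(−t/τ1)) + A2(1−e^(−t/τ2))`, anchored at
  `N(0) = 0` after background subtraction, reference bleach correction and
  span normalization; `A1+A2` is the mobile fraction, and the headline
  readout is the fitted percent recovery at 2 min.
- **Ensemble current**: repeat-averaged sweeps, maximal peak inward current
  over the voltage ladder, and monoexponential inactivation
  `I = Ip·e^(−t/τ) + c` fitted just after the peak.
- **Densitometry schemes**: per-experiment PKA/CON band ratios, degree of
  coimmunoprecipitation ([+]IP/WCL) and of surface biotinylation
  (biotinylated/WCL), each with its PKA:CON effect ratio.

## Worked example

Generate a myocyte phantom with a designed 2-fold lateral and 3-fold ICD
enrichment, image it with realistic optics and noise (SNR 10), and measure
the enrichment back:

```r
library(myoquant)

spec <- phantomSpec(cellLengthUm = 30, cellWidthUm = 12, cellHeightUm = 0.9,
                    lateralEnrichment = 2, icdEnrichment = 3,
                    photonScale = 100, seed = 42)
ph <- makeMyocyteStack(spec)
ph$stack
#> ImageStack: 340 x 160 px, 5 z-planes, 2 channel(s)
#>   pixel: 100 nm XY / 300 nm Z
#>   channels: target, ncad

plane <- getChannel(ph$stack, "target")[, , ph$truth$centralZ]
bg <- estimateBackground(plane, ph$truth$bgMask, ph$truth$cellMask)
lateralEnrichment(plane, ph$truth$cellMask, ph$truth$rimMask, background = bg)
#> EnrichmentResult (lateral): 42.36% of pixel content in 21.33% of area -> enrichment 1.985
icdEnrichment(plane, ph$truth$cellMask, ph$truth$icdMask, background = bg)
#> EnrichmentResult (icd): 8.14% of pixel content in 2.74% of area -> enrichment 2.974
```

The measured degrees of enrichment (1.985 and 2.974) recover the designed
factors (2 and 3) to within about 1% despite the Poisson–Gaussian noise and
the anisotropic PSF; with optics and noise switched off the recovery is
exact. The same pattern holds for FRAP:

```r
traces <- makeFrapDataset(frapSimSpec(noiseSd = 0.02, seed = 7))
analyzeFrap(traces, targetRoi = 1)$fit
#> FRAPFit: A1=0.3014 (tau1=5.52 s), A2=0.3709 (tau2=69.4 s)
#>   mobile fraction 0.672, recovery at 2 min 60.6%, rss 0.264
```

against a simulated truth of A1 = 0.3 (τ1 = 5 s), A2 = 0.4 (τ2 = 60 s),
mobile fraction 0.7.

`runPipeline()` chains phantom generation, enrichment measurement and group
summaries into a CON-vs-PKA cohort comparison from a single seeded
configuration (also available from the shell via
`inst/scripts/myoquant.R --config cfg.yaml`).

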