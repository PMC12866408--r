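# petkin

Kinetic quantification and test–retest reliability analysis for dynamic
small-animal PET studies that use an image-derived input function (IDIF).

## The problem

Radioligands without a reference region — for example tracers for mutant
huntingtin (mHTT) aggregates evaluated in zQ175DN mice — must be quantified
against a metabolite-corrected plasma input. That pipeline has many moving
parts: fitting the intact-parent fraction and the plasma-to-whole-blood
ratio from sparse blood samples, correcting the IDIF, fitting a
two-tissue compartment model (2TCM) to regional time–activity curves,
cross-checking with Logan graphical analysis, asking whether shorter scans
are admissible (time-stability), validating the cheaper SUV alternative,
and quantifying how repeatable each metric is across test and retest
sessions. petkin implements the whole chain as composable, tested R
functions, together with a synthetic-data generator that produces every
input with known ground truth.

## The models

* **Input**: plasma-parent curve built multiplicatively,
  `C_p(t) = C_wb(t) · (r0 + r1·t) · f(t)`, with a biexponential intact
  fraction `f(t) = a1·exp(−mu1·t) + a2·exp(−mu2·t)` (constrained to
  f(0) = 1 by default) and a linear plasma-to-whole-blood ratio.
* **Kinetics**: reversible 2TCM, `C = (1−vB)·(h ⊗ C_p) + vB·C_wb` with the
  standard biexponential impulse response in K1, k2, k3, k4;
  `V_T = (K1/k2)(1 + k3/k4)`. Convolution is exact for piecewise-linear
  inputs; fitting is weighted Levenberg–Marquardt on log-scale rates with
  seeded multi-start.
* **Logan**: slope of the late linear segment of the integrated-tissue vs
  integrated-plasma plot (each normalized by tissue activity) after t*.
* **SUV**: duration-weighted mean of the frames fully inside a late window
  (default 100–120 min), divided by injected dose per body weight.
* **Reliability**: rTRV = 100·(test−retest)/mean, aTRV = |rTRV|,
  Bland–Altman limits bias ± 1.96·SD, and a REML variance-component ICC
  (animal variance / sum of positive components).
* **Planning**: Cohen's d, percent genotype difference relative to the
  reference mean, and exact noncentral-t sample sizes for one-tailed
  two-sample designs.

## Worked example

```r
library(petkin)

fs <- defaultFrameSchedule()      # 45 frames, 12x10s ... 21x300s, 120 min
input <- simulateInput()          # synthetic whole-blood + plasma-parent input
het <- genotypeParams("HET")      # K1=0.3 k2=0.15 k3=0.06 k4=0.03 vB=0.03, V_T = 6
tac <- simulateTac(het, input, fs, noiseSpec(0.05, seed = 42))

fit2tcm(tac, input, seed = 42)
#> TwoTcmFit: V_T = 6.036 mL/cm^3 (converged, 10 starts)
#>   K1=0.297 k2=0.1458 k3=0.05951 k4=0.03031 vB=0.0384  wRSS=8.56

loganVt(tac, input, tStar = 30)
#> LoganResult: V_T = 5.678 mL/cm^3 (t* = 30 min, 18 points, r2 = 0.9998)

computeSuv(tac, dose = 4.1, weight = 30)
#> SUV = 0.413 g/mL (window 100-120 min, 4 frames, 56.4 kBq/mL mean)

as.integer(sampleSizeTwoSampleT(d = 2.0))   # one-tailed, alpha 0.05, power 0.80
#> [1] 4
```

The 2TCM fit recovers the generative V_T = 6 within noise (6.04); Logan
comes in slightly low (5.68) — the documented nonpositive bias of the
graphical method under truncation, noise and a fractional blood volume. The
SUV of 0.41 g/mL is the 100–120 min mean concentration (56.4 kBq/mL)
divided by dose per body weight (4100 kBq / 30 g).

A complete synthetic study (two genotypes × two sessions, five regions)
plus the full analysis chain:

```r
dir <- tempfile()
writeSyntheticStudy(dir, nPerGenotype = 8, seed = 1)
res <- runPipeline(studyConfig(dir))
res$trt     # region x metric table: rTRV/aTRV mean±SD per genotype + ICC
res$group   # per-region Welch tests, Cohen's d, percent differences
res$power   # sample sizes implied by the observed effect sizes
```

An equivalent command-line entry point lives at
`inst/scripts/run_pipeline.R`.

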