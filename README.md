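# wlcAFM

Simulation-assisted measurement of the intrinsic stiffness (persistence
length) of short DNA molecules from scanning atomic-force-microscopy (AFM)
height images.

## The problem and who this is for

AFM can image single dsDNA molecules adsorbed on a surface at near-basepair
resolution. For an ensemble of 2D-equilibrated molecules the worm-like-chain
(WLC) model links geometry to mechanics through the mean-square end-to-end
distance,

    <R^2> = 4 xi L_C (1 - (2 xi / L_C) (1 - exp(-L_C / 2 xi))),

which is inverted for the persistence length xi after measuring <R^2> and
the contour length L_C. The catch: near the rigid-rod limit this inversion
amplifies contour-length error enormously — for 100 bp DNA, a ~2%
underestimate of L_C (< 1 nm) overestimates xi by ~60%. Automated tracing of
pixelated, tip-broadened ridges always makes percent-level length errors, so
direct inversion fails exactly where short-DNA mechanics gets interesting
(DNA looping, nucleosome positioning, protein-induced stiffening).

wlcAFM implements the simulation-assisted fix, end to end, for anyone
analysing AFM images of short DNA (or benchmarking tracing algorithms):

1. **Simulate** 2D equilibrium WLC chains (Gaussian bend angles of variance
   delta/xi per 0.34 nm step).
2. **Render** them into mock AFM images: 2 nm ridge rasterisation,
   grey-scale dilation by a 3 nm spherical-cap tip, Gaussian background
   noise, background-plane flattening.
3. **Trace** with a threshold -> thinning -> single-pixel-contour pipeline
   and the chain-code (axial 1, diagonal sqrt(2)) length estimator.
4. **Calibrate** the tracer's length bias on the simulations: a constant
   endpoint bias C (from ensembles of different contour lengths) and a
   stiffness-dependent factor f(xi) = B (1 - A/xi) fitted over a stiffness
   grid (B = 1 reproduces the classical one-parameter form).
5. **Estimate** xi from real or simulated images by pooling non-overlapping
   equal-length contour segments across molecules and solving
   <R^2> = WLC(xi*, l*/f(xi*)) self-consistently, with bootstrap errors and
   a stiffness-vs-scale trend test.

## Worked example

Calibrate on simulations, then analyse an independent set of 100 mock
images of 170 nm DNA with true xi = 50 nm:

```r
library(wlcAFM)
cal <- calibrateFromSimulation(nPerCondition = 150, seed = 7)
cal$model
images <- simulateImageSet(100, persistenceLength = 50, nSteps = 500, seed = 8)
res <- analyzeImages(images, cal$model,
                     segmentLengths = c(20, 30, 50, 80, 120, 160), seed = 9)
round(res$estimates, 2)
```

which prints:

```
CalibrationModel: f(xi) = 1.0543 (1 - A/xi) with A = 0.5508 nm, C = 2.1088 nm
  pixel size 1 nm/px, valid for xi in [10, 100] nm, tracer config 'k=3;...'

  segment_length_nm n_segments n_molecules mean_R2_nm2 xi_raw_nm xi_corr_nm se_nm
1                20        800         100      364.21     21.52      44.70  1.88
2                30        500         100      780.36     26.65      47.75  2.15
3                50        300         100     2010.94     32.76      49.06  2.58
4                80        200         100     4738.11     39.09      52.46  3.10
5               120        100         100     9557.97     42.49      52.28  4.54
6               160        100         100    15088.45     42.78      49.91  3.81

trend slope: 0.0355 nm/nm, 95% CI [-0.020, 0.091] -> WLC-consistent
```

Reading the table: `xi_raw_nm` is the naive inversion at each segment
length — at 20 nm segments it is wrong by more than a factor of two, and it
drifts with segment length (an artefact, since the simulated molecules have
a single true xi). `xi_corr_nm` applies the calibrated length correction:
the estimates cluster around the true 50 nm at every scale, within their
bootstrap standard errors (`se_nm`, resampled over molecules; this small
example uses 150 calibration molecules per condition and 100 analysed
molecules), and the trend fit reports a slope consistent with zero — the
scale-free signature of a worm-like chain.

For real scans, pass float TIFF or plain-text height matrices (nm, square
pixels) to `analyzeImages()`; the calibration model refuses to apply to a
tracer configuration other than the one it was built with unless you
override explicitly.

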