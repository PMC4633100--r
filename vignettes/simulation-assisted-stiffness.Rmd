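---
title: "Simulation-assisted measurement of DNA persistence length from AFM images"
author: "wlcAFM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-assisted measurement of DNA persistence length from AFM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wlcAFM)
```

## The problem

Scanning AFM images individual DNA molecules adsorbed on a surface at
near-basepair resolution. Pooling many molecules, equilibrium statistical
mechanics turns geometry into mechanics: for a two-dimensional worm-like
chain (WLC) the mean-square end-to-end distance obeys

$$\langle R^2\rangle \;=\; 4\xi L_C\left(1-\frac{2\xi}{L_C}
  \left(1-e^{-L_C/2\xi}\right)\right),$$

where $\xi$ is the persistence length and $L_C$ the contour length.
Inverting this relation for $\xi$ after measuring $\langle R^2\rangle$ and
$L_C$ is exquisitely sensitive to contour-length error near the rigid-rod
limit: for a 100 bp molecule (34 nm) with $\xi = 50$ nm, underestimating
$L_C$ by ~2% (less than 1 nm) inflates the inferred $\xi$ by ~60%
(`errorPropagationCurve(34, 50, -0.02)`). Automated tracing of pixelated,
tip-broadened ridges inevitably makes percent-level length errors, so the
naive inversion is unusable for short DNA.

The remedy implemented here is to *calibrate the tracer against itself*:
simulate 2D WLC molecules whose true contour length and stiffness are known,
render them into mock AFM images with the same pixelation, tip broadening
and noise as real scans, trace those images with the identical pipeline, and
measure the tracer's length bias as a function of stiffness. The measured
bias then corrects real measurements inside a self-consistent inversion.

## The chain model and its assumptions

A 2D equilibrium WLC is grown step by step: `nSteps` segments of
$\delta = 0.34$ nm (one basepair), each step rotating the heading by an
independent Gaussian bend angle of mean zero and variance $\delta/\xi$ (the
2D WLC bend-angle law). Assumptions worth stating:

* **Equilibrated 2D adsorption.** The chain is generated in the plane at
  equilibrium; surface-trapping kinetics of a 3D coil projected onto the
  surface are not modelled.
* **Ideal chain.** No excluded volume; soft chains routinely self-cross
  (`isSelfCrossing`). Self-crossing molecules tend to skeletonise into
  branched or looped components, which the tracer rejects — the same
  selection a human operator applies when deleting uninterpretable traces.
* **Unwrapped Gaussian angles.** For $\xi \gg \delta$ the weight beyond
  $\pm\pi$ is negligible ($\mathrm{sd} \approx 0.08$ rad even at
  $\xi = 10$ nm), so no wrapped-normal correction is applied.
* The initial heading is uniform on $[0, 2\pi)$ per molecule (configurable
  to a fixed value), so ensembles carry no raster alignment.

Reproducibility: one master seed spawns per-molecule substreams
(`generateEnsemble`), so ensembles are exactly repeatable while molecules
stay independent.

## The forward imaging model

`rasterizeChain` renders the molecule as a flat-topped ridge of height equal
to its 2 nm diameter over every pixel whose centre lies within one radius of
the backbone (a hemicylindrical cross-section is available as a sensitivity
option). `dilateWithTip` applies grey-scale dilation by the tip's reflected
profile — a spherical cap of radius $R_T = 3$ nm by default (the drop
$z(r)=R_T-\sqrt{R_T^2-r^2}$ subtracted inside the footprint), or a flat
disk. `addNoise` adds i.i.d. Gaussian background noise; `flattenImage`
removes a least-squares background plane, the only processing applied to
raw scans.

Key parameter defaults, all exposed and all folded into the configuration
hash that tags calibration models:

| parameter | default | meaning |
|---|---|---|
| `stepLength` | 0.34 nm | basepair rise; fixes bp ↔ nm conversion |
| `diameter` | 2 nm | B-DNA width and ridge height |
| `pixelSize` | 1 nm/px | 512 px over a 512 nm scan |
| `TipModel(radius)` | 3 nm, spherical cap | tip broadening |
| `noiseSigma` | 0.15 nm | background roughness of synthetic fixtures |
| `thresholdK` | 3 | binarisation at 3 background sigmas over the median |
| `spurPx` | 3 px | skeleton spur pruning limit |
| `nPerCondition` | 500 | molecules per calibration condition |

The pixel count of the reference experimental scans is not recorded in the
source material, so 1 nm/px is adopted and exposed; calibration constants
are expected to change with pixel size, which is why models refuse to apply
to a mismatching configuration without an explicit override. The noise
magnitude of real scans is likewise unrecorded; 0.15 nm is a realistic
tapping-mode background for this kind of sample, and the tracer thresholds
in units of the *estimated* noise, so the pipeline transfers across noise
levels.

## Tracing

`traceImage` runs flatten → threshold → thin → extract → measure:

1. **Threshold** at the background median plus $k\sigma$ ($k = 3$), with
   $\sigma$ estimated robustly (MAD) from molecule-free pixels.
2. **Thinning** by the classical two-subiteration scheme, which removes
   border pixels without breaking 8-connectivity, followed by a sequential
   simple-point clean-up that deletes pixels whose neighbours remain
   mutually connected — this leaves every interior skeleton pixel with an
   unambiguous predecessor and successor.
3. **Extraction**: each component with exactly two endpoints and no branch
   pixels (after pruning spurs up to 3 px, the blunt-end artefacts of tip
   dilation) becomes one ordered trace, walked from its lexicographically
   smallest endpoint (a determinism tie-break). Components touching the
   border, loops, and irreducibly branched components are rejected with a
   recorded reason; interactive repair is replaced by an optional
   deterministic gap-merging hook, off by default.
4. **Length** by the chain-code estimator: axial moves count one pixel,
   diagonal moves $\sqrt2$ — exactly the Euclidean length of the polyline
   through pixel centres.

## Calibrating the length bias

The bias model is $\overline{L_C^*} = f(\xi)\,(L_S - C)$: a constant
endpoint bias $C$ plus a stiffness-dependent multiplicative factor.

**The constant C.** Comparing ensembles of identical stiffness but
different contour length cancels $f$. The package fits a weighted
regression of mean measured length on true length across three contour
lengths (34, 85, 170 nm by default); for exactly two lengths this reduces
algebraically to the classical ratio formula (`estimateC`). The regression
matters: an error $\mathrm{d}C$ rescales every measured $\hat f$ by
$\mathrm{d}C/(L_S-C)$, and the steep error propagation above turns a
0.1% scale error into several percent of $\xi$ at 20 nm segments. Three
lengths cut the standard error of $C$ several-fold relative to one pair.

**The factor f.** $\hat f(\xi) = \overline{L_C^*}/(L_S - C)$ is measured on
a grid $\xi \in \{10, 15, 25, 50, 75, 100\}$ nm at $L_S = 170$ nm,
bracketing both the stiff (~50 nm) and soft surface-adsorbed (~13 nm)
regimes, with bootstrap standard errors over molecules.

**The functional form.** The classical one-parameter form
$f(\xi) = 1 - A/\xi$ (available as `fitA`) presumes the tracer recovers
rigid contours exactly. Measured on this pipeline at 1 nm/px the bias curve
instead converges to $f(\infty) \approx 1.05$: the plain chain-code length
estimator over-reads smooth digitised curves by up to 8% depending on
orientation (~+5.4% on average), while skeleton smoothing under-reads
wiggly, soft molecules. Both effects are multiplicative per unit arc, so
the two-parameter form

$$f(\xi) \;=\; B\left(1-\frac{A}{\xi}\right)$$

fits the measured factors to within their bootstrap error
(`fitBiasModel`; residuals ~$10^{-3}$), with $B \approx 1.05$ and
$A \approx 0.55$ nm for the default configuration. $B = 1$ recovers the
classical form exactly; the bias form is an empirical property of each
tracing algorithm, and the `CalibrationModel` container carries whichever
the data demand. Forcing $B = 1$ here would inject percent-level length
errors — precisely the failure the calibration exists to remove.

## Estimating the persistence length

`segmentContour` walks each accepted trace from one end, cutting a segment
every time the accumulated chain-code length first reaches the requested
$\ell^*$ and discarding the incomplete remainder; each segment records its
*realised* arc length (within one chain-code step of the request — using
the realised mean removes the overshoot bias) and the Euclidean distance
between its cut pixels. `estimateXi` pools segments across molecules,
averages $R^2$ (molecules thereby weighted by their segment count), and
solves the self-consistent system

$$\overline{R^2} \;=\; \langle R^2\rangle_{\mathrm{WLC}}
  \!\left(\xi^*,\; \frac{\bar\ell^*}{f(\xi^*)}\right)$$

by fixed-point iteration from the uncorrected inversion (relative tolerance
$10^{-8}$, capped at 100 iterations; it reduces to a single shot when $f$
is flat and typically converges in ~5 steps). The correction uses only
$f$: segments are cut in the molecule interior, so the endpoint bias $C$
never enters the analysis stage. Uncertainties are bootstrap resamples of
*molecules*, not segments, respecting within-molecule correlation.
`trendFit` regresses the corrected estimates on segment length: a slope
confidence interval containing zero is the scale-free WLC signature,
whereas protein-stiffened DNA (e.g. by the nucleoid protein H-NS) shows a
scale-dependent trend.

## Numerical choices

* `wlcMSD` switches to the series
  $L^2(1 - x/3 + x^2/12 - x^3/60)$, $x = L/2\xi$, for $x < 10^{-3}$,
  avoiding catastrophic cancellation in the rigid limit; the branch point
  is seamless to $10^{-9}$ relative.
* `invertMSD` brackets the unique root on $\log\xi$ (the forward relation
  is strictly increasing from 0 to $L^2$) to $10^{-10}$ relative;
  $\overline{R^2} \ge L^2$ is a distinct, flagged non-physical condition.
* Degenerate inputs are first-class: empty foreground yields an empty trace
  list, loops and branched skeletons are rejected (not guessed at), tips
  smaller than half a pixel warn and act as identity, and calibrated
  inversion refuses to evaluate $f$ at $\xi^* \le A$.

## What the synthetic generator does and does not emulate

It emulates: tip-broadened ~2 nm ridges of ~170 nm molecules on a flat
background, square pixels, additive Gaussian roughness, background tilt,
self-crossing of soft chains, and the throughput of a ~400-molecule
experiment. It does not emulate: scan-line and feedback artefacts, thermal
drift, tip asymmetry or double tips, surface-trapping (non-equilibrium)
conformations, sequence-dependent flexibility, or molecule-molecule
overlap on crowded fields. Passing tests therefore demonstrate that the
*analysis chain* is unbiased for equilibrated 2D WLC molecules under
realistic imaging corruption — they cannot by themselves certify physical
conclusions about any particular surface chemistry.

## Statistical resolution at study scale

The package's own Monte-Carlo accounting (reproduced by the uncertainty
table in the test suite) puts the sampling SD of the pooled estimator at
$N = 400$ molecules at roughly 1.5% of $\xi$ for 20–30 nm segments, rising
to ~4% at 160 nm segments where each molecule contributes a single
segment. Segment pooling is exactly the point: spreads scale as
$N^{-1/2}$ and, across segment lengths, as $n_S^{-1/2}$ with $n_S$ the
segments per molecule. A worst-case check across all segment lengths at
the 2% level is therefore dominated by the long-segment column and can
exceed 2% at $N = 400$ purely through sampling noise even when the method
is unbiased; the short-segment columns, where calibration does the real
work, sit comfortably inside it. Problem sizes used by the shipped checks:
calibration at 500 molecules per condition, analysis at 400 molecules,
and an uncertainty study of 40 replicates at $N \le 200$.

## Known limitations

* Calibration constants are meaningful only for the exact tracer/imager
  configuration (hash-checked at load time); changing pixel size, tip,
  threshold or pruning re-requires calibration.
* At $\xi = 10$ nm roughly half of 170 nm molecules self-cross and are
  rejected, so the softest calibration point carries a selection bias that
  the fit down-weights via its larger bootstrap error but does not remove.
* The bias form is empirical; the package checks its residuals against
  bootstrap errors rather than asserting universality.
* Real-image workflows (`analyzeImages` on TIFF/text matrices) assume
  height maps in nm with square pixels and a reasonably flat substrate.
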