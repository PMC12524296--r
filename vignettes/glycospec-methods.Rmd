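---
title: "Methods: SWIR chemometrics for tuber glycoalkaloid prediction"
author: "glycospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SWIR chemometrics for tuber glycoalkaloid prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glycospec)
```

# The problem

Glycoalkaloids (the sum of alpha-solanine and alpha-chaconine, "TGA",
reported in ppm) accumulate in potato tubers under light exposure and are a
food-safety concern above regulatory limits. Reference quantification is
destructive wet chemistry (extraction + HPLC). The pipeline implemented
here predicts TGA non-destructively from short-wave infrared (SWIR,
900-2500 nm) hyperspectral reflectance images of whole tubers:

1. calibrate raw hypercubes to reflectance against white/dark reference
   tiles, `calibrateReflectance()`;
2. segment the tuber from the dark background with Otsu's threshold on the
   band-averaged intensity image and keep the largest connected component,
   `buildMask()`;
3. average the masked pixels per band into one spectrum per tuber,
   `meanSpectrum()` / `extractDataset()`, giving the n x 169 analysis
   matrix;
4. pre-process spectra (SNV, Savitzky-Golay derivatives, OSC),
   `applyChain()`;
5. select informative wavelengths (CARS or IRIV, then backward
   elimination), `carsSelect()` / `irivSelect()` / `backwardEliminate()`;
6. calibrate PLS or RBF-SVR models and report R2/RMSE for leave-one-out
   cross-validation, calibration and a random 70:30 prediction split, plus
   RPD, `evaluateModel()` / `runExperiment()`.

No public spectra with reference TGA values exist for this design, so the
package ships a synthetic-data module that generates spectra, hypercubes
and reference values with known ground truth; every claim the test suite
makes is made against that ground truth.

# The spectral forward model (synthetic data)

`generateSpectrum()` draws one tuber reflectance spectrum on the instrument
grid (169 bands, 901.121 + k * 9.527 nm; the printed instrument endpoint
2501.676 nm is inconsistent with that arithmetic, which gives 2501.657 nm —
the package follows the arithmetic):

R(lambda) = clip( g * [ R0 + b (lambda - mean) - sum_j d_j G(lambda; c_j, w_j)
            - t_eff * sum_k d_k G(lambda; c_k, w_k) ] + eps(lambda), 0, 1.2 )

* G is a Gaussian in wavelength; peak *width* parameters are Gaussian
  standard deviations. The matrix peaks sit at 976, 1214, 1431, 1781 and
  1905 nm (water and carbohydrate overtones; widths 30 nm, depths
  0.06-0.25, strongest at the 1905 nm water band). The TGA-linked peaks sit
  at 1166.3, 1649.3, 1791.4, 2047.1, 2085.0, 2378.5 and 1933.4 nm, widths
  20 nm, depth 8e-5 reflectance units per ppm each — at a typical 150 ppm
  the analyte signal is a few percent of reflectance, deliberately small
  against the matrix so that multivariate calibration (not a single band)
  is required, as in the real data.
* t_eff = tga * (1 + tga_nonlin * tga): the TGA effect is linear by
  default (`tga_nonlin = 0`), which is the regime in which PLSR is the
  right model; the knob exists for robustness experiments only.
* Nuisance terms emulate scatter and drift: multiplicative gain
  g ~ lognormal(0, 0.05), additive baseline slope b ~ N(0, 5e-5) per nm,
  white noise eps ~ N(0, 0.005). SNV and derivatives largely remove the
  first two, which is why those chains help, mirroring the real analysis.
* Clipping to [0, 1.2] is applied after noise; reflectance slightly above
  the white tile is a real artifact of calibration.

`generateDataset()` draws three light-exposure day groups (Day 0/7/14) of
70 tubers with mean TGA 97.13, 159.56 and 128.41 ppm — the non-monotone
Day-14 value reproduces the reported accumulation-then-decline pattern as a
group mean only; no kinetic mechanism is modelled. The within-group spread
(30 ppm) is a free choice: group standard deviations are not reported
anywhere, and 30 ppm puts split-evaluation RPD in the fair-to-good range
(about 1.4-2.5), the regime the real study operates in. Sampling is
normal truncated at zero (concentrations cannot be negative).
`generateHypercube()` renders an elliptical tuber (64 x 48 frame,
semi-axes 20 x 14 pixels) of per-pixel spectra with 2% pixelwise gain
jitter over a flat 0.02-reflectance background, and `generateReferences()`
produces the 99%-reflectance white tile and near-zero dark frame.

What the generator does *not* emulate: spatially structured TGA within a
tuber (the analysis averages to one spectrum per tuber anyway), wavelength-
correlated noise, detector nonlinearity, and any greening kinetics. Tests
passing on synthetic data therefore validate the *algorithms* under the
stated statistical structure, not instrument-specific artifacts.

# Pre-processing

* **SNV** centers and scales each spectrum to unit sample standard
  deviation; it is idempotent and errors on constant spectra.
* **Savitzky-Golay first derivative** defaults to window 11, polynomial
  order 2 (a free choice of this package; window
  11 spans about 95 nm, wide enough to smooth the 0.005-level noise and
  narrow enough to resolve 20-nm-wide analyte peaks). The derivative is
  taken per band index; on a uniform grid this differs from a per-nm
  derivative only by the constant 9.527, which rescales all coefficients
  jointly and is irrelevant to any model here. Edges are handled by the
  asymmetric polynomial fits, so the filter is exact on polynomials up to
  the fitting order everywhere.
* **OSC** removes components of X whose scores are orthogonal to y. The
  implementation is the direct constrained-eigenvector form: project the
  covariance direction X'y out of the weight space, take the leading right
  singular vector of the projected X, deflate, repeat. Compared with the
  common alternating-orthogonalization iteration this is deterministic,
  has no convergence tolerance, and the training scores are orthogonal to
  y *by construction* (the test bound |cor(t, y)| < 1e-8 is float noise,
  not an algorithmic tolerance). One component is removed by default (the
  conventional choice; removing more risks stripping predictive
  variance). The component count
  must stay below rank(X).
* **"|1st Der| + SNV"** is parsed as elementwise absolute value of the
  derivative, then SNV, matching the printed label.
* **Chains and leakage.** Response-dependent steps (OSC) are fitted on
  training rows only and applied frozen to test rows; within
  cross-validation the chain is refitted per fold. Fitting pre-processing
  once on the full dataset — which published chemometric analyses often do —
  is available behind the explicit `leaky_preprocess` flag and is never the
  default. Derivatives and SNV are applied to the full spectrum before any
  band subsetting: a local-polynomial derivative on a scattered band subset
  is meaningless.

# Calibration models and metrics

**PLS1 by NIPALS.** `plsFit()` mean-centers X and y and extracts latent
variables by NIPALS (for a univariate response the weight step needs no
inner iteration). The collapsed coefficient path B_a = W (P'W)^-1 q is
stored for every truncation a, so cross-validation over latent-variable
counts costs one fit. At full rank PLS1 equals ordinary least squares,
which the tests assert against the normal-equations solution. The
latent-variable ceiling defaults to 15, matching the operating point of
the emulated study design; the working count is chosen by the minimum of the
cross-validated RMSE path (`selectLV()`, ties to the smaller count).

The wavelength selectors evaluate thousands of band subsets, so the
cross-validated RMSE path is computed by a C++ engine using the Krylov
characterization of PLS1: the a-component coefficient vector minimizes the
training residual over span{s, Cs, ..., C^(a-1) s} with C = X'X, s = X'y.
A per-fold Gram matrix is computed once and each subset evaluation touches
only its k x k block; Lanczos with full reorthogonalization replaces
rank-one deflation. The engine agrees with the NIPALS route to machine
precision (tested), and all reported models come from the NIPALS fit.

**RBF-SVR.** Epsilon-insensitive support-vector regression
(`svrFit()`, via e1071/libsvm) with inputs standardized by training
statistics inside the fit. Standardization is done in-package because
libsvm's own scaling option also scales the response, which would silently
turn epsilon-in-ppm into epsilon-in-standard-deviations. If every training
target lies inside the epsilon tube the optimum is the constant predictor
(w = 0, intercept at the midpoint of the feasible interval), which the fit
detects and stores explicitly. `tuneSVR()` minimizes 5-fold RMSECV over a
grid (C in {1, 10, 100, 1000}, epsilon in {1, 5, 10, 20} ppm; the
tune-then-freeze protocol keeps one pair for every model of a run); ties resolve
toward smaller C, then larger epsilon, and the chosen pair is frozen for
every model of a run.

**Metrics.** R2 = 1 - SSE/SST with the mean taken over the actual values
of the evaluated set (cross-validation, calibration, prediction
respectively; pooled LOOCV uses the full-set mean); RMSE in ppm;
RPD = sd(prediction-set reference) / RMSEp, with the definitional identity
rpd = sd_p / rmse_p asserted on every report row. Evaluation is LOOCV for
cv metrics plus one random 70:30 split (unstratified by
default; day-group stratification is a caller option) for calibration/prediction metrics.

# Wavelength selection

**CARS.** Each of 50 Monte Carlo runs draws 80% of the samples, fits PLS
on the currently retained bands and converts coefficient magnitudes to
weights w = |beta|/sum|beta|. The exponentially decaying function (EDF)
fixes the retention budget ceil(r_i p), r_i = a e^(-k i), with the
two-point pinning a e^(-k) = 1 and r_N = 2/p, so run 1 keeps all bands and
run N keeps two (two-point
pinning is the standard choice for the decay constants). Adaptive reweighted sampling fills the
budget by weighted sampling without replacement; zero-weight bands are
never selected. After each run the retained set's pooled 5-fold RMSECV on
the full sample set is recorded and the run with the minimum wins. The
trace (retained counts, RMSECV path, coefficient magnitudes per run) is
sufficient to replot the usual three selection panels.

**IRIV.** Each round draws a binary inclusion matrix (100 rows by default,
inclusion probability 0.5, at least two bands per row) and scores every
row's band subset by 5-fold RMSECV; for every band, every row is also
scored with that band's column flipped, giving a paired
inclusion/exclusion design. Band classes follow the sign of
mean(excluded) - mean(included) and the two-sided Mann-Whitney p-value
(strongly/weakly informative vs uninformative/interfering at alpha =
0.05); the latter two classes are dropped and rounds repeat (cap 10) until
nothing is dropped. The row count is the package's choice: with the paired flip design every band receives 100 paired
comparisons per round, which is ample for the rank test, and the round
costs n_rows x (p + 1) cross-validated PLS evaluations — the dominant cost
of the whole pipeline.

**Backward elimination** greedily removes the band whose removal gives the
lowest evaluator RMSECV, accepting only if the RMSECV does not worsen by
more than `tolerance` (default 0; ties remove the lowest-index band;
tolerance = Inf degenerates to the single best band). The evaluator
averages the pooled 5-fold RMSECV over 10 fold partitions: comparing two
nested band sets on a single partition is dominated by fold-assignment
noise and the accept/reject decision near a tie is close to a coin flip;
averaging partitions stabilizes it. A caveat worth stating: cross-
validation on a fixed dataset partially rewards a spurious variable,
because the variable's realized sample correlation with the response is
shared by all folds. Removal of a genuinely uninformative band is
therefore accepted with high probability, not with certainty — this is a
property of cross-validated greedy selection itself, not of this
implementation.

**Mann-Whitney U** is implemented in-package with midrank ties, exact
two-sided p by enumeration of all labelings for combined sizes up to 12
(correct under ties, which the enumeration handles naturally and standard
exact routines refuse), and the tie-corrected normal approximation (no
continuity correction) above that.

# The recovery benchmark

`generateBenchmark()` makes selector recovery a well-posed question:
exactly `n_informative` (default 10) of 169 bands respond to a latent
concentration with band-specific coefficients; all bands additionally
carry smooth low-rank background variation that is *independent of the
response*, plus iid measurement noise (sd 0.05). Coefficients are scaled
analytically so the population R2 of the best linear predictor is 0.8
(SNR = R2/(1-R2)). Two design points matter:

* The background must be response-orthogonal. If the response were built
  from raw columns including their background content, every band would
  carry response information through the shared background and "the 10
  true bands" would not be the ground truth they claim to be.
* A band carrying only background is *not* conditionally uninformative: a
  multivariate model uses such bands as reference channels to cancel the
  background in the informative bands. A planted "pure noise" band for
  elimination tests must therefore carry neither response nor background.

The validation suite runs CARS, IRIV and BE over 20 benchmark seeds
(210 x 169, IRIV capped at 10 latent variables) and checks the recovery
rates; the end-to-end suite runs the full pipeline on a low-noise study
configuration and a three-level noise sweep.

# Numerical and degenerate-input policy

Constant spectra (SNV), constant images (Otsu), empty masks, zero-variance
responses, out-of-range latent-variable counts, white <= dark calibration
references, ellipses outside the frame, all-dropped IRIV rounds and
unknown fixture keys raise errors naming the problem. Argmin ties resolve
to the simpler model (fewer latent variables, smaller C, larger epsilon,
lowest band index, lowest threshold edge). The EDF budget guards the
pinned endpoints against floating-point round-up. Krylov breakdown (rank
exhaustion) truncates the latent-variable path, with predictions constant
beyond the truncation. All randomness flows through explicit seeds; the
pipeline derives per-stage seeds as seed * 1000 + stage index, so any
stage can be reproduced in isolation. Reports are written with full
precision ("%.17g") so identical runs are byte-identical.

# Problem sizes

The shipped validation uses the study scale throughout: 210 samples x 169
bands for datasets and benchmarks, 50 CARS runs, 100-row IRIV inclusion
matrices, 20 seeds for recovery statistics, LOOCV with per-fold
pre-processing refits for reported metrics. On one CPU the complete test
suite runs in a few minutes; a full CARS+BE+PLSR pipeline run takes under
half a minute.

# Known limitations

* Real acquisition effects (stray light, detector drift, dead pixels,
  spatial TGA gradients) are outside the generator; no dead-pixel or median
  filtering is implemented, matching an acquisition with no dead pixels.
* The ENVI reader supports the one dialect the workflow uses (BIL/BSQ,
  float32, little-endian, wavelengths in the header).
* Published wavelength tables are shipped as fixtures and matched to the
  uniform grid by nearest band, because the printed values do not fall
  exactly on that grid.
* The published full-study metrics were measured on 210 real tubers
  whose spectra are not deposited; nothing here re-estimates them, and
  the synthetic study is not calibrated to reproduce them numerically.
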