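---
title: "Monitoring probiotic juice fermentation with NIR spectroscopy and aquaphotomics"
author: "aquaferm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring probiotic juice fermentation with NIR spectroscopy and aquaphotomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaferm)
```

## The problem

Probiotic fermentation of fruit juice is conventionally tracked by
destructive reference assays: pH electrodes and plate counting of colony
forming units (CFU/mL). Near-infrared (NIR) transmission spectroscopy in the
first overtone region of water (1300–1600 nm) offers an indirect,
non-destructive alternative. As lactic acid bacteria acidify the juice and
grow, the water absorbance spectral pattern shifts — acidification and the
release of formerly bound water raise absorbance around 1400–1450 nm, while
strongly hydrogen-bonded water species above ~1460 nm lose intensity — and
increasing cell density adds multiplicative scatter (turbidity). Chemometric
models calibrated on these spectra can then classify the fermentation stage
and predict pH and log cell count in real time. Aquaphotomics summarizes the
same information on twelve conventional water matrix coordinates (WAMACs),
displayed as radar-plot aquagrams.

`aquaferm` implements this entire analysis chain — and, because the
underlying experimental spectra are not publicly deposited, it also ships a
seeded simulator that generates a complete synthetic experiment with known
ground truth, so every stage of the pipeline is testable end to end.

## The simulated experiment

The canonical design follows standard practice in fermentation-monitoring
studies: three starter cultures — *Bifidobacterium longum* (`BL`),
*Lactobacillus salivarius* (`LS`) and a 1:1 mixed culture (`MC`) — sampled
at 0, 4, 8, 16 and 24 h, with the unfermented 0 h juice measured once as a
shared `JUICE` baseline group. That gives 3 × 4 + 1 = 13 biological sample
groups; with 3 replicates and 3 consecutive instrument scans per replicate
the full set holds 117 spectra, and each per-strain subset (strain plus the
shared baseline) holds 45.

The 0 h samples are treated as replicates of one shared juice batch rather
than three per-culture batches: immediately after inoculation, the three
vessels contain the same juice at the same pH and the same starting
inoculum, so a single baseline group is both parsimonious and what makes
the per-strain subset size come out at 45.

### Reference trajectories

pH decays exponentially, $pH(t) = pH_{end} + (pH_0 - pH_{end})\,e^{-kt}$,
from 6.5 towards 4.0. An exponential family was chosen because observed pH
curves in this system are near-stationary after 16 h; the decay rate is the
only shape parameter that must be strain-specific. `BL` and `MC` use
$k = 0.20\,\mathrm{h^{-1}}$ (pH 4.10 at 16 h, 4.02 at 24 h — effectively
stationary), while `LS` uses $k = 0.12\,\mathrm{h^{-1}}$ so that its pH
still falls appreciably between every pair of consecutive sampling points.

Cell counts are modeled on the log10 scale with piecewise parametric
curves rather than a mechanistic growth model — the observations to
emulate are curve *shapes*, not kinetic constants. All curves pass through
log10 CFU = 7 at 0 h (the inoculum level):

* `BL`: a logistic rise into a stationary phase near 9.0 (no decline
  within 24 h);
* `LS`: a normalized logistic rise that reaches $\log_{10}(2\times 10^9)$
  at exactly 8 h, followed by a linear decline of 0.15 log/h — the
  early-peak-then-crash pattern of a fast, acid-sensitive fermenter;
* `MC`: a lag phase, a logistic rise to 9.2 at 16 h, then a 0.10 log/h
  decline.

### Spectra

Each scan is built as

$$A(\lambda) = B(\lambda) + \sum_{k=1}^{12} a_k\,
G(\lambda; c_k, \sigma_k) + s(\lambda) + \varepsilon$$

* $B(\lambda)$ is a smooth juice/water baseline (offset 0.15 plus a broad
  Gaussian of amplitude 0.5 centered at 1445 nm, width 55 nm), emulating
  the dominant water first-overtone band seen through a 1 mm cuvette.
* The twelve Gaussian component bands sit at the WAMAC centers
  (1342–1512 nm, widths 7–10 nm). Each amplitude is affine in the
  reference state, $a_k = \alpha_k + \beta_k (pH_0 - pH) + \gamma_k
  (\log_{10}\mathrm{CFU} - 7)$. The acidification couplings $\beta_k$ are
  positive up to 1452 nm (strongest at 1412–1440 nm, so the difference
  spectrum peaks inside 1400–1450 nm) and negative above 1462 nm,
  reproducing the characteristic see-saw of the water spectral pattern
  during fermentation. A few bands carry small cell-density couplings
  $\gamma_k$ so that log CFU is spectrally identifiable beyond its
  correlation with pH.
* $s(\lambda)$ is the turbidity term: a slope/offset tilt proportional to
  $\log_{10}\mathrm{CFU} - 7$ (0.004 and 0.010 AU per log unit) plus a
  random per-scan slope/offset jitter (sd 0.002) emulating cuvette
  refills.
* $\varepsilon$ combines a flat replicate offset (sd 0.002 AU, shared by
  the three consecutive scans of a replicate — biological variation) and
  per-wavelength scan noise (sd 0.001 AU — instrumental). Replicate-level
  noise also enters the reference values themselves (pH sd 0.01, log CFU
  sd 0.05), and the spectra are generated *from the noisy reference*, so
  spectra and reference table are consistent the way a real paired data
  set is.

The noise scale was fixed once at a level where the fermentation-time
classes are well separated — the regime in which the emulated study
operates (its reported models classify time points essentially perfectly).
The balance between the couplings and the turbidity tilt was calibrated at
design time against the qualitative constraints the simulator must honor
(difference spectra peaking at 1400–1450 nm; aquagram coordinates rising
below 1452 nm and falling above 1462 nm for late fermentation times) and
then frozen; the acceptance checks were not used to adjust it.

What the simulator deliberately does **not** emulate: chemical speciation
(acids are represented only through band-amplitude effects, not as
spectral components of lactic/acetic acid), wavelength-dependent detector
noise, temperature perturbations of the water spectrum, batch-to-batch
juice variation, and any structure outside 1300–1600 nm. Consequently,
passing tests demonstrate that the *pipeline* is correct and that the
analysis behaves as expected *under the stated statistical structure*;
they do not certify performance on real instrument data.

## Pretreatments

All six standard operators are provided, each shape-preserving over the
wavelength grid: Savitzky–Golay smoothing (2nd-order local polynomials;
boundary points use the terminal-window fits, so the grid never shrinks),
polynomial detrending (default degree 2; the degree is a parameter because
either convention is common and the choice is not critical for these
data), SNV (per-spectrum standardization, $n-1$ denominator), MSC
(regression on the set-mean reference by default), and Savitzky–Golay
derivatives of order 1 or 2 scaled per nm. MSC and SNV are mutually
alternative scatter corrections, and a `pretreatmentSpec` refuses to chain
both. Group averaging (`averageBy`) and per-culture difference spectra
against the 0 h baseline complete the set. Typical window presets are 21,
35 and 43 points, shipped per analysis in `defaultRunConfig()`.

## Chemometrics

**Grouped three-fold cross-validation.** The three consecutive scans of a
replicate are nearly identical, so any fold plan that splits them between
training and validation leaks. `makeFoldPlan()` assigns fold = replicate
index; every fold therefore holds one full measurement repetition of every
sample. The no-split invariant is asserted *inside* every CV loop, not
just at plan construction.

**PCA-LDA.** PCA (column-mean-centered SVD, with the sign of each loading
fixed so its largest-magnitude element is positive) compresses the spectra;
a linear discriminant with pooled within-class covariance and equal priors
classifies the scores. Equal priors reflect the balanced design. Inside
cross-validation the PCA is refit on the training rows of each fold and
validation rows are projected into that model — the standard
leakage-avoiding convention. A singular pooled covariance (inevitable when
the retained components approach the training degrees of freedom) is
ridge-regularized with $\epsilon = 10^{-8}$ times the mean diagonal.
`selectNrPCs()` scans 1..30 components and picks by highest validation
accuracy, then smallest train-validation gap, then parsimony; the
precedence puts validation accuracy first because the gap criterion alone
would favor uninformative models that are equally poor in both sets. The
full candidate table is always returned for audit.

**PLSR.** Univariate NIPALS with X-deflation; the regression vector is
reconstructed as $b = W(P^TW)^{-1}q$ so predictions are a single linear
map plus intercept (asserted to 1e-8 in the tests). Latent variables are
selected by minimal RMSECV over the grouped folds, ties broken towards
fewer variables; components are truncated automatically when X is
exhausted (noiseless data have low rank, and requesting more components
than the rank supports is not an error but a warning). R²CV is computed
from the pooled held-out predictions rather than averaged per-fold, which
keeps it a single comparable number. Note that RMSEC ≤ RMSECV is *not*
asserted anywhere — with grouped folds and small n the inequality can
legitimately fail.

The cell-count model is fit on spectra averaged per culture × time
(n = 12) because replicate-level plate counts are noisy; after averaging,
replicate identity is gone, so its three-fold plan is a seeded shuffle
stratified by culture (every fold sees every culture). This is flagged in
the pipeline report since it is a weaker validation than the
replicate-grouped plan.

## Aquagrams

`wamacCoordinates()` registers the twelve coordinates at 1342, 1364, 1374,
1384, 1412, 1426, 1440, 1452, 1462, 1476, 1488 and 1512 nm. The exact
nominal set varies between studies, so the registry is fully overridable;
these values are the conventional centers inside the ranges used in the
aquaphotomics literature. The classic normalization is used: smooth + SNV,
average per display group, then standardize each coordinate across the
displayed groups, $(A_g - \mu)/\sigma$. The temperature-perturbation
variant ("aquagram 2.0") is out of scope because this design has no
temperature gradient. Coordinates resolve to the nearest grid wavelength
(exact on the default 0.5 nm grid); a band-mean option exists because the
coordinates are strictly wavelength *ranges*. Difference aquagrams
subtract the 0 h baseline group, mapping it to the zero vector.

## Numerical choices and degenerate inputs

* Savitzky–Golay windows must be odd, exceed the polynomial order and fit
  the grid; derivatives require an even grid.
* SNV refuses constant spectra (naming the offending rows); MSC refuses a
  constant reference and spectra orthogonal to it.
* PCA caps components at min(n − 1, p); candidate counts in model
  selection are additionally capped by the training-split rank, with a
  warning rather than an error.
* All model fits are deterministic: fixed sign conventions in PCA and the
  LDA canonical directions, no randomized initialization anywhere. The
  only RNG use is the simulator and the stratified fold shuffle, both
  seeded.
* Ties in model selection always resolve towards the smaller model.

## Problem sizes

The shipped configuration operates at the scale of the emulated study: 117
spectra × 601 wavelengths, per-strain subsets of 45, a 12-row averaged set
for cell count. A full `runPipeline()` — simulation, difference spectra,
PCA, three classification models with component selection up to 30, three
pH regressions with latent-variable selection, one cell-count regression
and three aquagrams — completes in a few seconds on a single core, and the
test suite regenerates everything from code; no data files ship with the
package.

## Reproducing the pipeline

```{r, eval = FALSE}
library(aquaferm)

params  <- simParams(seed = 20250405)
design  <- simulateDesign()
ref     <- simulateReference(design, params)
spectra <- simulateSpectra(design, ref, params)

# classification of fermentation time for one strain
sub  <- applyPretreatment(subsetSpectra(spectra, culture = "BL"),
                          list(list(step = "savgol", window = 21)))
plan <- makeFoldPlan(sub)
lab  <- factor(scanInfo(sub)$time_h)
sel  <- selectNrPCs(sub, lab, plan, maxPcs = 30)
pcaLdaClassify(sub, lab, sel$nrpcs, plan)

# or everything at once
runPipeline(defaultRunConfig(), "pipeline-out")
```
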