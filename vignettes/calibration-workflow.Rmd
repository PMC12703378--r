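---
title: "Vis-NIR calibration of grape quality parameters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vis-NIR calibration of grape quality parameters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinispec)
```

This vignette explains the models and procedures `vinispec` implements,
the parameters that matter, the design decisions taken where the
methodology is genuinely open, and what the synthetic-data validation
does and does not establish about real spectra.

## The problem

A Vis-NIR reflectance spectrum of an intact grape berry is a long
(here ~1400-point) vector dominated by three nuisance effects —
multiplicative scatter from berry size/surface, additive baseline
offsets, and white detector noise — on top of which the analytes of
interest (sugars, organic acids) leave comparatively small absorption
features, e.g. around the 970 nm water/carbohydrate O–H region.
Calibration means learning a map from spectrum to a wet-lab reference
value (SSC in %, TA in g/L, pH) that survives to new samples. The
package decomposes this into pretreatment → partition → wavelength
selection → regression → evaluation, each stage fitted strictly on
calibration rows.

## Spectral pretreatments

Six chains are supported: `raw`, `fd`, `sg`, `fd+sg`, `msc`, `snv`.

* **First derivative (`fd`)** removes baseline shifts. It is computed as
  grid-aware central differences (one-sided at the endpoints), *divided
  by the wavelength spacing* so units are 1/nm; whether to divide is a
  convention, so `scale = FALSE` is available. FD is deliberately plain
  finite differences, not a Savitzky–Golay derivative, because FD and
  S–G appear both separately and composed (`fd+sg`, FD first) in the
  evaluated set, and conflating them would make the composition
  redundant.
* **Savitzky–Golay (`sg`)** smoothing uses window 11, order 2 by
  default — standard chemometric choices for ~0.5 nm grids; both are
  exposed. The implementation delegates the convolution to
  `signal::sgolayfilt`, whose edge handling evaluates the same local
  least-squares polynomial at off-centre positions, so polynomials up to
  the chosen order are reproduced exactly everywhere. The interior
  kernel for (window 5, order 2) is the classic (−3, 12, 17, 12, −3)/35.
* **SNV** autoscales each spectrum (mean 0, sd 1 with the n−1
  denominator), which removes per-scan gain and offset exactly.
* **MSC** regresses each spectrum on the *calibration mean* spectrum and
  corrects to `(x − b0)/b1`. The reference is fitted once on calibration
  spectra and frozen; correcting prediction spectra against their own
  mean would leak information across the partition.

## Gradient (rank-stratified) partition

`gradient_split()` sorts samples by the target reference value and, in
consecutive blocks of four (for the default 3:1 ratio), sends the
block's second-ranked sample to the prediction set. Leftover samples go
to calibration. This construction was chosen because it (a) yields
exactly `floor(n/4)` prediction samples — 36 of 145, with 109
calibrated — and (b) guarantees the calibration range encloses the
prediction range, since ranks 1 and n can never occupy a block's second
slot. Position 2 rather than 1 or 4 is exactly what preserves the
extremes. Splits are per-parameter by default (each parameter ordered by
its own reference values, mirroring how per-parameter set statistics are
reported); a single global split can be forced with `split_by`.

## Wavelength selection

All three selectors operate on preprocessed calibration spectra only.

**SPA.** For every candidate start, a chain is grown by repeatedly
taking the column with the largest norm after orthogonal projection
onto the complement of the chain's span; each chain prefix is scored by
the RMSE of a multiple linear regression on an internal validation
split, and the best (start, size) pair wins. Two implementation points:
the internal validation split is itself a `gradient_split()` of the
calibration responses, which keeps SPA fully deterministic; and the
projections are computed by updating squared column norms against an
orthonormal basis of the chain rather than deflating a copy of the
matrix, which is algebraically identical (the test suite checks
equivalence against an explicit Gram–Schmidt deflation oracle) but an
order of magnitude faster at p ≈ 1400. The default cap of 30 variables
matches common practice for SPA on fruit spectra.

**UVE.** A noise matrix (uniform on [0, `noise_scale`], default
`1e-10 * max|X|`, the original tiny-noise convention) is appended to X;
leave-one-out PLS with `n_lv` components (default 10) yields per-fold
coefficient vectors, and each variable's stability is `t = mean(b)/sd(b)`
across folds. Real variables must beat `threshold_factor` (default 0.99)
times the largest |t| among the noise columns. A variable with zero
coefficient variance across folds gets |t| = ∞ and a degenerate-run
warning. UVE may legitimately retain nothing when no variable beats the
noise ceiling (and retains everything at `threshold_factor = 0`); the
pipeline treats an empty selection as an error at fitting time.

**CARS.** At run *i* of `n_runs` (default 100, matching the
conventional 1–100 sampling-run axis), a PLS model is fitted on a random
80 % of the calibration samples using the currently retained variables;
normalised |coefficients| act as fitness weights. The retention target
follows the exponential schedule `r_i = a e^{-k i}` with `r_1 = 1` and
`r_{n\_runs} = 2/p` (`cars_schedule()` gives the closed form), clamped
below at 2 variables. The literature's two-step reduction (a forced cut
followed by with-replacement adaptive resampling) leaves the retained
count random; here the enforced reduction restricts the candidate pool
to the top `2 m_i` weights and adaptive reweighted sampling then draws
*exactly* `m_i` variables without replacement with probability
proportional to weight. This keeps the competitive, stochastic character
of the selection while making the count trace exactly the schedule —
non-increasing by construction — and every run reproducible from the
mandatory seed. Each run's subset is scored by 5-fold RMSECV on
deterministic interleaved folds; the minimum-RMSECV run is returned.

## Regression models

**PLSR** is NIPALS PLS1 on centred (not scaled) data. For a single
response the NIPALS weight has the closed form `w = X'y/||X'y||`, so no
inner iteration is needed; coefficients for the whole latent-variable
path come from `B_k = W (P'W)^{-1} q` accumulated by forward
substitution. The number of latent variables (max 20 by default) is
chosen by 5-fold RMSECV on interleaved folds — deterministic, which the
bit-identical-rerun guarantee of the evaluation grid relies on.

**SVR** is epsilon-SVR with an RBF kernel (the QP core is `e1071`'s
libsvm). Inputs are standardised with calibration statistics. Cost and
gamma are grid-searched over `2^-8 … 2^8` (17 log-spaced points each,
a deliberately wide default since no narrower range is canonical), with
epsilon defaulting to `0.01 * sd(y)`. Ties in the grid go to the first
candidate in iteration order, again for reproducibility. Epsilon-SVR
(rather than nu-SVR) is the default formulation choice.

**ELM** draws input weights and biases uniformly from [−1, 1] under a
mandatory seed, computes sigmoid hidden activations on standardised
inputs (50 hidden neurons by default), and solves the output weights by
Moore–Penrose pseudo-inverse. ELM is intentionally the fragile member of
the trio — random features plus a least-norm linear solve make it
noise-sensitive, which is precisely the behaviour worth comparing
against.

## Evaluation

`compute_metrics()` returns Pearson R and RMSE with the *n* denominator;
`compute_rpd()` divides the prediction-set reference sd (*n−1*
denominator) by RMSEP. This denominator pairing is not arbitrary: it is
the combination under which a prediction-set sd of 2.23 and an RMSEP of
0.984 give RPD = 2.266 to three decimals, i.e. the standard published
arithmetic is reproduced exactly. Because "correlation coefficient" and
"coefficient of determination" are used interchangeably in this
literature, the report carries both R and R². `run_grid()` executes the
full comparison — per-parameter split, chain fitting, one selector run
per (parameter, chain, selector) shared across models (as comparison
tables report a single wavelength count per selector), model fits, and
metrics — flagging the best cell per parameter by maximal RPD, the usual
ranking criterion.

## The synthetic-data generator

No public grape spectra accompany this workflow, so the generator is a
first-class, tested module that defines the study conditions:

* **Grid and size.** 145 samples on 400–1100 nm at 0.5 nm (1401
  points). An instrument that reports a different variable count simply
  has a non-uniform pixel grid; the grid is treated as data throughout
  and never hard-coded.
* **References.** SSC, TA, pH are truncated-normal with means/sds/ranges
  typical of a white-grape storage trial (SSC 9.23–22.73 %, mean 17.35,
  sd 2.30; TA 3.87–9.79 g/L, mean 5.92, sd 1.46; pH 3.06–4.59, mean
  3.82, sd 0.20), over a 3-temperature (2.7/10.0/20.6 °C) × 15-day
  design. A monotone storage trend (SSC up, TA down, fastest when warm)
  is carried by a standardised day×temperature score inside the variance
  budget: `value = mean + sd (ρu + sqrt(1−ρ²) z)`. The trend share ρ is
  derived from a target shift of ±10 % of the mean at day 15 under the
  warmest temperature (±2 % for pH, which physically moves little), and
  the degenerate case sd = 0 collapses exactly to the mean.
* **Spectra.** Fixed background shape (peaks near 580/720/810 nm,
  valleys near 670/970 nm, as in white-grape reflectance) + Σ band
  coefficients × reference value × Gaussian(centre, width) + polynomial
  baseline, all multiplied by a per-scan gain (uniform 0.9–1.1), plus an
  additive offset (sd 0.01) and white noise (sd 0.002, also the
  replicate-scan noise), clipped to (0, 1]. Negative band coefficients
  deepen absorption with concentration, keeping the 970 nm valley a
  local minimum.
* **Planted bands.** SSC at 970 and 840 nm; TA at 890 and 1040 nm; pH a
  single broad weak band at 1010 nm. The pH analogue is deliberately
  hard — pH reflects hydrogen-ion activity rather than any one
  chemical species, so its spectral response is weak and indirect — and
  the test suite asserts the resulting qualitative ordering (pH scores
  below SSC and TA) rather than any absolute pH accuracy.
* **RNG.** One seed governs a dataset; references draw from `seed` and
  the scatter/noise stream from `seed + 1`, each in a fixed documented
  order, so datasets are bit-reproducible and the caller's RNG state is
  never touched.

**What passing tests show, and what they do not.** The generator's
band-sum + scatter model makes SNV/MSC *provably* effective and gives
selectors a known ground truth, so green tests demonstrate that the
machinery is implemented correctly and that the pipeline recovers
planted structure under realistic noise. They do not demonstrate
real-world accuracy: real berry spectra have correlated (not white)
noise, overlapping analyte bands, nonlinear light-tissue interactions
and cultivar effects, none of which are modelled. Absolute metrics on
synthetic data (RPDs in the teens) are therefore far above what intact
fruit yields in practice; only the relative behaviour (scatter
correction helps, derivatives amplify noise, pH ranks last) transfers.

## Numerical choices and degenerate inputs

* NIPALS stops early when the residual covariance norm falls below
  `1e-12` of the response scale; CV folds that stop early reuse their
  last latent variable's predictions.
* SPA treats projected squared norms below `1e-12 × max` as exhausted
  (exact duplicates of chosen columns can never be selected);
  `which.max` tie-breaks to the lowest index.
* MSC slopes with `|b1| < 1e-10` and zero-variance spectra under SNV are
  errors naming the offending sample.
* Constant responses: PLSR and the selectors refuse them (correlation
  and covariance are undefined); SVR degrades to a constant predictor
  with a warning.
* `compute_rpd()` reports +Inf with a warning when RMSEP is 0.
* All derived seeds stay far below 2³¹.

## Problem sizes used in the shipped checks

The unit tests exercise a coarse 5 nm grid (141 points) where full
resolution adds nothing; the end-to-end checks and
`scripts/acceptance.R` run the full default conditions — 145 × 1401,
CARS with 100 runs, the 18-row pretreatment screen and the 27-row
selector × model grid — sizes at which the complete suite still runs in
a few minutes on one CPU.

## Known limitations

* No EMSC, detrending, OSC or wavelet pretreatments; no Kennard–Stone /
  SPXY partitioning; no GA/iPLS/VIP selectors — deliberately out of
  scope.
* No instrument physics beyond gain/offset/noise, and no biochemical
  kinetics of ripening; the storage trend is phenomenological.
* JCAMP-DX and vendor binary formats are not read; the CSV dialect is
  the exchange format.
* UVE's leave-one-out loop is O(n) PLS fits and is the slowest selector
  at large n; the fold scheme is not configurable.
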