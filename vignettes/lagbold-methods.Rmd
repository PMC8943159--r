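---
title: "Methods behind lagbold: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind lagbold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagbold)
```

`lagbold` implements a complete analysis chain for two-condition
block-design BOLD fMRI — data-driven HRF estimation, condition-specific
activation and gPPI connectivity, and voxel-wise longitudinal
mixed-effects mapping — together with a synthetic-data module that plants
known effects so every stage can be validated against ground truth. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

## The signal model and its basis

The BOLD series in a voxel or ROI is modelled as the sum of two parallel
causal FIR systems, one per experimental condition (novelty and repetition
of face–name pairs):

$$y(n) = \sum_{m=0}^{M} h_1(n-m)\,x_1(m) + \sum_{m=0}^{M} h_2(n-m)\,x_2(m) + e(n),$$

with finite memory $M$ (24 s at the default TR of 2 s, i.e. $M = 12$
samples). Each condition HRF is expanded on $L$ orthonormal basis
functions, $h_i = \mathbf{B} c_i$, which turns the estimation problem into
ordinary least squares $\mathbf{Y} = \mathbf{Vc} + \mathbf{e}$ with
regressors $v_{ij} = x_i * b_{ij}$ plus an intercept.

The basis is built from spherical Laguerre functions

$$d_j(n) = \sqrt{\frac{j!}{(j+2)!}}\,
  \frac{e^{-n/(2\alpha)}}{\sqrt{\alpha^3}}\, K_j(n/\alpha),$$

where $K_j$ is the generalized Laguerre polynomial of order 2 and
$\alpha > 0$ sets the exponential decay scale. Note the sign of the
exponent: these functions must decay — a growing exponential cannot model
a causal finite-memory system — so the package uses $e^{-n/(2\alpha)}$
throughout. Each $d_j$ is convolved with a discrete Gaussian kernel of SD
$\sigma = 1$ s centred at a pure delay $\tau \ge 0$ s (truncated at
$\pm 4\sigma$ and renormalized to unit sum), which shifts and smooths the
family so its leading members resemble plausible hemodynamic responses.
The smoothed columns are then orthonormalized in index order. We compute
the orthonormalization by Householder QR with a sign-fixed diagonal, which
produces exactly the classical Gram–Schmidt result with better numerical
conditioning; orthonormality holds to $10^{-14}$ across the whole
$(\alpha, \tau)$ search grid.

Units: $\alpha$, $\tau$ and $\sigma$ are all in **seconds**, and the basis
is sampled at the TR by default (`dt` is configurable for oversampled
work). Whether the delay-kernel SD should be read in samples or seconds is
genuinely ambiguous; seconds keeps the basis invariant under TR changes,
so that is the package's convention.

## Parameter selection

Two free parameters and one order determine a basis set:

* `alpha` (decay, s) — default search grid $0.25, 0.5, \ldots, 3.0$;
* `tau` (pure delay, s) — default grid $0, 0.5, \ldots, 4.0$;
* `L` (number of functions) — candidates $1 \ldots 4$, shared by both
  conditions.

The grids cover canonical HRF dynamics (time-to-peak of roughly 2–8 s and
onset delays up to 4 s). $(\alpha, \tau)$ are selected per subject by
minimizing the cross-validated generalization error
$\mathrm{mse} = N^{-1}\sum_n (\hat y(n) - y(n))^2$, with leave-one-run-out
folds: runs are the natural independent units of a multi-run session, and
six runs give six folds. The error is averaged over ROIs within subject
before the minimum is taken, yielding one subject-level basis (the
two-step scheme: ROI-level selection first, voxel-level estimation
second). Ties are broken toward smaller $\tau$, then smaller $\alpha$ —
the least delayed, fastest-decaying representation — which makes the
selection deterministic on degenerate (e.g. all-zero) inputs.

`L` is selected by BIC, $N\ln(\mathrm{RSS}/N) + p\ln N$, on the stacked
runs; at the defaults the selected order is 2, and simulations in the test
suite show BIC recovers a generating order of 2 in well over 90% of
high-SNR replicates. A guard (`RSS` floored at $10^{-300}$) keeps the
criterion finite on noiseless data, where ties then resolve to the
smallest candidate order.

Amplitude summaries are **signed**: the HRF amplitude is the value at the
extremum of largest magnitude, so predominantly negative responses (which
occur in some regions) report negative amplitudes; FWHM is measured on
that lobe with linear interpolation, bounded by the curve's support when a
lobe never falls to half height.

## Activation and connectivity stages

The activation GLM deliberately **re-fits** the data with the full
reconstructed HRFs instead of reading amplitudes off the estimated curves:
regressors $x_i * \hat h_i$ are z-transformed per run, fitted with an
intercept by OLS, and per-run parameter estimates are averaged. Using the
whole response shape rather than its peak gives more stable condition
contrasts.

The gPPI stage uses the five-regressor construction: a physiological
regressor (seed-mask mean), two psychological regressors (condition block
series convolved with the *group-level* seed HRF, aligning them in time
with the physiological series), and two interactions (elementwise
products). Two deliberate choices:

* the physiological regressor is **demeaned before multiplication** —
  otherwise the interaction aliases the psychological main effect through
  the seed's mean offset;
* the product is formed at the **BOLD level**, without deconvolving the
  seed to a neural-level signal first. This matches the construction the
  activation results are meant to parallel, but differs from gPPI variants
  that deconvolve; users should be aware when comparing across tools.

Whether the psychological regressors should be z-transformed here is
unspecified in common practice; the package defaults to *not*
z-transforming them (the transform is described only for the activation
GLM) and exposes `z_psych` to switch.

## Preprocessing emulation

The preprocessing module reproduces the parts of a brainstem-oriented
pipeline that act on voxel series: the 30-column confound set (three ROI
means — 4th ventricle, lateral ventricles, white matter — six motion
parameters, their backward-difference derivatives with a leading zero, and
the squares of all fifteen), DVARS-based scrubbing, and separable
anisotropic Gaussian smoothing whose per-axis FWHM can be elongated along
the brainstem axis. Deliberate simplifications: the smoothing kernel is
axis-aligned (orienting it is a registration problem, out of scope here),
and the DVARS threshold — unstated in most protocols — defaults to the
robust upper fence $Q_3 + 1.5\,\mathrm{IQR}$ of the run's own DVARS
distribution, with an absolute override. Scrubbing *removes* flagged
volumes (with their design rows) rather than interpolating. Kernel rows
are renormalized at volume edges so constant images pass through exactly.
The seed–ventricle Pearson correlation is provided as the standard
partial-volume contamination diagnostic for small nuclei adjacent to CSF.

## The longitudinal model

Cognitive outcomes over time are modelled per voxel (or ROI) with a linear
mixed model fitted by maximum likelihood:

$$\mathrm{Outcome}_{ij} = \beta_0 + \beta_1\mathrm{Age}_i +
\beta_2\mathrm{Sex}_i + \beta_3\mathrm{Edu}_i + \beta_4\mathrm{PredA}_i +
\beta_5\mathrm{PredB}_i + \cdots +
\beta_{11}(\mathrm{PredA}_i \times \mathrm{PredB}_i \times \mathrm{Time}_{ij})
+ b_{0i} + b_{si}\mathrm{Time}_{ij} + e_{ij},$$

with correlated subject random intercepts and time slopes. PredA is the
imaging predictor (activation or connectivity contrast), PredB the
amyloid burden (continuous DVR or the dichotomous flag at 1.324). The
*fitting* model includes all lower-order terms of the three-way
interaction (a main Time effect and PredA:PredB), which the generating
equation above does not require but standard interaction inference does.
Covariate-by-time interactions are pruned when $p > 0.10$ **and** their
removal changes the predictor-of-interest estimates by less than 10%
(relative); the guard is restricted to the predictor terms because
nuisance coefficients near zero make relative change meaningless. When the
random-slope variance converges to the boundary (singular fit), the model
falls back to a random intercept only.

Inference on fixed effects uses the Wald statistic $Z =$
estimate/SE with a normal reference. Voxel-wise mixed-model inference has
no universally agreed df convention; the Wald Z is transparent and fast at
cohort scale (150 subjects, 5 visits), where simulations in the test suite
put its type-I error near, though detectably above, the nominal 5% (about
6–7%). Users needing exact small-sample calibration should interpret
borderline voxels conservatively or raise the cluster-defining threshold.

Cluster-level control uses **sign-flip permutation** of subject-level
contrast maps: clusters are formed at a preset cluster-defining threshold
(|Z| > 4.5, 3.1 or 2.3) with 26-connectivity, and the familywise-corrected
p-value of each observed cluster is its rank against the permutation
distribution of the maximum cluster size. This is self-contained and
assumption-light (exchangeability under symmetric errors) compared to
parametric random-field correction, which an external package would
otherwise supply. Within the permutation loop the |Z| threshold is applied
as the equivalent |t| quantile, which is mathematically identical and
avoids per-permutation probability transforms.

Moderation is summarized by simple slopes at the moderator mean and ±1 SD,
and by a floodlight scan: the conditional slope
$\beta_{\mathrm{base}} + m\,\beta_{\mathrm{inter}}$ is Wald-tested at each
point of a moderator grid, BH-FDR is applied across grid points, and the
smallest significant moderator value is reported as the lower detection
bound. With strong effects this bound agrees with the analytic
Johnson–Neyman boundary (the root of
$(\beta_b + m\beta_i)^2 = z^2 \mathrm{Var}(\beta_b + m\beta_i)$) to within
one grid step; the FDR adjustment can only shift it by sharpening the
p-value transition.

Composites follow the baseline-z rule: each subtest is z-transformed with
the mean and SD of the baseline (time 0) visits, reversed-direction
subtests (e.g. timed trail-making) are sign-flipped, and the composite is
the mean of available z-scores with at most one subtest missing (missing
subtests are excluded; two or more missing yields a missing composite).
Reliability uses the two-way mixed-effects, consistency, single-measure
ICC — the variant is rarely stated in applied reports; this one matches
the "same raters, systematic visit effects ignored" reading of repeated
cognitive testing.

## The synthetic-data module

The generator is the package's study-conditions oracle, not a tuning knob:

* **Design**: 6 runs; per run a 5-s fixation, four 40-s task blocks
  (novelty, repetition, twice each) separated by 25-s fixations, and a
  closing 5-s fixation — 245 s scheduled. Each task block holds 7 trials
  of 4.75 s; the 6.75 s of slack is the jittered inter-trial fixation,
  spread evenly by default (the jitter distribution is unstated in typical
  protocols; a seeded uniform option is exposed). At 127 volumes × TR 2 s
  the run is 254 s, so the trailing 9 s are padded fixation — this
  reconciles the two printed run lengths. Onsets snap to the nearest TR
  sample; no slice-timing structure is simulated.
* **BOLD phantoms**: a 12×12×8 grid with disjoint block masks for seed,
  target, 4th ventricle, lateral ventricles, white matter and extra task
  voxels. Task voxels carry the two-condition convolution; target voxels
  add condition-scaled copies of the demeaned simulated seed mean (the
  gPPI coupling, modulated by the seed HRF for both conditions, mirroring
  the one-group-HRF convention of the analysis); noise is AR(1)
  (innovation SD 0.3–1, coefficient 0.3) plus linear drift plus
  random-phase sinusoids at 0.1 and 0.25 Hz standing in for respiratory
  and cardiac signal. Six motion series are smoothed random walks.
* **Cohorts**: 128 subjects by default with baseline age N(70, 8), sex
  0/1, education uniform 12–20 years; amyloid DVR from a two-component
  Gaussian mixture (low 1.10 ± 0.05, high 1.60 ± 0.15) whose high-component
  weight is solved so the mass above 1.324 is exactly 36/128 — the
  observed prevalence of elevated amyloid in the cohort being emulated;
  visit times 0–4 years with optional dropout; outcomes from the mixed
  model above with planted coefficients, random SDs (1, 0.3), residual SD
  0.5.

Every generator is a pure function of its seed.

What the synthetic validation shows: the estimation chain inverts its own
generative model — HRF recovery at signal-SD = noise-SD, grid and order
identification at high SNR, unbiased coupling and interaction recovery,
calibrated familywise error. What it does not show: robustness to the
things real data add — HRF shapes outside the basis span, non-AR(1) and
non-stationary noise, motion-by-susceptibility interactions, registration
error, sampling bias in cohort retention. Passing tests are evidence of
correctness of the implementation, not of validity of the model for any
particular dataset.

### A note on identifiability of $(\alpha, \tau)$

Neighbouring grid points generate nearly identical basis *spans*, so at
low SNR the error surface is shallow near its minimum: the selected basis
then still reconstructs the HRF almost perfectly (curve correlation
> 0.99) even when the labelled $(\alpha, \tau)$ is an adjacent grid point.
Exact grid-point identification is therefore checked at high SNR, while
curve recovery is checked at signal-SD = noise-SD; conflating the two
would test label recovery where only span recovery is identified. The
default recovery fixture ($\alpha = 1$ s, $\tau = 2$ s, coefficient
vectors (1, 0.5) and (0.6, 0.3)) was chosen once as a well-identified,
physiologically shaped pair.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is statistically decidable: 50 seeds
for HRF/grid/order recovery, 100 runs for coupling recovery, 2000 (tests)
or 500 (script) replicates for type-I calibration at n = 150 subjects × 5
visits, 1000 (tests) or 300 (script) outer replicates of the familywise
error simulation on the 12×12×8 grid with 199 sign-flips each. The grid
and cohort sizes mirror the simulation targets described above rather than
full-brain dimensions.

## Known limitations

* No slice-timing, realignment, registration or ICA-based denoising; the
  preprocessing module only emulates the confound-regression core.
* The ellipsoid kernel is axis-aligned.
* One shared $(\alpha, \tau)$ per subject for both conditions (a
  per-condition override exists on `build_expansion_design` via separate
  basis objects, but the selection utilities share the optimum).
* Wald-Z inference is mildly anti-conservative at n ≈ 150 (see above).
* The gPPI construction does not deconvolve the seed series.
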