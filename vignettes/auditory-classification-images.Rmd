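---
title: "Estimating auditory classification images from simulated phoneme categorization in noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating auditory classification images from simulated phoneme categorization in noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

An Auditory Classification Image (ACI) is a spectrotemporal map of
regression weights that shows *where in time and frequency* the energy of a
masking noise sways a listener's phoneme decision — a behavioral analogue of
a spectrotemporal receptive field. The experimental paradigm is a forced
binary categorization (/da/ vs /ga/, embedded in the four nonwords *alda*,
*alga*, *aRda*, *aRga*) of speech targets presented in trial-unique white
noise, with the signal-to-noise ratio driven by a 3-down 1-up adaptive
staircase so that every listener operates near 79% correct. Because the
noise is unique on every trial, regressing the trial-by-trial responses on
the noise's time-frequency content reveals the listener's internal decision
template.

Formally, each 680 ms stimulus is reduced to a cochleogram — a 54 x 81
matrix of log band energies through a quasi-logarithmically spaced
filterbank — whose bins, flattened to a vector $S_i$ for trial $i$, are the
predictors of a penalized logistic regression on the binary response $r_i$
(0 = 'da', 1 = 'ga'):

$$\hat\beta,\hat a \;=\; \arg\min_{\beta, a}\;
  \mathrm{Dev}(r, \mathrm{logit}^{-1}(a + S\beta))
  \;+\; \lambda\,(\lVert D_t\beta\rVert^2 + \lVert D_f\beta\rVert^2)
  \;+\; \epsilon\,\lambda\,\lVert\beta\rVert^2,$$

where $\mathrm{Dev}$ is the binomial deviance, $D_t$ and $D_f$ are
first-difference operators along the time and frequency axes of the
unflattened weight map, and $\epsilon = 10^{-3}$ is a small relative ridge
that removes the constant-map null space of the difference penalty and
makes the objective strictly convex. The intercept is never penalized. The
weight map $\hat\beta$ is the ACI.

The smoothing level $\lambda$ is chosen by 10-fold cross-validation: the
trials are split at random into 10 equal sets, and for each $\lambda$ and
fold the model is fitted on the other 9 sets and scored on the held-out set
by its deviance (CVD) and by the percentage of correctly predicted
responses (CVR). Before both fitting and scoring, the proportions of
correctly and incorrectly categorized trials are equated by subsampling the
majority class, so that a listener's accuracy level cannot bias the
estimate. In a cohort, one shared $\lambda^*$ minimizes the mean CVD over
all observers, and each observer's final ACI is refitted on their complete
balanced trial set at $\lambda^*$.

Three statistical layers sit on top of the fitted maps:

* **Cluster-based permutation test** (group comparison): a per-bin
  two-sample running t-test is thresholded (default $p < 0.05$,
  two-tailed), surviving bins are grouped into 4-connected components split
  by sign, each cluster is scored by the sum of its t values, and the
  maximum absolute cluster mass under random relabelings of the group
  membership (default 5000) provides the null distribution.
* **ROI analysis**: regions of interest are clusters of at least 7 adjacent
  bins that are consistently nonzero across the pooled cohort in a
  one-sample running t-test at $p < 10^{-10}$; per-ROI mean weights are then
  compared between groups with an ordinary two-sample t-test.
* **Auto/cross-prediction**: each observer's held-out balanced test folds
  are predicted by their own per-fold models (auto-prediction CVD) and by
  every other observer's models (cross-prediction CVD). The difference
  between the mean cross-prediction deviance of a listener's data and their
  auto-prediction deviance is the *specificity* of their strategy: it is
  positive exactly when part of their behavior is predictable only by
  their own template.

A two-step individual deviance analysis is also provided for scalar
performance measures: a case is deviant when it lies more than 1.65 SD (the
normal fifth percentile) from the control mean, after controls more than
1.65 SD from their own mean have been trimmed and the mean/SD recomputed.

## The synthetic-data generator

No human data ship with the package; the generator produces trial tables
with the statistical structure the estimator assumes.

* **Targets.** Four /aCCa/ nonwords are built by additive formant synthesis
  (four AM sinusoids following piecewise-linear F1-F4 tracks): 680 ms at
  48 kHz, first syllable 328 ms, all power-normalized to unit RMS. The
  second-syllable onsets carry the place cues: F2 near 1380 Hz and F3 near
  2557 Hz for /da/, F2 and F3 converging near 1950-2050 Hz for /ga/, F1
  onset near 665 Hz for both. These synthetic stand-ins preserve the cue
  geometry of natural recordings, not their spectral richness: harmonic
  structure, bursts, aspiration and amplitude microdynamics are absent, so
  passing tests demonstrate correct estimator behavior on cue-bearing
  stimuli, not natural-speech generality.
* **Noise.** Gaussian white noise, one seed per trial; the seed alone
  reproduces the waveform bit-identically, so trial tables serialize as
  small CSVs. SNR is defined on full-waveform RMS, and each mixture is
  re-normalized to unit RMS so absolute level is uninformative.
* **Observers.** A template observer computes the inner product between a
  54 x 81 weight template and the stimulus cochleogram, adds Gaussian
  internal noise, and answers 'ga' when the result exceeds its criterion.
  The ideal template is the difference between the mean clean 'ga' and
  'da' cochleograms (centred, unit norm); distinct strategies are modelled
  by translating this template on the lattice. Because log band energies
  shift asymmetrically when noise is added, the criterion is calibrated as
  the class-conditional midpoint of template matches on noisy mixtures at a
  reference SNR of -12 dB; without this the observer is strongly response
  biased. With the default settings the calibrated ideal observer converges
  near -16 dB SNR at 79% correct with d' about 1.7, a realistic operating
  point for this task. A psychometric observer (logistic function of SNR
  only) is also provided for testing the staircase machinery analytically.
* **Staircase.** 3-down 1-up on SNR, converging on the
  $0.5^{1/3} = 79.4\%$ correct point. Step size and starting point are not
  dictated by the paradigm, so the package pins its own: start 0 dB, 2 dB
  steps until the first reversal, 1 dB after, clipped to [-30, +20] dB.
  Targets are drawn uniformly at random per trial.

## Numerical choices

* **Cochleogram front end.** Only the lattice itself — 54 quasi-
  logarithmically spaced channels by 81 time frames — is fixed by the
  paradigm; everything else about the front end is the package's own,
  config-pinned choice: 4th-order gammatone
  responses on an ERB-spaced grid from 100 to 8000 Hz. The default
  implementation frames the waveform into 81 contiguous equal windows
  (zero-padding 32,640 samples to 81 x 403 so frames are exactly equal,
  which also makes the one-frame time-shift invariance exact) and weights
  each frame's FFT power spectrum by the gammatone power responses — the
  fast gammatonegram construction. A time-domain alternative
  (`method = "gammatone"`: gammatone filtering, half-wave rectification,
  2nd-order Butterworth lowpass at 150 Hz, frame averages) is provided and
  agrees with the spectral method on peak channels; the spectral method is
  the default because the simulator computes one cochleogram per trial and
  is roughly 50x faster. Log compression uses a -60 dB floor relative to
  the map maximum, so silence maps to a finite constant.
* **Standardization.** Predictors are z-scored per bin across a
  participant's trials before fitting (stored with the model and reapplied
  at prediction time), making $\lambda$ comparable across observers. The
  map reported by `tidy()` is back-transformed to the raw dB scale.
* **Optimizer.** L-BFGS-B with analytic gradients, warm-started across
  folds and smoothing levels; for lattices of at most 600 predictors a
  dense Newton polish then drives the gradient infinity-norm below 1e-8,
  which is how the small-problem oracle-equivalence tests reach 1e-6
  relative objective agreement. At the full 4374-bin lattice the terminal
  gradient norm is recorded in the model object.
* **Ties and degenerate inputs.** Probabilities are clipped to
  [1e-12, 1 - 1e-12]; a predicted probability of exactly 0.5 counts as
  predicting 'ga'; equal mean CVD at two smoothing levels resolves to the
  larger (smoother) one; zero-variance bins in running t-tests get t = 0
  and p = 1 with a warning; a zero trimmed control SD in the individual
  deviance analysis is an error rather than a silent division by zero.
* **Cluster test conventions.** The per-bin cluster-forming threshold
  (0.05 two-tailed), 4-connectivity without diagonals, and the sum-of-t
  cluster mass are package choices that the paradigm leaves open;
  all are exposed as arguments because ROI sizes and cluster masses depend
  on them. With small cohorts the permutation null is enumerated
  exhaustively whenever the number of distinct label splits does not
  exceed the requested permutation count.

## Problem sizes used by the test suite

The acceptance-level checks run the full design where the claim depends on
it and reduced designs where the claim is scale-free. The reference
observer completes the full 10,000-trial, 54 x 81 design (structure,
staircase convergence, parameter recovery at n = 2,500 vs n = 10,000,
refit smoothing level 1000). The specificity cohort runs four observers at
5,000 trials each (auto- and cross-prediction are contrasted within
observer, so halving the per-observer trial count widens estimation noise
but cannot flip the sign structure being tested); its identical-strategy
pair uses equal trial counts so that estimation precision cannot
masquerade as strategy specificity. The permutation-test validity and
power simulations use reduced lattices (10 x 12 to 12 x 15) because
type-I calibration and cluster detection are lattice-size agnostic, with
1600 replicates at 500 permutations for the type-I check (Monte Carlo
error of the rate estimate about 0.55 percentage points).

## Limitations

* The formant-synthesized targets are caricatures; analyses of natural
  recordings will meet richer covariance structure in the predictors.
* The template observer is the same model family the estimator assumes
  (linear template on the log cochleogram), so parameter recovery tests
  validate the estimation machinery, not the psychological adequacy of the
  GLM.
* Reaction times, learning across sessions, and multiple listenings per
  trial are not modelled.
* Deviance magnitudes depend on the balanced test-set sizes, which in turn
  depend on each observer's accuracy; comparisons should therefore stay
  within observer (as in the specificity index) or be accompanied by the
  stored per-fold test sizes.

## A minimal session

```{r}
library(aclimage)

targets <- synthesize_targets()
fb <- gammatone_filterbank()
observer <- ideal_observer(targets, fb)

trials <- run_experiment(observer, targets, n_trials = 10000, seed = 1,
                         filterbank = fb, keep_predictors = TRUE)
performance_summary(trials)

model <- fit_aci(trials, predictors = attr(trials, "predictors"),
                 lambda_grid = default_lambda_grid(), seed = 1)
glance(model)
autoplot(model)
```

For a full synthetic study (cohorts, shared smoothing selection,
specificity, cluster test, ROIs) see `run_aci_study()` and
`study_config()`.
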