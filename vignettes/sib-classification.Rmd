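---
title: "Classifying self-injurious behavior from wrist accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying self-injurious behavior from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibmlr)
```

## The problem

Self-injurious behavior (SIB) — head banging, self-hitting, skin picking —
affects roughly half of children with autism spectrum disorder and is usually
tracked by manual functional assessment, which is slow and observer-dependent.
`sibmlr` implements a group-level detection pipeline for tri-axial wrist
accelerometry: sessions are filtered and cut into short overlapping windows,
each window is summarized by 96 features spanning time-domain, frequency-domain,
and nonlinear motor-variability measures, the feature space is reduced by lasso
selection followed by PCA, and windows are classified by a multilevel logistic
regression whose intercept and slopes vary by participant. The multilevel
structure is the scientific core: SIB presentation differs markedly between
individuals, so a pooled classifier underfits while per-participant models do
not generalize; random intercepts and slopes let the group model borrow
strength across participants while following each one.

## Model

For window $i$ belonging to participant $j[i]$ with component scores
$X_1, \dots, X_K$:

$$\Pr(Y_i = 1) = \mathrm{logit}^{-1}\Big(\alpha_{j[i]} + \sum_k \beta_{j[i],k} X_k\Big),$$

with participant-level effects drawn independently around the fixed
coefficients,

$$\alpha_j \sim N(\gamma_0, \sigma_\alpha^2), \qquad
  \beta_{j,k} \sim N(\gamma_k, \sigma_{\beta k}^2).$$

The random effects are mutually independent (diagonal covariance, one variance
per slope), read directly off the per-component variance terms of the model;
a correlated-effects variant is out of scope. The level-2 regressors that
could shift the random-effect means are fixed to the constant 1 — the random
effects are centered on the fixed coefficients — because no concrete
participant-level covariates are part of this design. Estimation maximizes
the Laplace-approximated marginal likelihood (`lme4::glmer`); per-participant
effects are posterior modes; fixed effects get Wald tests. Variance components
can be tested by a likelihood-ratio test against the model with that component
removed, referred to the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (off by default, since each test refits
the model). Wald standard errors for the random-effect SDs are available from
the numerical Hessian of the Laplace deviance in $(\theta, \beta)$
(`se_variances = TRUE`); these drive the parameter-recovery checks. On
numerically degenerate training data (e.g. a perfectly separable fold) the
penalized IRLS inner loop can abort; the fit then retries with the `nAGQ = 0`
approximation and finally falls back to pooled logistic regression with a
warning. With a single participant the multilevel structure is unidentifiable
and the pooled fallback is used directly.

## Preprocessing and the feature battery

* **Filtering.** A causal, single-pass 4th-order Butterworth low-pass at
  20 Hz (sampling rate 60 Hz). Causal rather than zero-phase filtering is
  deliberate: the intended deployment is real-time monitoring, where future
  samples are unavailable. Filtered data feed the time/frequency features;
  **raw** data feed the nonlinear battery, since phase-space structure is
  distorted by filtering.
* **Windowing.** 2-s windows advancing by 1 s, aligned to the session start;
  the trailing partial window is dropped. A window is labeled positive when
  *any* sample in its span is labeled (presence rule); majority labeling was
  rejected because brief high-risk events must not be outvoted by background.
* **Time domain (19 × 3 = 57).** Per channel: cross-correlation coefficient
  and mean difference of the cyclically paired channels (X:XY, Y:YZ, Z:ZX),
  variance, local extrema counts, peak, minimum, seven amplitude percentiles,
  zero crossings about the window mean, mean, mean absolute value, RMS, and
  jerk. The published feature list names 18 items while counting 19 per
  channel; the 19th is taken to be the mean absolute value, which appears
  throughout the reported component loadings. Jerk is computed as the mean
  absolute first difference times the sampling rate — robust at 120 samples
  per window. A constant channel yields cross-correlation 0 (flagged), never
  NaN.
* **Frequency domain (4 × 3 = 12).** The two largest local maxima of the
  magnitude spectrum of the mean-removed window (DC excluded, ties toward the
  lower frequency) give two frequencies and two amplitudes. "First two" is
  read as the two dominant peaks rather than the two lowest bins; a
  lowest-bin reading would make the features nearly constant across windows.
  Missing peaks are 0, flagged.
* **Nonlinear battery (9 × 3 = 27).** Per raw channel: DFA exponent, sample
  entropy, cross-sample entropy against the cyclic partner channel, and six
  recurrence measures (recurrence, determinism, laminarity, divergence,
  maximum diagonal length, trapping time) of the delay-embedded signal.

## Nonlinear estimators: conventions and numerical choices

* **Embedding.** $X(t) = [x(t), x(t+\tau), \dots, x(t+(M-1)\tau)]$ with
  $K = N - (M-1)\tau$ vectors. Defaults $\tau = 5$ samples and $M = 4$ are
  pinned as the values this class of wrist-accelerometer data selects; the
  selection procedures themselves are implemented so the choice can be
  reproduced on synthetic data. The delay comes from the first local minimum
  of the average mutual information (16 equal-width histogram bins) checked
  against the lag at which the autocorrelation drops below $1/e$; a
  divergence of more than one sample between the two is flagged. The
  dimension comes from global false nearest neighbors with the two standard
  criteria: distance-ratio tolerance 15 and attractor-size tolerance 2. The
  ratio test alone is insufficient — on stochastic signals near-neighbor
  distances grow with dimension and the ratio collapses, so noise would
  spuriously "unfold"; the attractor-size test keeps the noise fraction high,
  which is the expected behavior. Nearest-neighbor distances are floored at a
  scale-relative epsilon so the exact recurrences of noiseless periodic
  signals do not masquerade as false neighbors.
* **Sample entropy.** Templates use delay 1 (the standard convention) with
  template length $M$; the delayed embedding is used only for RQA, because
  the template-count normalization over $N - M + 1$ vectors is only
  consistent with delay 1. $\phi^m$ averages raw match counts over all
  $N - m + 1$ templates with Chebyshev distance and tolerance
  $r = 0.2\,\mathrm{SD}(x)$, self-matches excluded; the match relation is
  $\le r$. SaEn $= -\ln(\phi^{M+1}/\phi^M)$. Constant input returns 0;
  zero matches at $M+1$ return an $+\infty$ sentinel, which the feature
  battery caps at the conventional maximum finite estimate
  $-\ln\frac{2}{(N-M)(N-M-1)}$ so tables stay finite (always flagged).
* **Cross-sample entropy.** Both series standardized, templates of one
  matched against templates of the other, $r = 0.2$ on the standardized
  scale; symmetric by construction. Note that identical streams do **not**
  give exactly 0 — the conditional matching ratio is below 1 whenever some
  templates match at $M$ but not $M+1$ — but identical or synchronized
  streams score far below independent ones, which is the semantics the
  feature relies on.
* **RQA.** Euclidean distance matrix between embedded vectors; the radius is
  chosen as the off-diagonal distance quantile whose strict `<` thresholding
  puts the recurrence percentage as close as possible to 1% while staying
  inside the 0.1–2% band; the percentage is recomputed from the final matrix
  and verified. A Theiler window of 1 excludes the main diagonal from all
  counts. Line minima are $l_{\min} = v_{\min} = 2$. Inputs on which no
  radius can satisfy the band (e.g. constant channels, where any positive
  radius makes everything recurrent) raise an error naming the band; the
  feature battery catches it and emits zeroed, flagged RQA values.
* **DFA.** Profile = cumulative sum of the mean-centered series; 12
  log-spaced box sizes from 4 to $N/4$; per-box linear detrend; $\alpha$ is
  the log–log least-squares slope. White noise gives $\alpha \approx 0.5$,
  integrated white noise $\approx 1.5$. Zero fluctuation at any box size
  (a constant series, whose profile is identically zero) yields a flagged
  result rather than `-Inf` in the regression.

## Dimension reduction and evaluation protocol

The lasso stage fits the binomial (logistic) L1 path with tenfold
cross-validation and keeps the features with nonzero coefficients at the
one-standard-error penalty — the 1-SE rule is how "the sparsest model" is
operationalized; the prompt indicator enters as a candidate alongside the 96
features. PCA is fit on the standardized selected features; the component
count is the smallest reaching 65% cumulative explained variance (a fixed
count can be forced), with each loading column signed so its
largest-magnitude entry is positive, making loadings tables reproducible.

Evaluation follows the 8:2 protocol: the split is stratified by participant
**and** class so every participant appears in training (required for
participant-level random effects — the random intercept of an unseen
participant is unidentified) and the held-out pool keeps the natural class
ratio. The pool is materialized twice — balanced by undersampling, and
natural — so both test variants come from the same held-out rows. Training
data are balanced by seeded random undersampling. Tenfold cross-validation is
stratified by class; probabilities are thresholded at 0.5; metrics with a
zero denominator are reported as 0 with a flag so degenerate folds do not
crash sweeps. The comparison bank mirrors the study design: varying-intercept
LR, plain LR, forward-stepwise LR over main effects and two-way interactions
by BIC (implemented without the marginality restriction so a pure interaction
can enter), per-participant LR, kNN ($k = 11$), linear/cubic/Gaussian SVMs,
and a decision tree. SVM scores are logistic transforms of the signed margin:
monotone in the decision value (thresholding at 0.5 reproduces the SVM class
decision) but not calibrated probabilities. Timing per observation is
recorded but never asserted — it is hardware-dependent.

## What the synthetic generator does and does not emulate

The signal-level generator produces per-participant sessions: background
motion is pink ($1/f$) noise plus a 0.1 Hz postural drift — a naturalistic
non-white baseline chosen so the nonlinear features are non-degenerate —
and SIB episodes are sinusoidal bursts (2–8 s, ~1.5–3 per minute, dominant
frequency 2–5 Hz, amplitude 0.5–1.2 g against a 0.1–0.25 g baseline) with
per-episode jitter in frequency, amplitude, phase, and channel gain, placed
uniformly without overlap and truncated at the session end. About half of the
episodes are preceded by a 2-s prompt interval, emulating in-session
behavioral prompting. These ranges are what rhythmic wrist-measured SIB
plausibly looks like; they were fixed once as the package's study conditions.
Each participant's session is generated under a deterministic child seed
(cohort seed + 1000·index), so participants are independent yet the cohort
reproduces from one integer.

The feature-level generator draws directly from the two-level logistic model
above and returns the realized parameters, enabling parameter-recovery tests
with known truth.

What the generator does *not* claim: real non-SIB activity content (play,
rest, transitions) is far richer than pink noise; real SIB topographies
(head banging vs. picking) differ in more than frequency/amplitude/duration;
sensor artifacts, gravity orientation changes, and missing data are absent.
Passing tests therefore demonstrate that the pipeline's machinery is correct
and self-consistent under known structure — not that its accuracy on these
cohorts transfers to clinical recordings. Synthetic cohorts here are highly
separable (strong bursts over a quiet baseline), so pipeline accuracies are
high; the published group-level accuracies on real data are far lower, and no
equivalence is implied.

## Problem sizes

Default analysis runs use 6 participants × 150 s at 60 Hz (≈ 900 windows),
tenfold CV, and the full nine-model bank — roughly a minute of computation.
Parameter-recovery experiments use 30 participants × 500 windows with one
feature, 20 replicates; lasso-recovery experiments plant 5 signal features
among 50 noise features at n = 2000. These sizes were chosen so that every
documented property is measurable with comfortable statistical margins while
an entire verification run stays fast on a laptop.

## Known limitations

* The package analyzes a single (wrist) sensor stream; multi-sensor fusion
  and per-site individual models are outside its scope.
* Random effects are independent by design; correlated intercept–slope
  structure is not fitted.
* The SaEn/cross-SaEn sentinel cap, the RQA band-failure zeroing, and the
  0-with-flag convention for undefined metric ratios are pragmatic choices
  for uninterrupted batch processing; single-window analyses should inspect
  the flags.
* No streaming/online inference, no caregiver-alert thresholding, no Bayesian
  or autoregressive extensions.
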