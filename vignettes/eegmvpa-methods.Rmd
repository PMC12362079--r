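---
title: "Decoding infant EEG: models, inference, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding infant EEG: models, inference, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmvpa)
```

## The analysis problem

The package implements a complete multivariate pattern analysis (MVPA)
pipeline for epoched infant EEG from an event-related face experiment with
four stimuli: two human identities and two monkey identities. Three binary
comparisons are analysed: *face categorization* (human vs monkey), *human
individuation* (human 1 vs human 2) and *monkey individuation* (monkey 1 vs
monkey 2). The scientific questions are **when** class information is present
in the signal (time-resolved decoding with group-level cluster inference),
**which** channels carry it (Haufe activation patterns), **which individual
subjects** carry it (full-trial decoding with shuffled-label permutation
tests), and **what fraction of the population** carries it (Bayesian
prevalence).

The pipeline operates on trial-balanced, session-concatenated epochs;
upstream continuous-recording steps (filtering, ICA, re-referencing, channel
interpolation, attentiveness rating) are out of scope and assumed done by a
standard preprocessing stack.

## Time-resolved decoding

For each timepoint $t$, the feature vector is the 31-channel voltage at $t$.
Within a stratified 10-fold cross-validation, each channel feature is
z-scored using *training-fold* statistics, and an L2-penalized linear
logistic regression is fit:

$$\min_w \sum_i \log\left(1 + e^{-s_i (x_i^\top w + b)}\right)
  + \frac{\lambda}{2}\lVert w\rVert^2, \qquad \lambda = 1,$$

equivalent to an inverse regularization strength $C = 1$, with no tuning —
the common default, fixed for reproducibility. Test-fold accuracies are
averaged across folds, yielding one accuracy time series per subject and
comparison. The same fold partition is reused at every timepoint, so the
series reflects signal dynamics rather than fold-assignment noise.

Two deliberate choices:

* **Leak-free standardization by default.** Scaling each timepoint/channel
  across *all* epochs before the CV split (the common toolbox convention)
  leaks test statistics into training. The default standardizes within
  folds; `paper_exact = TRUE` reproduces the global convention. On balanced
  data the difference is typically < 0.01 in accuracy.
* **Degenerate features** (zero variance in a training fold) are left
  centered at zero rather than divided by zero.

### Activation patterns

Linear decoder weights are not interpretable as sources: a channel can
receive weight purely to cancel noise. The Haufe transformation converts
weights into activation patterns via the feature covariance,
$A_t = \Sigma_t w_t$, with $\Sigma_t$ the channels-by-channels covariance of
the raw microvolt features at $t$. Patterns are computed from a single
all-trials refit per timepoint (the covariance needs no inversion, so
singular covariances are unproblematic) and averaged across subjects for
group maps. Recovery of a planted generative pattern ($x = y\,a +$ noise)
exceeds cosine similarity 0.9 at moderate SNR, which the test suite checks.

## Group-level cluster inference

Subject-by-timepoint accuracy matrices are tested against chance (0.5) with
one-sample sign-flip permutation tests:

* **Cluster mass test.** The statistic is the subject mean of
  $(a_t - 0.5)$; clusters are maximal runs strictly above the
  cluster-forming threshold 0.01 (one percent above chance, taken
  literally; a t-statistic variant is available via `statistic = "t"` since
  the threshold convention is ambiguous in the field). A cluster's mass is
  the summed statistic over the run. The null flips the sign of each
  subject's entire series (the canonical one-sample exchangeability scheme
  for accuracy-vs-chance), and the permutation distribution is the maximum
  cluster mass per permutation. This controls the family-wise error rate at
  the cluster level.
* **Cluster depth test.** Refines inference to individual timepoints: for
  each permutation, in-cluster timepoints are indexed by their depth from
  the cluster head and tail; depth-wise null maxima feed a Troendle-style
  max-T step-down (hypotheses ordered by observed statistic, each compared
  against the null maximum over the depths of not-yet-rejected hypotheses,
  with monotonicity enforced). Head- and tail-based p-values are combined
  conservatively by their maximum; a head-only variant is exposed because
  the one- vs two-ended convention differs between implementations.
  Timepoints outside observed clusters get p = 1.

Monte-Carlo p-values use the add-one rule $(1 + \#\{\text{null} \ge
\text{obs}\})/(1 + P)$ throughout, so p is never zero. For 20 or fewer
subjects, `exhaustive = TRUE` enumerates all $2^n$ sign assignments and the
test is exact; the suite verifies both tests value-for-value against
independently coded brute-force enumerations. Under a simulated global null
the mass test's family-wise error rate at $\alpha = 0.05$ sits inside
[0.03, 0.07] (500 cohorts of 20 subjects by 300 timepoints). Clusters
touching the series boundary are retained.

## Full-trial decoding and subject-level inference

Two decoders consume whole epochs after causal per-channel *exponential
moving standardization* ($f = 10^{-3}$, variance floor
$\varepsilon = 10^{-4}$, first 75 samples standardized jointly by their own
statistics):

* **`compact_cnn`** — a native implementation of the EEGNet-v4 topology:
  temporal convolution (8 filters, kernel half the sampling rate), depthwise
  spatial convolution over all channels (depth 2, max-norm 1), batch
  normalization, ELU, average pooling (4), dropout 0.25, separable temporal
  convolution (16 filters, kernel 16), batch normalization, ELU, pooling
  (8), dropout, and a linear head (max-norm 0.25). Training uses Adam
  (learning rate $10^{-3}$, batch 16) on binary cross-entropy; 200 cycles at
  study scale. Optimizer and learning rate are package constants since the
  upstream toolbox default is what they pin down. Backpropagation is
  hand-derived and verified against finite differences in the test suite.
* **`flat_linear`** — the same ridge logistic model on the flattened
  standardized trial. With more features than trials the fit uses the dual
  (kernel) form, so a full cross-validation costs milliseconds. This decoder
  exists so every statistical property of the inference chain is testable in
  minutes; it agrees with the network at the extremes (both near 1.0 at high
  SNR, both at chance on null data).

**Shuffled-label permutation.** Each of `n_perm` iterations permutes the
class labels over all trials (train and test alike) and re-runs the
identical CV procedure — same fold partition, a deliberate choice since
re-drawing folds per permutation only adds variance to the surrogate
distribution. For the linear decoder the fold Gram matrices are label-free
and are computed once across all permutations; the procedure is otherwise
identical. The one-sided Monte-Carlo p-value again uses the add-one rule, so
the smallest attainable p is $1/(n_\mathrm{perm}+1)$. Study scale is 1000
iterations; the package's simulations use 200 (or 199 where only the 0.05
threshold matters), which the calibration test shows is sufficient for
uniform null p-values.

BH-FDR correction across participants is applied for reporting;
*uncorrected* p-values feed the prevalence estimate, which models the false
positive rate explicitly.

## Population prevalence

With $k$ of $n$ subjects individually significant at level $\alpha$, each
subject is significant with probability
$\theta(\gamma) = \alpha + \gamma(1-\alpha)$ under population prevalence
$\gamma$ (sensitivity within carriers treated as one, so the estimand is the
prevalence of *detectable* effects — the cited framework's lower-bound
convention, and the convention whose closed-form MAP
$\hat\gamma = \mathrm{clamp}\!\left(\frac{k/n - \alpha}{1-\alpha}, 0, 1\right)$
reproduces the published estimates: $k=22$, $n=38$, $\alpha=0.05$ gives
MAP 0.56 with 95% HDI [0.39, 0.71]). The posterior under a uniform prior is
evaluated on a $10^{-4}$ grid — transparent and directly checkable against
the closed form — and the HDI is found by water-level descent on the grid
density (shortest interval, boundary-touching allowed).

```{r prevalence-example}
prevalence_posterior(22, 38)
```

## The synthetic cohort generator

Every statistical claim above is exercised on simulated cohorts with known
ground truth, since the pipeline's validity — not any single dataset — is
what the package tests. Each subject's epochs are built as:

* **Evoked background**: a class-independent waveform (early positivity,
  mid-latency negativity, slow late wave) with per-channel gains drawn once
  per subject — present in every trial, hence invisible to decoders and to
  trial-to-trial covariance.
* **Species pattern**: added with opposite sign for human vs monkey trials
  on eight occipito-parietal channels (full weight on O1/O2/Oz/POz, 0.6 on
  P7/P8/P3/P4) inside 200–770 ms. The temporal envelope is a plateau with
  half-cosine ramps over 15% of the window at each end — a broad plateau
  matches the reported effect, and soft edges avoid ringing artifacts in
  cluster-recovery tests that a boxcar would cause.
* **Identity pattern**: analogous, contrasting the two identities within a
  species; amplitude defaults to zero (the null-individuation regime).
* **Noise**: per trial and channel, eight sinusoids (1–34 Hz) with 1/f
  amplitude scaling and random phases carrying 70% of the variance plus
  white noise, and a shared per-trial component giving cross-channel
  correlation 0.3. This reproduces the temporal autocorrelation and spatial
  correlation that make naive trial counts optimistic, at negligible cost.
* **Heterogeneity**: multiplicative lognormal amplitude jitter per trial
  (sd 0.2, preventing degenerate perfect separability) and per subject
  (sd 0.4, driving realistic variation in who reaches individual
  significance). A `prevalence_true` fraction of subjects (the first
  `round(n * prevalence_true)` by index, so counts are exact) carries the
  species effect at all.

Time axes are endpoint-inclusive (301 samples for −200…1000 ms at 250 Hz).
Everything is deterministic given `(seed, subject_index)`; doubling the
amplitude exactly doubles the injected pattern.

**What the generator does not emulate:** volume-conduction from a head
model, ocular/muscle artifacts, non-stationary noise, latency jitter across
trials, or realistic between-channel covariance beyond a single shared
component. Passing recovery tests therefore demonstrates the statistical
machinery is correct and calibrated — not that any particular real dataset
will yield the same effect sizes.

### Choice of default amplitudes

The study reports no per-subject SNR or effect sizes, so the default regime
is a package constant chosen once: `noise_sd_uv = 10` (infant-EEG-like
trial noise) and `species_effect_uv = 1.65`, calibrated so that with the
default geometry (20 subjects, 40 trials per stimulus per session, two
sessions) roughly half the subjects — 55% was the calibration target —
reach individual significance in full-trial decoding, the regime the
published cohort occupies. The recovery simulations in the acceptance tests
use a moderately stronger amplitude (1.8 µV) at a reduced geometry
(15 trials per stimulus per session, 125 Hz), where group-level cluster
recovery is reliable while individual-subject significance remains
heterogeneous.

## Numerical choices

* Ridge logistic fits use Newton/IRLS (compiled) with the primal form when
  trials outnumber features and the dual (kernel) form otherwise; weights
  match `glmnet` on the same objective to three decimals (unit-tested).
  IRLS weights are floored at $10^{-9}$; iteration caps make fits finite
  even on separable data, where the penalty bounds the solution anyway.
* Prediction ties ($\eta = 0$) resolve to class 0; they occur with
  probability zero for continuous data.
* Stratified folds shuffle within class with the stage's derived seed; every
  pipeline stage draws from its own named substream of one top-level seed,
  so full reruns are byte-identical.
* Problem sizes in the test suite (20-subject cohorts at 125 Hz with 15
  trials per stimulus and session for recovery; 500 null cohorts for error
  calibration; 50 replicates for p-value uniformity) were chosen as the
  smallest sizes at which the Monte-Carlo bands in the assertions are
  meaningful.

## Known limitations

* The cluster depth test's head/tail combination takes the conservative
  maximum; the head-only variant is available but the exact convention of
  the original method is not fully specified by its description.
* The compact network trains on one CPU; at study scale (1000 permutations
  of 200-cycle trainings per subject) the shuffled-label test is a
  cluster-computing job, which is why the linear decoder backs the
  simulation studies.
* Baseline correction is applied by default (the standard convention when a
  baseline window is defined); whether the original analysis subtracted the
  baseline is not stated, so the step is a switch (`baseline = FALSE`).
* The inclusion rule reads "category" as the four stimulus identities and
  applies strict inequalities, the literal reading of the stated thresholds.
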