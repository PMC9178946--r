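---
title: "Classifying the mental context of relaxation responses from RR and EDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the mental context of relaxation responses from RR and EDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rresp)
library(dplyr)
```

## The problem

A relaxation response (RResp) is a short physiological episode in which the
organism relaxes or compensates the effects of stress. The same episode can
occur in three different mental contexts — sustained relaxation, basal rest,
or the middle of a stressful situation — and telling these contexts apart is
what makes the episode clinically interpretable. Two signals carry the
information. The RR tachogram (seconds between successive heartbeats)
reflects both autonomic branches: long intervals mean a slow, relaxed heart.
Electrodermal activity (EDA, skin conductance in µS) is driven purely by the
sympathetic branch: sweating rises under arousal, and its slow *tonic*
component drifts down during sustained calm while fast *phasic* responses
(SCRs) punctuate stress.

`rresp` implements the full chain from raw register files to a statistically
grounded comparison of classifiers: preprocessing, sliding-window feature
extraction (50 features plus the adaptive `RR_Band`), correlation-based
feature selection, a 12-learner repeated cross-validation harness, and
classifier comparison by the Friedman omnibus test plus pairwise Bayesian
correlated t-tests with a region of practical equivalence (ROPE).

## Preprocessing

Both signals pass a zero-phase low-pass filter with a 2 Hz cutoff: this
keeps the whole RR band of interest (0.05–0.5 Hz) and the tonic EDA
component (below ~0.05 Hz) while discarding measurement noise. The filter is
a 4th-order Butterworth applied forward and backward. We implement the
forward–backward pass with odd-reflection padding and steady-state initial
conditions so that window edges carry no start-up transient — a constant
signal passes through bit-exact, and passband components keep their
amplitude within 1%. Zero phase matters here because features are indexed
by window timestamps; a causal filter would shift events by its group
delay.

The tachogram is unevenly sampled (one value per beat), so slopes, residual
surfaces and spectra need an even grid: we interpolate it at 4 Hz
(conventional for heart-rate-variability spectra and comfortably above the
0.5 Hz band edge) with monotone cubic (Fritsch–Carlson) interpolation,
clamped to the observed beat range. At this grid the 2 Hz cutoff equals the
Nyquist frequency, so the low-pass applies to the RR grid only when a finer
grid is requested; the band of interest is unaffected either way.

Normalised features use the linear min–max map
$X_{norm} = (X_i - X_{min}) / (X_{max} - X_{min})$ with the extrema taken
from the **whole register's** RR signal, so every window is expressed on the
same subject-relative scale. Note this leaks future signal into early
windows — acceptable for offline analysis, not for an online system — so a
causal variant (running extrema up to each window's end) is available via
`preprocess_register(..., normalization = "causal")`.

## Windowing

Windows are 20 s long with a 5 s overlap (15 s stride), half-open
`[t_start, t_end)` on an axis anchored at the first instant both signals
exist. 20 s is long enough to hold one full period of the slowest RR
component (0.05 Hz) and to blend tonic and phasic EDA information, while
still being short enough to localise a response. Trailing partial windows
are discarded rather than padded; windows with fewer than two beats are
dropped with a warning. A window receives a ground-truth label only when a
single annotation interval covers at least half of it; ties (e.g. a window
straddling two equal annotations) stay unlabelled and are excluded from
training tables.

## The feature set

Per window, 51 features:

* **13 time-domain features** — extremes, range and mean of the windowed RR
  (raw and normalised), least-squares slopes of RR and EDA, and three
  "surfaces": the time-integral of the absolute difference between a signal
  and a linear regression over the window. `RR/RR_SurfDiff` and
  `EDA/EDA_SurfDiff` use each signal's own regression; `EDA/RR_SurfDiff`
  integrates the RR signal against the EDA's regression with both series
  co-sampled on the RR grid. We interpret "surface" as the absolute-residual
  integral because a signed surface around a signal's own regression cancels
  to zero by construction. The mixed `EDA/RR` surface deliberately combines
  µS and s without unit reconciliation, mirroring its definition; it mostly
  tracks the offset between the EDA level and the RR level, which is
  exactly why it reacts to sympathetic arousal. The integral is computed
  exactly for the piecewise-linear interpolant (trapezoid with analytic
  zero-crossing splits), so it agrees with dense numerical integration to
  high precision.
* **26 rolling statistics** — for each time-domain feature, the mean
  (`_Avg`) and sample standard deviation (`_Std`, $n-1$ denominator,
  defined as 0 for a single value) over a trailing inclusive span of four
  windows, expanding at the register start. These act as a short-time
  memory of the recent physiological past.
* **2 spectral features** — the periodogram of the mean-detrended RR window
  is aggregated into ten 0.05 Hz bins spanning 0.05–0.5 Hz; `P_max` is the
  largest bin power and `f_Pmax` its frequency, ties broken toward the
  lowest bin. With 20 s windows the 0.05 Hz bin holds exactly one
  fundamental period: the low-frequency end has coarse resolution by
  construction, which we document rather than silently widening windows.
* **9 Poincaré descriptors** — from the lag-1 scatter of the raw beat
  intervals inside the window. `SD1c`/`SD2c` are RMS centroid-referenced
  distances across/along the identity line (the ellipse's semi-axes);
  `SD1b` measures dispersion about the bisector $x = y$ itself,
  $\sqrt{\sum_i (x_i - y_i)^2 / (2n)}$, and splits exactly into a
  deceleration part `SD1e` (points above the bisector) and an acceleration
  part `SD1d` (below), both normalised by the same $2n$. That shared
  normaliser is what makes $SD1e^2 + SD1d^2 = SD1b^2$ an identity and the
  contributions $Ce + Cd = 1$ for every non-degenerate window; for a
  constant window `Ce`/`Cd` are reported as `NA`, never 0/0. Points exactly
  on the bisector contribute zero and are counted in neither $n_e$ nor
  $n_d$. Descriptors are computed per analysis window (typically 15–35
  beats) because instances are windows.
* **`RR_Band`** — the register's RR span `[min, max]` is cut into three
  equal bands and each window's `RR_Mean` is discretized: band 1 (top
  third, longest intervals) is the relaxation band, band 2 basal, band 3
  stress. Band edges belong to the calmer band; values outside the span
  (possible only when boundaries come from another register) clamp to the
  nearest band. Because the boundaries derive from the subject's own
  extrema the feature adapts across subjects and is invariant to any
  increasing affine rescaling of the RR signal.

## Feature selection

`cfs_select()` implements correlation-based feature selection: features are
first discretized with the supervised MDL criterion (recursive entropy
splits accepted only when the information gain beats the
minimum-description-length cost), correlations are symmetrical
uncertainties on the discretized codes, and a forward best-first search
maximises the merit
$M(S) = k \bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$ — relevance to the
class rewarded, redundancy among features penalised. The search stops after
five consecutive expansions without improvement. On small problems the
search recovers the exhaustive-search optimum almost always; the test suite
measures this directly.

## Cross-validation harness

`run_cv()` evaluates twelve classifiers spanning the classical paradigms:
1R, decision tree, 1-/5-nearest neighbours, naive Bayes, an RBF-kernel
machine, a linear SVM, logistic regression, AdaBoost, Bagging and random
forest (each ensemble combining 10 decision trees), and a multilayer
perceptron. Hyperparameters are the documented defaults of the underlying R
implementations (`rpart`, `randomForest`, `e1071`, `nnet`), plus in-package
implementations of 1R (Holte's rule with equal-width fallback
discretization), vote-fraction k-NN, SAMME AdaBoost and bagged trees where
the ecosystem lacks a suitable implementation. No attempt is made to
reproduce any other toolkit's defaults bit for bit, so headline accuracies
on other groups' data are explicitly outside the test surface.

The protocol is 10-run 10-fold cross-validation: ten repetitions of
stratified 10-fold CV with reshuffled partitions, yielding 100 paired
measurements per algorithm. The same seeded partitions are reused across
all algorithms so that per-fold differences are valid paired data. Folds
are stratified by class so every class appears in every fold. Accuracy,
prevalence-weighted F1 and prevalence-weighted one-vs-rest AUC are recorded
per fold, alongside mean confusion matrices and the majority-class
baseline.

Overlapping windows of one subject share signal, so pooled folds measure
within-register interpolation as much as state recognition. When the
scientific question is generalization to unseen subjects, pass
`groups = "subject_id"`: folds are then assembled from whole subjects.

## Comparing classifiers

The Friedman test (rank-based, `stats::friedman.test`, $\alpha = 0.05$)
asks whether the algorithms perform equivalently across the 100 paired
blocks; when every block is a complete tie the statistic is reported as 0
with $p = 1$.

Pairwise comparisons use the Bayesian correlated t-test: for the difference
vector $x$ of per-fold metrics (runs pooled into one 100-length vector),
the posterior of the mean difference $\mu$ is a Student-t with $n-1$
degrees of freedom, location $\bar x$ and squared scale
$(1/n + \rho/(1-\rho))\, s^2_x$. The correlation correction uses the
test-fraction heuristic $\rho = 1/\text{folds} = 0.1$ (a choice, since
fold overlap makes the true correlation unidentifiable). Posterior mass is
split over $(-\infty, -r)$, $[-r, r]$ and $(r, \infty)$ with ROPE
half-width $r = 0.01$ on the accuracy scale: differences below one
percentage point are treated as practically equivalent. Each matrix cell
reports the probability of its winning region — the verdict's own mass —
because a single number per cell must summarise a three-way split. Swapping
row and column mirrors the left/right masses exactly.

As $\rho \to 0$ the posterior reduces to the standard one-sample t
posterior; a zero-variance difference vector collapses to a point mass,
assigned to the ROPE when it lands exactly on an edge (flagged as a
boundary case).

## The synthetic generator

No physiological recordings ship with the package, so `generate_register()`
produces labelled registers with the statistical structure the classifier
assumes. RR intervals are generated beat by beat: state mean + respiratory
sinus arrhythmia (RSA) sinusoid + AR(1) noise, truncated at 0.25 s. EDA is
a piecewise-linear tonic drift per state plus bi-exponential SCR kernels at
Poisson event times plus white noise, sampled at 8 Hz (well above the 2 Hz
cutoff while keeping registers small).

Defaults (all repo choices, fixed once): mean RR 1.00 / 0.80 / 0.62 s and
RSA amplitude 0.05 / 0.03 / 0.015 s at 0.25 Hz for Relax / Basal / Stress;
AR(1) noise sd 0.02 s ($\phi = 0.4$); tonic slopes −0.012 / −0.004 /
+0.025 µS/s; SCR rates 1.5 / 2 / 8 per minute (2 s rise, 8 s decay,
~0.3 µS). The parameters are deliberately arranged so that EDA alone
separates stress well but confuses relaxation with rest — the RR side
carries that distinction — and so that Basal, the intermediate class,
overlaps both neighbours and is the hardest to classify.
`scale_separation()` pulls all state-dependent parameters toward their
common mean, letting tests verify that recovery accuracy fades to chance
as the states merge.

Two artefacts of synthetic cohorts deserve naming because they mimic real
confounds. First, overlapping windows leak: two windows 15 s apart share
5 s of signal and three of four rolling-memory windows, so pooled
cross-validation scores exceed between-subject generalization. Second,
when every subject experiences the segments in the same order, slow drifts
(the tonic EDA level) predict the state through the clock rather than the
physiology; `synth_cohort_table(counterbalance = TRUE)` permutes the
segment order per subject, as counterbalanced protocols do. The package's
recovery tests use subject-grouped folds and counterbalanced cohorts for
exactly these reasons: at default separations the forest recovers the
state in over 90% of windows of unseen subjects, and as separations shrink
to zero accuracy falls to chance.

What the generator does **not** emulate: electrode artefacts and signal
gaps, ectopic beats, between-subject variability in baseline physiology
beyond the adaptive features' reach, and real RResp episode dynamics.
Passing tests therefore show the pipeline is correct and the method
behaves as designed — not that any particular accuracy will transfer to
clinical recordings.

## Problem sizes used by the test suite

The identity and oracle checks run on thousands of small random windows.
The recovery study uses cohorts of 10 subjects × 600 s (six 100 s
segments), about 390 labelled windows, evaluated with a 10-tree random
forest under 2-run 5-fold subject-grouped CV at three separation levels
(1, 0.05, 0). These sizes were chosen to make the suite quick to run on a
laptop while keeping the Monte-Carlo bands meaningful.

## Worked example

```{r example}
reg <- generate_register(synth_schedule(), seed = 7)
tab <- build_feature_table(reg)
dplyr::count(tab, label)

sel <- cfs_select(tab)
sel

cv <- run_cv(tab, rresp_algorithms(c("DT", "NB", "RF")), runs = 2,
             folds = 5, seed = 7)
glance(cv)

cmp <- build_comparison_matrix(cv)
tidy(cmp) |> dplyr::select(row, column, probability, verdict)
```

```{r plots, fig.width = 6, fig.height = 4, eval = FALSE}
autoplot(reg)
plot_poincare(reg$rr_beats$rr[1:200])
autoplot(cmp)
```

## Known limitations

* Exact parity with any other toolkit's default hyperparameters is a
  non-goal; algorithm rankings on borderline problems may differ.
* The spectral estimator is a binned periodogram on the resampled grid; a
  Lomb–Scargle estimator on raw beats would avoid interpolation bias for
  very irregular rhythms.
* The label-assignment rule (half-coverage, ties unlabelled) is a design
  choice; real protocols may need event-aligned windows instead.
* The Bayesian comparison assumes the paired-fold design; feeding it
  metrics from different partitions silently violates its model.
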