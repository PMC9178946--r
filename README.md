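# rresp

Mental-state classification of relaxation responses from RR-interval and
electrodermal-activity signals.

A relaxation response (RResp) is a short physiological episode in which the
body relaxes or compensates stress. The same episode can occur in three
different mental contexts — sustained **relaxation**, **basal** rest, or in
the middle of **stress** — and telling these contexts apart is what makes
the episode interpretable for a psychologist or clinician. `rresp`
implements an end-to-end pipeline for that three-class problem, for
researchers in physiological computing and affective state monitoring:

* **Preprocessing** — zero-phase 2 Hz low-pass filtering of both signals,
  4 Hz monotone-cubic resampling of the RR tachogram, register-level
  min–max normalisation `X_norm = (X_i − X_min)/(X_max − X_min)`.
* **Sliding-window feature extraction** — 20 s windows with 5 s overlap;
  per window 13 time-domain features, their 26 four-window rolling
  statistics, 2 spectral features (`P_max`, `f_Pmax` over 0.05–0.5 Hz at
  0.05 Hz resolution), and 9 Poincaré-plot descriptors: SD1c, SD2c,
  `SD1b = sqrt(Σ(xᵢ−yᵢ)²/2n)` with its exact split into deceleration and
  acceleration parts (`SD1e² + SD1d² = SD1b²`, `Ce + Cd = 1`), and the
  side counts nₑ, n_d.
* **RR_Band** — an adaptive single feature that cuts the register's RR
  span into three equal bands (1 = relaxation, 2 = rest, 3 = stress) and
  discretizes each window's mean RR; invariant to affine rescaling of the
  subject's RR signal.
* **Evaluation harness** — 12 classifiers (1R, DT, 1NN, 5NN, NB, RBF,
  SVM, LR, AdaB, Bag, RF, MLP; ensembles combine 10 decision trees) under
  10-run 10-fold stratified cross-validation with partitions shared across
  algorithms, plus CFS feature selection (MDL discretization, symmetrical
  uncertainty, best-first search).
* **Statistical comparison** — Friedman omnibus test at α = 0.05 and
  pairwise Bayesian correlated t-tests: posterior of the mean metric
  difference is a Student-t with scale² = (1/n + ρ/(1−ρ))·s², ρ = 1/folds,
  with a ±0.01 region of practical equivalence on the accuracy scale.
* **Synthetic generator** — seeded labelled registers (state-dependent RR
  level/variability, EDA tonic drift plus phasic SCRs) so the entire
  pipeline is testable without recordings.

## Worked example

```r
library(rresp)
library(dplyr)

reg <- generate_register(synth_schedule(), seed = 7)  # 600 s, 6 state segments
tab <- build_feature_table(reg)                       # 39 windows x 51 features
count(tab, label)
#>   label            n
#> 1 Relax-RResp     13
#> 2 Basal-RResp     12
#> 3 Stress-RResp    14

cv <- run_cv(tab, rresp_algorithms(c("DT", "NB", "RF")),
             runs = 2, folds = 5, seed = 7)
glance(cv)
#>   algorithm accuracy_mean accuracy_sd f1_mean  f1_sd auc_mean auc_sd
#> 1 DT                0.841      0.182    0.799 0.234     0.912 0.102
#> 2 NB                0.967      0.105    0.956 0.141     0.975 0.0791
#> 3 RF                0.978      0.0703   0.975 0.0791    1     0

friedman_test(cv)
#>   statistic    df p_value
#> 1      6.42     2  0.0403

tidy(build_comparison_matrix(cv)) |> select(row, column, probability, verdict)
#>   row   column probability verdict
#> 1 DT    NB           0.784 column_better
#> 2 DT    RF           0.877 column_better
#> 3 NB    DT           0.784 row_better
#> 4 NB    RF           0.505 column_better
#> 5 RF    DT           0.877 row_better
#> 6 RF    NB           0.505 row_better

round(confusion_matrix(cv, "RF"), 1)
#>              Relax-RResp Basal-RResp Stress-RResp
#> Relax-RResp           12           0            1
#> Basal-RResp            0          12            0
#> Stress-RResp           0           0           14
```

Read as: the mean accuracies rank RF ≥ NB > DT on this register; the
Friedman test rejects equivalence of the three at α = 0.05; the pairwise
Bayesian cells say the forest beats the tree with probability 0.88 while
RF-vs-NB is a toss-up (0.505), and the forest's confusions are confined to
the neighbouring relaxation/basal boundary. `autoplot()` methods render the
register, the Poincaré scatter and the comparison matrix.

A thin command-line front end over the same functions lives in
`inst/cli/rresp.R` (`simulate`, `features`, `evaluate`, `compare`
subcommands).

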