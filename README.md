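# semgpipe

Surface electromyography (sEMG) hand-gesture classification pipeline.

Forearm sEMG from four muscles — Extensor Digitorum (ED), Palmaris
Longus (PL), Flexor Carpi Ulnaris (FCU), Extensor Carpi Radialis
(ECR) — can be decoded into 15 functional hand-gesture classes: rest,
grasp, radial/ulnar wrist deviation and four finger pinches, in both
pronated and supinated arm positions. This matters for myoelectric
control of hand assistive devices, and especially for whether decoding
remains reliable in seniors, whose grip strength and motor consistency
decline with age.

`semgpipe` provides the whole analysis as tested, reusable R functions:

* a **synthetic-data generator** producing seeded, annotated 4-channel
  recordings (1024 Hz) under timed gesture protocols, with senior/young
  cohort structure (no recordings are distributed with the package);
* **segmentation** into overlapping 250 ms / 125 ms windows with pure or
  majority labelling;
* **features**: per channel, waveform length
  `y = Σ |t_r − t_{r−1}|`, windowed RMS
  `sqrt((m_1² + … + m_n²)/n)` and the four Burg-estimated AR(4)
  coefficients of `t_n = Σ q_i t_{n−i} + w_n` — 24 features per window;
* a **one-vs-one multi-class RBF-SVM**
  (`k(x_i, x_j) = exp(−γ‖x_i − x_j‖²)`) tuned by stratified 8-fold
  cross-validated grid search over `c ∈ (0, 100]`, `γ ∈ (0, 3]`, on a
  stratified 90/10 train/test split with training-set standardization;
* **evaluation**: per-subject accuracy and confusion matrices,
  adjacent finger-pinch confusion, and cohort summaries of accuracy
  against maximum force/torque, including the reference per-subject
  tables of a 12-senior / 7-young study shipped in `inst/extdata/`.

## Worked example

```r
library(semgpipe)

# one subject end to end: simulate -> segment -> features -> tune -> score
run <- run_subject_pipeline(default_config(seed = 1), group = "young")
print(run)
#> <semg_subject_run> YNG01 [young]: best c = 5, gamma = 0.1; test accuracy 96.43% (28 windows)
```

The printed line reports the grid-search optimum (`c`, `gamma`) and the
held-out test accuracy over this subject's ~28 test windows (10% of
~280 windows; about 6 s of signal per protocol).

A full two-cohort study and its group summary:

```r
study <- run_cohort_study(default_config())
print(study$summary)
#> <semg_cohort_summary>
#>    group  n mean_accuracy_pct mean_force_N mean_torque_Nm ...
#> 1 senior 12             87.50        3.635          6.442 ...
#> 2  young  7             96.94        4.667          3.225 ...
#> young -> senior: force -22.1%, ... accuracy -9.44 points
```

Senior cohorts classify less accurately than young cohorts, and
misclassified pinch windows concentrate on the adjacent finger
(middle vs ring), mirroring the co-contraction confusion structure of
real forearm recordings:

```r
pooled <- Reduce(`+`, lapply(study$runs, function(r) r$report$confusion))
adjacent_pinch_confusion(pooled)
#> [1] 0.74   # vs <= 2/14 under uniform error spreading
```

A thin command-line wrapper lives at `inst/scripts/semgpipe.R`
(`simulate`, `run-subject`, `run-cohort` subcommands, YAML configs via
`read_config()`).

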