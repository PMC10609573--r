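# augcls

Augmented classical least squares (CLS) calibration for UV
spectrophotometric analysis of multi-component mixtures, built around a
comparative study of four calibration models on a quinary system: three
analytes — pyrantel pamoate (PYR), cyclizine (CYC), mecloquine (MEC) — plus
two related impurities (BEP, BEH) that overlap the analytes across the
221–370 nm range.

## What it does

Plain CLS models absorbance as `A = C %*% S` (Beer–Lambert: spectra linear
in all component concentrations). It is exact when every absorbing species
is in the concentration matrix, but degrades when the spectra carry
variation unrelated to the modelled concentrations — baseline drift,
scatter, an unmodelled interferent. The package implements three
preprocessing filters that remove concentration-orthogonal variation before
the CLS step, and the tooling to compare all four models end to end:

- **`fit_cls()`** — classical least squares via a rank-revealing SVD
  pseudoinverse, with an explicit error naming collinear components.
- **`fit_osc()`** — orthogonal signal correction: iteratively extracts
  spectral factors of maximal variance constrained to be orthogonal to the
  concentration block, and deflates them.
- **`fit_dosc()`** — direct (non-iterative) orthogonal signal correction:
  projects the concentrations onto the data's row space, removes principal
  components of the part of the data orthogonal to that projection.
- **`fit_nap()`** — net analyte preprocessing: projects spectra onto the
  orthogonal complement of one analyte's interferent subspace, leaving its
  net analyte signal.
- **`fit_augmented()`** / **`predict()`** — filter + CLS quantitation in
  one model object.
- **`generate_design()`** — the 25-mixture, five-level, five-factor cyclic
  calibration design (balanced: each level appears exactly five times per
  component), plus the 16-sample validation set with 8 in-space and 8
  out-of-space mixtures.
- **`generate_dataset()` / `simulate_study()`** — a seeded Gaussian-band
  spectra simulator with configurable artifacts (iid noise, low-rank
  polynomial baseline, multiplicative scatter, an unmodelled interferent);
  artifacts are off by default and every draw is reproducible from
  `artifact_config(seed = ...)`.
- **`cv_factor_scan()` / `loo_press()` / `select_factors()`** —
  leave-one-out PRESS over a factor range with Haaland–Thomas (default) or
  minimum-PRESS selection.
- **`evaluate_run()` / `run_comparison()`** — per-sample recoveries,
  mean/SD per subset, RMSEC (divisor n = 25) and RMSEP over the
  out-of-space samples (divisor 8), with CSV/JSON/plot output.
- **`compute_fom()` / `fom_table()`** — net-analyte-signal figures of
  merit: sensitivity, analytical sensitivity, selectivity.
- **`replay_published_tables()`** — recomputes every derivable summary
  statistic (mean, SD, RMSEC, RMSEP, pooled t, variance-ratio F) from the
  published per-sample recovery and summary fixtures shipped in
  `inst/extdata/`, reproducing the reference study's printed tables from
  their own inputs.

## Worked example

```r
library(augcls)

# a study with noise and a planted rank-2 baseline artifact in both sets
study <- simulate_study(artifact_config(noise_sd = 0.002, baseline_rank = 2,
                                        baseline_scale = 0.2, seed = 1))

# LOO-CV factor selection, model fitting, evaluation, figures of merit
res <- run_comparison(study, factor_range = 1:4)

res$n_factors
#> $osc
#> [1] 3 3 2
#> $dosc
#> [1] 2 2 2     # the planted artifact rank, recovered per analyte
#> $nap
#> [1] 4 4 4

subset(res$report$summary, subset == "OUT" & analyte == "MEC")
#>  analyte model subset n mean_recovery sd_recovery   rmse
#>      MEC   CLS    OUT 8           103       7.980 0.4316
#>      MEC  DOSC    OUT 8           100       0.646 0.0369
#>      MEC   NAP    OUT 8           100       0.684 0.0404
#>      MEC   OSC    OUT 8           100       0.640 0.0366
```

The qualitative finding of the study reproduces on synthetic data: plain
CLS is biased by the artifact, all three augmented models remove it, and
their selectivity after filtering is 1 (no analyte signal lost to overlap):

```r
res$fom
#>   analyte model sensitivity analytical_sensitivity selectivity
#> 1     PYR   OSC      0.4124                  412.4           1
#> 2     PYR  DOSC      0.4124                  412.4           1
#> ...
```

Replaying the published tables from the shipped fixtures:

```r
head(replay_training_table(), 3)
#>   analyte model  n mean_recovery sd_recovery     rmsec
#> 1     PYR   CLS 25      100.0960    1.503953 0.1092485
#> 2     CYC   CLS 25       99.7280    5.721142 0.3739452
#> 3     MEC   CLS 25      100.7216    4.967079 0.4536449
```

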