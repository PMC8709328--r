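# mpus

Multiparametric-ultrasound (MPUS) decision pipeline for focal liver lesions
(FLLs) that remain **inconclusive after contrast-enhanced ultrasound (CEUS)**.

When the arterial-phase impression of a liver lesion does not allow a
confident CEUS diagnosis, three quantitative features can still be combined:

1. **liver stiffness** (elastography, dichotomised at fibrosis stage F4 =
   cirrhosis),
2. **late-phase washout**, quantified from the CEUS time–intensity curve
   (TIC), and
3. the **arterial enhancement pattern** read from parametric imaging.

This package implements that pipeline end to end for researchers in
quantitative ultrasound and clinical decision modelling: the washout model
and its AREA statistic, the fixed three-step binary decision tree that
turns the three features into malignancy and lesion-type calls, the
evaluation statistics, and a seeded synthetic cohort generator so the whole
pipeline is reproducible without patient data.

## The model

The late phase (> 120 s after bolus) of each ROI — one outlining the
lesion, one in adjacent parenchyma — is fit with the exponential washout
curve

```
F(t) = A · exp(−k · (t − t0)) + B,        k ≥ 0
```

where `B` is the asymptotic intensity (dB), `A` the drop from the
start-frame intercept to `B`, and `k` the decay rate (s⁻¹). `fit_washout()`
solves this by variable-projection least squares: `(A, B)` are exact linear
least-squares solutions for each `k`, reducing the fit to a deterministic
1-D search. From the fit come the initial gradient `−A·k`, the time to peak,
and the **AREA** statistic

```
AREA = (1/T) ∫ [F(t) − F(t_start)] dt  =  A · [ (1 − e^(−kT)) / (kT) − 1 ]
```

— the time-averaged deviation of the curve from its start-frame value, in
dB. A falling curve gives negative AREA; **AREA ≤ −19.3 dB flags washout**,
the late-phase hallmark of malignancy. The decision tree then calls
washout-positive lesions malignant and assigns a type from the
(cirrhosis, washout, pattern) rule table; a screening OR-rule
(`mpus_malignancy()`: cirrhotic OR washout) is provided as the
high-sensitivity variant.

## Worked example

```r
library(mpus)

cohort <- sample_cohort(cohort_config(), seed = 7)
cohort
#> Synthetic MPUS cohort: 91 lesions (51 malignant, 34 cirrhotic)
#>   lesion AREA: malignant mean -30.8 dB, benign mean 3.4 dB
#> ...

## one lesion's washout fit
tic <- subset(cohort$tic, lesion_id == "L001" & roi == "lesion")
fit <- fit_washout(tic_series(tic$t_seconds, tic$intensity_db))
fit
#> Exponential washout fit: F(t) = A*exp(-k*(t - t0)) + B
#>        A        B        k
#> 116.4640 -57.3838   0.0199
#>   AREA -84.9140 dB  gradient(t0) -2.3225 dB/s  TtoPk 0.0000 s  MSE 1.144 dB^2
```

AREA is −84.9 dB — far below the −19.3 dB cutoff, so this lesion (a
metastasis in the simulated truth) shows unambiguous washout. Running the
whole cohort through the tree and scoring it:

```r
results <- classify_cohort(cohort)
evaluate_results(results, cohort$lesions)
#> MPUS evaluation over 91 lesions
#> Confusion counts: TP 32  FP 11  TN 29  FN 19  (n = 91)
#>   Se 62.7%  Sp 72.5%  PPV 74.4%  NPV 60.4%  accuracy 67.0%  F1 68.1%
#>   AREA AUROC (lower = malignant): 0.768
#>   type detection: 29 of 61 correctly-classified lesions (48%)
```

The malignancy call is driven by washout alone, so with the configured
class overlap (malignant AREA −25.08 ± 37.98 dB vs benign −7.08 ± 42.6 dB)
accuracy sits in the 50–70% range depending on the cohort draw; the type
call additionally needs the arterial pattern to be read correctly.
`run_pipeline(config, out_dir)` performs simulate → quantify → classify →
evaluate in one call and writes all artifacts (cohort/TIC/results CSVs,
report and log JSON); `inst/cli/mpus.R` exposes the same stages as shell
subcommands.

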