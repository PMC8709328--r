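---
title: "Methods: washout quantification and the MPUS decision tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: washout quantification and the MPUS decision tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpus)
```

# The clinical problem

Contrast-enhanced ultrasound characterises a focal liver lesion by how
microbubble contrast arrives (arterial phase, 10–45 s) and leaves (late
phase, beyond 120 s). A malignant lesion typically *washes out*: its
late-phase intensity falls below the surrounding parenchyma. For a subset
of lesions the subjective CEUS reading stays inconclusive, and the
multiparametric (MPUS) approach re-examines them with three quantitative
features: the liver-stiffness dichotomy (cirrhotic F4 vs below), a
quantitative washout statistic from the time–intensity curve (TIC), and
the arterial enhancement pattern from parametric imaging. This package
implements that pipeline plus everything needed to exercise it on
simulated cohorts.

# The washout model

For each region of interest the late-phase TIC, in log-compressed decibel
units, is modelled as

$$F(t) = A\,e^{-k (t - t_0)} + B, \qquad k \ge 0,$$

with $B$ the asymptotic intensity (dB), $A$ the difference between the
start-frame intercept and $B$ (dB), and $k$ the decay rate (s⁻¹). The
model assumes the bolus peak has passed: no wash-in term is included, and
the clock is re-zeroed at the analysis-window start frame. Noise is taken
as additive i.i.d. Gaussian in dB, the usual working approximation for
ROI-averaged log-compressed intensities.

## Fitting: variable projection

`fit_washout()` minimises the mean squared error over $(A, B, k)$. For any
fixed $k$ the model is linear in $(A, B)$, so those two are solved exactly
by ordinary least squares on the basis $e^{-k\tau}$; the fit therefore
reduces to a one-dimensional search over $k \in [0, 10]$ s⁻¹ — a 60-point
log-spaced coarse grid from $10^{-3}/T$ to 10 followed by golden-section
refinement (`stats::optimize`, tolerance $10^{-8}$) in the bracketing grid
interval. This is deterministic (no random restarts), cannot diverge, and
is exact in the linear coordinates. The constant model ($A = 0$) is
evaluated explicitly and kept whenever no exponential beats it, with the
tie-break $A = 0, k = 0, B = \bar y$; consequently the fitted MSE never
exceeds the variance about the mean. A fit needs at least 4 samples (three
parameters plus one residual degree of freedom). The test suite
cross-checks the optimum against an independent Levenberg–Marquardt fit
(`minpack.lm`) started from $A_0 = y_1 - y_n$, $B_0 = y_n$, $k_0 = 2/T$.

## Derived TIC parameters

* **gradient at the start frame**: $-A k$ (dB/s), the model's initial
  slope;
* **time to peak**: time from the start frame to the maximum *observed*
  intensity, first occurrence on ties (so a monotone washout curve has
  TtoPk = 0);
* **AREA** (dB): the time-averaged deviation of the fitted curve from its
  own start-frame value,
  $$\mathrm{AREA} = \frac{1}{T}\int_{t_0}^{t_0+T} \bigl(F(t) - F(t_0)\bigr)\,dt
    = A\left[\frac{1 - e^{-kT}}{kT} - 1\right].$$

Two AREA conventions are plausible — the raw integral (dB·s) or the
time-averaged one (dB). The time-averaged form is the default because the
quantity is reported and thresholded in plain dB (class means near −25 and
−7 dB, a cutoff of −19.3 dB), which only makes sense after dividing by the
window length; `compute_area(..., normalize = FALSE)` gives the raw
integral, and `mode = "raw"` integrates the observed samples (trapezoidal
rule) instead of the fitted curve for users who prefer a fit-free
statistic.

## The washout flag

Washout is declared when lesion AREA ≤ −19.3 dB, boundary inclusive. The
sign convention deserves a note: thresholds for this statistic are
sometimes quoted as ">19.3 dB" or ">−19.3 dB", but with malignant lesions
*averaging* −25 dB and benign −7 dB the only direction consistent with
washout-implies-malignancy is "at or below −19.3 dB", which is what
`washout_flag()` implements. `curves_intersect()` offers the qualitative
secondary sign — the fitted lesion and parenchyma curves crossing within
the window — located by bisection after bracketing a sign change on a
256-point grid.

# The three-step decision tree

`bdtc_classify()` applies, in order: (1) the fibrosis branch (cirrhotic F4
or not — an input label here; elastography signal processing is out of
scope); (2) the TIC branch (washout flag); (3) a lesion-type lookup keyed
by (cirrhosis, washout, pattern). The malignancy call is driven by the
washout branch alone; the fibrosis branch conditions the type lookup and
also powers the separate high-sensitivity screen `mpus_malignancy()`
(cirrhotic OR washout — an OR rule, which by construction can only raise
sensitivity and lower specificity relative to the washout rule).

The rule table is *data*, not code (`default_rule_table()`, JSON
(de)serialisation via `write_rule_table()`), because the exact branch
layout of such clinical trees admits alternative readings. The default
reading maps, under washout: hyper-enhancement → HCC (in both fibrosis
branches), rim enhancement → metastasis, rim-like with central
hypo-enhancement → cholangiocarcinoma; without washout: peripheral nodular
→ haemangioma, centrifugal → FNH, peripheral with septa → abscess, and
iso-enhancement → regenerative nodule (cirrhotic) or focal fatty change
(non-cirrhotic). Whether a *non-cirrhotic* hyper-enhancing washout lesion
should instead read as adenoma is genuinely undecidable from the available
description; the default routes it to HCC, and
`inst/extdata/rules_hyper_noncirrhotic_adenoma.json` ships the alternative
reading. Keys absent from the table, or lesions without a readable
pattern, yield the type `"indeterminate"` while the malignancy call is
still made — mirroring a reader who can always assess washout but can only
type a subset of lesions. Adenoma is unreachable in the default tree (it
has no distinctive arterial row), so benign lesions with washout score as
malignancy false positives, which matches binary scoring practice.

# The synthetic cohort generator

No patient data accompany this pipeline, so `sample_cohort()` generates
cohorts with the statistical structure the analysis assumes. The defaults
*are* the study conditions:

| parameter | default | unit | note |
|---|---|---|---|
| `n`, `composition` | 91, fixed census | — | 34 HCC, 13 metastasis, 7 haemangioma, 7 regenerative, 5 focal fatty, 3 fatty free, 4 cholangiocarcinoma, 2 abscess, 5 adenoma, 4 biliary cyst, 5 infarction, 2 vascular |
| `cirrhotic_fraction` | 34/91 | — | assigned as an exact count, preferentially (8:1 weight) to HCC and regenerative nodules |
| `area_mean_malignant` ± sd | −25.08 ± 37.98 | dB | class-conditional lesion AREA |
| `area_mean_benign` ± sd | −7.08 ± 42.6 | dB | |
| `regression_intercept`, `slope` | −12.21, 0.16 | dB, — | lesion~parenchyma AREA line |
| `k_decay` | 0.02 | s⁻¹ | visible but incomplete washout over 180 s |
| `baseline_B` | −57.3 | dB | typical late-phase asymptote |
| `noise_sd` | 1 | dB | ROI-averaged speckle residual |
| window | 120–300 s at 1 Hz | s | late phase starts at 120 s; acquisition rate is a choice |
| `pattern_confusion_rate` | 0.3 | — | see below |

**Pattern noise.** The lesions being emulated were inconclusive *by
definition*, so their arterial patterns cannot be read reliably; each
simulated lesion keeps its type's canonical pattern with probability 0.7
and is otherwise assigned a uniformly random other pattern. The 0.3 rate
was chosen once as a realistic misread rate for this population and is not
a calibration dial.

**Joint calibration of AREA.** Parenchyma AREA is drawn first, and lesion
AREA follows the regression line plus a class shift and residual. Three
published summaries must hold simultaneously: both class-conditional means,
and the pooled regression line as the exact OLS estimand. They pin down the
parenchyma AREA location: pooled mean lesion AREA is
$w_m(-25.08) + w_b(-7.08) \approx -17.16$ dB (with the census's 51/40
malignancy split), so the parenchyma location must be
$(\bar y - a)/b \approx -30.9$ dB. The generator therefore *derives* this
location from the composition (overridable via `parenchyma_area_mean`);
with it, the class shifts average to exactly zero, so pooled OLS recovers
$(-12.21, 0.16)$ unbiasedly, which the tests verify at $n = 10^4$ within
3 standard errors. A consequence worth stating plainly: a parenchyma mean
of −7 dB cannot coexist with those class means and that regression line —
the three published summaries are mutually inconsistent with it under any
linear Gaussian model — and this package resolves the conflict in favour
of the quantities the pipeline actually uses. Residual SDs are
$\sqrt{\sigma_c^2 - b^2 \sigma_x^2}$ per class so the *total* class SDs
equal the configured 37.98/42.6 dB.

**Truncation.** An optional cap `area_max` bounds AREA draws (rejection
sampling with the location recalibrated by root-finding so class means stay
exact). It defaults to `Inf`: with ~40 dB class SDs a physically motivated
cap near +30 dB would truncate 7–19% of each class's mass and attenuate
the recoverable regression slope from 0.16 to roughly 0.11, silently
breaking the generator's own parameter-recovery guarantees. Users who need
bounded draws can enable the cap, accepting that the pooled regression
estimand then flattens.

**TIC synthesis.** Each drawn AREA is inverted analytically to an
amplitude ($A = \mathrm{AREA} / [(1-e^{-kT})/(kT) - 1]$,
`params_from_area()`), and the exponential is sampled on the window grid
with Gaussian noise. The fit therefore recovers the drawn AREA up to noise
(±0.7 dB at the defaults), which couples the generator and the quantifier
and is exploited by the round-trip tests.

**What the generator does not emulate:** wash-in kinetics and bolus
transit, pixel-level arterial-phase data (the pattern is a label), motion
and depth-dependent attenuation artifacts, inter-operator ROI variability,
and any correlation between fibrosis and AREA beyond the type-mediated
one. Passing tests therefore demonstrate the *pipeline's* correctness and
calibration on its assumed data model — not the clinical performance of
the method on real lesions.

# Evaluation statistics

`confusion_metrics()` uses the standard definitions, reporting undefined
ratios as missing rather than zero. `auroc()` is the pairwise-concordance
(Mann–Whitney) estimator with ties counted ½ — identical to trapezoidal
integration of the empirical ROC — with a `direction` flag because more
*negative* AREA means more malignant; the tests verify it against a
brute-force all-pairs oracle up to $n = 50$ and against an independent ROC
implementation. `roc_curve()` sweeps every observed score and returns the
Youden-optimal cutoff (max $Se + Sp - 1$), breaking ties toward the higher
sensitivity. `compare_groups()` gates between Student's t (pooled
variance) and the Mann–Whitney test on per-group Shapiro–Wilk normality at
$\alpha = 0.05$; groups below $n = 4$ go straight to the rank test, where
the Shapiro test has essentially no power. `two_proportion_test()` is the
pooled-variance z test (chi-square without continuity correction), which
is the convention that reproduces two-decimal p-values such as 0.39 for
66/91 vs 71/91; Fisher's exact test is an option. The lesion~parenchyma
regression is ordinary least squares via `stats::lm`.

One arithmetical caveat is reproduced deliberately rather than "fixed":
the published detection counts (44 correct of 55 called malignant, 27 of
35 called benign) cannot form a single 91-lesion confusion matrix — they
sum to 90 — and the sensitivity/specificity printed alongside them (62%,
45%) are not consistent with any such matrix either. The self-consistent
arithmetic (PPV = 44/55 = 80%, accuracy = 71/91 = 78.0%, and the F1 that
combines tp = 44, fp = 11 with fn = 27 to give 69.8%) is what the
acceptance checks compute; the inconsistency itself is documented here and
left unresolved, as no choice of matrix can satisfy all printed values at
once.

# Numerical choices and degenerate inputs

* Fit search bounds $k \in [0, 10]$ s⁻¹; objective tolerance $10^{-8}$;
  flat series short-circuit to the constant model.
* `params_from_area()` refuses $kT < 10^{-8}$ (the inversion factor loses
  all precision) — a degenerate-window error, not a silent 0.
* Truncated-normal locations are calibrated with `uniroot` at tolerance
  $10^{-10}$; draws use inverse-CDF sampling so they stay reproducible
  under a single seed.
* All randomness flows through one seed argument; the caller's RNG state
  is saved and restored, and equal seeds give byte-identical cohorts.
* CSV numerics are written with 12 significant digits; the round-trip
  tests assert value equality at $10^{-11}$ relative tolerance.
* Ties: time-to-peak takes the earliest frame; the Youden cutoff takes the
  higher-sensitivity threshold; rule lookups take the first matching row.

# Problem sizes used by the tests

The suite exercises calibration checks at $n = 10^4$ lesions (drawn AREAs
only — TIC fitting at that scale adds nothing to the claim), fit-bias
Monte Carlo over 500 noisy series of 121 samples, interval-coverage checks
over 500 regressions of $n = 30$, and full pipeline runs (two TIC fits per
lesion) at the 91-lesion default — sizes chosen so each check's Monte
Carlo error is well below the tolerance it asserts.

# Known limitations

* Fibrosis enters only as the F4 dichotomy; the continuous kPa scale, and
  elastography itself, are out of scope.
* The arterial pattern is an input label; no parametric-imaging colour-map
  computation from pixel data is attempted.
* The decision tree is a fixed clinical rule set — there is deliberately
  no impurity-based tree learning here.
* The generator's Gaussian-in-dB noise and exponential-only kinetics are
  idealisations; real TICs show recirculation, drift, and heavier-tailed
  noise.
* Printed-value reproduction is limited to quantities that are functions
  of published counts; cohort-dependent results (AUROCs near 0.58–0.72,
  specific sensitivities) vary across synthetic draws exactly as they
  would across clinical samples, and are reported by the pipeline rather
  than asserted.
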