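---
title: "Temporal features of BOLD cerebrovascular reactivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal features of BOLD cerebrovascular reactivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrtime)
```

## The measurement problem

Cerebrovascular reactivity (CVR) is the capacity of cerebral vessels to
dilate in response to a vasoactive stimulus, here an inhaled CO~2~
challenge. In a boxcar gas paradigm the subject alternates between room
air and a CO~2~ mixture while BOLD fMRI is acquired; the BOLD signal
rises during hypercapnia and recovers afterwards. Conventional analysis
summarizes the whole run with a single general-linear-model (GLM)
amplitude. `cvrtime` instead decomposes the response into *temporal
features*: a per-challenge CVR amplitude estimated non-parametrically,
and a *transition rate* describing how fast the signal returns to
baseline when normocapnia resumes. The package's central scientific
question is whether the recovery rate after a first challenge predicts
the amplitude of the response to a second challenge.

## The non-parametric CVR estimate

For the dilation window of each challenge, the trend is estimated with
Sen's slope (the Theil–Sen estimator): the median of all
$n(n-1)/2$ pairwise slopes

$$\hat\beta = \operatorname{median}\left\{ \frac{y_j - y_i}{j - i} : i < j \right\},$$

with indices in samples. The slope is converted to a percent signal
change over the window,

$$\Delta \mathrm{BOLD} \,[\%] = \frac{\hat\beta \cdot n}{\bar y_{\text{baseline}}} \times 100,$$

where $\bar y_{\text{baseline}}$ is the mean signal over the 30 s
preceding the window (truncated at the start of the series), and
normalized by the end-tidal CO~2~ step:

$$\mathrm{CVR} = \frac{\Delta \mathrm{BOLD}\,[\%]}{\Delta \mathrm{PETCO_2}} \quad [\%/\mathrm{mmHg}].$$

The median of pairwise slopes has a ~29% breakdown point, so spike
artifacts that would bias an ordinary-least-squares (OLS) trend leave
the estimate essentially unchanged (this is verified quantitatively in
the test suite: 20% gross contamination of a line moves Sen's slope by
less than 5% in every trial while OLS is off by more than 5% in the
majority).

## The transition rate

The hypercapnia-to-normocapnia recovery is summarized by an OLS fit of
the BOLD signal on time *in seconds* over the transition window; the
slope $\tau$ (a.u./s) divided by $\Delta \mathrm{PETCO_2}$ gives the
transition rate (a.u./s/mmHg). Both are negative for a recovering
signal. Note the deliberate asymmetry of units: Sen's slope is kept in
per-sample units because Eq. 2 multiplies it straight back by the
sample count, while the transition fit uses seconds so the rate is
comparable across the two acquisition TRs.

## Designs and analysis windows

Two boxcar paradigms are built in:

| | Design A | Design B |
|---|---|---|
| blocks (s) | 120/180/120/180/120 (air/CO~2~/air/CO~2~/air) | 45/45/90/120/180 |
| TR (s) | 1.55 | 2.0 |
| volumes (acquired/discarded) | 478 / 25 | 255 / 5 |
| CVR windows (s) | [40, 280), [360, 580) | [10, 80), [135, 280) |
| transition windows (s) | [280, 360), [580, 660) | [80, 135), [280, 390) |

All windows live on the post-discard time axis and are closed-open:
a sample at time $t$ belongs to $[t_0, t_1)$ iff $t_0 \le t < t_1$.
The CVR windows deliberately extend past the gas switch because the
BOLD response lags and often keeps rising after the stimulus ends;
the transition windows start where the dilation windows end.

```{r windows}
windows_for_design("A")
```

## The parametric comparator and AIC

The conventional pipeline is provided for comparison: the 0/1 paradigm
boxcar is convolved with a single-gamma hemodynamic response function
with mean lag 6 s and SD 3 s (shape 4, scale 1.5, 30 s support,
renormalized to unit sum so a sustained block converges to the full
amplitude), and the series is regressed on it; the regressor
coefficient is the COPE.

Model comparison uses the Gaussian AIC with additive constants dropped,
$n \log(\mathrm{RSS}/n) + 2k$, with $k = 2$ for both the GLM (intercept
+ regressor) and the Sen line (intercept + slope). Because both models
are scored with the same convention, AIC *differences* — the only
quantity interpreted — are convention-free; the test suite confirms the
differences agree with the full-constant formula to 1e-10. A
zero-residual fit (possible only on noise-free input) is reported as
$-\infty$ rather than an error during model comparison.

## The fast/slow simulation study

Two idealized single-challenge responses probe when each model wins:

* **fast** — a logistic rise completing within a 20 s rise time of the
  gas switch (steepness $8/\text{rise time}$, so the curve traverses
  2%–98% of its plateau within one rise time);
* **slow** — a linear ramp spanning the whole 180 s challenge.

Each epoch is 120 s baseline + 180 s challenge at TR 1.55 s, baseline
1000 a.u., amplitude 2%. White Gaussian noise with
$\sigma = \text{baseline}/\text{tSNR}$ sweeps nominal temporal SNR
(tSNR) from 5 to 100. Both models are fitted to the whole epoch.

```{r epoch}
e <- simulate_epoch("slow", noise_sd = 20, seed = 42)
compare_models(e)
```

At moderate-to-high tSNR (nominal tSNR of roughly 47 and above on this
grid) the parametric model attains the lower mean AIC on fast
responses — the gamma-HRF convolution is nearly the correct shape — and
the non-parametric line attains the lower mean AIC on slow responses,
whose ramp a single fixed-lag HRF cannot track. Mean AIC falls
monotonically as tSNR rises for both models and both shapes (Spearman
correlation $-1$ across the per-cell means in our runs; see
`scripts/acceptance.R` and the acceptance tests, which reproduce these
findings on a 2 × 10 × 30 grid). At very low tSNR the comparison is
noise-dominated and neither direction is asserted.

## The synthetic cohort generator

Since subject-level MRI data cannot ship with a package, the group
models are validated on synthetic cohorts whose ground truth is known.
The generator's design went through three substantive decisions, each
made for a scientific reason rather than to satisfy a test:

1. **Recovery is linear across the whole transition window.** Each
   challenge contributes a response bump that ramps up across the
   dilation window and then declines at the true recovery slope $\tau$
   (a.u./s) across the *entire* transition window, mildly undershooting
   baseline if $\tau$ is steep — as post-stimulus BOLD undershoots do —
   and resettling afterwards. An earlier formulation floored the
   recovery at baseline; then a steep $\tau$ finished early, the window
   OLS saw a long flat tail, and the measured rate became a *non-
   monotone* function of the true rate, which is a generator artifact,
   not a measurement property: the transition-rate metric is defined as
   a linear read-out over a fixed window, so the planted physiology
   must be linear over that window for "truth" to be well defined.
2. **Truths are planted on the PETCO~2~-normalized scale.** Each
   subject draws a true first-challenge CVR $c_1$ (%/mmHg), a true
   per-mmHg recovery rate $r$ (a.u./s/mmHg), and a second-challenge CVR
   $c_2 = \alpha + \beta r + \varepsilon$; signal-scale amplitudes are
   then $a_j = c_j\,\delta$ and $\tau = r\,\delta$ for the subject's own
   step $\delta$. Planting raw amplitudes independently of $\delta$
   instead makes the *measured* (normalized) metrics share a $1/\delta$
   divisor, which induces a spurious association between them even when
   $\beta = 0$ — the classic ratio-correlation artifact. BOLD responses
   do scale with the stimulus; that is exactly why the metrics divide
   it back out, and the generator must respect it for the null to be a
   true null.
3. **Default tSNR is 200, an ROI-mean figure.** Published tSNR ranges
   like 30–80 describe single voxels; the package analyzes ROI-*mean*
   series, which average hundreds to thousands of voxels and have
   several-fold higher tSNR. A per-subject nominal tSNR of 200 for the
   simulated ROI-mean series is therefore conservative, not optimistic.

The default cohort mirrors a two-site composition: 54 subjects, 40 on
Design A (20 "cognitive", 20 "sleep apnea") and 14 on Design B (all
"cognitive"); ages ~N(67, 11) clamped to [40, 95]; Design B uses a
targeted 10 mmHg step while Design A steps are drawn uniformly from
7–10 mmHg. The strong-effect preset is $\beta = -7$ (steeper recovery
predicting a larger second response); $\beta = 0$ gives the null.
Optionally a breath-modulated capnometry trace is generated per
subject; its end-tidal level follows the gas timing with a 20 s
washout — end-tidal CO~2~ is the stimulus and returns within a few
breaths of the gas switch, unlike the slow BOLD recovery.

## Group-level models

With the per-subject table in hand, two OLS models are fitted per ROI:

* **Model 1**: `cvr2 ~ transition_rate_1 + age + sex + group + design`;
* **Model 2**: adds `cvr1` and replaces the transition rate by its
  residual after regression on `cvr1`.

Continuous variables are standardized (so PEs are standardized
effects); sex, group and design enter as 0/1 indicators. The default
orthogonalization target is `cvr1`: residualizing a predictor against
the *outcome* (`cvr2`) is statistically incoherent — it builds the
outcome into the design matrix and distorts both the estimate and its
p-value — so while `orth_target = "cvr2"` is selectable for
comparability with pipelines that made that choice, `cvr1` is the
defensible default. Significance across four ROIs uses a Bonferroni
threshold of $\alpha/m = 0.05/4 = 0.0125$, applied inclusively
($p \le 0.0125$).

```{r cohort}
tab <- cohort_table(synthesize_cohort(n_subjects = 20, seed = 7))
fit_model1(tab)
```

In our Monte-Carlo acceptance runs (200 strong-effect and 200 null
cohorts at the defaults, seeds 1–200 and 5001–5200), Model 1 returned a
negative standardized transition-rate PE in 100% of strong cohorts with
$p \le 0.0125$ in 97.5%, while the null rejection rate was 2% against a
nominal 1.25% — within binomial Monte-Carlo error.

## Numerical choices

* Windows are closed-open on the post-discard axis; slicing warns when
  a window is truncated by the series end and errors when it misses
  entirely.
* `sens_slope` drops `NA` samples while preserving their index gaps, so
  censored volumes do not distort the per-sample time base.
* The high-pass filter is a Gaussian-weighted running-line detrend
  ($\sigma$ = half the cutoff period) with the series mean re-added;
  it attenuates drift far below the cutoff while leaving
  half-Nyquist oscillations within 5% of their amplitude.
* All simulator randomness flows through explicit integer seeds; seeded
  draws use a scoped RNG that restores the caller's `.Random.seed`, so
  library calls never perturb user-level reproducibility. Outputs are
  byte-identical across reruns with the same seed.

## Limitations

* Simulated noise is white Gaussian; real BOLD noise is autocorrelated
  and drifts, so the simulated power figures are optimistic in that
  specific respect (and conservative in the tSNR choice).
* The response shapes are idealized (logistic, ramp, triangular bump);
  real responses vary in lag and shape across vascular territories.
* The COPE comparator's scale depends on paradigm geometry — how much
  of the response falls under the convolved boxcar differs between
  Designs A and B — so COPE-based CVR values are not directly
  comparable across designs (observed directly in the synthetic
  cohorts, where the pooled COPE-vs-CVR correlation is markedly weaker
  than the within-design correlation).
* Group-model validation is desk-scale Monte Carlo on synthetic
  cohorts; clinical effect sizes estimated from real cohorts cannot be
  reproduced without the underlying MRI data.
* One series in, one ROI at a time: no spatial modeling, voxelwise
  mapping or mixed-effects pooling across ROIs.
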