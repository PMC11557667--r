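---
title: "Measuring the gaze cone: models, simulators, and the overestimation correction"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(gazecone)
```

## The problem

The *gaze cone* is the wedge of gaze directions that an observer experiences
as directed at themself. Its half width — the *threshold of direct gaze* —
is a standard psychophysical quantity, but the number one measures depends
on the task used to measure it. This package implements the three classic
tasks side by side, together with a generative observer model, so that the
whole measurement pipeline can be exercised, compared, and validated by
parameter recovery on synthetic cohorts:

* **Method of constant stimuli** (dyadic yes/no): fixed gaze directions are
  presented in random order; the observer judges "looked at" or "not looked
  at" on every trial.
* **Method of adjustment**: the observer steers the looker's gaze until they
  just feel looked at (*ascending* series, starting averted) or just feel no
  longer looked at (*descending* series, starting direct).
* **Triadic task**: the observer reports *where* the looker is fixating by
  reading a position off a scale, which measures perceived gaze direction
  independently of the direct-gaze judgement.

## Geometry

All stimuli live on a fixation plane at viewing distance $D$; an offset of
$x$ cm from the observer's midline corresponds to an eye rotation of
$\theta = \arctan(x / D)$, computed exactly (no small-angle approximation).
Angles are in degrees; gaze to the observer's left is negative. The per-eye
vergence needed to fixate the observer is $\arctan((\mathrm{IPD}/2)/D)$.

```{r}
geom <- gaze_geometry(viewing_distance_cm = 165, ipd_cm = 6.5)
offset_to_angle(2, geom)     # a 2 cm offset at 165 cm
vergence_per_eye(geom)
```

The canonical one-sided design places fixation offsets at 0 and at the
powers of a 2.5 cm base step:

```{r}
design <- exponential_stimulus_design(2.5, 4, geom, repetitions = 25)
design
```

Note a deliberate bookkeeping choice: the widest offset, 39.0625 cm, maps to
13.3 degrees under the arctan rule. Summary tables of this design are often
labelled with 13.9 degrees for the widest direction; the generator reports
the value the geometry implies and leaves the conventional labels
(0, 0.9, 2.2, 5.4, 13.9) available as regression breakpoints for data keyed
to them (see below). Angles are never rounded in computation, only at
presentation.

## The generative observer

`observer_params()` maps each observed phenomenon to one parameter.

**Dyadic rule.** A trial at direction $\theta$ is judged "looked at" with
probability
$$P(\text{direct}\mid\theta) = (1-\lambda)\,\Phi\!\left(\frac{T - |\theta - c|}{\sigma}\right) + \lambda/2,$$
with criterion $T$ (degrees, the true threshold), psychometric width
$\sigma$ (degrees), lapse rate $\lambda \in [0, 0.1]$, and cone center $c$
(one-sided designs use $|\theta|$ and ignore $c$). Defaults: $T = 3.3$,
$\sigma = 1.5$, $\lambda = 0.02$, $c = 0$. The width and lapse are not
reported by cohort summaries in this literature; 1.5 degrees gives
individual thresholds spanning roughly 1–6 degrees in a cohort with SD 1,
and a 2% lapse is a typical attentional slip rate.

**Adjustment rule.** Ascending series stop at magnitude
$T_a - h/2 + \varepsilon$, descending at $T_a + h/2 + \varepsilon$, with
$\varepsilon \sim N(0, s)$; stops are clipped to the adjustable range and
quantized to the device step (0.05 degrees for a fine mouse-wheel mapping,
1 degree for a coarse one). Hysteresis $h$ is symmetric around the
adjustment criterion $T_a$, so averaging the two series is unbiased for
$T_a$ — the rationale for running both series in the first place. $T_a$
defaults to the dyadic criterion but can be set separately: empirically the
adjustment task yields systematically larger thresholds, and a shared
criterion cannot generate that phenomenon. The default stop-point noise
$s = 1.05$ degrees is the average within-observer SD reported for this task
with a live looker.

**Triadic rule.** Perceived direction is a continuous two-slope function
$$g(\theta) = \operatorname{sign}(\theta)\left[\alpha \min(|\theta|, \kappa) + \beta \max(0, |\theta| - \kappa)\right],$$
shallow ($\alpha = 0.18$) below the knot $\kappa = 0.9$ degrees and steep
($\beta = 1.8$) above it — gaze near straight ahead is underestimated,
peripheral gaze overestimated. The perceived direction is projected to cm
on the response scale, perturbed by report noise (default SD 2 cm), and
rounded to the whole centimetre the observer reads off the scale. The
rounding is a quantization step exactly like the adjustment step, and it is
configurable (`round_to_cm = FALSE`) because sub-centimetre perceived
offsets near straight gaze — the entire first regression section at 165 cm
— are unrecoverable from integer-cm reports: noiseless-recovery checks must
run on the unquantized scale.

`simulate_cohort()` draws per-observer parameters from fixed values or
truncated-normal specs, derives per-observer seeds from the master seed by a
fixed counter scheme, and persists the drawn truth table beside the trial
data, so every simulated dataset carries its own recovery ground truth and
is byte-reproducible from its configuration.

## Fitting

**One-sided threshold.** "Looked at" judgements are inverted and a
cumulative Gaussian
$P(\text{averted}\mid\theta) = (1-\lambda)\Phi((\theta - T)/\sigma) + \lambda/2$
is fitted by maximizing the binomial log-likelihood; $T$, the 50% point, is
the threshold of direct gaze. 0% and 100% cells are handled through the
likelihood itself (probabilities clamped at $10^{-12}$ for log-safety); no
empirical-logit transform is used. The optimizer is bounded L-BFGS-B with
five deterministic starts (threshold at the direction quantiles, two width
scales), so fits are reproducible without randomness; `converged` is
reported honestly and a non-converged best point is still returned with a
warning. The lapse is fixed at 0 by default; `lapse = "free"` bounds it to
$[0, 0.05]$. The free mode is the right choice whenever the data-generating
process can lapse: on simulated cohorts with a 2% lapse, the fixed-0 fit
leaves a ~0.2 degree upward threshold bias that the free fit removes, and
the cohort-level pipeline examples below therefore use it.

**Two-sided threshold.** For two-sided designs a Gaussian bell
$P(\text{direct}\mid\theta) = a\exp(-(\theta - c)^2/2w^2)$ is fitted the
same way; the SD $w$ is the threshold and $c$ the cone's center shift. The
amplitude is free in $(0, 1]$ (fixable at 1 via `fix_amplitude`).

Both fits can be checked against `grid_fit_oracle()`, an exhaustive
log-likelihood evaluation over a finite grid; the test suite requires the
quasi-Newton optimum to sit within one grid step of the exhaustive one.

**Adjustment summaries.** Cell means are computed per series (and side) and
combined *unweighted* — the threshold is the mean of the two (or four) cell
means, not the pooled trial mean, which matters when cells are unbalanced.
Two-sided data are folded by sign (left-side magnitudes) before pooling;
signed side means are kept alongside. The hysteresis contrast is a paired t
test on per-observer descending-minus-ascending means.

## The overestimation correction

Triadic cm reports are converted to degrees through the geometry and
regressed on true direction, globally (`fit_linear`, the classical
overestimation slope) and in four sections with fixed breakpoints
(`fit_piecewise`). Sections are closed intervals fitted independently by
OLS — discontinuities between sections are allowed — and boundary points
enter both adjacent fits. A dyadic threshold $T$ is corrected by the full
regression line of the section containing it:
$$T^{*} = \hat\beta_k T + \hat\alpha_k, \qquad k : b_{k-1} \le T \le b_k,$$
with interior boundary ties resolved to the higher section and thresholds
above the last breakpoint extrapolated with the last section; the
*estimation bias* is $T^*/T$. These tie-break rules are stated because they
change corrected values for thresholds near a section edge. Using the
intercept as well as the slope matters: section intercepts are materially
non-zero, and slope-only correction would shift every corrected threshold.

```{r}
segs <- data.frame(observer_id = 1, segment = 1:4,
                   lower = c(0, 0.9, 2.2, 5.4), upper = c(0.9, 2.2, 5.4, 13.9),
                   slope = c(0.18, 1.71, 1.70, 1.97),
                   intercept = c(0.76, -0.58, -0.57, -2.01))
pw <- piecewise_from_segments(segs)[["1"]]
correct_threshold(3.0, pw)[c("segment_index", "corrected_threshold")]
```

When fitting *simulated* data from the exponential design, the breakpoints
must be the design's generated directions (`design$directions_deg`), since
the conventional labels do not exactly equal the generated angles and the
second section would otherwise contain a single abscissa.

## Cohort statistics

`paired_t()`, `pearson_r_test()` and `rm_anova_slopes()` are implemented
from their defining formulas (and cross-checked in the test suite against
`t.test`, `cor.test` and `aov`): two-sided p values throughout, paired
Cohen's $d = \bar{d}/s_d$, correlation df $= n-2$, ANOVA df
$=(k-1, (k-1)(n-1))$ with $\eta^2 = SS_{cond}/(SS_{cond}+SS_{err})$. No
multiple-testing adjustment is applied to post-hoc contrasts.
`compare_methods()` joins the per-observer thresholds of the two dyadic
methods (failing loudly on id mismatches), applies the per-observer segment
correction, and reports means, the adjustment/constant-stimuli ratio
(computed before any rounding), paired t tests and correlations for the raw
and corrected blocks.

```{r}
cfg <- cohort_config(n_observers = 18,
                     criterion = c(3.3, 0.2), psycho_width = c(1.5, 0.2),
                     adjust_criterion = c(5.2, 0.3), adjust_noise_sd = 1.05,
                     adjustment = adjustment_plan("one", 6),
                     triadic_repetitions = 1, master_seed = 501)
cohort <- simulate_cohort(cfg)
fits_cs <- fit_cohort_psychometric(cohort$dyadic, "one_sided", lapse = "free")
adj <- summarize_adjustment_cohort(cohort$adjustment, "one")
compare_methods(fits_cs, adj)
```

## Problem sizes and what the tests show

Validation runs use cohorts of 18 observers on the canonical designs (125
dyadic trials, 12–60 adjustment trials, 5–140 triadic positions per
observer), 10–20 master seeds per stochastic check, and a 0.1-degree grid
for the exhaustive oracle — sizes at which recovery standard errors are
well below the effects being checked. With those sizes the pipeline
recovers mean dyadic criteria to within 0.3 degrees, mean adjustment
criteria to 0.2 degrees, a 4.4-degree hysteresis within 3 standard errors,
and noiseless triadic section slopes to 0.02.

The simulator emulates binomial response noise, series hysteresis,
stop-point settling noise, device quantization, the nonlinear perceived-
direction gain, and report rounding. It does **not** emulate a live
looker's fixation error, sequential effects (learning, fatigue,
trial-to-trial anchoring beyond the single hysteresis parameter), response
times, or asymmetric response criteria. Passing recovery tests therefore
demonstrate that the analysis correctly inverts this generative family —
not that real observers are members of it; in particular the low
between-method correlation seen with live lookers is plausibly driven by
stimulus noise the model omits.

## Known limitations

* The correction composes a gaze-direction measurement with a direct-gaze
  threshold; for observers with very small thresholds the first section's
  shallow slope *shrinks* the corrected threshold, and whether the
  composition is meaningful at all is a substantive, not statistical,
  question.
* Correlation df is always $n-2$ and paired-t df always $n-1$; published
  tables sometimes mix other conventions, and no attempt is made to chase
  them.
* The rm-ANOVA uses standard uncorrected df (no sphericity correction);
  with four sections and small cohorts this is anticonservative under
  sphericity violations.
* One-sided designs estimate the cone's half width on one side only and
  assume symmetry by construction.
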