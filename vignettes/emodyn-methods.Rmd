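---
title: "Models and methods behind emodyn"
author: "emodyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emodyn)
```

## The scientific problem

Immersive, EEG-instrumented interventions (interactive art installations,
VR environments) aim to regulate affect, and the question is how well
neural markers and self-report jointly predict the affective change they
produce. emodyn implements a dual-model account of that question:

1. **A linear response surface.** Affect change on each PANAS subscale is
   modelled as a quadratic/interaction polynomial in three predictors:
   the raw pre-to-post change in frontal-midline theta power
   (\eqn{\Delta\theta}, cognitive control), the raw change in
   frontal-parietal gamma power (\eqn{\Delta\gamma}, arousal), and the
   affective shift (\eqn{AS}, net self-reported reappraisal):

   \deqn{\Delta E = \beta_0 + \beta_1\Delta\theta + \beta_2\Delta\gamma +
   \beta_3 AS + \beta_4(\Delta\theta \cdot AS) + \beta_5\Delta\gamma^2 +
   \beta_6 AS^2 + \varepsilon.}

   The interaction term captures context-dependent modulation of the
   theta effect by the participant's subjective state; the quadratics
   capture saturation or synergy. All inference is by participant-level
   case-resampling percentile bootstrap.

2. **A feedback simulation on the fitted surface.** The same polynomial,
   read as an "emotional payoff", is ascended by per-parameter gradient
   steps \eqn{x_{t+1} = x_t + \eta \odot \nabla \Delta E(x_t)} until the
   payoff change falls below a tolerance — a stylized model of a person
   (or an adaptive environment) iteratively recalibrating cognitive load,
   arousal and appraisal.

Because the underlying participant-level dataset is external, the package
ships a generative module that emulates the study conditions (50
participants, PANAS subscale scores, band-power changes at 1e-11/1e-12
magnitudes), so every stage is testable end to end and coefficient
recovery can be verified against known generative truth.

## The reference generative configuration

`default_generative_config()` pins the package's reference condition:

* **Coefficients.** The published fitted coefficients are used as
  generative truth. The shift coefficient of the negative-affect equation
  is −3.96 and of the positive-affect equation 1.69; the theta main
  effect (2.68e-11) and the theta-by-shift interaction (1.77e-10) sit in
  the negative-affect equation, reflecting the cognitive-control
  hypothesis, while the gamma main effect (1.70e-12), the gamma quadratic
  (1.03e-23) and the shift quadratic (79.43) sit in the positive-affect
  equation, reflecting the arousal hypothesis. The published table also
  contains an unexplained standalone shift row (5.63) that cannot be a
  coefficient of either equation simultaneously with the outcome rows; it
  is deliberately left out of the generative model rather than silently
  reassigned.
* **Predictor moments.** Published bootstrap means and 95% intervals for
  the key variables are converted to population moments by
  `SE = (hi − lo)/(2·1.96)` and `SD = SE·sqrt(50)`. The affective shift
  has no published row; under the net definition
  (`delta_positive − delta_negative`) its mean is the difference of the
  outcome means (5.58 PANAS points) and its SD combines the two outcome
  SDs in quadrature (10.93), treating the subscale changes as
  independent.
* **Noise.** The error distribution is never stated in the source
  analysis; independent Gaussian noise is the standard OLS reading and is
  what the generator uses. Its default scale, 4.0 PANAS points per
  outcome, is a tuning default of this package (not a published value),
  chosen once so that cross-validated self-report-only models on
  shift-driven synthetic cohorts land in the ~0.6 out-of-fold R² regime
  reported for self-report-dominant prediction.
* **PANAS back-fill.** Pre-session subscale scores are drawn around
  PA 28 (SD 6) and NA 22 (SD 6) — typical non-clinical student values —
  and post scores are `pre + delta`. In `shift_mode = "latent"` (default)
  the shift is drawn directly; `"derived"` draws provisional post scores
  first and computes the shift from genuine score arithmetic, reproducing
  the instrument circularity of a shift constructed from the same scale
  as the outcomes. Item-level back-fill distributes each score across ten
  Likert items by round-robin increments from all-ones.

One caveat the package surfaces rather than hides: with a positive shift
quadratic of 79.43 and shift SD ≈ 10.9, the generative equations produce
outcome magnitudes far beyond the ±40-point range a real PANAS difference
can take. The generator therefore clips scores only in item-emitting mode
(where integer 10–50 scores are structurally required, with clipping
counted), and otherwise preserves the generative identity exactly — the
reference configuration is a coefficient-recovery testbed, not a
simulator of realistic PANAS marginals.

### What recovery can and cannot show

The identifiability of each coefficient is set by its term's contribution
relative to the noise. The shift-side terms contribute tens to thousands
of PANAS points and are recovered to well under 1% at n = 100,000. The
EEG-scale terms are different: a theta coefficient of 2.68e-11 acting on
a predictor with SD 1.37e-10 contributes ~4e-21 PANAS points, while its
least-squares standard error at n = 100,000 and noise 4 is ~9e-8 — orders
of magnitude larger than the coefficient itself. No solver and no
feasible sample size recovers such terms; even with zero noise their
contribution sits below double-precision resolution of the outcome
values. The acceptance suite therefore checks *exact* recovery (to 1e-6
relative, with degenerate bootstrap intervals) on a configuration that
keeps the raw 1e-11/1e-12 predictor scales but uses coefficients whose
terms contribute O(1) — that is the genuine numerical-conditioning
contract — and documents the EEG-scale limit as a failing check rather
than weakening it.

## EEG features

The spectral pipeline is: fourth-order Butterworth band-pass (1–50 Hz),
applied forward-backward per channel (zero phase; the effective order
doubles); 2-s non-overlapping epochs with the trailing remainder dropped;
per-channel mean subtraction per epoch (the minimal baseline correction
available in continuous sessions without pre-stimulus intervals); Welch
PSD with Hann-windowed 1-s segments at 50% overlap (variance reduction
while keeping 0.5–1 Hz-scale resolution); trapezoidal band integration
with interpolated band edges, which makes adjacent bands exactly
additive. Band edges follow the canonical delta/theta/alpha/beta/gamma
table with gamma capped at 50 Hz, matching the filter ceiling and the
30–50 Hz reading of the gamma predictor.

Change scores are raw post-minus-pre differences of epoch-averaged,
channel-set-averaged absolute band power — never standardized, because
the downstream regression is defined on the raw scale. Whether powers
should be absolute or relative, and how epochs should aggregate, is not
specified by the source analysis; absolute power with arithmetic epoch
means is assumed, isolated behind `recording_band_power()` so the
assumption lives in one place. The default aggregation sets are
frontal-midline `{Fz, FCz, Cz}` for theta and frontal-parietal
`{F3, F4, Fz, P3, P4, Pz}` for gamma; the source names regions rather
than channels, so both sets are arguments, not constants.

The synthetic EEG generator produces 1/f-weighted background noise plus
band-limited theta and gamma components shared between the pre and post
recordings, with the post components scaled by the square root of the
configured multiplier so band power scales by the multiplier itself.
Sharing components makes the multiplier the *only* pre/post difference —
ideal for sign and monotonicity tests — at the cost of realism: real
recordings differ in background activity, contain artifacts (blinks,
EMG), and have inter-channel covariance, none of which is modelled.
Passing the feature-extraction tests on this generator demonstrates
correct spectral arithmetic, not robustness to artifacts.

## Nonparametric battery and bootstrap

Shapiro–Wilk acts as the routing gate (flag false at p < 0.05), after
which the battery is deliberately standard: Mann–Whitney U (statistic
`min(Ux, Uy)`, midrank ties; exact p when `nx·ny ≤ 400` and tie-free,
else normal approximation with tie and continuity corrections),
Kruskal–Wallis with tie correction, Spearman rho from midranks with the
t approximation, and Cliff's delta. Cliff's delta uses the rank identity
`delta = (2Ux − nx·ny)/(nx·ny)`, which equals the O(n²) definition
exactly (ties contribute half a win to each side and cancel); the test
suite checks that equality on hundreds of random tied instances, and the
exact Mann–Whitney path against full enumeration of group assignments.

The bootstrap engine is the percentile method over participant-level
case resamples, 1,000 resamples by default. Percentile rather than BCa
is the minimal defensible reading of "bootstrapped confidence
intervals"; it needs no jackknife machinery and reproduces exactly under
a seed. Its finite-sample coverage for a Gaussian mean at n = 30 is
known to undershoot nominal slightly — the acceptance suite pins the
empirical rate to [0.92, 0.97] at the 95% level rather than pretending
to exact coverage. No multiple-testing correction is applied anywhere,
mirroring the source analysis; the battery reports the number of tests
it ran so users can correct downstream if they wish.

## Regression, mediation, model comparison

The design matrix keeps the fixed column order (intercept, theta, gamma,
shift, theta-by-shift, gamma², shift²), with derived columns computed
from the raw predictors. The solver standardizes each non-intercept
column internally and maps the coefficients back exactly — the raw
columns span ~24 orders of magnitude, and `kappa` on the raw matrix
would be astronomical, while the standardized matrix is benign (condition
numbers of a few units). Internal standardization does not contradict
the raw-scale contract: stored features and reported coefficients are
always on the original scale, and the tests require original-scale and
solver-scale predictions to agree to 1e-8 relative on reference cohorts.
Ridge and friends are deliberately excluded so coefficients remain
directly interpretable. Rank deficiency is an error naming the offending
columns, never a silent drop.

Coefficient uncertainty comes from refitting on case resamples
end-to-end (design rebuilt from the resampled raw rows). Mediation is
the exploratory product-of-coefficients method (`a` from mediator ~
predictor, `b` from outcome ~ mediator + predictor, indirect `a·b` with
a percentile interval); the known circularity of a mediator built from
the outcome instrument is preserved, not residualized away.

Model comparison evaluates three nested predictor sets — multimodal (all
seven terms), EEG-only (theta, gamma, gamma²) and self-report-only
(shift, shift²); each unimodal model keeps its own nonlinear terms from
the full equation, a choice the source leaves open. "Mean" RMSE/R² is
read as repeated k-fold cross-validation (5 folds × 20 repeats by
default), with one shared fold assignment across models per repeat,
out-of-fold predictions pooled within each repeat, and metrics averaged
over repeats.

## The payoff simulation

The ascent runs in standardized coordinates (per-predictor center/scale
from the generative configuration or a fitted cohort) so that a single
learning-rate scale η = 0.1 is meaningful despite raw scales from 1e-12
to 1e1. The gradient is closed-form:
∂/∂θ = β₁ + β₄·AS, ∂/∂γ = β₂ + 2β₅·γ, ∂/∂AS = β₃ + β₄·θ + 2β₆·AS,
combined across the two outcome surfaces according to the payoff mode
(default `net` = predicted positive change minus predicted negative
change; the source plots a single payoff while fitting two outcomes, so
the composite is a package choice exposed as configuration).

The single largest gap between the published narrative and its own
numbers: the fitted quadratic coefficients are *positive*, so the payoff
surface is convex in shift and unconstrained ascent diverges. The
simulation therefore projects every step onto a box (default ±3
standardized units per coordinate), and "equilibrium" means a fixed
point of the box-projected ascent map satisfying the payoff-change
tolerance (ε = 1e-6) — a constrained stationary point on the boundary,
not an interior optimum. Under the reference coefficients the shift
coordinate pins to the box edge after the first step and the tolerance
criterion fires on the second iteration, comfortably inside the
published 15–20-iteration stabilization bound; for genuinely concave
surfaces the same iteration converges to the analytic vertex, which the
tests verify to 1e-3. The published second update equation contains an
evident typo (the gamma update starts from the theta state); the
per-parameter reading is used. Learning rates, bounds, ε and the start
(the origin) are all package defaults — the source states none of them.

## Numerical choices and degenerate inputs

* CSV round trips use 17 significant digits, so doubles (including
  1e-11-scale powers) survive exactly.
* All random draws flow through per-variable sub-streams derived from
  one seed by fixed offsets; enlarging a cohort extends each stream
  without perturbing earlier participants, and pipeline stages derive
  sub-seeds by fixed stage offsets so inserting a stage never reshuffles
  another.
* Constant predictors make the design rank-deficient and error out;
  zero-variance mediators error; bootstrap statistics failing on more
  than 1% of resamples error rather than silently dropping.
* Shape moments of constant channels are reported as `NA`
  (undefined), not zero.

## Problem sizes used by the shipped checks

Coefficient recovery runs one cohort of n = 100,000 (about half a second
to generate and fit); the bootstrap coverage experiment uses 1,000
replications of 1,000 resamples at n = 30; the cross-validation pattern
check uses 20 replicate cohorts of n = 50 with 5×20-fold CV; EEG
monotonicity averages 10 seeds across four multipliers at 8-s,
27-channel recordings. These sizes were chosen as the smallest that make
the corresponding checks statistically sharp.

## Known limitations

* The generator emulates marginal distributions and the generative
  equation, not realistic EEG artifacts, inter-channel covariance, or
  bounded PANAS outcome ranges under the reference coefficients (see
  above).
* EEG-scale coefficients of the reference configuration are not
  identifiable from its own data — an inherent property of the published
  magnitudes that users should keep in mind before interpreting
  recovered EEG terms on real cohorts of this design.
* The mediation check is exploratory; no causal identification is
  claimed.
* The ascent models a single agent on a static fitted surface; no
  multi-agent or stochastic dynamics.
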