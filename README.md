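# emodyn

Dual-model analysis of emotion regulation from EEG band power and PANAS
self-report, for researchers studying affect change in immersive,
EEG-instrumented interventions (interactive installations, VR
environments, neurofeedback-adjacent settings).

The package implements two linked models of one session's affective
change:

**1. A quadratic/interaction response surface.** For each PANAS outcome
(ΔE = Δ_Positive or Δ_Negative),

    ΔE = β0 + β1·Δθ + β2·Δγ + β3·AS + β4·(Δθ·AS) + β5·Δγ² + β6·AS² + ε

where Δθ and Δγ are raw pre-to-post changes in frontal-midline theta
(4–8 Hz) and frontal-parietal gamma (30–50 Hz) band power, and AS is the
affective shift (net PANAS change, ΔPA − ΔNA). Coefficients are
estimated by OLS on internally standardized columns (the raw columns
span ~24 orders of magnitude) and reported on the original scale, with
participant-level case-resampling percentile bootstrap intervals.

**2. A feedback payoff simulation.** The same polynomial, read as an
emotional payoff, is ascended by box-projected per-parameter gradient
steps `x[t+1] = clip(x[t] + η ⊙ ∇ΔE)` in standardized coordinates until
the payoff change drops below ε — a stylized model of feedback-sensitive
recalibration of cognitive load, arousal and appraisal, with surface and
trajectory exports.

Around these sit the supporting modules: a seeded synthetic-cohort and
synthetic-EEG generator emulating the reference study conditions (n = 50,
PANAS subscales in 10–50, band-power changes at 1e-11/1e-12 magnitudes),
a spectral feature pipeline (Butterworth 1–50 Hz, 2-s epochs, Welch PSD,
band integration), PANAS scoring, a nonparametric battery
(Shapiro–Wilk gate, Mann–Whitney U, Kruskal–Wallis, Spearman, Cliff's
delta), and an end-to-end pipeline runner.

## Worked example

Generate a reference-condition cohort, fit the negative-affect surface,
bootstrap its coefficients, and run the payoff ascent:

```r
library(emodyn)

cohort <- generate_cohort(default_generative_config(seed = 7L))
fit <- fit_model(build_design_matrix(cohort), cohort$delta_negative,
                 "delta_negative")
fit
#> Response-surface fit for delta_negative (n = 50, R^2 = 0.9944, residual sd = 3.85)
#>       intercept    theta_change    gamma_change affective_shift   theta_x_shift
#>    -3.24963e-02    -4.74972e+09    -8.00001e+10    -4.00559e+00    -2.08708e+08
#>        gamma_sq        shift_sq
#>     1.08616e+22    -1.68318e-03

ci <- bootstrap_coefficients(cohort, "delta_negative",
                             n_resamples = 1000, seed = 7)
ci[c(1, 4), ]
#>              term estimate ci_low ci_high
#> 1       intercept  -0.0325 -1.701   1.526
#> 4 affective_shift  -4.0056 -4.166  -3.828

ascend(reference_payoff_model())
#> Payoff ascent: 2 iterations, converged (tolerance), final payoff 117109
```

Reading the output: at n = 50 the affective-shift coefficient is
recovered close to its generative value of −3.96 with a tight bootstrap
interval excluding zero — each point of net positive reappraisal
predicts about a 4-point drop in negative affect. The EEG-scale
coefficients (±1e9 and beyond) are noise: their true contributions sit
at ~1e-21 PANAS points and are not identifiable at these magnitudes (see
the methods vignette). The ascent pins the shift coordinate to the box
boundary after one step — the fitted shift-squared curvature is positive,
so the "equilibrium" is a constrained boundary fixed point, reached well
inside the 15–20-iteration stabilization regime.

The full pipeline (simulate → nonparametric battery → regression →
model comparison → payoff ascent) runs with:

```r
report <- run_pipeline(pipeline_config(seed = 42L, out_dir = "run1"))
```

## Vignette

`vignettes/emodyn-methods.Rmd` documents the models and their
assumptions, the reference generative configuration and how its moments
were derived, every numerical choice (standardization, Welch settings,
bootstrap flavor, box projection), what the synthetic generators do and
do not emulate, and the identifiability limits a user should know about
before interpreting EEG-scale coefficients.
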