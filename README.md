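# tempobias

An R package for analyzing **pitch-induced biases in perceived tempo** from
relative tempo judgment experiments — the paradigm in which a listener
hears a metronomic standard (550-ms interonset interval, 109.1 BPM)
followed by a repeating tone, and rates the tone's tempo on a 0–100 slider
(0 = "half as fast", 50 = "equal rates", 100 = "twice as fast").

It is written for auditory psychophysicists who need the full pipeline:
stimulus/trial design, participant screening, per-subject response-scale
calibration, the illusory-tempo-shift statistic, polynomial curve
characterization over pitch, and the group-level multivariate tests — plus
a synthetic rater generator so every stage is testable end to end without
any behavioral data download.

## The model

Tempo is treated as perceived on a log-linear scale. The slider's labels
define a ground-truth mapping

r_true(t) = 50 + 50·log₂(t / t_ref),

and each participant gets a personal calibration line
r̂ᵢ = β₀ + β₁·log₂(tᵢ/t_ref) fit to their own trials (OLS, with trials of
Cook's distance > 4/n flagged on the initial fit and the line refit once
without them). The per-trial **illusory tempo shift**

τᵢ = 100% · ρᵢ/β₁ = 100% · log₂(t̂ᵢ/tᵢ),  ρᵢ = rᵢ − r̂ᵢ

is a log2-percent: τ = 100 means the trial was rated as if its tempo had
doubled. Per-subject orthogonal-polynomial coefficients of τ over pitch
code feed Hotelling's T², repeated-measures MANOVA (Wilks' Λ),
repeated-measures ANOVA with Mauchly/Greenhouse–Geisser/Huynh–Feldt
sphericity handling, Holm–Bonferroni post hocs, Cohen's d and partial η².

## Worked example

```r
library(tempobias)
study <- simulate_study(sim_config(n_subjects = 100, seed = 7))
res <- run_pipeline(study$trials, degree = 5)
res$omnibus
#> one-sample Hotelling T2: F(5, 95) = 2.654, p = 0.0273, eta_p^2 = 0.123
res$posthoc[, c("label", "t", "p", "p_holm", "d")]
#>   label      t       p p_holm      d
#> 1    c1  0.829 0.40898 1.0000 0.0829
#> 2    c2 -3.147 0.00218 0.0109 0.3147
#> 3    c3 -0.917 0.36113 1.0000 0.0917
#> 4    c4  1.076 0.28444 1.0000 0.1076
#> 5    c5  0.958 0.34017 1.0000 0.0958
```

The simulated world injects an inverted-U pitch bias (quadratic −2.0 on
the unit-norm basis). The omnibus Hotelling test rejects the null of a
flat curve (p = .027), and the Holm-corrected post hocs attribute it to a
negative quadratic coefficient (c2: t(99) = −3.15, adjusted p = .011) —
i.e., mid-range pitches rated faster than the extremes. Per-pitch mean
shifts for the same run:

```r
inc <- res$shifts[!res$shifts$is_outlier, ]
round(tapply(inc$tau, inc$pitch_code, mean), 2)
#>     2     3     4     5     6     7
#> -0.86 -0.33  0.44  1.27  0.17 -0.69
```

About 4.7% of trials are flagged as influence outliers by the 4/n rule,
comparable to real slider data.

## Command line

```sh
Rscript exec/tempobias simulate --seed 7 --subjects 100 --out out/
Rscript exec/tempobias report --trials out/trials.csv --out out/
Rscript exec/tempobias render-audio --f0 440 --ioi 550 --out out/
```

Verbs: `simulate`, `screen`, `score`, `curves`, `infer`, `report`,
`render-audio`. All artifacts are plain CSV/JSON/WAV; result files embed
the configuration hash and seed.

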