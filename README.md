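# covertrace

Quantitative analysis of the cover test from video-oculography gaze
traces.

Covering one eye interrupts binocular fusion and lets the covered eye
drift to its fusion-free position, exposing the full latent-plus-manifest
horizontal deviation. Clinically this is quantified with the alternate
prism cover test (APCT), which is examiner-dependent and blind to the
covered eye itself. Eye-tracking devices that image each eye behind an
occludable display record the covered eye throughout the test;
`covertrace` turns those recordings into numbers. It is aimed at
orthoptists, strabismus researchers and oculomotor-signal analysts.

## What it computes

For each trial, the signed deviation signal (covered minus fixating eye,
exodeviation negative) is fitted with a four-parameter logistic

    f(t) = L0 + a / (1 + exp(-k (t - t0)))

by bounded Levenberg–Marquardt, and four per-trial statistics are
extracted:

| statistic | definition |
|---|---|
| deviation angle `a` | difference of the two asymptotes (deg, and PD via `100·tan`) |
| peak deviation speed `b` | maximum slope of the fit, `|a|·k/4` (deg/s) |
| stabilization time | time from occlusion onset to 90% of the deviation, `t0 + ln(9)/k` (s) |
| overshoot depth `d'` | excursion of the (median-smoothed) trace beyond the fitted far asymptote (deg) |

plus a rebound-saccade flag for tropic refixation (velocity-threshold
detector) and the raw finite-difference peak speed. Cohort summaries add
overshoot categories (>1°, 0.5–1°, <0.5°), Spearman rank correlations
(angle↔speed, angle↔stabilization time, depth↔speed) with **exact
permutation p-values up to n = 13** (bit-mask dynamic program over the
null distribution of `S`, verified against full `n!` enumeration), and a
paired t-test of APCT versus device-measured deviation on a common
prism-diopter scale.

Because no clinical recordings are distributable, the package ships a
seedable synthetic trace generator (phoric sigmoidal drift with optional
overshoot transient, tropic saccadic refixation with rebound-saccade,
Gaussian noise, blink dropouts) that attaches analytic ground truth to
every trace, making the whole pipeline testable end to end.

## A worked example

```r
library(covertrace)

p <- phoria_params(deviation_deg = -6, rate_per_s = 2, midpoint_s = 1.5,
                   overshoot_amp_deg = 0.8, seed = 42)
trace <- simulate_phoria_trace(p)
fit <- fit_logistic(trace)
trace_metrics(trace, fit = fit)
#> <deviation_metrics> angle -6.44 deg (-11.30 PD), peak speed 3.71 deg/s
#>   stabilization 2.46 s, overshoot 0.66 deg (mid), rebound-saccade: FALSE
```

The simulated subject deviates 6.4° exo (the true −6° plus noise and the
transient's influence), drifts at a 3.7 °/s peak, stabilizes 2.5 s after
occlusion and transiently overshoots its final position by 0.66°
(category 0.5–1°). A full cohort run:

```r
cfg <- run_config("simulate", out_dir = tempfile(), seed = 1,
                  sim_config = cohort_config(n_subjects = 13),
                  spearman_method = "exact_s")
res <- run_pipeline(cfg)
res$summary
#> Cohort summary (13 subjects, 13 exophoria)
#>   deviation angle:     -6.39 +/- 2.69 deg ( -11.22 +/- 4.77 PD )
#>   peak speed:          4.11 +/- 3.17 deg/s
#>   stabilization time:  2.88 +/- 0.71 s
#>   overshoot depth:     0.66 +/- 0.20 deg
#>   overshoot categories: >1: 1, 0.5-1: 8, <0.5: 4
#>   angle vs speed     : rs = -0.929, p = 0.0000 (exact_permutation)
#>   angle vs stab. time: rs = 0.709, p = 0.0086 (exact_permutation)
#>   depth vs speed     : rs = 0.714, p = 0.0079 (exact_permutation)
#>   APCT vs device: mean diff = 5.39 PD, t = 17.675, p = 5.875e-10
```

Larger deviations move faster (negative angle–speed correlation) and
stabilize sooner (positive angle–stabilization correlation), deeper
overshoots accompany faster drifts, and the device reads ~5 PD more
exotropic than the APCT — the sign structure expected when near-target
prism testing partially controls convergence. `run_pipeline()` writes
per-subject trace CSVs, a metrics table, a JSON summary, optional
trajectory figures (both eyes, occlusion bar, fitted curve, dotted
stabilization line) and a manifest; identical configuration and seed
reproduce every output byte. A thin command-line wrapper lives at
`inst/cli/covertrace.R`.

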