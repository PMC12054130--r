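---
title: "Quantifying ocular deviation under occlusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ocular deviation under occlusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covertrace)
```

## The measurement problem

The cover test interrupts binocular fusion by occluding one eye. Freed
from fusion, the covered eye drifts to its *fusion-free position*,
exposing the full (latent plus manifest) horizontal deviation. Clinical
practice quantifies this with the alternate prism cover test (APCT), a
manual procedure that is slow and examiner-dependent, and that cannot see
the covered eye at all — neither how far it ends up nor how long it takes
to get there. Video-oculography (VOG) devices that image each eye behind
its own occludable display can record the covered eye throughout, which
raises the questions this package addresses: how large is the deviation,
how fast does it develop, when has it stabilized, and does it transiently
overshoot its final position?

`covertrace` implements that analysis as a tested pipeline: a trace
model, a per-trial fitting stage, per-trial metrics, and cohort-level
statistics, together with a synthetic trace generator that stands in for
clinical recordings.

## Trace model and sign conventions

A trial is a two-eye horizontal gaze record (`gaze_trace`) on a uniform
grid (default 30 Hz) spanning 10 s before to 10 s after occlusion onset,
with onset at $t = 0$. Both eyes share a rightward-positive angular
coordinate. The *deviation signal* is

$$d(t) = \pm\,(\text{covered}(t) - \text{fixating}(t)),$$

negated when the covered eye is the right one, so that exodeviation
(temporal drift of whichever eye is covered) is always negative and
esodeviation positive. Blink dropouts are explicit missing flags, never
zeros; a zero is a legitimate gaze angle and silently corrupts fits.

## The logistic deviation model

The phoric response is modeled by a four-parameter logistic,

$$f(t) = L_0 + \frac{a}{1 + e^{-k (t - t_0)}},$$

with baseline $L_0$ (the pre-occlusion deviation), asymptote difference
$a$ (the deviation angle, in degrees, exo negative), rate $k$ (1/s) and
midpoint $t_0$ (s). Three of the four per-trial statistics are closed
forms in these parameters:

* **deviation angle** $a$, also reported in prism diopters via
  $\mathrm{PD} = 100\tan(a)$;
* **peak deviation speed** $b = |a|\,k/4$, the logistic's maximum
  absolute slope, attained at $t_0$;
* **stabilization time** $t_{90} = t_0 + \ln(9)/k$, the time from onset
  at which the curve has covered 90% of its asymptotic deviation. If the
  90% level is already passed at onset the function returns 0 with a
  warning.

The fourth, **overshoot depth**, cannot come from the fitted curve: a
symmetric logistic is monotone and never exceeds its asymptote. It is
measured on the data — the most extreme post-onset value of the
deviation signal after a 3-sample running median, relative to the fitted
far asymptote:

$$d' = \max\bigl(0,\ |d_{\max} - L_0| - |a|\bigr),$$

and classified clinically as $>1^\circ$, $0.5$–$1^\circ$, or
$<0.5^\circ$.

### Fitting

`fit_logistic()` minimizes least squares by Levenberg–Marquardt
(`minpack.lm::nls.lm`) with an analytic Jacobian. Starting values come
from the data: $L_0$ from the pre-onset median, $a$ from the last-2-s
median minus $L_0$, $t_0$ from the half-crossing time, and $k$ from the
25–75% crossing interval (a logistic rises from 25% to 75% in
$2\ln 3/k$). The rate is box-bounded to $(0.01, 200]$ s$^{-1}$ and the
midpoint to the fit window: a response centered beyond the record would
be extrapolation, not measurement. A fit is flagged non-converged when
the optimizer fails, exhausts its iterations, or lands on a bound;
non-converged fits refuse to yield metrics, and the pipeline excludes
such subjects with a logged reason rather than guessing.

Missing samples are excluded from the loss, never interpolated —
interpolating across a blink at saccadic speeds would invent data.

Two further numerical choices matter:

* **Overshoot-aware refitting.** An overshoot transient in the data
  drags a plain least-squares asymptote beyond the true final position,
  which simultaneously biases $a$ and hides the overshoot being
  measured (in simulation, a $1.2^\circ$ transient lost $0.1$–$0.7^\circ$
  of its depth this way). After an initial pass, post-onset samples
  lying beyond the fitted far asymptote by more than twice the residual
  RMS are excluded and the model refitted, iterating until stable. On
  monotone data no sample is ever flagged, so noise-free recovery is
  untouched (the suite verifies recovery to $10^{-6}$).
* **Small-deviation flag.** When the fitted deviation — the smaller of
  $|a|$ and the realized in-window change of the curve — is below twice
  the residual RMS, the fit carries a small-deviation warning. On
  deviation-free data the $(a, k, t_0)$ likelihood is flat in some
  directions and the asymptote parameter alone can be arbitrarily
  large; the realized in-window change is the honest effect size.

### Tropic trials and rebound-saccades

In a manifest deviation (tropia) the inter-eye angle barely changes at
occlusion; what changes is which eye fixates. The newly fixating eye
executes a refixation saccade, frequently overshooting and correcting
back — Mehdorn's *rebound-saccade*. `detect_rebound_saccade()` flags a
trial when the uncovered eye's central-difference velocity exceeds a
saccadic threshold (default 30 °/s, configurable; phoric drifts are an
order of magnitude slower) first in one direction and then, within 1 s,
in the opposite direction. Because the fitted logistic underestimates
saccadic speeds, the raw maximum finite-difference deviation speed is
reported alongside the model-based peak speed.

## The synthetic cohort

No recordings are distributed with the device study this design targets,
so the generator is a first-class module whose defaults encode the study
conditions: 30 Hz sampling, ±10 s windows, 13 exophoric subjects,
deviation magnitudes 2–10°, Gaussian measurement noise of 0.2° and 1%
blink dropouts (device noise and blink rates are unpublished; these are
stipulated as realistic for pupil-tracking VOG), and an APCT that reads
about 4.5 PD less exotropic than the device (near-target convergence
during prisms biases the APCT toward less exo).

Phoric traces are the forward model itself — baseline, logistic drift,
optional overshoot pulse, noise — so fitting them is a genuine
forward–inverse experiment with analytic ground truth attached to every
trace. The overshoot pulse is
$g(t) = \mathrm{sign}(a)\,A\,\frac{t - t_0}{\tau} e^{1 - (t - t_0)/\tau}$
for $t > t_0$: the minimal smooth single-extremum shape with depth $A$
(peaking at $t_0 + \tau$) and controllable decay. Tropic traces use a
raised-cosine saccade velocity profile (smooth, bounded, resolvable at
30 Hz; peak speed $2A/D$ for amplitude $A$ and duration $D$), a 0.1 s
refixation latency, a 0.15 s intersaccadic interval, and a corrective
saccade at the same peak speed; the covered eye moves conjugately,
scaled to its own endpoint.

Cohort-level couplings are the one place the generator goes beyond the
forward model, because the study's headline findings are correlations:

* the rate grows with the deviation magnitude,
  $k = 2\,(|a|/6)^{c}\,\varepsilon$ with coupling exponent $c$ (default
  1) and lognormal jitter — this yields peak speeds of roughly 1–10 °/s
  and stabilization times around 3 s over the 2–10° range, and makes
  larger (more negative) angles faster and quicker to stabilize;
* the overshoot amplitude is drawn from a two-part distribution
  (probability `overshoot_frac` of exceeding 0.5°) rank-coupled to peak
  speed through a Gaussian copula ($\rho = 0.8$), so faster deviations
  overshoot deeper;
* the APCT value is the per-subject degree→PD conversion plus the
  systematic offset plus 2 PD of measurement noise (APCT prisms step in
  ~2 PD increments).

All randomness flows from one explicit seed per call; the caller's RNG
state is saved and restored, and per-subject seeds are derived from the
master seed, so cohorts are bit-reproducible.

**What passing tests do and do not show.** The generator emulates the
statistical structure the analysis assumes — sigmoidal drift, saccadic
refixation, stationary Gaussian noise, independent dropouts. Real
recordings add drift of head position, pursuit intrusions, asymmetric
redeviation, calibration error and non-stationary noise; parameter
recovery here demonstrates correctness of the estimator, not device
accuracy on patients.

## Statistics

Angles convert to prism diopters by the exact orthoptic definition
$\mathrm{PD} = 100\tan\theta$ (no small-angle shortcut), inverted by
$\theta = \arctan(\mathrm{PD}/100)$. Note that the mean of per-subject
conversions is not the conversion of the mean angle; the package always
converts per subject and then averages, which is also the more defensible
reading of published group values in PD.

Rank correlations use Spearman's $r_s$ with a two-sided p-value. For the
sample sizes this field works at, the $t$ approximation is rough, so the
package computes the exact permutation distribution: the null
distribution of $S = \sum_i (R_i - Q_i)^2$ follows from that of
$T = \sum_i i\,\pi(i)$ (they differ by an affine map), and $T$'s
distribution over all $n!$ permutations is counted exactly by a bit-mask
dynamic program over value subsets — $O(2^n n)$ vector operations
instead of $n!$ enumeration, exact up to $n = 13$ where counts still fit
in a double. Untied samples of $n \le 9$ get the exact p-value by
default; `method = "exact_s"` opts in up to $n = 13$; ties or larger $n$
fall back to $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n - 2$ df. The exact
route is verified in the test suite against a literal $n!$ enumeration
oracle for $n \le 7$, and its null rejection rate at $\alpha = 0.05$,
$n = 13$ sits at about 5% over 10,000 draws (recomputed by both the test
suite and the acceptance script). The APCT-versus-device comparison is
a two-sided paired t-test on the common PD scale, refusing zero-variance
differences. No multiplicity correction is applied across the three
correlations, matching standard practice for a three-outcome descriptive
battery.

`summarize_cohort()` computes group means ± SD, overshoot category
counts and the three correlations (angle↔speed, angle↔stabilization
time, depth↔speed) over the phoric subgroup only; tropic cases are
individually reported and enter only the APCT comparison.

## Known limitations and problem sizes

* The logistic is symmetric; genuinely asymmetric (e.g. Richards-type)
  drifts will show midpoint bias. No asymmetric sigmoid is offered.
* The overshoot depth estimator has a noise floor: taking an extremum
  over ~300 smoothed post-onset samples of 0.2° noise yields a median
  apparent depth of about 0.5° even without a transient. Depths below
  the floor are not individually interpretable; categories are applied
  to the floored value.
* On deviation-free traces the asymptote parameter is unidentified;
  rely on the `small_deviation` flag and the convergence flag rather
  than the raw $a$.
* Vertical and torsional deviation, pupil dynamics and blink-artifact
  reconstruction are out of scope.

The test suite runs its Monte-Carlo checks at 100–200 replicates of
20-s, 30-Hz traces and 100 replicates of 13-subject cohorts; the null
calibration uses 10,000 draws. These sizes give the quoted bounds
comfortable margins while keeping the default check quick.

## A worked example

```{r example, eval = FALSE}
library(covertrace)

# one phoric trial with known truth
p <- phoria_params(deviation_deg = -6, rate_per_s = 2, midpoint_s = 1.5,
                   overshoot_amp_deg = 0.8, seed = 42)
trace <- simulate_phoria_trace(p)
fit <- fit_logistic(trace)
trace_metrics(trace, fit = fit)

# a full cohort run
cfg <- run_config("simulate", out_dir = tempfile(), seed = 1,
                  sim_config = cohort_config(n_subjects = 13),
                  spearman_method = "exact_s")
res <- run_pipeline(cfg)
res$summary
```
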