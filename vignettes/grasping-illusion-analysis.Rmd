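---
title: "Do size illusions move the maximum grip aperture? Models, statistics and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Do size illusions move the maximum grip aperture? Models, statistics and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspillusion)
```

## The scientific question

When we reach out and grasp an object between thumb and index finger, the hand
opens to a maximum grip aperture (MGA) before closing onto the object. A
long-standing question in sensorimotor research is whether that opening is
controlled by the object's *perceived size* or by the *perceived positions* of
the intended contact points on its surface. Visual size illusions are the
classical probe: if a context drawing makes a bar look ~10% longer without
changing its physical size, does the hand open ~10% wider?

Three hypotheses make distinct predictions:

* **size-based control** — the grip is scaled to the judged size, so the
  illusion transfers fully to MGA at every object size;
* **position-based control** — each digit is steered to a contact location;
  an illusion that distorts only perceived *size* (not edge positions) leaves
  MGA untouched;
* **optimal switching** — the brain uses whichever cue is more *precise*.
  Reproducing a size obeys Weber's law (SD proportional to size), while
  localising an edge has size-independent noise, so the two precision curves
  cross: size information wins for small objects, position information for
  large ones. The illusion should then affect MGA only below the crossover.

This package implements the full computational chain needed to test these
predictions on matching + grasping experiments: a synthetic-data generator, the
trajectory-level kinematics, the illusion-effect statistic, the precision
model, and the within-subject inferential layer. It is exercised end-to-end on
simulated cohorts, so every stage is testable without any data download.

## The precision model

`precision_model()` encodes the two noise channels in quadrature,

$$SD_\text{size}(s) = \sqrt{a^2 + (w\,s)^2}, \qquad
  SD_\text{pos} = \sqrt{a^2 + c^2},$$

with Weber fraction $w$ (default 0.06), positional noise $c$ (mm) and an
optional common baseline $a$ (default 0). The channels cross at $s^* = c/w$;
with the defaults $c = 1.8$ mm and $w = 0.06$ this is 3 cm, the boundary used
throughout to split objects into *small* (1.5, 2.5 cm) and *large* (4, 5 cm)
categories. The published precision curves this reproduces were described
without formulas; the quadrature form is the minimal model with the right
limiting behaviour and crossing point, and $a$ is exposed because a motor
noise floor common to both channels cannot be excluded — it fattens both
curves without moving the crossover. Sizes are in cm at every interface and
SDs in mm, matching how such curves are conventionally plotted.

`predicted_effect()` turns the model into the three illusion-transfer curves:
a constant at the perceptual effect (size), a constant zero (position), and a
step that drops from the perceptual effect to zero exactly at $s^*$ (optimal).

## The synthetic-data generator

`generator_config()` + `simulate_cohort()` emulate the reference study
conditions: 19 participants, 4 bar lengths $\{1.5, 2.5, 4, 5\}$ cm in two
illusion-inducing contexts, 10 repetitions (80 trials), each trial a perceptual
match followed by a grasp; grasps are 0.6 s reaches sampled at 200 Hz starting
30 cm lateral to the target with a 4 mm starting aperture.

Model equations, per participant $i$ with stable susceptibilities drawn once
($p_i \sim N(p, \sigma_p)$, defaults $p = 0.10$, $\sigma_p = 0.03$):

* perceived size: $s(1 \pm p_i/2)$ — the illusion is split symmetrically, so
  the between-configuration difference is exactly $p_i s$ (only the difference
  is empirically constrained; the split is a convention);
* matching: $b_m + g\,s(1 \pm p_i/2)(1+\varepsilon)$ with $g = 1.10$,
  $b_m = -0.43$ cm and multiplicative noise $\varepsilon \sim N(0, w)$,
  $w = 0.08$. Gain and intercept are derived from the published cell means
  (1.2 cm matched at 1.5 cm; 5.0 cm at 5.0 cm), which are inconsistent with a
  pure gain through the origin;
* MGA, position rule: $M + k\,s(1 \pm q_i/2) + \eta$, $k = 0.92$,
  $M = 3.43$ cm (from mean MGAs of 4.8 cm at 1.5 cm and 8 cm at 5 cm), with
  *additive* noise $\eta \sim N(0,\ 0.32 + 0.03\,s\ \text{cm})$ — about
  4.2 mm on average with a moderate increase over size, rather than pure Weber
  scaling. The positional illusion $q$ is 0 by default (a modified diagonal
  figure alters perceived size only); setting $q > 0$ emulates an
  Ebbinghaus-like figure;
* MGA, size rule: $M + k\,s(1 \pm p_i^{g}/2)(1+\varepsilon)$ with the grasp
  susceptibility $p_i^g$ drawn *independently* of the matching one. This
  deliberate independence reproduces a null cross-task correlation of illusion
  effects; its corollary is that within this generator cross-task correlations
  are null under every control hypothesis, and the discriminating
  across-participant signature is the small-vs-large correlation *within* a
  task;
* MGA, optimal rule: size rule below the 3 cm switch, position rule above.

Matching noise multiplies the gain term only, not the intercept: the intercept
represents a constant response offset, and a Weber process acts on the
magnitude being reproduced.

Trajectories (`synth_trajectory()`) are a modelling convenience — the events,
not the trajectory form, are empirically specified. Transport follows a
minimum-jerk profile; the aperture opens along a half-cosine to its peak at
65% of movement time (snapped to a sample so the peak is exactly
representable) and closes to the bar length; thumb height is single-peaked and
returns essentially to table level, so the near-target detector fires at
~85% of the movement, safely after the aperture peak.

What the generator does *not* emulate: online corrections and feedback,
trial-to-trial carry-over, hand anatomy limits on aperture, marker noise and
dropouts, skewed MGA distributions, or grasp errors needing repetition.
Passing tests therefore demonstrate that the analysis chain is correct and
calibrated, not that real data are this clean; the optional 10 Hz low-pass in
the kinematics exists for real recordings and is off for generator data.

## Kinematics

Grip aperture is the 3-D marker distance per sample. MGA is the maximum of
that series between *movement onset* and the *near-target moment* — the first
sample after the thumb's height peak at which the thumb has descended to less
than 1 cm above its initial height — which guarantees the digits have not yet
contacted the object. Movement onset is not empirically pinned down; the
package uses a thumb-speed threshold of 2 cm/s sustained for 5 samples
(25 ms at 200 Hz), a standard kinematic criterion, exposed as an argument.
Velocities are central differences (one-sided at the ends). "Peak height" is
the global maximum over the trial. Visual screening of trials is replaced by
two hard error conditions (no onset; thumb never descending) plus a per-trial
QC flag that propagates into the analysis report. Indices are 1-based (R
convention) and windows inclusive. `aperture_at_distance()` provides the
20 cm mid-movement checkpoint used to rule out late visual-feedback
corrections.

## The illusion-effect statistic

Per participant, task and stimulus, the *median* response is the central
tendency (robust to outliers and to the skew of MGA distributions; means are
available via `use_means = TRUE` as a robustness variant). The raw effect at
each size is the difference between the expanding- and contracting-context
medians. Raw effects are divided by the participant's OLS slope of the eight
medians on actual size, converting them to object-size units, and expressed as
a percentage.

The percentage base was a genuinely open design point. Dividing the
slope-scaled effect by the mean *response* looks natural but double-corrects:
MGA carries a ~3.4 cm safety-margin intercept, so a true 10% size distortion
would read as only 3–6% of the mean MGA, and the three hypothesis curves would
no longer be comparable across tasks. The package therefore defaults to
`percent_base = "size"`: the slope-scaled effect relative to the *actual
object size*, which recovers the true fractional distortion exactly for both
tasks regardless of intercepts (on noise-free data it returns exactly 10% at
every size for a 10% illusion, consistent with a matching gain of 1.10). The
response-relative form (`"response"`) and the fully unscaled form (`"raw"`)
are provided, as is per-category slope scaling (`per_size_scaling = TRUE`).
Percentages are averaged over the two sizes within each category, per
participant and task; a category average requires both sizes and is otherwise
missing (missingness propagates, it is never imputed as zero). Groups with a
non-positive response slope are excluded with a warning rather than producing
sign-flipped percentages.

## Inference

`rm_anova()` computes fully within-subject ANOVAs (one or two factors) from
the classical sums-of-squares decomposition, each effect tested against its
participant-by-effect interaction. It is implemented directly — not delegated
— so that an independent brute-force oracle and `stats::aov` can both
cross-check it in the tests. Designs must be complete and balanced; missing
cells raise an error naming the participant; zero error variance with a
non-zero effect raises an error (F undefined), while an all-constant table
returns F = 0. No sphericity correction is applied (the factors of interest
here have 2 levels); for 4-level factors the Greenhouse–Geisser epsilon is
reported alongside the uncorrected test. The 2 (size category) × 2 (task)
ANOVA on percent effects is the primary inference; 4 (size) × 2
(configuration) ANOVAs on the per-cell SDs form the variability analysis.

`weber_fit()` is the through-origin least-squares slope of per-cell SDs on
cell means, $\sum m\,sd / \sum m^2$ — a fraction is proportionality, so the
origin constraint is the model; an affine option explores a noise floor.
`pearson_r2()` reports squared Pearson correlations with two-sided p values.
`power_one_sample_t()` computes exact noncentral-t power; for the design
values (1.5 mm effect, 1.8 mm SD, n = 19) it gives 0.93 two-sided and 0.97
one-sided — both sidednesses are always reported because published power
claims for this design are ambiguous about sidedness.

Confidence intervals across participants are mean ± $t_{0.975, n-1}$ · SEM.

## Numerical choices and degenerate inputs

* Trajectory validation: strictly increasing timestamps, uniform spacing to
  1%, ≥ 10 samples; event detectors raise informative errors on degenerate
  trials instead of guessing.
* MGA tie-break: earliest sample of the window maximum.
* The aperture peak is snapped onto a sample, so on noise-free trajectories
  the detector recovers the embedded MGA to floating-point accuracy; the test
  tolerance is nevertheless stated as one sample of aperture-profile change,
  the honest resolution bound for off-sample peaks.
* ANOVA degeneracy thresholds are absolute at 1e-12 on sums of squares.
* All randomness flows from the single seed in `generator_config`; identical
  seeds give bit-identical cohorts.

## Problem sizes used by the test suite

The suite simulates at the study scale (19 × 80 trials) where calibration is
asserted, averaging 20 replicate cohorts for recovery checks and 50 cohorts
per hypothesis for the discrimination checks; trajectory-level checks use
1000 synthetic grasps; Monte-Carlo noise-model checks use $10^4$–$2\cdot10^4$
draws with 3-SEM bounds. One statistical invariant deserves a note: with
position-based control the category × task interaction is a *true* null, so
its non-rejection count over 100 cohorts is Binomial(100, 0.95); the test
asserts the 0.999 lower binomial bound (≥ 88/100) rather than the nominal 95,
which would fail by chance almost half the time.

## Worked example

```{r, eval = FALSE}
cfg <- generator_config(seed = 1)          # position-based control, defaults
cohort <- simulate_cohort(cfg)
fit <- illusion_analysis(cohort)
summary(fit)
coef(fit)

# the competing predictions
m <- precision_model()
predict(m, size_cm = c(1.5, 2.5, 4, 5), what = "effect")
```

## Known limitations

* The generator's trajectory shape is stylised; kinematic defaults (onset
  threshold, filter cutoff) matter more for real recordings than for it.
* `rm_anova()` covers fully within-subject designs with up to two factors
  only — exactly the designs this analysis needs.
* The correlation analysis inherits the generator's independence assumption
  between task susceptibilities; it cannot, by construction, show cross-task
  correlations.
* Reading foreign per-trial deposits is supported through a column mapping,
  but no downloader is included; analyses of real data require a local copy.
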