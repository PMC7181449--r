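# graspillusion

Do visual size illusions change how wide the hand opens when grasping?

When people reach to grasp a bar between thumb and index finger, the hand
opens to a **maximum grip aperture (MGA)** that scales with object size. If a
context drawing makes the bar *look* ~10% longer without changing its physical
size or the perceived positions of its ends, three hypotheses about grip
control make three different predictions for the MGA:

* **size-based control** — the illusion transfers fully at every size;
* **position-based control** — no effect at any size (the digits are steered
  to contact *positions*, which the illusion leaves untouched);
* **optimal switching** — effects only for objects smaller than the ~3 cm
  crossover where size information becomes more precise than position
  information. The crossover comes from a Weber-law precision model:
  SD_size(s) = √(a² + (w·s)²) grows with size, SD_pos = √(a² + c²) does not,
  and they cross at s\* = c/w (3 cm for w = 0.06, c = 1.8 mm).

`graspillusion` implements the full analysis chain for matching + grasping
experiments of this kind, together with a calibrated synthetic-data generator
so the chain can be validated end to end without any data download:

* **simulation** — `generator_config()`, `simulate_cohort()`,
  `synth_trajectory()`: cohorts of 19 participants × 80 trials (4 bar lengths
  × 2 illusion contexts × 10 repetitions), with matched lengths, MGAs drawn
  under a selectable control hypothesis, and optional 200 Hz thumb/finger
  marker trajectories;
* **kinematics** — `grip_aperture()`, `detect_onset()`,
  `detect_near_target()`, `extract_mga()`, `aperture_at_distance()`: MGA is
  the aperture maximum between movement onset (2 cm/s thumb-speed criterion)
  and the moment the thumb, past its height peak, descends to within 1 cm of
  its initial height;
* **scoring** — `median_table()`, `response_slope()`, `percent_effects()`,
  `category_effects()`, `variability_table()`: per-cell medians, raw
  expanding−contracting differences, slope scaling to object-size units,
  percentage normalisation, small/large category averages, and per-cell
  SD/mean tables;
* **precision model** — `precision_model()`, `sd_size()`, `sd_position()`,
  `optimal_sd()`, `predicted_effect()`;
* **inference** — `rm_anova()` (within-subject ANOVA from sums of squares),
  `pearson_r2()`, `weber_fit()` (through-origin SD-on-mean slope),
  `power_one_sample_t()` (exact noncentral t);
* **one fitting function** — `illusion_analysis()` runs everything and
  returns a classed object with `print`, `summary`, `coef` and `plot`
  methods. `read_trials()` / `write_trials()` handle the on-disk CSV layout
  (foreign column names and mm units supported via a mapping);
  `inst/scripts/graspillusion` is a thin command-line wrapper
  (simulate / kinematics / score / analyze).

## Worked example

Simulate a cohort under position-based control (the generator default:
a 10% perceptual illusion that grasping should ignore) and fit the analysis:

```r
library(graspillusion)

cohort <- simulate_cohort(generator_config(seed = 1))
fit <- illusion_analysis(cohort)
fit
#> Illusion-effect analysis of a matching + grasping cohort
#>   19 participants; tasks: matching, grasping; percent base: 'size'; cell medians
#>   mean percent illusion effects (across participants):
#>     grasping_small     2.60 %
#>     matching_small     9.79 %
#>     grasping_large     0.69 %
#>     matching_large    10.81 %
```

Matching shows the ~10% illusion at both size categories; grasping does not.
`summary(fit)` adds the inferential layer (excerpt):

```r
summary(fit)
#> === 2 (size category) x 2 (task) ANOVA on percent effects ===
#>         effect df_num df_den ss_effect ss_error       F        p
#>       category      1     18     3.812    523.3  0.1311 7.21e-01
#>           task      1     18  1424.000    665.5 38.5100 7.42e-06
#>  category:task      1     18    40.750    405.9  1.8070 1.96e-01
#>
#> === Response-on-size slopes ===
#>   grasping : 0.913 +/- 0.010 (mean +/- SEM)
#>   matching : 1.109 +/- 0.006 (mean +/- SEM)
#>
#> === Variability ===
#>   matching : Weber fraction 0.0882; SD-on-size slope 0.0883
#>   grasping : Weber fraction 0.0653; SD-on-size slope 0.0328
#>   mean within-participant MGA SD: 4.26 mm
```

Read: a strong task main effect with no size effect and no interaction is the
signature of position-based control — the illusion moves perception, not the
grip. Matching variability follows Weber's law at ~8–9% of the matched size;
grip-aperture variability is ~4.3 mm with only a mild size trend. The
competing predictions themselves come from the precision model:

```r
predict(precision_model(), size_cm = c(1.5, 2.5, 4, 5), what = "effect")
#>   size_cm size position optimal
#> 1     1.5   10        0      10
#> 2     2.5   10        0      10
#> 3     4.0   10        0       0
#> 4     5.0   10        0       0
```

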