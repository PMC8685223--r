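# fogait

Motion-phase-wise detection and prediction of Freezing of Gait (FoG)
from a single foot-worn inertial sensor.

Freezing of Gait is an episodic inability to produce effective steps
that affects many people with advanced Parkinson's disease and sharply
raises their risk of falling. On-demand (closed-loop) cueing systems
need to recognise a freezing episode — festination, shuffling, shank
trembling, or akinesia — within about one gait cycle, from hardware no
more obtrusive than a sensor in the shoe. `fogait` implements a complete
pipeline for that problem:

1. **Gait-phase segmentation.** A causal state machine splits a 6-channel
   foot-IMU recording (3D specific force *a(t)*, 3D angular rate *ω(t)*,
   nominally 200 Hz) into *rest*, *unrest* and nested *motion* phases
   (toe-off → initial contact). Orientation comes from a complementary
   quaternion filter (gyro strap-down + gravity-gated inclination
   correction); rest-phase offsets are removed with an *n*<sub>d</sub> = 10
   sample moving average. Motion starts on a pitch maximum
   φ<sub>pitch</sub> > φ<sub>p</sub> or a roll/acceleration peak pair
   within Δ = 0.25 s; it ends on a jerk spike
   *j(t)* > α·max<sub>τ&lt;t</sub> *j(τ)* with both horizontal
   velocities below β times their running maxima (conditions D1 ∧ D2),
   or on a qualified pitch minimum (condition E). A control state Z
   (conditions F/G/H) re-arms the search inside an ongoing unrest phase,
   which is what keeps festinating step sequences segmentable.
2. **Feature extraction.** Ten spatio-temporal features per completed
   motion phase — max acceleration norm, max/min pitch, stride length
   and max gait velocity from strap-down integration with a
   zero-end-velocity drift correction, turning angle and flag, max/mean
   turn rate, and step duration — plus univariate chi-square feature
   ranking (importance = −log₁₀ *p*; > 1.3 ⇔ *p* < 0.05).
3. **Classification.** RBF-kernel SVMs (all features or top-5) and
   AdaBoost over depth-limited decision trees, for detection from the
   current phase (C₀), detection with the two preceding phases
   (C₋₂,₋₁,₀), and one-phase-ahead prediction (C₋₂,₋₁), evaluated with
   leave-one-patient-out cross-validation (sensitivity, specificity,
   accuracy, AUC; paired t-tests; best-foot selection). Both learners
   are implemented in the package (SMO in C++, weighted CART in R).
4. **Freezing-Index baseline.** The classical spectral power ratio of
   the 3–8 Hz freeze band to the locomotor band over a sliding window,
   with single-axis thresholding and a 6-axis majority vote.
5. **Synthetic gait generator.** Closed-form step kinematics with
   ground-truth toe-off/initial-contact times, FoG-subtype episodes and
   two simulated raters, so the whole pipeline is testable without
   clinical recordings.

## Worked example

```r
library(fogait)

sim <- simulate_recording(
  list(list(mode = "normal",      n_steps = 6),
       list(mode = "festination", n_steps = 5),
       list(mode = "akinesia",    duration = 3)),
  seed = 1)

ps <- segment_recording(sim$series, gpd_params())
ps
#> Phase sequence: 15 rest/unrest intervals, 10 motion phases, 3 Z reactivations
```

Six clean strides segment as six motion phases; the festinating burst
stays inside a single unrest interval and is carved into further motion
phases by Z reactivations; akinesia produces none. Each phase yields one
feature row:

```r
head(extract_feature_table(ps)[, c("t_end", "stride_length",
                                   "max_velocity", "max_pitch",
                                   "step_duration")], 3)
#>   t_end stride_length max_velocity max_pitch step_duration
#> 1  2.90         0.595         1.60     0.349         0.705
#> 2  4.33         0.598         1.60     0.347         0.705
#> 3  5.76         0.595         1.60     0.348         0.705
```

(the generator's true stride is 0.60 m, swing 0.7 s, heel-off pitch
20° = 0.349 rad — strap-down recovery is within 1 %). Labeling the
phases with the OR-combination of the two simulated raters and ranking
features marks step duration as the discriminative feature of this
little recording (importance 1.73 > 1.3, i.e. *p* < 0.05):

```r
labels <- label_motion_phases(
  ps$motion, rbind(sim$raters$expert1, sim$raters$expert2), "OR")
rank_features(extract_feature_table(ps)[, feature_names()], labels)[1, ]
#>         feature chi_sq df p_value importance relevant rank
#> 1 step_duration     10  3  0.0186       1.73     TRUE    1
```

On a synthetic 8-subject cohort with a strong FoG effect, the
three-phase SVM detector generalises across held-out subjects:

```r
rows <- simulate_cohort(n_subjects = 8, fog_prevalence = 0.65,
                        effect_size = 2, seed = 7, phases_per_foot = 40)
lopo_cross_validate(rows, classifier_spec("C210", "SVM_10"), seed = 7)
#> LOPO-CV C210 SVM_10: 16 (subject, foot) results
#>       metric      mean          sd
#>  sensitivity 0.9895105 0.024149604
#>  specificity 0.9828216 0.038935762
#>     accuracy 0.9873143 0.018263339
#>          auc 0.9992003 0.002188552
```

## Command line

```sh
Rscript inst/cli/fogait.R simulate --scenario scen.yaml --seed 1 --out sim/
Rscript inst/cli/fogait.R segment  --in sim/recording.csv --out phases.json
Rscript inst/cli/fogait.R extract  --in sim/recording.csv --out features.csv
Rscript inst/cli/fogait.R train    --in features.csv --variant C210 --model SVM_10 --out model.json
Rscript inst/cli/fogait.R evaluate --in features.csv --variant C210 --model SVM_10 --out eval.json
Rscript inst/cli/fogait.R baseline-fi --in sim/recording.csv --window 6 --threshold 1 --out fi.csv
```

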