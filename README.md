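# graspglove

Secure-grasp detection and agency-based feedback training analysis for an
instrumented sensor glove.

## What this is for

Sensor gloves for grasp rehabilitation can detect when the wearer achieves
a *secure grasp* — all force/flex channels settled into the steady-hold
band — and feed that back as a beep and LED. Delivering the cue at
progressively shorter delays after the grasp exploits *intentional
binding* (the perceived compression of time between a voluntary action and
its sensory consequence, an implicit marker of the sense of agency), with
the aim of accelerating motor learning on a grasp-move-place task.

`graspglove` implements that study's computational chain end to end, at
desk scale, for methodologists who want to exercise, test or extend it:

1. **Synthetic data** — seeded generators for 10-channel glove sensor
   trials (40 Hz; hold / tap / rest protocols across precision-pinch,
   tri-pod and whole-hand grips) and for motion-capture object trajectories
   (120 Hz; 15 pre / 30 training / 15 post trials per session, one session
   per feedback mode) with configurable learning effects.
2. **Labeling** — a frame is secure iff every active channel is within
   ±10% of its steady-hold mean; frames pool into a 70/15/15
   train/validation/test dataset per subject.
3. **Classifier** — a 10-input, 10-hidden-unit (tanh) feedforward network
   with logistic output, trained from scratch by Møller's scaled conjugate
   gradient on mean binary cross-entropy with early stopping:

   ŷ = σ( w₂ᵀ tanh(W₁ᵀx + b₁) + b₂ ),  rounded at 0.5

   evaluated against an analytical pinch force-equilibrium baseline
   (thumb and index voltages within 10% of each other and above 10% of the
   sensor range).
4. **Feedback** — NF / IF / IBF schedules; the IBF delay ramps linearly
   from 1 s (trial 1) to 0 s (trial 30), a 34 ms decrement per trial;
   secure-onset detection and beep/LED event records.
5. **Metrics** — completion time (moving time at 100 Hz), pathlength
   (accumulated 3-D displacement while moving) and placement error
   (in-plane distance from the projected final pose to the target).
6. **Statistics** — intra-subject normalization by the pre-training mean,
   de-normalization by the group mean, intra-training rate (OLS slope over
   30 trials, β) and post-training effect (Δ = post − pre), then
   repeated-measures ANOVA, one-way ANOVAs across feedback modes, Tukey HSD
   (optional Bonferroni scaling) and one-/two-sample t-tests.

## Worked example

```r
library(graspglove)

# per-subject training corpus -> labeled dataset -> detector
corpus  <- generate_training_corpus("s1", seed = 42)   # 125 trials
dataset <- assemble_dataset(corpus, seed = 42)
dataset
#> <labeled_dataset> 50125 frames (12626 secure / 37499 insecure)
#> split
#> train   val  test
#> 35088  7519  7518

model <- train_ann(dataset, seed = 42)
model
#> <ann_model> 10-10-1 (tanh / logistic); stopped at iteration 109 (early_stop)

evaluate_ann(model, dataset)
#> <evaluation_report>
#>  split       ce     pe mse_continuous mse_rounded
#>  train 0.008497 0.3648       0.002556    0.003648
#>    val 0.010680 0.4522       0.003196    0.004522
#>   test 0.009313 0.3591       0.002544    0.003591
#> true-positive rates (%), test split:
#>        grip n_secure ann_tp analytical_tp
#>       pinch      647  99.07         75.27
#>      tripod      648  99.69          0.00
#>  whole_hand      625  99.52          0.00
```

The network's cross-entropy, percent error and mean squared errors are
comparable across the three splits (the early stop did its job), rounded
MSE exceeds continuous MSE, and the network beats the analytical
equilibrium rule on precision pinch — which collapses entirely on tri-pod
and whole-hand grips, where the thumb opposes several digits at once and
its force sensor never clears the 10%-of-range floor.

```r
build_schedule("IBF", 30)
#> <feedback_schedule> mode=IBF, 30 trials; delay 1.000 -> 0.000 s (step 34.5 ms)

# a 17-subject synthetic study through the statistics battery
study <- generate_study(17, seed = 2021)               # 3060 trials
stats <- build_report(study$trials)
stats$group_pre_means
#>     time_s     path_m    error_m
#> 1.47082450 0.25136221 0.00558239

subset(stats$outcome_anova, metric == "time_s",
       c(outcome, F, p, mean_NF, mean_IF, mean_IBF))
#>               outcome        F            p     mean_NF     mean_IF    mean_IBF
#>   intra_training_rate 49.98754 1.841887e-12 0.006081131 -0.00369395 -0.00399079
#>  post_training_effect 12.33915 4.743249e-05 0.019030711 -0.06670908 -0.07640800
```

Group pre-training means land at the configured baselines (1.47 s, 25.1 cm,
5.6 mm). Completion time worsens across training without feedback
(β ≈ +0.006 s/trial) and improves under immediate and intentional-binding
feedback (β < 0), with the feedback modes differing significantly — the
effect structure the statistics layer is built to detect.

## Notes

See the methods vignette (`vignettes/grasp-feedback-pipeline.Rmd`) for the
signal and trajectory models, every tunable parameter with its default and
rationale, the numerical choices (quantization of completion time, speed
gates, degenerate-input handling), and what passing tests do and do not say
about real device data.
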