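# famlift

Simulation and analysis of object-family motor memory lifting
experiments.

## The problem

To lift an object smoothly you must predict its weight before your
muscles feel it. When people repeatedly lift a set of visually similar
objects whose size and weight covary (a constant density), how is the
learned size-to-weight mapping stored? Two accounts disagree about what
happens to an **outlier** — a mid-sized object that is heavier (or
lighter) than its companions' density predicts:

* Under a **categorical ("object families") account**, the objects are
  encoded as a family with a shared density estimate ρ̂, and each
  member's weight is predicted as *F = ρ̂ V g*. An outlier whose weight
  discrepancy stays inside the participant's category boundary is kept
  in the family and its true weight is *never* learned, despite
  repeated large errors; an outlier beyond the boundary is expelled and
  learned completely. Learning is all-or-nothing, so across participants
  the end-of-test outlier forces are **bimodal**.
* Under an **associative-map account** (a smooth map with local
  generalization), every outlier is partially learned and the
  distribution across participants stays unimodal.

famlift is aimed at researchers in sensorimotor learning who want to
simulate, analyze, or power such experiments. It provides, as
tibble-in/tibble-out functions:

* `condition()` / `make_objects()` / `generate_schedule()` — the eleven
  task designs (laboratory and web variants) with their constrained
  pseudo-random trial schedules;
* `simulate_release()`, `lab_score()`, `web_score_and_penalty()`,
  `update_tolerance()` — the release-phase spring–mass–damper physics
  and scoring;
* `simulate_cohort()` with two generative agents
  (`family_params()`, `associative_params()`) implementing the competing
  hypotheses;
* `preprocess_behavior()` — scaled-MAD trial exclusion, donor-mean
  imputation, non-learner screening;
* `endphase_correlation()`, `family_predicted_weight()`,
  `outlier_learning_test()`, `single_trial_generalization()`,
  `rt_epoch_anova()`, `switch_cost()`, `group_comparison()` — the
  family-level statistics;
* `fit_gmm()`, `compare_models()`, `bootstrap_component_ci()`,
  `classify_learners()` — one- vs two-component Gaussian-mixture
  bimodality analysis by EM, compared via
  ΔAIC = AIC₁ − AIC₂ with relative likelihood exp(|ΔAIC|/2);
* `power_for_n()` / `power_curve()` — simulation-based power to detect
  bimodality;
* `run_pipeline()` — the end-to-end driver, plus broom-style `tidy()` /
  `glance()` methods and ggplot2 plotting helpers.

See `vignettes/famlift-methods.Rmd` for the models, their assumptions,
and every numerical choice.

## Worked example

Simulate a 37-participant cohort lifting a family with an extreme
(+5.89 N) outlier under the categorical hypothesis, preprocess it, and
ask whether end-of-test outlier learning is bimodal:

```r
library(famlift)

cond <- condition("Linear++")
raw  <- simulate_cohort(cond, model_type = "family",
                        n_participants = 37, seed = 7)
pre  <- preprocess_behavior(raw)
pre
#> <preprocess_result>
#>   retained participants: 37 of 37
#>   imputed trials: 116 (0.98%)

outlier_learning_test(pre$table)
#> # A tibble: 1 × 8
#>   mean_outlier_N mean_family_predicted_N mean_learning_N statistic    df p_value
#>            <dbl>                   <dbl>           <dbl>     <dbl> <dbl>   <dbl>
#> 1           11.5                    9.60            1.88      3.40    36 8.28e-4

bm <- bimodality_analysis(mixture_input(pre$table)$value, seed = 8)
tidy(bm)
#> # A tibble: 2 × 4
#>   component   mean    sd weight
#>       <int>  <dbl> <dbl>  <dbl>
#> 1         1 -0.853 0.261  0.595
#> 2         2  5.90  0.227  0.405
```

Read: on average the cohort shows 1.88 N of outlier learning (one-tailed
p ≈ 8×10⁻⁴), but the average is a fiction — the mixture analysis splits
the cohort into non-learners sitting at zero learning (−0.85 N) and
learners sitting at the full 5.89 N discrepancy, with the two-component
model overwhelmingly favored (ΔAIC = 136.5). Running the same cohort
with `model_type = "map"` instead yields unimodal partial learning —
the discriminating prediction of the two accounts. `autoplot(bm)` draws
the histogram with both fitted mixtures;
`plot_force_timelines(pre$table)` shows the learning curves.

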