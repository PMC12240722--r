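# bayeschoice

Simulation, fitting and analysis tools for a Bayesian sequential-sampling
account of binary value-based choice, written for decision scientists who
want to explore how **attention** and **value confidence** shape preferential
choice through precision-weighted belief updating.

## The model in brief

An agent choosing between two items (rated 0–10) cannot read off their values
directly; it samples them. While an item is on screen it emits noisy value
signals

&nbsp;&nbsp;&nbsp;&nbsp;*x<sub>t</sub>* ~ N(*u*<sup>(i)</sup>, 1/τ<sup>(i)</sup>),&nbsp;&nbsp;&nbsp;τ<sup>(i)</sup> = β<sub>conf</sub> · conf<sub>i</sub>,

so attention controls the *quantity* of evidence and rating confidence
(1–5) its *precision*. Samples are integrated with a Gaussian context prior
fit to the rater's own value ratings; after *N* samples with mean *x̄*,

&nbsp;&nbsp;&nbsp;&nbsp;λ = λ<sub>prior</sub> + *N*τ,&nbsp;&nbsp;&nbsp;μ = μ<sub>prior</sub> + (*N*τ/λ)(*x̄* − μ<sub>prior</sub>).

Sampling stops when no candidate amount of further sampling is expected to
improve the chosen option's value by at least its linear time cost
(a Directed-Cognition style menu over geometric horizons, split between the
items by their average presentation shares); the item with the larger
posterior mean is then chosen. One sample takes 10 ms; the 5 s deadline
caps a trial at 500 samples.

The headline prediction is a *crossover*: extra presentation time (or higher
confidence) pushes estimates away from the prior mean, so the favored item
gains choice share when option values are above the context average and
*loses* share when they are below it. Alternative variants — zero prior,
flat prior, equal-weight updating, biased (over/under-confident) updating —
break this pattern in diagnostic ways, and the analysis layer tests all of
these signatures by regression on simulated choice tables.

## Worked example

```r
library(bayeschoice)

study  <- generate_study(study_config(n_subjects = 8, seed = 42))
prior  <- fit_prior(study_ratings(study))
params <- model_params(beta_conf = 0.01, cost = 0.01)

choices <- simulate_experiment(study$specs, prior, params, n_reps = 3, seed = 42)
stats   <- summary_stats(choices)
coefs   <- choice_regression(choices)
```

Output:

```
Gaussian prior (empirical): mu = 4.944, lambda = 0.2529 (sd = 1.988)
accuracy 0.830, median RT 840 ms, 0.3% aborted
                        term  estimate     se       z
1                  rel_value  5.131701 0.1574 32.6110
2               rel_duration -0.001261 0.0392 -0.0321
3              overall_value -0.016008 0.0381 -0.4206
4                   rel_conf  0.013473 0.0386  0.3489
5               overall_conf -0.000919 0.0391 -0.0235
6 rel_duration:overall_value  0.256508 0.0379  6.7633
7     overall_value:rel_conf  0.159638 0.0378  4.2214
8     rel_value:overall_conf  0.548472 0.1356  4.0437
crossover at 4.93 (prior mean 4.94)
```

Reading the table: choices track relative value strongly (`rel_value`);
presentation duration confers **no overall advantage** (`rel_duration`,
z ≈ 0) but interacts positively with overall value
(`rel_duration:overall_value`, z = 6.8) — longer-shown items are chosen more
above the context mean and less below it — and relative confidence behaves
the same way (`overall_value:rel_conf`). The estimated crossover point
(4.93) sits at the prior mean (4.94). `qualitative_signature()` automates
these sign checks across model variants, `grid_search()` fits
(β<sub>conf</sub>, cost) to accuracy and median RT, and
`sensitivity_scan()` repeats the crossover check over the parameter grid.

A thin command-line front end over the same functions lives at
`inst/cli/bayeschoice.R` with subcommands `synth`, `simulate`, `fit`,
`analyze`, `sensitivity`.

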