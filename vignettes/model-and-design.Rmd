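---
title: "A Bayesian sampling model of attention- and confidence-weighted choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian sampling model of attention- and confidence-weighted choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`bayeschoice` simulates binary value-based choice as sequential Bayesian
inference. On each trial an agent faces two items with true subjective values
$u^{(i)}$ on a 0–10 rating scale, but has no direct access to them. At each
time step (one step per $\delta t = 10$ ms) the agent attends to whichever
item the exogenous presentation schedule has on screen and receives a noisy
value sample

$$x_t \sim \mathcal N\!\left(u^{(i)},\, 1/\tau^{(i)}\right),$$

where the sample precision is proportional to the rater's confidence in that
item's value, $\tau^{(i)} = \beta_{\text{conf}} \cdot \text{conf}_i$ with
$\text{conf}_i \in \{1,\dots,5\}$. Samples are combined with a Gaussian
context prior $\mathcal N(\mu_{\text{prior}}, 1/\lambda_{\text{prior}})$ fit
to the empirical distribution of the rater's own value ratings. After $N$
samples with running mean $\bar x$, conjugate updating gives

$$\lambda = \lambda_{\text{prior}} + N\tau, \qquad
  \mu = \mu_{\text{prior}} + \frac{N\tau}{\lambda}\,(\bar x - \mu_{\text{prior}}).$$

Two properties of this update carry all of the package's predictions.
*Expectation dependence*: the estimate starts at the prior mean and moves up
or down depending on whether samples exceed expectations. *Precision
weighting*: the size of the move grows with accumulated precision $N\tau$ —
the product of sample quantity (attention) and sample quality (confidence).
Together they imply the signature crossover: more attention (or higher
confidence) *raises* the estimated value of better-than-average items and
*lowers* it for worse-than-average items, so the attended/confident item is
favoured above the prior mean and disfavoured below it.

### Stopping rule

Sampling is costly (linear in time, $c$ value units per second). After every
sample the agent assesses the value of computation: for a geometric menu of
candidate additional-sample counts $h \in \{1, 2, 4, \dots, \text{remaining}\}$,
it splits $h$ between the items in proportion to their expected
presentation-time shares (500 : 200 ms means, i.e. 5/7 vs 2/7), computes the
preposterior spread of each future posterior mean,
$s_i = \sqrt{1/\lambda_i - 1/(\lambda_i + h_i\tau_i)}$, and evaluates the
expected improvement in the chosen option's value via the closed form for the
expected maximum of two independent Gaussians. If some $h$ has expected gain
at least equal to its cost $c\,h\,\delta t$, sampling continues; otherwise it
stops and the item with the larger posterior mean is chosen (exact ties break
at random). Response time is the number of samples times $\delta t$. Trials
still sampling at the 5 s deadline (500 samples) are aborted and excluded
from analysis, as in the experimental task the design emulates. This menu
approximation is in the Directed Cognition family; the exact
dynamic-programming stopping policy is deliberately out of scope.

Two numerical choices matter here. First, the expected gain is evaluated in
the cancellation-free form $\theta\,\varphi(z) - |\Delta\mu|\,\Phi(-z)$ with
$z = |\Delta\mu|/\theta$, which stays strictly positive whenever sampling is
planned instead of underflowing to zero late in a trial. Second, the agent
continues on a *non-negative* net value and stops only when every candidate
is strictly negative: under any positive cost the boundary has probability
zero, and in the zero-cost limit a free agent then keeps sampling to the
deadline, which is the behaviour the cap is defined by.

### Model variants

The alternative models differ only in the prior or in the precision the
agent *assumes while updating* — the sampling distribution itself never
changes, so performance differences are attributable to the updating policy:

* **zero prior** — $\mu_{\text{prior}} = 0$ (the scale minimum): sampling can
  only raise estimates, so longer presentation helps everywhere (a main
  effect of attention instead of a crossover);
* **flat prior** — $\lambda_{\text{prior}} = 10^{-6}$: no prior information,
  estimates are unbiased at any sampling amount, and attention effects
  vanish;
* **equal-weight updating** — all items updated with the average precision
  $\beta_{\text{conf}}\cdot\overline{\text{conf}}$: confidence still shapes
  the noise but not the weighting, eliminating relative-confidence effects
  and making high-confidence (low-noise) choice sets *slower*, because less
  noise keeps the two estimates close and the expected gain high;
* **biased confidence** — updating uses
  $\beta_{\text{bias}} + \beta_{\text{conf}}\cdot\text{conf}_i$:
  overconfidence ($\beta_{\text{bias}} > 0$) inflates assumed precision, so
  beliefs harden too fast and choices become faster but less consistent.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `beta_conf` | precision per confidence unit | (rating units)$^{-2}$ per confidence point | 0.01 |
| `cost` | time cost of sampling | value units / s | 0.01 |
| `beta_bias` | updating-precision offset (biased variant) | (rating units)$^{-2}$ | 0 |
| `dt_ms` | time per sample | ms | 10 |
| `deadline_ms` | response deadline | ms | 5000 |
| `flat_lambda` | prior precision, flat variant | (rating units)$^{-2}$ | 1e-6 |
| `default_confidence` | imputed confidence when unrated | 1–5 scale | 4.18 |

`beta_conf` and `cost` are the model's two free parameters; fitting searches
a 30 × 30 logarithmically spaced grid on (0.001, 0.1) for each, minimizing
squared error on accuracy (normalized by 1) and median RT (normalized by the
5 s deadline), with simulated summary statistics. The defaults above sit at
the geometric midpoint of the fitting range and produce accuracies around
0.8 and median RTs below 1 s on the default design — the regime the fitting
grid is built around. `default_confidence = 4.18` is the average confidence
rating observed when confidence is measured on this kind of consumer-item
task. Trial-level likelihood fitting is deliberately not offered: these
models do not capture trial-by-trial RT distributions under exogenous
presentation, and likelihood fits degenerate.

Grid-search cells share random substreams (the same per-trial, per-repetition
seeds in every cell), so between-cell loss differences reflect parameters,
not simulation noise. Substreams are keyed by `(trial_id, rep)`, which makes
any trial reproducible in isolation and results independent of execution
order.

## The synthetic study generator

`generate_study()` emulates a standard two-alternative forced-choice design
with exogenous presentation: per subject, `n_items` ratings drawn from a
clipped Gaussian on the 0–10 scale (default mean 5, SD 2) with confidence
levels 1–5 drawn independently of value (default distribution mean ≈ 4.2);
choice sets built by rank-ordering items into terciles — 40 high, 40 medium
and 40 low matched pairs (|Δrating| ≤ 1, "zero or close to zero value
difference") plus 120 mixed pairs stratified across the value-difference
range; and per-trial presentation schedules alternating the two items with
segment durations drawn from the long (M = 500, SD = 100 ms) and short
(M = 200, SD = 50 ms) distributions, truncated below at `dt_ms` and rounded
to whole sample counts. Which item gets the long stream, and which is shown
first, are independent fair coin flips — value-independent by construction.

What this generator does *not* emulate: familiarization and item-exclusion
phases, post-choice re-rating, and any dependence of presentation on the
participant's gaze. Two realism options are off by default: a U-shaped
confidence mode (`conf_mode = "u_shaped"`, tilting confidence upward for
extreme ratings, as seen in rating data) and integer ratings
(`integer_ratings = TRUE`, mimicking the response format; continuous ratings
are the default since the model operates on continuous values).
Passing the package's checks therefore demonstrates the model's internal
predictions on a faithful design skeleton, not agreement with any particular
human dataset.

## Analyses

Simulated choice tables are analysed with fixed-effects approximations of
the mixed-effects models standard for such designs: logistic regression of
choosing the first item on standardized relative value, relative
presentation duration (share of screen time for item 1), overall value, and
their interactions (plus relative/overall confidence terms when confidence
varies), with subject indicator intercepts; and OLS on log RT with absolute
value difference, overall value, and overall confidence. Random slopes add
nothing for sign/zero claims on simulated data and would drag in a
mixed-model solver, so they are intentionally omitted. Predictors are
standardized with the population SD (making estimates invariant to
duplicating the table); the crossover point
$-b_{\text{dur}}/b_{\text{dur}\times\text{value}}$ is mapped back to rating
units and should sit at the prior mean.

A sign criterion is |z| ≥ 1.96 for directed effects and |z| < 1.96 for
predicted nulls, evaluated across seeded replications with a ≥ 80% holding
rate at the reference design (30 subjects × 240 trials × 3 repetitions).

## Problem sizes used by the test suite

The packaged checks choose simulation sizes that keep the full suite within
a desktop run while preserving the study conditions: the reference-design
signature checks use 20 replications of 30 subjects × 240 trials × 3
repetitions; variant dissociations use the same design at 1 repetition per
trial across 20 replications (the dissociation effects are order-of-magnitude,
so single-repetition tables retain wide margins); parameter recovery uses a
10 × 10 grid, a single subject's 240 trials, and 2 repetitions per cell
across 10 replications; and the sensitivity scan covers a 5 × 5 parameter
grid at 10 repetitions per trial — a third of the 30 used for headline
predictions, which still gives the weakest grid corner
(`beta_conf` = 0.1, `cost` = 0.001, where near-free high-precision sampling
saturates posterior weights and shrinks the crossover effect to a
standardized ≈ 0.08) comfortable detection margins. `scripts/acceptance.R`
recomputes the same quantities at moderately reduced replication counts.

## Known limitations

* Two items per trial only; the belief types generalize but schedules and
  stopping are specified and tested for pairs.
* The stopping rule is an approximation; its candidate menu (geometric) and
  rounding of the future-sample split (short item rounded, long item takes
  the remainder) are implementation-defined details of the Directed
  Cognition discretization.
* The crossover prediction needs values on both sides of the prior mean; in
  degenerate designs (all items nearly equal in value) the interaction is
  unidentifiable.
* Group-level fitting on two summary statistics is intentionally coarse; do
  not expect it to pin parameters tightly when accuracy and median RT trade
  off weakly along a grid diagonal.
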