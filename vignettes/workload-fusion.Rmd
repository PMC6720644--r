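---
title: "Fusing multi-sensor data into a workload score: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-sensor data into a workload score: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlfuse)
```

## The problem

An operator's workload in a high-tempo control task (here: a pilot flying a
simulated takeoff and initial climb with injected failures) is reflected
jointly in task performance and physiology. Subjective instruments such as
the NASA-TLX capture it well but only after the fact; individual sensors
capture it continuously but one-sidedly. `wlfuse` learns a mapping
y = f(x1, …, x11) from eleven per-phase features — three flight-stability
dispersions (SD of pitch angle, heading, airspeed) and eight physiological
summaries (heart rate, heart-rate variability, respiratory rate and depth,
pupil diameter, gaze/glance/blink time proportions) — to a single workload
score on the TLX 0–100 scale.

## Model

The model is a layered Mamdani-type fuzzy neural network with a PCA front
end. Writing z for the z-scored feature vector:

* **Layer 2 (PCA).** The correlation matrix of the training z-scores is
  eigendecomposed. Component p carries contribution rate
  $C_p = 100\,\lambda_p/\sum_i \lambda_i$; the model keeps the smallest n
  whose cumulative rate reaches the threshold (default 0.75). Because the
  input is z-scored, the covariance of any two columns *is* their Pearson
  correlation — the two formulations coincide.
* **Layer 3 (fuzzification).** Each component score is mapped to
  memberships in $m_p$ ordered partitions via one Z-shaped function, a run
  of Gaussians with shared width, and one S-shaped function. The Z and S
  plateaus extend to ±∞, so extreme inputs need no clamping; the Gaussian
  tails never reach zero, so the total rule activation is strictly positive
  for every finite input.
* **Layer 4 (rules).** One rule per combination of partitions,
  $m = \prod_p m_p$ in total; rule j fires with the **minimum** of its
  antecedent memberships (min t-norm). The linguistic consequent labels
  (NB…PB) are metadata only — they play no numeric role.
* **Layer 5 (normalization).** $\bar R_j = R_j / \sum_j R_j$.
* **Layer 6 (defuzzification).** $y_i = \sum_j w_{ij}\bar R_j$: a convex
  combination of the weight matrix, so predictions are always bounded by the
  weight range.

Only the Layer 5→6 weights are learned. With memberships and PCA frozen the
model is *linear* in the weights, so the training objective is a convex
quadratic: batch gradient descent with per-sample cost
$E_c = \sum_i (y_{e,i}-y_{a,i})^2/2$ and gradient
$\partial E_c/\partial w_{ij} = -(y_{e,i}-y_{a,i})\bar R_j$ decreases the
cost monotonically for small enough learning rates and recovers exactly any
target function generated by a model of the same structure.

One printed form of the weight-update equation in the source literature sums
over the very indices it updates; we read it as a typographic rendering of
the accumulated batch step implied by the gradient and iteration equations,
and implement exactly that: per-sample deltas
$\beta(y_{e}-y_{a})\bar R_j$ are accumulated over the whole pass and applied
once per epoch.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `threshold` | cumulative contribution to keep | 0.75 | inside the conventional 70–90% band; yields n = 4 on 11-feature campaigns like the motivating one |
| `preset` | membership family per input | `partitions4` | Z(−1.5,−0.5), Gaussians ±0.5 with σ = 0.2690, S(0.5,1.5); `partitions8` offers the finer NB…PB lattice (σ = 0.1213, centers ±0.25, ±0.75, ±1.25) |
| `beta` | learning rate | 0.75 | fastest of the commonly compared 0.25/0.50/0.75 settings on this convex problem |
| `tau` | stopping tolerance on dataset RMSE (TLX units) | 5 | the TLX grid's minimum division — finer fits are not meaningful on a scale quantized to 5 |
| `max_epochs` | epoch cap | 10000 | non-convergence is reported in the trace, never thrown |
| `init` | weight init | zeros | deterministic; seeded-uniform over [0, 100] (the output scale) is available |

The membership presets interpret the published parameter sets as Gaussian
*centers* (the ± lists) plus a shared *width* (the scalar): a width cannot
be negative or set-valued, and this reading produces ordered, overlapping
partitions. The two constants 0.1213 and 0.2690 have no stated derivation
and are treated as opaque preset values.

Rule order is frozen and documented: lexicographic over the partition tuple
with the first input slowest-varying (`lex-q1-slowest`). Serialized weight
vectors are meaningless without it, so it is stored in the model JSON.

## Error aggregation and stopping

The stopping rule compares an aggregate error against τ. The per-sample cost
is the half-squared error above; the aggregate reported in the trace and
compared to τ is the dataset RMSE across samples and outputs (for one output,
RMSE = √(2 · mean per-sample cost)). Both are inspectable in the training
trace (`rmse`, `mean_cost` columns).

## Degenerate inputs and numerical choices

* Zero-variance feature columns are an error naming the column (they carry
  no information and break z-scoring).
* Tiny negative eigenvalues from roundoff are clamped to zero before
  contribution rates; eigenvector signs are fixed (largest-magnitude entry
  positive) so decompositions are reproducible across platforms, and models
  always serialize their loadings so no result depends on the convention.
* Eigenvalue ties keep the decomposition's stable order.
* If every rule fires at exactly zero — reachable only with degenerate
  hand-built partitions, since Gaussian tails are positive — normalization
  errors by default; an optional fallback substitutes the uniform vector
  with a warning.
* Grid unification rounds to the nearest multiple of 5 with ties away from
  zero. The published prediction tables contain no tie, so the tie rule is a
  free choice, documented here. Sign and magnitude are preserved: raw scores
  outside [0, 100] (they arise; see below) unify to the nearest grid point,
  not to a clipped value.
* A learning rate beyond the stability bound of the quadratic objective
  diverges; the first non-finite weight aborts training with a diagnostic
  rather than silently overflowing.

## The synthetic campaign: what it emulates, and what it does not

The generator (`generate_campaign`) emulates the *design* of a 14-subject ×
3-difficulty simulator campaign with four phases per run and TLX
questionnaires per run:

* a latent workload level per run-phase: phase base + post-failure
  difficulty effect + subject random effect + noise, clipped to [0, 100];
* phase bases (taxiing 40, normal climbing 25, failure 70, flare-out 32)
  encode the orderings reported for such campaigns: failure highest, taxiing
  above normal climbing (vigilance-heavy vs. attitude-holding), flare-out in
  between;
* difficulty effects (−12 / 0 / +12 for LL/ML/HL) apply only from the
  failure onward, so pre-failure phases are statistically indistinguishable
  across difficulties;
* features respond linearly to latent workload with the documented
  physiological signs (heart rate, HRV, respiratory rate, pupil diameter,
  gaze share rise; respiratory depth, glance and blink shares fall), plus
  Gaussian noise, truncation for physical plausibility and renormalization
  of the eye-time proportions; flight dispersions are given a positive
  response as an artifact choice;
* TLX answers are the fault-phase latent workload plus per-dimension offsets
  and noise, quantized to multiples of 5 and clipped to [0, 100].

All distributional choices (Gaussian latent and noise, the specific bases,
slopes and SDs) are artifact constants fixed once; the emulated design
dictates only sample sizes, orderings, signs and the TLX grid. The generator
does **not** simulate waveforms, cockpit dynamics, learning effects across
runs, or heavy-tailed sensor artifacts — so a green test establishes that
the pipeline recovers the stated statistical structure, not that it would
survive every pathology of real recordings. Notably, z-scoring deliberately
retains outliers, and out-of-range predictions (raw scores outside [0, 100])
are expected on real data and are counted, not suppressed, by the report
stage.

## Design choices where the design was open

* **Standardization population.** z-score parameters are fitted on the whole
  training stratum, not per subject: per-subject fitting would erase the
  between-subject component of workload that the TLX targets, and a deployed
  monitor must score a new phase before it has seen enough of that subject's
  data to standardize by.
* **PCA scope.** Fitted once globally rather than per difficulty level: the
  correlation structure among features is assumed task-generic, and
  per-level fits would make component meanings (and hence weights)
  incomparable across levels.
* **Training target.** The six TLX dimensions are averaged to a single
  r = 1 target, each dimension holding comparable weight in this task; the
  defuzzification and learning code paths support r > 1 for joint
  six-dimensional fitting.
* **Training stratum.** Models are fitted on the failure-phase records: the
  questionnaire is answered after the flight, when the failure response
  dominates the impression, so that stratum carries the clearest label
  signal. Other phases act as held-out strata; the report stage summarizes
  them per phase and difficulty.
* **Heading dispersion** is the plain SD of heading values, no circular
  statistics — consistent with the magnitudes reported for such campaigns
  (heading SDs above 100° are only possible with linear SD).

## Known limitations

* The rule lattice grows as $\prod m_p$; beyond ~6 retained components with
  4 partitions the weight vector outgrows any plausible campaign, and plain
  batch gradient descent on near-duplicate rule activations becomes
  ill-conditioned (see the scaled-down recovery test in the acceptance
  suite). Dimension reduction is not an optimization nicety — it is what
  makes the fuzzy layer feasible.
* Training fits only the output weights; membership parameters and the PCA
  are frozen. Misspecified partitions cannot be repaired by the learner.
* The published per-component contribution rates, loadings and prediction
  tables for the motivating campaign derive from an unpublished dataset;
  they are used here only as format fixtures and arithmetic checks (grid
  unification, cumulative-rate sums), not as reproduction targets. One
  published weight count (625 for the five-component variant) contradicts
  the rule-count formula and is knowingly left failing in the acceptance
  suite.

## A minimal run

```{r example, eval = FALSE}
dir <- tempfile()
paths <- cli_simulate(outdir = dir, seed = 7)
model <- cli_fit(paths["features"], paths["tlx"], file.path(dir, "model.json"))
pred <- cli_predict(file.path(dir, "model.json"), paths["features"],
                    file.path(dir, "pred.csv"), unify = TRUE)
cli_report(file.path(dir, "pred.csv"))
```
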