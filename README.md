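# wlfuse

Multi-sensor fusion of flight-performance and physiological data into a
single operator-workload score, for human-factors researchers working with
cockpit (or other control-station) simulator campaigns.

Continuous workload monitoring needs an objective mapping from what sensors
can measure in real time — flight-path stability, ECG, respiration, eye
tracking — to the workload construct that subjective instruments like the
NASA-TLX measure after the fact. `wlfuse` implements that mapping as a
Mamdani-type fuzzy neural network with a dimension-reduction front end:

1. **Standardization.** Each of the k = 11 features (pitch-angle SD,
   heading SD, airspeed SD; heart rate, heart-rate variability, respiratory
   rate, respiratory depth, pupil diameter; gaze/glance/blink time
   proportions) is z-scored, y = (x − x̄)/s, with s the sample SD
   (denominator n − 1).
2. **PCA.** The correlation matrix R of the z-scores is eigendecomposed;
   component p has contribution rate C_p = 100·λ_p/Σλ, and the smallest n
   with cumulative rate ≥ threshold (default 0.75, within the conventional
   70–90% band) is retained. Scores are X_p = a_pᵀ·z.
3. **Fuzzification.** Each component is mapped to memberships in m_p ordered
   partitions by a composite family: one Z-shaped function, Gaussians with a
   shared width, one S-shaped function (presets: 4 partitions with
   Z(−1.5,−0.5), Gaussians at ±0.5, σ = 0.2690, S(0.5,1.5); or the finer
   8-partition NB…PB set).
4. **Rule matching and normalization.** Each of the m = ∏ m_p rules fires
   with the *minimum* of its antecedent memberships, R_j; firing strengths
   are normalized to R̄_j = R_j / Σ R_j.
5. **Defuzzification.** The crisp output is the weighted sum
   y_i = Σ_j w_ij R̄_j — a convex combination of the learned weights, on the
   NASA-TLX 0–100 scale.

The weights are trained by error-feedforward batch gradient descent on the
cost E_c = Σ_i (y_e,i − y_a,i)²/2 (gradient −(y_e − y_a)·R̄_j, learning rate
β, default 0.75) until the dataset RMSE drops below the error-tolerance
threshold τ (default 5, the TLX grid's minimum division). Raw outputs can be
snapped back to the TLX grid (nearest multiple of 5, ties away from zero).

A seeded synthetic campaign generator reproduces the experimental design the
model targets — 14 subjects × 3 difficulty levels × 4 flight phases
(taxiing, normal climbing, maneuvering under failure, flaring out), with
physiologically signed feature responses and quantized TLX answers — so the
whole pipeline is testable without any recordings.

## Worked example

```r
library(wlfuse)

dir <- tempfile()
paths <- cli_simulate(outdir = dir, seed = 7)        # 42 runs, 168 records
model <- cli_fit(paths["features"], paths["tlx"],
                 file.path(dir, "model.json"))
#> [wlfuse] fit: n_selected=4 rules=256 epochs=10 final_rmse=4.6711 converged=TRUE ...

pred <- cli_predict(file.path(dir, "model.json"), paths["features"],
                    file.path(dir, "pred.csv"), unify = TRUE)
report <- cli_report(file.path(dir, "pred.csv"))
#> [wlfuse] report: 168 predictions, 0 out of range (0.00%)
str(report$phase_means)
#> $ taxiing        : num 27.1
#> $ normal_climbing: num 26.1
#> $ fault          : num 68.8
#> $ flaring_out    : num 30.2
```

With this seed the PCA keeps 4 of 11 components (256 rules) and training
converges in 10 epochs to RMSE 4.67 < τ = 5. The phase means behave as a
workload monitor should: the failure phase is far highest (68.8), and the
pre-failure phases sit low. Difficulty means order HL (40.4) > ML (39.4) >
LL (34.4). Re-fitting with β = 0.25 / 0.50 / 0.75 takes 31 / 15 / 10
epochs — larger learning rates converge faster on this convex problem.

The same workflow is available from the shell via the wrapper in
`inst/cli/wlfuse`:

```sh
Rscript inst/cli/wlfuse simulate --seed 7 --out campaign/
Rscript inst/cli/wlfuse fit --features campaign/features.csv \
    --tlx campaign/tlx.csv --model model.json
Rscript inst/cli/wlfuse predict --model model.json \
    --features campaign/features.csv --out pred.csv --unify
Rscript inst/cli/wlfuse report --predictions pred.csv --out report.json
```

## Documentation

See `vignette sources under vignettes/` for the model, its assumptions, the
synthetic generator's scope, and the numerical design choices.
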