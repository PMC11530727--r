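# moodfuse

Personalized daily mental-health monitoring from multimodal ecological
momentary assessment (EMA) data. `moodfuse` models nine self-rated mood
dimensions (vigorous, gloomy, concerned, happy, unpleasant, anxious,
cheerful, depressed, worried — the DAMS items) from two passively collected
modalities: wrist actigraphy, as 60-minute windows of zero-crossing-mode
(ZCM) counts and proportional-integration-mode (PIM) intensities preceding
each prompt, and fixed-width speech embeddings extracted from short voice
recordings. It is aimed at affective-computing and digital-phenotyping
researchers who want a fully testable, desk-scale implementation of
uncertainty-weighted multimodal multitask learning with per-participant
personalization — including a synthetic EMA simulator, so that every part of
the pipeline runs without access to any private study data.

## The model

Three two-layer feed-forward encoders map the ZCM window, the PIM window and
the speech embedding to d-dimensional vectors; the two actigraphy embeddings
are merged into one physiological stream *h_a*. Fusion with the speech
stream *h_s* uses **dynamic restrained uncertainty weighting (DRUW)**: with
learnable log-variances `s_m = log σ_m²` and weights `w_m = exp(−s_m)/2 =
1/(2σ_m²)`,

    fused = w_a · h_a + w_s · h_s
    penalty = Σ_m s_m/2 + λ_f (Σ_m w_m − τ_f)²,   τ_f = M/2

so the uncertainty of each modality sets its weight, the log term stops
weights from growing without bound, and the restraint keeps the total weight
mass near its symmetric value (at `s = 0` the penalty vanishes and fusion is
plain averaging). The fused vector passes through an emotional FFNN and one
transformer encoder layer (4 heads, feed-forward width 4d) over the three
tokens (fused, physiological, speech) with learned token-type embeddings;
mean-pooling gives the shared **macro** emotional embedding M. A
per-participant **micro** layer FFNN_i (a residual one-hidden-layer
perturbation, zero-initialized so personalization starts at the identity)
then yields the personalized embedding

    P_i = α · M + (1 − α) · FFNN_i(M),   α ∈ [0, 1] (default 0.5)

and nine logistic heads predict the normalized labels, `ŷ_k =
logistic(a_k·P_i + b_k) ∈ (0, 1)`. The nine per-task losses L_k are combined
by the **DRUW multitask loss**

    total = Σ_k w_k L_k + Σ_k s_k/2 + λ (Σ_k w_k − τ)²,   w_k = exp(−s_k)/2, τ = K/2.

Training follows a fixed schedule: SGD with Nesterov momentum 0.9, initial
learning rate 0.001, batch size 16, weight decay 1e-4 (excluded for the
uncertainty parameters and α), up to 100 epochs with the learning rate
multiplied by 0.9 after 5 consecutive epochs without development-set
improvement; the checkpoint with the best development mean CCC is kept.
Agreement is measured by the concordance correlation coefficient

    CCC = 2 ρ σ_x σ_y / (σ_x² + σ_y² + (μ_x − μ_y)²)

(population moments), reported per emotion with mean (SD) across the nine
dimensions, and the comparison grid of alternative fusion / personalization /
multitask strategies is available through `ablation_spec()` and
`run_ablation()`. `within_individual_validation()` complements the CCC with
a mixed linear model (observed ~ predicted + participant random intercept,
via lme4) reporting slope, Wald z, 95% CI, and group/residual variances per
emotion.

## Worked example

```r
library(moodfuse)

cfg <- sim_config(n_participants = 12, n_days = 14, speech_dim = 64, seed = 42)
sim <- simulate_ema(cfg)

data  <- sim$data |> clean_records() |> normalize_labels()
split <- partition_by_time(data)            # first 70% / 15% / 15% per participant
stats <- fit_standardization(data, split)   # training split only, no leakage
data  <- apply_standardization(data, stats)

model <- mf_model(speech_dim = 64, d = 32)  # DRUW fusion, macro-micro, DRUW loss
fit   <- mf_train(data, split, model, train_config(epochs = 15, seed = 42))
fit
#> <mf_fit> druw/macromicro/druw | 15 epochs, best dev mean CCC 0.5342 at epoch 15

evaluate(fit, data, split, part = "test")
#> <eval_table> test records: 132, mask: all, mean CCC 0.574 (SD 0.021)
#> # A tibble: 9 × 2
#>   emotion      ccc
#>   <chr>      <dbl>
#> 1 vigorous   0.609
#> 2 gloomy     0.576
#> 3 concerned  0.569
#> # … 6 more rows

fusion_weights(fit)
#> # A tibble: 2 × 3
#>   modality     s weight
#>   <chr>    <dbl>  <dbl>
#> 1 phys     -1.01   1.37
#> 2 speech   -1.04   1.41
```

The evaluation table is the per-emotion test-set CCC of the selected
checkpoint with its mean (SD) across the nine mood dimensions; the fusion
weights are the learned DRUW modality weights `w = exp(−s)/2` (near-equal
here because both simulated modalities are informative). `validate_fit()`
adds the mixed-model rows (slope ≈ 0.7–0.9 with strongly significant z in
this example, group variance the between-participant share the model leaves
unexplained), `predict()` returns per-record `.pred_*` tibbles, and
`autoplot()` draws the learning curve or the CCC bar chart.

A thin command-line interface wraps the same functions
(`inst/cli/moodfuse`): `simulate`, `train`, `evaluate`, `validate` and
`ablate` subcommands with YAML configuration (`model:` and `train:`
sections; flag > file > default precedence) and a JSON run manifest per
output directory.

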