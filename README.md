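# sncnirs

Inter-subject prediction of n-back working-memory load (1-back vs 2-back)
from four-channel NIRS time series, built around the **Sigmoid Normal-form
Classifier (SNC)** — a non-parametric, one-step-regression classifier — plus
everything needed to exercise it end to end: a synthetic fNIRS cohort
generator, the standard preprocessing chain, four per-channel feature
families, a subject-wise cross-validation harness, and adapters for the
usual baseline classifiers.

## The method

Feature vectors of the two task conditions form task spaces
𝕋₁ (1-back, label 0) and 𝕋₂ (2-back, label 1). Fitting proceeds in five
deterministic steps:

1. **Dissimilarity ratio** `r = E[‖p‖, p ∈ 𝕋₁] / E[‖p‖, p ∈ 𝕋₂]` — the
   ratio of mean Euclidean norms of the two classes.
2. **Class-wise rescaling**: 𝕋₁ vectors are multiplied by `r`, 𝕋₂ vectors
   by `max(τ, 1 − r)` with τ = 0.5, broadening the separation between the
   classes while preserving each class's internal shape.
3. **Geometric medians** of the scaled classes (Weiszfeld iteration) give a
   robust center per class.
4. **Normal-equation regression** `W = (XᵀX)⁻¹Xᵀy` on the scaled data
   (SVD pseudo-inverse when singular), optionally after element-wise
   polynomial expansion of degree ∈ [0, 12].
5. **Sigmoid boundary** `β = σ(Wᵀx̄)` at the midpoint `x̄` of the two
   medians; a new vector `p` is labeled 2-back iff `σ(Wᵀp) ≥ β`.

Around the classifier: per channel, signals are baseline-normalized against
a 1-minute rest, band-passed 0.01–0.6 Hz (order-5 Butterworth, zero-phase),
then linearly and quadratically detrended. Task-period samples are split
into four equal sub-streams, from which four feature families are computed —
signal mean & slope (SM&SS, 8-dim), contrast-to-noise ratio (CNR, 4-dim),
moving average (4-dim), and differential entropy (DE, 4-dim,
`½·ln(2πeσ̂²)` nats). Evaluation is subject-wise: training fractions
90%…50% in 5% steps, 20 repetitions each, every participant's data entirely
on one side of each split — 4 channels × 4 families × 9 fractions × 20
repetitions = 2880 cells per classifier, ×12 polynomial degrees = 34,560
for the SNC.

## Worked example

Generate a synthetic 10-participant cohort whose planted effect lives in
the variance (hence DE) of the left-lateralized channel, preprocess it, fit
an SNC, and run the full harness:

```r
library(sncnirs)

cfg    <- sim_preset_de_dominant(n_participants = 10, seed = 2026)
cohort <- preprocess_cohort(generate_cohort(cfg))

feats <- extract_features(cohort, family = "DE", channel = "Left1")
model <- snc_fit(feats$X, feats$y, tau = 0.5, degree = 0)
model
#> <snc> r = 0.1461, tau = 0.50, degree = 0, beta = 0.6174, 4 weights

report <- run_algorithm1(cohort, snc_classifier(),
                         plan = split_plan(repetitions = 5, seed = 1))
report
#> <snc_eval_report> snc: 720 cells (0 invalid)
#>   best: channel Left1, family DE, mean accuracy 0.9978
```

Reading the output: the fitted dissimilarity ratio `r = 0.146` says 1-back
DE vectors carry about 15% of the norm mass of 2-back vectors (the planted
4:1 oscillation-amplitude ratio on a log-variance feature); `beta = 0.617`
is the sigmoid score of the midpoint of the class medians, the decision
threshold. The harness ran 4 channels × 4 families × 9 fractions × 5
repetitions = 720 cells and identified (`Left1`, `DE`) as the best
configuration with 99.8% mean held-out-subject accuracy — the configuration
the cohort was built to favor. The runner-up configurations sit visibly
lower:

```r
head(report$summary[order(-report$summary$mean_accuracy),
                    c("channel", "family", "mean_accuracy")], 3)
#>    channel family mean_accuracy
#> 13   Left1     DE     0.9977778
#> 2    Left3   SMSS     0.9048148
#> 3   Right1   SMSS     0.8783333
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/sncnirs` (subcommands `simulate`, `preprocess`, `extract`,
`train`, `predict`, `evaluate`, `segment-demo`; YAML configuration,
JSON/CSV outputs).

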