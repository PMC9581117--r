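# trgb — instance-based transfer learning with gradient boosting

Clinical classifiers for diseases like Alzheimer's are often needed on
cohorts with only tens of labeled subjects, while a much larger auxiliary
cohort exists that was collected under different scanners, inclusion
criteria or even diagnostic label sets. `trgb` implements **transfer
gradient boosting**: a gradient boosting machine with log-likelihood loss
in which the auxiliary (*source*) training instances are re-weighted at
every boosting iteration, so that instances distributed unlike the cohort
of interest (the *target*) fade from the fit while compatible ones keep
contributing.

At iteration $t$, with pseudo-residuals $r_i = y_i - p_i$ and
$\bar r_T$ the mean absolute residual over the **target** instances only,
the learner strength is

$$\lambda = \tfrac12 \log\frac{1 - \bar r_T}{\bar r_T},$$

and each instance's weight factor is 1 when
$(\tfrac12 - |r_i|)\lambda > 0$, otherwise

$$w_i = \begin{cases} e^{-2(|r_i| - 1/2)\lambda} & i \in \text{source} \\
e^{+2(|r_i| - 1/2)\lambda} & i \in \text{target.} \end{cases}$$

Under a strong learner a misclassified source instance is down-weighted —
it likely follows a different distribution — while a misclassified target
instance is up-weighted. A depth-limited regression tree is then fit to
the pseudo-residuals under these weights, followed by a per-leaf Newton
step and a shrunken model update. With an empty source set every weight
stays at 1 and the engine is a plain GBM, which is also how the
`target_only`, `source_only` and `pooled` baselines are built — all
methods share one tree builder, so comparisons isolate the weighting.

The package ships:

* `trgb()` / `predict()` — the binary engine, with per-iteration
  diagnostics (`training_log()`) and versioned JSON serialization
  (`write_trgb()` / `read_trgb()`);
* `trgb_multiclass()` — one-vs-rest extension for K classes;
* `fit_baseline()` — target-only, source-only, pooled GBM and TrAdaBoost
  comparison arms;
* `scenario_spec()` / `generate_domain_pair()` — a synthetic generator
  emulating multi-cohort biomarker tables: covariate shift, concept
  shift, label-space mismatch, class imbalance, hundreds-vs-tens size
  asymmetry, optional demographic columns;
* `run_experiment()` — stratified-CV / holdout method comparisons with
  imbalance-aware metrics (accuracy + macro precision/recall/F1) and a
  grouped-bar figure;
* `map_label_space()`, `read_feature_table()` — cross-label transfer and
  validated CSV I/O;
* a command line (`inst/cli/trgb.R`) with `simulate`, `fit`, `predict`,
  `evaluate` and `reproduce-synthetic` subcommands.

## Worked example

```r
library(trgb)

pair <- generate_domain_pair(transfer_scenario(seed = 1))
pair
#> Synthetic domain pair
#>   source: 600 rows (CN/AD)
#>   target: 40 labeled + 400 test rows (CN/AD)
#>   seed: 1

fit <- trgb(pair$source, pair$target_labeled)
fit
#> TrGB transfer gradient boosting model
#>   classes: CN vs AD (positive: AD)
#>   training instances: 600 source + 40 target
#>   iterations: 100 (depth 3, learning rate 0.1, weight mode cumulative)
#>   final: lambda 1.1049, target avg |residual| 0.0989, train loss 0.1338
```

The training log shows the transfer mechanism at work: the learner
strength `lambda` grows as the target residuals shrink, and the source
weight distribution drifts away from 1 as incompatible source instances
fade:

```r
training_log(fit)[c(1, 50, 100), c("iteration", "lambda",
                                   "target_avg_residual", "source_w_median")]
#>     iteration lambda target_avg_residual source_w_median
#> 1           1 0.0000              0.5000          1.0000
#> 50         50 0.7157              0.1929          1.1362
#> 100       100 1.1049              0.0989          1.1477
```

A single seed is noisy at 40 labeled target instances, so method
comparisons run over replicate draws; on the packaged moderate-shift
scenario (30% of source labels from a flipped boundary plus a mean shift):

```r
st <- run_experiment(
  experiment_plan(methods = c("trgb", "target_only", "source_only", "pooled"),
                  n_seeds = 5),
  transfer_scenario())
st
#> Score table (mean over 5 replicates, holdout protocol; percent)
#>     metric trgb target_only source_only pooled
#>   accuracy 75.5        70.9        72.0   73.3
#>  precision 76.4        71.2        72.6   74.1
#>     recall 75.5        70.9        72.0   73.3
#>         f1 75.3        70.8        71.8   73.1
```

Here the weighted transfer beats training on the 40 target instances
alone (+4.6 accuracy points), the source-trained model (+3.5) and naive
pooling (+2.2): the gain comes from *filtering* the source, not merely
from having more data. `plot_score_table(st)` draws the grouped-bar
comparison figure.

See `vignettes/transfer-gradient-boosting.Rmd` for the full model
description, the generator's calibration, and known limitations —
including an honest account of when the residual-based weighting fails
(a fully adversarial source much larger than the labeled target set).

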