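# tanhrelunet

A self-contained R implementation of a TanhReLU-based convolutional neural
network for classifying 4-second multichannel EEG segments (major
depressive disorder vs. healthy control), with every moving part — the
activation, the differentiable layers, the training loop, the validation
protocol and a synthetic data generator — written and tested inside this
package.

## The model

The TanhReLU activation fuses the hyperbolic tangent with a half-slope
linear tail, switching at a segmentation parameter *a* (default 0.25):

```
TanhReLU(x) = tanh(x)   if |x| <= a
            = 0.5 * x   if |x| > a
```

Its derivative is bounded in [0.5, 1], so gradients neither vanish in the
tails (the tanh failure mode) nor die on negative inputs (the ReLU failure
mode).  The definition is implemented literally, including its jump of
`tanh(a) - 0.5a` at the branch point (see `discontinuity_gap()`); an
optional continuity-corrected tail is available behind a flag.

The network consumes one EEG segment as a `20 x 32 x 32` tensor (each
channel's 1024-sample window reshaped row-major to `32 x 32`) and applies:
a depthwise 5x5 convolution (one filter per electrode, 20 filters), a
standard 5x5 convolution (20 filters), flatten (11520), an "hourglass"
fully connected block `128 -> 32 -> 1`, and a sigmoid head.  Batch
normalization follows each conv and hidden FC layer.  Training is SGD
(learning rate 0.01, weight decay 1e-6 on weights only), MSE loss, batch
size 15, max 40 epochs, early stopping with patience 10 and best-epoch
restoration; evaluation is subject-wise leave-one-out with pooled
accuracy / sensitivity / specificity.

## Worked example

Generate a small synthetic cohort (alpha-band power contrast over 1/f
noise), train on 48 windows and score 12 held-out windows:

```r
library(tanhrelunet)

cfg  <- synth_config(n_subjects_per_class = 3, duration_s = 40, seed = 42)
recs <- generate_dataset(cfg)                       # 6 labeled recordings
segs <- unlist(lapply(recs, segment_recording), recursive = FALSE)
length(segs)                                        # 60 segments of 20x32x32

set.seed(7)
held <- sample(length(segs), 12)                    # segment-wise hold-out
res  <- train_network(build_network(network_config(seed = 1)),
                      segs[-held], train_config(shuffle_seed = 1))
tail(res$learning_curve, 1)
#>    epoch  train_loss   val_loss train_acc val_acc
#> 40    40 0.005969619 0.02980886         1       1

classification_metrics(evaluate_network(res$net, segs[held]))
#> $accuracy     [1] 1
#> $sensitivity  [1] 1
#> $specificity  [1] 1
```

All 12 held-out windows are classified correctly — but note these windows
come from subjects the network saw during training.  The stricter protocol,
`loo_validate(recs, ..., unit = "subject")`, holds out entire subjects; on
this synthetic world it exposes subject-level overfitting (each subject's
fixed per-channel oscillation phases act as identity fingerprints), and
pooled accuracy drops to near chance.  The methods vignette discusses this
limitation in detail.  `learning_curve_report()` writes per-fold CSVs/PNGs
with an overfitting flag.

A command-line front end (`inst/cli/tanhrelunet`) exposes `generate`,
`train`, `evaluate` and `loo` over EDF files + a CSV manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline from scratch — synthetic cohort generation,
segmentation, network construction, training and subject-wise leave-one-out
evaluation — prints the pooled metrics it computed, and writes the JSON
report to `--out`.
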