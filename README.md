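# braggscreen

Convolutional screening of serial crystallography diffraction frames.

## The problem

Serial femtosecond crystallography at X-ray free-electron lasers records one
detector frame per pulse, at 100 Hz and beyond. Most frames contain no
crystal diffraction — the jet missed the beam, or the shot hit solvent only
— yet every frame consumes network bandwidth, storage and downstream
processing. A *veto* (screening) step discards worthless frames at the time
and place of collection. The decision is deceptively hard: a frame counts
as a **Hit** when ten or more Bragg spots are recognizable, a **Maybe**
with four to nine, and a **Miss** otherwise; spots can be single pixels on
direct-detection devices (CSPAD-class), smeared over tens of pixels on
phosphor-coupled ones (Rayonix-class), and the grainy speckle of the water
ring mimics Bragg spots well enough to fool threshold-based spotfinders.

`braggscreen` implements the full screening stack for this problem, in R:

* **Synthetic data** (`generate_dataset()`): a diffraction-frame simulator
  with known ground-truth spot counts, emulating sparse-to-crowded
  reciprocal-lattice patterns, detector point-spread differences, grainy
  water rings, panel gaps and elevated panel borders, jet spikes, partial
  shadowing, saturation and beam-off blanks. Two bundled detector profiles:
  `cspad_like`, `rayonix_like`.
* **Preprocessing** (`preprocess_stack()`): dark/gain correction,
  photon-preserving n×n binning, center/random cropping, augmentation, and
  contrast conditioning — global normalization `v(x) = (x − μ)/σ` followed
  by **local contrast normalization**
  `LCN(x) = (v(x) − μ_N(x)) / max(σ_N(x), ε)` over a window neighborhood
  `N(x)`, or the display-style linear contrast `D = min(1, M·P_x / P₉₀)`.
* **Spotfinder baseline** (`find_spots()`, `count_threshold_classify()`):
  a pixel is *strong* iff it is trusted, exceeds a global ADU threshold and
  `value − μ_local > σ_strong · max(σ_local, √(gain·μ_local))`; strong
  pixels group by 4-connectivity, candidates need a minimum area, and a
  per-image candidate count at or above a threshold declares a Hit.
* **CNN classifier** (`cnn_architecture()`, `train_cnn()`,
  `predict_cnn()`): stages of convolution (k = 3, stride 2, zero-padded) →
  batch normalization → ReLU → 2×2 max-pooling, channels 4/8/16/32 by
  default, a fully connected layer, and SoftMax over (Hit, Maybe, Miss).
  With the default 720-pixel input the flattened feature vector has
  exactly 288 entries. Training is mini-batch SGD (batch 64, lr decaying
  exponentially 0.1 → 10⁻⁴) on the mean cross-entropy
  `L = −(1/N) Σ log p_target` with class-balanced batches; the hard
  decision adds the Hit and Maybe probabilities and retains the frame iff
  `p_hit + p_maybe ≥ p_miss` (winner-takes-all, ties fail open).
* **Evaluation** (`confusion_matrix()`, `success_rate()`,
  `confidence_histogram()`, `saliency_map()`): row-normalized confusion
  matrices (3-class or Hit∪Maybe vs Miss), binary screening success rate,
  confidence of correct decisions, and |∂L/∂x| input-gradient saliency with
  a 3σ mask; plus drivers for cross-detector transfer
  (`cross_dataset_experiment()`) and the preprocessing ablation
  (`ablation_experiment()`).
* **CLI** (`braggscreen_cli()`, `inst/cli/braggscreen`): `simulate`,
  `preprocess`, `spotfind`, `train`, `predict`, `evaluate` and an
  end-to-end `run`, all seeded and config-driven (YAML), writing the
  resolved configuration next to every output.

Frame stacks travel as HDF5 (`/frames` N×H×W int32, optional `/mask`,
beam-center attributes), annotations as CSV
(`frame_id,label,spot_count,source`).

## Worked example

```r
library(braggscreen)

profile <- builtin_profile("rayonix_like", shape = c(128, 128))
ds <- generate_dataset(800, demo_scene_mixture(), profile, seed = 7)
table(ds$annotations$label)
#>  Hit Maybe  Miss
#>  280   129   391

pp <- preprocess_stack(ds$stack, bin = 1, crop_size = 112, contrast = "lcn")
parts <- split_dataset(ds$annotations, split_spec(c(0.75, 0, 0.25), seed = 3))
pick <- function(p) list(x = pp$inputs[, match(p$frame_id, pp$frame_ids)],
                         y = p$label)
tr <- pick(parts$train); te <- pick(parts$test)

arch <- cnn_architecture(input_size = 112, channels = c(4, 8, 16))
fit <- train_cnn(tr$x, tr$y, arch,
                 train_config(batch_size = 64, batches_per_epoch = 60,
                              epochs = 20, seed = 5))
pred <- predict_cnn(fit$weights, te$x, frame_ids = parts$test$frame_id)
100 * success_rate(te$y, pred$binary)
#> [1] 95
confusion_matrix(te$y, pred$binary, binary = TRUE)
#> confusion matrix (row %):
#>           predicted
#> truth      Hit-like Miss
#>   Hit-like     94.1  5.9
#>   Miss          4.1 95.9
```

95% of held-out frames receive the correct binary keep/veto decision; 95.9%
of true Misses are vetoed (the number that controls wasted storage) while
94.1% of spot-bearing frames are retained. The same world defeats the
threshold spotfinder when frames carry only a grainy water ring — the
speckle is counted as Bragg candidates — which is the failure mode the CNN
is there to fix.

The shape-chain anchor:

```r
arch <- cnn_architecture()   # 720-pixel input, 4 stages
shape_chain(arch)
#>   stage channels conv_edge pool_edge
#> 1     1        4       360       180
#> 2     2        8        90        45
#> 3     3       16        23        11
#> 4     4       32         6         3
arch$n_features
#> [1] 288
```

## End-to-end run

```sh
inst/cli/braggscreen run --seed 1 --out demo_run
```

writes `frames.h5`, `preprocessed.h5`, `truth.csv`, `model.bin`,
`history.csv`, `predictions.csv`, `report.json` and the resolved
`config.yaml` into `demo_run/`.
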