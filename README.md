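# sanet: scale-attention U-Net for medical image segmentation

Segmentation targets in medical images span huge size ranges — retinal
vessel calibres run from one pixel to dozens within a single fundus
photograph, lungs fill large smooth regions, blastocyst tissues nest as
thin rings around large interiors. `sanet` implements a U-Net whose bridge
(the deepest encoder-decoder junction) carries a **scale-attention block**:
the bottleneck's channels are split into k subsets chained through 3x3
convolutions,

    y_1 = x_1
    y_2 = F_2(x_2)
    y_i = F_i(concat(x_i, A_{i-1}(y_{i-1})))    for 2 < i <= k

so subset i accumulates i−1 convolutions' worth of receptive field, and a
channel-attention gate A (sigmoid of a 1x1 convolution over summed global
max- and average-pooled channel statistics) decides per channel how much
coarse context flows forward. Training minimizes per-pixel cross-entropy
plus L2 weight decay, `Loss = L_ce + 0.0002 * ||W||^2`, with Adam,
rotation-only augmentation and a plateau rule that selects the last epoch
whose trailing 20-epoch loss window fluctuates by less than 0.01.

The package is self-contained for desk-scale work: convolution kernels and
reverse-mode differentiation are implemented in C++/R (no external deep
learning framework), and seeded phantom generators emulate all four tasks
the method targets (vessel, lung, artery/vein, blastocyst), so everything
trains and evaluates in minutes on one CPU. It is aimed at researchers who
want to study the scale-attention mechanism, its ablations (plain backbone
/ ResNet bottleneck / hierarchical split without gates / full
scale-attention), and the associated evaluation protocol, with fully
reproducible inputs.

Also included: the complete metric suite (sensitivity, specificity,
accuracy, MCC, F1, ROC AUC, per-class Jaccard, overlapping error, balanced
accuracy for artery/vein), FOV-restricted scoring, stratified k-fold
splitting, CLAHE-based fundus preprocessing, and skeleton-based vessel
diameter profiling.

## Worked example

```r
library(sanet)

# 1. a ready-to-train synthetic dataset: 12 vessel phantoms on a disc FOV
ds <- gen_dataset(phantom_spec(size = c(64, 64), task = "vessel",
                               max_width = 6, noise_sd = 0, seed = 100), 12)

# 2. a small scale-attention U-Net (depth 2, base width 8, k = 4)
model <- build_model(network_config(depth = 2, base_width = 8,
                                    bridge_variant = "sa", k = 4, seed = 1))
count_parameters(model)
#> [1] 34986

# 3. train on 8 phantoms, score the 4 held-out ones
fit <- train(model, ds[1:8],
             train_config(max_epochs = 50, batch_size = 4, seed = 1))
fit$history$selected_epoch
#> [1] 50
pr <- predict_samples(fit$model, ds[9:12])
rep <- evaluate(pr$masks, pr$probs, lapply(ds[9:12], `[[`, "mask"),
                lapply(ds[9:12], `[[`, "fov"), "vessel")
round(unlist(rep), 4)
#>     se     sp    acc    mcc     f1    auc
#> 0.9405 0.9938 0.9872 0.9406 0.9479 0.9987

# 4. calibre spectrum of a predicted mask
dp <- diameter_profile(pr$masks[[1]])
round(range(dp$diameters), 1)
#> [1] 1.8 7.2
```

The model has ~35k parameters; after 50 epochs (100 gradient steps) it
segments held-out phantoms at F1 0.95 with AUC 0.999 inside the field of
view, and the skeleton diameter map of a predicted mask spans calibres
from ~2 to ~7 pixels — the width range the generator drew. Metrics are
micro-pooled over all test pixels; `run_cv()` wraps the same pipeline in
stratified k-fold cross-validation.

A command-line interface covering the same pipeline (synthesize / train /
predict / evaluate / cross-validate / ablation parameter counts) installs
with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "sanet", package = "sanet"))')" \
    synth --seed 1 --out-dir data/
```

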