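# amcnn — mask-guided attention CNNs for hierarchical bird image classification

`amcnn` is an R implementation of an attention-enhanced convolutional
classifier for fine-grained bird recognition, aimed at researchers who
want a fully inspectable, dependency-light reference of the method: every
layer (convolution, batch norm, pooling) and every analytic gradient is
implemented in single-precision `RcppArmadillo` code and verified against
independent oracles, so the whole pipeline runs offline on a single CPU.

## The model

Distinguishing bird species is a fine-grained problem: the discriminative
cues (plumage pattern, bill colour, torso shape) are local,
high-frequency, *shallow* image features that deep networks tend to lose
with depth. The classifier counteracts this in two ways on top of a
ResNet18-style backbone:

**Mask-guided attention.** A binary foreground mask
*U* ∈ {0,1}<sup>56×56</sup> over the bird region is mapped to a weight map

&nbsp;&nbsp;&nbsp;&nbsp;*A<sub>ij</sub>* = ω if *U<sub>ij</sub>* = 1, and 1 otherwise,

which multiplies the stem feature map elementwise (broadcast over
channels). Foreground activations are amplified by ω (> 1 enhances, 1
disables); background passes unchanged. The default ω = 1.2 is the
optimum of the reference sweep, reproducible with `omega_sweep()`.

**A shallow-feature branch.** The first residual stage's output
(56×56×64) is pooled by spatial pyramid pooling at levels (1, 2, 4) into
a fixed 1344-vector that is concatenated with the 512-long
global-average-pooled deep feature, so shallow evidence reaches the
classifier directly: 1344 + 512 = 1856 → 512 → *K* softmax classes.

Training follows the reference protocol: SGD (momentum 0.9, batch 32),
initial learning rate 0.005 decayed to 10% every 7 epochs, 50 epochs,
validation each epoch. Dataset curation drops species with fewer than 20
images; splits are 80/10/10. Species-level predictions roll up the
family/genus/species taxonomy for per-level accuracy, and per-class
accuracies are binned into <85%, 85–90%, >90% intervals.

A seeded synthetic generator (`generate_dataset()`) produces
hierarchically labelled images with exact foreground masks — family →
silhouette, genus → hue, species → stripe frequency, on cluttered
backgrounds — so everything is testable without downloading data.

## Worked example

```r
library(amcnn)

dir <- file.path(tempdir(), "birds")
manifest <- generate_dataset(synthetic_spec(2, 2, 2, 50, seed = 1), dir)
summarize_manifest(manifest)
split <- split_manifest(manifest, seed = 1)

fit <- amcnn_fit(manifest, split,
                 train_config(epochs = 5, seed = 1, omega = 1.2),
                 mask_provider = mask_provider_oracle(dir),
                 image_root = dir)
print(fit)
report <- evaluate_model(fit, manifest, split, part = "test",
                         mask_provider = mask_provider_oracle(dir),
                         image_root = dir)
print(report)
```

```
    level classes images mean_images
1  family       2    400         200
2   genus       4    400         100
3 species       8    400          50

Attention-masked CNN fit (species level, 8 classes)
  omega = 1.2 (mask-weighted attention); 5 epochs
  final train loss 0.1757; best val accuracy 0.975 (epoch 5)

Evaluation (rollup, test part, n = 40)
  family   accuracy 1.0000 | class bins <85%: 0.000  [85-90%]: 0.000  >90%: 1.000
  genus    accuracy 1.0000 | class bins <85%: 0.000  [85-90%]: 0.000  >90%: 1.000
  species  accuracy 1.0000 | class bins <85%: 0.000  [85-90%]: 0.000  >90%: 1.000
```

The manifest summary counts classes per taxonomic level (8 species in 4
genera in 2 families, 50 images each). After five epochs the fit
separates the eight synthetic species; the report lists accuracy at each
level (monotone non-decreasing up the hierarchy, since a correct species
implies a correct genus and family) and the fraction of classes falling
in each per-class-accuracy bin.  The run takes a few minutes on one CPU.

Ranked prediction for a single image:

```r
predict(fit, file.path(dir, manifest$records$path[1]), type = "topk", k = 3)
```

```
  rank class                      label  confidence
1    1     0 family01_genus01_species01 0.981415791
2    2     1 family01_genus01_species02 0.018436892
3    3     2 family01_genus02_species01 0.000125874
```

A command-line interface wrapping the same functions (commands
`generate`, `train`, `evaluate`, `predict`, `sweep-omega`, `summarize`)
is installed at `system.file("cli", "amcnn.R", package = "amcnn")`.

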