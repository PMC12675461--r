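# sobelnet

Edge-aware dual-branch convolutional networks for binary brain-MRI tumor
classification, with a four-method explainability layer — implemented
end-to-end in R, testable without any external image data.

## The problem and who this is for

Convolutional classifiers reach very high accuracy on binary tumor/healthy
MRI classification, but two practical obstacles keep them out of clinical
workflows: plain backbones under-use the *boundary* information that makes
lesions visually salient, and black-box predictions are hard to audit.
`sobelnet` addresses both. It is aimed at medical-imaging ML researchers who
want a fully inspectable, dependency-light reference implementation of an
edge-aware fusion architecture together with the attribution methods used to
audit it — plus a synthetic phantom generator so that every stage of the
pipeline, from data layout to Grad-CAM overlays, can be exercised and
regression-tested on a laptop with no dataset download.

## The model

A single input image `X ∈ R^{H×W×3}` (pixels normalized by
`preprocess(x) = x/127.5 − 1` onto `[−1, 1]`) feeds two parallel branches:

- **Edge branch.** Fixed Sobel kernels approximate the first-order image
  gradients `G_x = I * S_x`, `G_y = I * S_y`; the edge-strength map
  `G = √(G_x² + G_y²)` passes through one learnable 3×3 convolution with
  rectifier and global average pooling, yielding a compact edge feature
  vector `f_edge`.
- **Semantic branch.** A convolutional backbone (three conv/pool stages,
  16/32/64 filters) produces a feature map `F ∈ R^{h×w×C}`, recalibrated by
  a squeeze-and-excitation block: squeeze `z_c = mean(F_c)`, excite
  `s = σ(W₂ · ReLU(W₁ z))`, reweight `F̂_c = F_c · s_c`; global average
  pooling gives `f_cnn`.

The fused vector `f_combined = concat(f_cnn, f_edge)` passes through a dense
layer (1,024 units, ReLU), dropout, and a softmax head, trained with
categorical cross-entropy and Adam. Early-stopping and
reduce-LR-on-plateau callbacks monitor the validation loss. The forward and
backward passes are hand-derived and verified against finite differences in
the test suite; the same backward machinery supplies the input and
feature-map gradients that the attribution methods consume:

- **Vanilla saliency** — per-pixel channel-max of `|∂y_c/∂x|`;
- **Grad-CAM** — `ReLU(Σ_k α_k A^k)` with `α_k = mean(∂y_c/∂A^k)`;
- **Grad-CAM++** — location-dependent higher-order weighting for sharper
  maps;
- **LIME** — a distance-weighted linear surrogate over superpixel on/off
  perturbations.

The evaluation suite implements accuracy, log loss, precision, recall, F1,
Jaccard, per-class ROC/AUC with class-frequency-weighted AUC, and a
one-sample t test for comparing a model against a body of previously
reported accuracies.

## Worked example

Reproduce the statistical comparison of a proposed model (accuracy 0.9958)
against twenty previously reported accuracies (mean 0.9634, sd 0.0366):

```r
library(sobelnet)
one_sample_t(0.9958, 0.9634, 0.0366, 20, alternative = "greater")
#> 	One sample t-test (summary statistics)
#>
#> data:  x_bar = 0.9958 vs n = 20 prior values
#> t = 3.9589, df = 19, p-value = 0.0004208
```

The t statistic of 3.96 on 19 degrees of freedom says the proposed accuracy
sits almost four standard errors above the prior mean — a significant
improvement at any conventional level.

Generate a phantom, train the dual-branch model at desk scale, and evaluate:

```r
cfg <- phantom_config(seed = 42)
img <- generate_phantom("tumor", cfg, index = 0)
dim(img)                        # 64 64 3, with attr(img, "lesion_mask")
sum(attr(img, "lesion_mask"))   # 216 ground-truth lesion pixels

run <- run_pipeline(list(
  seed    = 7,
  phantom = list(n_tumor = 164, n_healthy = 136, image_size = 64, format = "png"),
  model   = list(img_size = 64, epochs = 15, learning_rate = 1e-3)
), out_dir = "desk_run")
```

On this 300-phantom corpus (class balance mirroring the 2,513/2,076 tumor/
healthy corpus the architecture was designed for) the run finishes in about
90 seconds on one CPU core and prints, via `metrics.json`:

```
confusion: TP 24  TN 20  FP 0  FN 0   (N = 44)
accuracy 1.0000  precision 1.0000  recall 1.0000  f1 1.0000  jaccard 1.0000
log loss 0.0001  weighted AUC 1.0000
```

i.e. the held-out test split (24 tumor, 20 healthy phantoms) is classified
perfectly — the phantom task is intensity-separable by construction, so
this is the expected ceiling, and the interesting check is *where* the model
looks: the Grad-CAM overlays written next to the report place the peak
relevance inside the ground-truth lesion disc on every tumor test phantom.

```r
autoplot(grad_cam(model, x, "tumor"))   # heatmap for one image
```

## Command-line use

A thin CLI over the same functions ships in `inst/cli/sobelnet`:

```sh
sobelnet generate --n-tumor 164 --n-healthy 136 --out data/
sobelnet split --source data/ --target split/ --ratios 0.7,0.15,0.15 --seed 42
sobelnet run --config run.yaml --out runs/exp1 --verbose
sobelnet version
```
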