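# cacpnet

Compact convolutional classifiers for plant leaf disease images, built by
combining **channel attention** and **structured channel pruning** around an
18-layer residual (ResNet-18-style) backbone.

Plant-disease identification models are routinely deployed on compute-limited
field equipment (drones, inspection robots), where a full ResNet-18 — 1.8
GFLOPs and 11.2M parameters per 224×224 image — is expensive. cacpnet
implements the two-step recipe for shrinking it without giving up accuracy:

1. **Improved efficient channel attention.** Each feature-map channel is gated
   by a weight in (0,1) computed from a per-channel global descriptor
   `G(x) = G_avg(x) + G_max(x)` (spatial mean **plus** maximum, so small
   lesion responses survive the pooling), mixed across neighbouring channels
   by a shared 1D convolution of adaptive odd size `k` (a band matrix across
   the channel axis; `k = 3` at 64 channels, `5` at 512) and squashed with a
   sigmoid: `ω = σ(Conv1D_k(G(x)))`. One module is attached after every 3×3
   convolution (stem included, projection shortcuts excluded) — 17 modules and
   only `Σk = 75` extra parameters on the default backbone.
2. **Norm-based structured channel pruning.** After training, output channels
   are ranked by the L1 norm of their filters; each basic block removes
   `P = floor(R·n)` channels per its local compression ratio, shallow blocks
   pruned less than deep ones (default schedule
   `R = 0,0,0.1,0.1,0.2,0.2,0.3,0.3`). Residual shortcuts stay consistent by
   *index sharing*: all block outputs in a stage (and the coupled stem for
   stage 1) share one surviving channel set, and the shortcut is pruned by
   `P_r = O_r − O_conv2`. The pruned architecture is rebuilt (not masked),
   weights are transferred by index selection, and the model is retrained.

The package also provides closed-form FLOPs/parameter/size profiling with a
forward-pass measurement cross-check, a seeded synthetic leaf-disease image
generator (healthy / scorch / rust / scorch+rust / leaf-spot), stratified 4:1
splitting and ×5 rotation/flip amplification, an SGD training and evaluation
harness (confusion matrix, macro precision/recall/F1, one-vs-rest ROC/AUC),
Grad-CAM heatmaps, and a one-call `run_pipeline()` implementing
attend → train → prune → retrain → report. A thin command-line front end
lives at `inst/cli/cacpnet.R` (subcommands `synth`, `train`, `prune`,
`retrain`, `profile`, `evaluate`, `gradcam`, `pipeline`).

## Worked example

Profile the 5-class baseline, attach attention, prune with the default
schedule, and profile again:

```r
library(cacpnet)

spec <- spec_peanut()                         # 18-layer backbone, 5 classes
profile_model(spec)
#> <cacp_complexity> 1.814 GFLOPs (mac) | 11.179 M params | 42.7 MiB | input 224

net  <- build_model(spec, seed = 1)
att  <- attach_attention(net, seed = 2)       # 17 modules, +75 parameters
profile_model(att)
#> <cacp_complexity> 1.814 GFLOPs (mac) | 11.179 M params | 42.7 MiB | input 224

plan <- make_pruning_plan(att, default_schedule(), norm_kind = "l1")
plan
#> <cacp_pruning_plan>
#>   schedule: 0, 0, 0.1, 0.1, 0.2, 0.2, 0.3, 0.3 | norm: l1
#>   stage widths: 64,128,256,512 -> 64,116,205,359

pruned <- apply_plan(att, plan)
profile_model(pruned)
#> <cacp_complexity> 1.399 GFLOPs (mac) | 6.192 M params | 23.6 MiB | input 224
```

1.814 GFLOPs is the multiply–accumulate count for convolutions and the head
(`include_elementwise = TRUE` adds batch-norm/rectifier/pooling elementwise
ops, giving 1.819); 11.179M counts conv weights, batch-norm affine terms and
the head; 42.7 MiB is 4 bytes per parameter and batch-norm buffer. Attention
is free at this precision. The pruned totals are the *achieved* values of the
per-block schedule; the originally published pruned model reports
1.267 GFLOPs / 4.699M / 18.0 MiB, which the literal schedule reading does not
reproduce — both are always emitted side by side (see
`reference_complexity()` and the methods vignette).

A desk-scale end-to-end run on generated data (64×64, 200 images per class,
narrow 16/32/64/128 backbone) takes a few CPU minutes:

```r
res <- run_pipeline(run_config(image_size = 64, n_per_class = 200,
                               stage_widths = c(16, 32, 64, 128),
                               epochs = 4, retrain_epochs = 3,
                               learning_rate = 0.01, seed = 1))
res
#> <cacp_pipeline>
#>   complexity: 0.011 -> 0.009 GFLOPs | 0.703 -> 0.395 M params | 2.7 -> 1.5 MiB
#>   reductions: gflops 18.72%, mparams 43.81%, size_mib 43.74%
#>   test accuracy: attended 1.000 | pruned+retrained 1.000
```

The pruned, retrained model keeps full accuracy on the synthetic five-class
task while dropping ~44% of its parameters.

## Scope

Training to the published accuracies on PlantVillage or the original peanut
photographs (external/unavailable data), GPU memory, inference-time and
throughput benchmarking, and comparator architectures are out of scope. See
`vignettes/cacpnet-methods.Rmd` for the full method description, parameter
choices and known limitations.
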