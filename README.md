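# msfseg — mis-segmentation-focused loss and two-stage training for 3D multi-label segmentation

`msfseg` is an R package for training and evaluating multi-label 3D tissue
segmentation models (brain-MRI style: adjacent, nested tissues with
overlapping intensity distributions) with an objective that explicitly
targets the regions the model currently gets wrong.

The core idea: a network trained on a *global* loss fits tissue interiors
easily and plateaus with persistent errors along ambiguous boundaries and in
small structures. After that coarse stage, `msfseg` extracts the
**mis-segmentation region** of each label — the symmetric difference between
the one-hot ground truth and the argmax prediction,

    Mn = (yn ∪ y'n) − (yn ∩ y'n),

dilates each `Mn` with a 6-connected elementary element (`factor` times,
default 2) and merges them into one binary error mask `Md` (a clamped
voxel-wise OR). Stage 2 then minimises

    L2 = L_Global + λ · L_MSF,      λ = 1 by default,

where both terms are the same deep-supervised compound loss

    L(y, y') = Σ_j a_j [ L_Dice(y_j, y'_j) + ω · L_CE(y_j, y'_j) ],
    a_j = 2^−(j−1) / Σ_k 2^−(k−1)   (a = 4/7, 2/7, 1/7 for 3 levels),

and `L_MSF` is that loss evaluated on `Md ⊙ y` and `Md ⊙ y'` — only the
error regions and their dilated surroundings contribute. Dice uses the
−2·Σty′/(Σt+Σy′+ε) sign convention (−1 is perfect); CE is per-element binary
cross-entropy with ε-clipping. Training uses Adam with an
exponential-moving-average plateau rule: if the EMA training loss has not
dropped by 5e-3 within the last 30 epochs, the learning rate is divided
by 5.

Everything runs on synthetic multi-label phantoms (nested ellipsoidal
shells with jittered boundaries and overlapping intensity distributions),
so the complete pipeline — phantom generation, two-stage training, Dice/HD95
evaluation — is exercisable on one CPU with no external data. The 3D CNN
(encoder–decoder with deep-supervision sigmoid heads) and its backward
passes are implemented in the package (im2col + BLAS GEMM via a small Rcpp
kernel) and verified against finite differences in the test suite.

## Worked example

```r
library(msfseg)

# 10 seeded phantoms: 24^3 voxels, 4 tissue classes, ambiguous boundaries
subs <- lapply(1:10, function(i)
  generate_phantom(phantom_spec(seed = i))[c("image", "labels")])

fit <- msf_train(subs[1:8],
                 schedule = "global_then_total",     # global stage, then +MSF
                 network  = network_preset("desk", n_labels = 4),
                 train    = train_preset("desk", stage1_epochs = 10,
                                         stage2_epochs = 10, seed = 1))
summary(fit)
#> Two-stage mis-seg-focused segmentation model ('global_then_total')
#>   stage 1: 10 epochs | loss 0.2282 -> -0.5044 | monitor Dice 0.4391 -> 0.6789 | mis-seg 13790 -> 3414
#>   stage 2: 10 epochs | loss -1.1513 -> -1.6887 | monitor Dice 0.6806 -> 0.7141 | mis-seg 3331 -> 1916
#>   lambda 1 | omega 1 | dilation 2 | dn 3 | lr decays: 0

pred <- predict(fit, subs[[9]]$image)
evaluate(subs[[9]]$labels, pred)
#> <eval_report>
#>  label      dice     hd95
#>      0 0.9843947 1.000000
#>      1 0.9314747 1.000000
#>      2 0.8867574 2.236068
#>      3 0.0000000       NA
#>   mean Dice 0.7007 | mean HD95 1.4120 | mis-seg voxels 638
```

The numbers above are what this exact script prints at these desk-scale
settings. The loss scale changes between stages because the stage-2
objective gains the λ·L_MSF term; `misseg_voxels` tracks the monitoring
subset's total disagreement count, the quantity stage 2 is designed to
shrink (13790 → 3414 during stage 1, down to 1916 by the end of stage 2).
The tiny core structure (label 3, under 2% of voxels) is the hardest class
and is still unsolved at this very short 10+10-epoch schedule — its HD95 is
undefined (`NA`) because the predicted mask is empty. The longer desk
schedule used by the acceptance experiment (30+30 epochs) partially learns
it, and refining with the MSF term is what lifts it further.

Region extraction and the losses are usable directly:

```r
gt <- label_volume(array(0L, c(8, 8, 8)), n_labels = 2)
pr <- gt; pr$data[4, 4, 4] <- 1L
r <- extract_misseg(gt, pr, factor = 2)
sum(r$merged)          # 25: one flipped voxel, dilated twice (6-connected)
ds_weights(3)          # 0.571... 0.285... 0.142...  (4/7, 2/7, 1/7)
```

A thin command-line interface wraps the same functions
(`inst/cli/msfseg`): subcommands `generate`, `train`, `evaluate`, `misseg`
and `experiment`, with a YAML run configuration (`load_config()` validates
it and rejects unknown keys).

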