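# dpfnet

Dual-path fusion network (DPF-Net) for volumetric segmentation of
intracranial aneurysms, implemented entirely in R with compiled (Rcpp)
convolution kernels — no external deep-learning runtime.

Intracranial aneurysms occupy well under 0.2% of the voxels of a 3D
rotational DSA volume and share the intensity of their parent vessels.
Encoder–decoder networks lose the fine detail that separates a small
bleb from the vessel it sits on. DPF-Net pairs a down-sampling
**semantic branch** with a full-resolution **detail branch**, exchanges
information between them through **cross-fusion modules**, condenses the
detail stream with a 1/3/5/7 kernel-pyramid **detail aggregation
module**, and trains with deep-supervised soft Dice loss:

    DL(ŷ, y)  = 1 − 2·|y ∩ ŷ| / (|y| + |ŷ|)
    loss      = DL(ŷ_main) + β₁·DL(ŷ_aux_sem) + β₂·DL(ŷ_aux_det)

Training samples patches from the axial, coronal and sagittal
permutations of each volume; at test time per-view sliding-window
predictions are fused by majority vote (or mean probability) and
connected components under 10 voxels are discarded. Evaluation reports
DSC / Precision / Recall / IoU on complete scans, stratified by lesion
size (Small < 5 mm ≤ Medium < 15 mm ≤ Large, equivalent-sphere
diameter).

The package also ships a synthetic vascular **phantom generator**
(bright spline-tube vessels plus millimetre-scale ellipsoidal aneurysm
blebs on a dark noisy background) so the complete pipeline — I/O,
training, inference, evaluation — runs and is tested without clinical
data.

## Worked example

```r
library(dpfnet)

# the reference architecture and its parameter budget
cfg <- network_config()          # widths (12, 24, 49), Cd = 12
count_parameters(cfg)
#> $count
#> [1] 380924
#> $storage_mb
#> [1] 1.45

# a synthetic DSA-like case: 96^3 voxels at 0.5 mm, one 3-6 mm aneurysm
spec <- phantom_spec()
cs <- generate_phantom_case(spec, seed = 1)
cs$mask
#> <dpf_mask> 96 x 96 x 96 | spacing 0.5 x 0.5 x 0.5 mm | labels {0, 1} | foreground 90 voxels
cs$aneurysm_diameters   # realized equivalent-sphere diameter, mm
#> [1] 2.780042
stratify_by_diameter(cs$mask)
#> [1] "Small"

# desk-scale training (widths (4, 8, 16), patch 32^3, 300 iterations;
# minutes on one CPU) and three-view majority-vote inference
cases <- lapply(1:10, function(i) generate_phantom_case(spec, seed = i))
net <- network_config(semantic_widths = c(4L, 8L, 16L), detail_width = 4L,
                      patch_size = 32L)
model <- train_dpfnet(cases, net,
                      train_config(lr0 = 3e-3, total_iterations = 300L,
                                   patch_size = 32L, seed = 1L))
held_out <- generate_phantom_case(spec, seed = 99)
pred <- predict_case(held_out$image, model, fusion = "mv", stride = 24L)
round(unlist(segmentation_metrics(pred, held_out$mask)), 3)
#>       dsc precision    recall       iou
#>     0.647     0.479     0.995     0.478
```

A 300-iteration CPU run recovers the aneurysm almost completely
(recall 0.995) while still over-calling some vessel voxels
(precision 0.48) — the expected behaviour of a heavily scaled-down
training budget; the 30-case configuration used by the test suite
reaches a held-out mean DSC of about 0.64.

The parameter count enumerates every learnable array (conv and
transposed-conv kernels, instance-norm scale/shift pairs, logit biases);
`storage_mb` is float32 bytes in 2^20-byte MB — the default widths are
calibrated so this rounds to 1.45. The phantom's mask stores only the
aneurysm bleb (vessels are background), which is why 90 foreground
voxels in an 884,736-voxel volume ≈ 0.01% foreground.

A command-line wrapper over the same functions lives at
`inst/cli/dpfnet.R` (verbs `simulate`, `folds`, `train`, `predict`,
`evaluate`); ready-made YAML profiles are under `inst/configs/`.

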