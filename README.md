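# attnkd

Attention-guided localization and decoupled knowledge distillation for
fine-grained image classification, in R.

Fine-grained recognition (bird species being the canonical case) has to
separate classes that differ only in local markings, from limited data,
with models small enough to deploy in the field. `attnkd` implements the
two techniques this calls for, as composable, unit-tested primitives:

* **Attention-guided augmentation and localization–recognition.** The
  channel sum of a backbone's final feature stack is a spatial attention
  map `A`. Thresholding `A` at its mean, boxing the largest 8-connected
  component, and rescaling to image pixels localizes the object without
  any box supervision; sliding windows ranked by mean attention locate
  key parts. Object and part crops augment training, and at test time the
  prediction comes from the object crop (localize, then recognize),
  suppressing background.

* **Decoupled knowledge distillation (DKD).** Classical logit
  distillation `KD = KL(P^T ‖ P^S)` at temperature `T` decomposes exactly
  into a target term and a non-target term,

  ```
  KD = TCKD + (1 − p_t^T) · NCKD
  ```

  so a confident teacher (`p_t^T → 1`) mutes exactly the non-target term
  that carries inter-class similarity. DKD replaces the coupled weight
  with a free one: `DKD = TCKD + α · NCKD` (defaults `T = 4`, `α = 2`).

Around the core: multi-branch teacher and five-stream student training
loops on a small built-in CNN, an analytic parameter/MAC profiler with
exact layer tables for DenseNet121 and ShuffleNetV2 ×1.0, macro-averaged
accuracy/precision/recall/F1, a synthetic-fixture generator with planted
objects/parts and ground-truth boxes, CUB-200-2011-style and
class-per-folder dataset readers, and a small CLI
(`inst/cli/attnkd`).

## Worked example

```r
library(attnkd)

## DKD on a 5-class logit pair: confident teacher, uncertain student
zt <- c(6, 3, 1, 0, 0)          # teacher logits, target class 0
zs <- c(2, 2.5, 0.5, 0, -1)     # student logits
b <- dkd_loss(zt, zs, target = 0, T = 4, alpha = 2)
str(b[c("tckd", "nckd", "teacher_pt", "total")])
#> $ tckd      : num 0.0902
#> $ nckd      : num 0.00289
#> $ teacher_pt: num 0.453
#> $ total     : num 0.096
kd_loss(zt, zs, T = 4)          # classical KD = TCKD + (1 - pt) * NCKD
#> [1] 0.09182
```

`total` is `tckd + 2 * nckd`; with the coupled weight `1 − 0.453` instead
of 2 you recover the classical value 0.09182 — the decomposition the
whole module is built around.

```r
## Localize a planted object by attention
s <- gen_blob_image(fixture_params(), seed = 42)
box <- localize_object(s$image, intensity_backbone())
unclass(box)
#> x0 y0 x1 y1
#> 16 14 62 54
iou(box, s$object_box)
#> [1] 1
```

The recovered box equals the generator's ground truth here; across 200
seeded fixtures the mean IoU is ≈ 0.95.

```r
## Profile the student architecture
profile_architecture(arch_shufflenet_v2_x10())
#> shufflenet_v2_x1.0 @ 448x448: 2,278,604 params (trunk 1,253,604, head 1,025,000), 576.6 M MACs
```

Against the DenseNet121 trunk (6,953,856 parameters) that is a 67%
parameter reduction — the compression the teacher/student pairing is
designed to deliver.

Training at desk scale:

```r
ds  <- gen_dataset(fixture_params(n_classes = 5, n_samples = 40, seed = 7))
cfg <- tiny_train_config(seed = 1)
teacher <- train_teacher(tiny_cnn(5), ds, cfg)$model
student <- distill_student(tiny_cnn_student(5), teacher, ds, cfg)$student
predict_image(student, ds$samples[[2]]$image)$label
```

See `vignette("methods", package = "attnkd")` for the model, the
numerical conventions, and the design rationale.

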