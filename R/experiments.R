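#' Numerical check of the distillation decomposition identity
#'
#' Draws random teacher/student logit pairs (including near-one-hot
#' teachers) across a range of class counts and temperatures and returns
#' the largest absolute deviation of `KD - (TCKD + (1 - p_t^T) * NCKD)`,
#' which is zero in exact arithmetic.
#'
#' @param n Number of logit pairs (default 10000).
#' @param C_range Range of class counts to draw from (default 2--200).
#' @param T_list Temperatures to evaluate (default 1, 2, 4).
#' @param seed Integer seed.
#' @return A list: `max_abs_error`, `n_pairs`, `n_evaluations`,
#'   `max_teacher_pt` (largest raw-softmax teacher target probability seen,
#'   to confirm the confident regime was exercised).
#' @export
dkd_identity_check <- function(n = 10000L, C_range = c(2L, 200L),
                               T_list = c(1, 2, 4), seed = 1L) {
  worst <- 0
  max_pt <- 0
  n_eval <- 0L
  chunk <- 500L
  done <- 0L
  idx <- 0L
  while (done < n) {
    idx <- idx + 1L
    C <- with_seed(seed + 7L * idx,
                   sample(seq(C_range[1], C_range[2]), 1L))
    m <- min(chunk, n - done)
    pairs <- gen_logit_pairs(C, m, seed = seed + 1000L * idx)
    for (p in pairs) {
      max_pt <- max(max_pt, softmax_t(p$z_teacher, 1)[p$target + 1L])
      for (temp in T_list) {
        b <- dkd_loss(p$z_teacher, p$z_student, p$target, T = temp, alpha = 1)
        err <- abs(kd_loss(p$z_teacher, p$z_student, temp) -
                     (b$tckd + (1 - b$teacher_pt) * b$nckd))
        worst <- max(worst, err)
        n_eval <- n_eval + 1L
      }
    }
    done <- done + m
  }
  list(max_abs_error = worst, n_pairs = done, n_evaluations = n_eval,
       max_teacher_pt = max_pt)
}

#' Localization recovery on planted-object fixtures
#'
#' Generates `n` seeded synthetic samples and measures the IoU between the
#' attention-recovered object box and the planted ground truth under the
#' given backbone.
#'
#' @param n Number of samples (default 200).
#' @param params [fixture_params()] controlling the image ensemble.
#' @param model Backbone used for localization (default
#'   [intensity_backbone()]).
#' @param seed_base Sample i uses seed `seed_base + i`.
#' @return A data frame with columns `seed` and `iou`; attribute
#'   `pass_rate` gives the fraction with IoU >= 0.8.
#' @export
evaluate_localization <- function(n = 200L, params = fixture_params(),
                                  model = intensity_backbone(),
                                  seed_base = 1000L) {
  ious <- vapply(seq_len(n), function(i) {
    s <- gen_blob_image(params, seed = seed_base + i)
    iou(localize_object(s$image, model), s$object_box)
  }, 0)
  out <- data.frame(seed = seed_base + seq_len(n), iou = ious)
  attr(out, "pass_rate") <- mean(ious >= 0.8)
  out
}

#' Scaled-down distillation ablation
#'
#' Mirrors the knowledge-distillation ablation at desk scale: a teacher is
#' trained on a synthetic fine-grained task, then students are distilled
#' under three regimes -- no distillation, classical logit distillation
#' (coupled `1 - p_t^T` non-target weight), and decoupled distillation
#' with `alpha = 2` -- over several seeds, reporting the training-set
#' accuracy of each final student measured deterministically (raw-image
#' forward, no augmentation).
#'
#' Geometry and schedules are fixed desk-scale choices: 48-px images, 5
#' classes, 20 training images; teacher 15 epochs at lr 0.01; students 30
#' epochs at lr 0.003 with milestones 18 and 25.
#'
#' @param n_seeds Student seeds per regime (default 5).
#' @param seed Base seed; dataset, teacher, and student seeds derive from
#'   it.
#' @param modes Regimes to run (default all three).
#' @return A list: `accuracy` (matrix of per-seed train accuracies, one
#'   row per mode), `medians` (named vector), `teacher_train_accuracy`.
#' @export
distillation_experiment <- function(n_seeds = 5L, seed = 7L,
                                    modes = c("none", "kd", "dkd")) {
  fp <- fixture_params(image_size = 48L, n_classes = 5L, n_samples = 40L,
                       seed = seed)
  ds <- gen_dataset(fp)
  train <- ds$samples[ds$split == "train"]
  tcfg <- tiny_train_config(seed = seed + 4L, epochs = 15L,
                            lr_milestones = c(10L), lr0 = 0.01,
                            raw_size = 48L, object_size = 48L, part_size = 24L)
  teacher <- train_teacher(tiny_cnn(fp$n_classes, seed = seed + 4L), ds, tcfg)$model
  train_acc <- function(model) mean(vapply(train, function(s)
    which.max(classify(model, s$image)) - 1L == s$label, logical(1)))
  acc <- matrix(NA_real_, length(modes), n_seeds,
                dimnames = list(modes, NULL))
  for (mode in modes) {
    for (k in seq_len(n_seeds)) {
      scfg <- tiny_train_config(seed = seed + 193L + k, soft_mode = mode,
                                lr0 = 0.003, epochs = 30L,
                                lr_milestones = c(18L, 25L), raw_size = 48L,
                                object_size = 48L, part_size = 24L)
      st <- tiny_cnn_student(fp$n_classes, seed = seed + 193L + k)
      acc[mode, k] <- train_acc(distill_student(st, teacher, ds, scfg)$student)
    }
  }
  list(accuracy = acc,
       medians = apply(acc, 1, stats::median),
       teacher_train_accuracy = train_acc(teacher))
}
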