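#' Training configuration
#'
#' Bundles every knob of teacher training and student distillation. The
#' full-scale defaults follow the reference recipe: SGD with momentum 0.9
#' and weight decay 1e-4, 120 epochs with the learning rate cut to 0.1x at
#' epochs 60 and 100, raw/object inputs at 448 px and part inputs at
#' 224 px, distillation temperature T = 4 and non-target weight alpha = 2.
#' [tiny_train_config()] scales the geometry down to the 64-px synthetic
#' fixtures and the built-in [tiny_cnn()].
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Images per SGD step.
#' @param lr0 Initial learning rate (> 0).
#' @param momentum,weight_decay SGD hyperparameters.
#' @param lr_milestones Strictly increasing epoch indices at which the rate
#'   drops; must be < `epochs`.
#' @param lr_gamma Multiplicative drop factor.
#' @param T Distillation temperature.
#' @param alpha Non-target (NCKD) weight.
#' @param soft_mode `"dkd"`, `"kd"`, or `"none"` -- see
#'   [student_total_loss()].
#' @param raw_size,object_size,part_size Input sizes in pixels.
#' @param window_fracs Part-window sides as fractions of the attention-map
#'   side.
#' @param stride Sliding-window stride in map cells.
#' @param max_iou Window-suppression IoU threshold.
#' @param top_n Part windows kept per image (0 disables the part branch).
#' @param augment Apply random horizontal flip and brightness/contrast
#'   jitter to the raw image (crops inherit it).
#' @param seed Run seed; all randomness flows from it.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 120L, batch_size = 4L, lr0 = 0.001,
                         momentum = 0.9, weight_decay = 1e-4,
                         lr_milestones = c(60L, 100L), lr_gamma = 0.1,
                         T = 4, alpha = 2, soft_mode = "dkd",
                         raw_size = 448L, object_size = 448L, part_size = 224L,
                         window_fracs = c(1/2, 1/3, 1/4), stride = 1L,
                         max_iou = 0.25, top_n = 2L, augment = TRUE,
                         seed = 1L) {
  stopifnot(epochs >= 1L, lr0 > 0, batch_size >= 1L,
            all(diff(lr_milestones) > 0), all(lr_milestones < epochs) ||
              length(lr_milestones) == 0L,
            T > 0, alpha >= 0, top_n >= 0L,
            soft_mode %in% c("dkd", "kd", "none"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, momentum = momentum, weight_decay = weight_decay,
                 lr_milestones = as.integer(lr_milestones), lr_gamma = lr_gamma,
                 T = T, alpha = alpha, soft_mode = soft_mode,
                 raw_size = as.integer(raw_size),
                 object_size = as.integer(object_size),
                 part_size = as.integer(part_size),
                 window_fracs = window_fracs, stride = as.integer(stride),
                 max_iou = max_iou, top_n = as.integer(top_n),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed on to [train_config()].
#' @export
tiny_train_config <- function(epochs = 30L, batch_size = 4L, lr0 = 0.01,
                              lr_milestones = c(15L, 25L),
                              raw_size = 64L, object_size = 64L,
                              part_size = 32L, top_n = 1L, ...) {
  train_config(epochs = epochs, batch_size = batch_size, lr0 = lr0,
               lr_milestones = lr_milestones, raw_size = raw_size,
               object_size = object_size, part_size = part_size,
               top_n = top_n, ...)
}

#' Learning rate at a given epoch
#'
#' `lr0 * lr_gamma ^ (number of milestones already reached)`: the rate
#' drops exactly at each milestone epoch.
#'
#' @param config A [train_config()].
#' @param epoch 1-based epoch index.
#' @return The learning rate.
#' @export
lr_schedule <- function(config, epoch) {
  config$lr0 * config$lr_gamma^sum(epoch >= config$lr_milestones)
}

# Random horizontal flip plus brightness/contrast jitter; consumes RNG.
augment_image <- function(img) {
  if (runif(1) < 0.5) img <- img[, dim(img)[2]:1, , drop = FALSE]
  img <- (img - 0.5) * runif(1, 0.8, 1.2) + 0.5 + runif(1, -0.15, 0.15)
  pmin(pmax(img, 0), 1)
}

# SGD with momentum and decoupled-from-nothing classic weight decay:
# v <- mu v + g + wd p ; p <- p - lr v
sgd_step <- function(params, grads, vel, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    vel[[nm]] <- momentum * vel[[nm]] + g
    params[[nm]] <- params[[nm]] - lr * vel[[nm]]
  }
  list(params = params, vel = vel)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

# Normalize dataset input: a "synthetic_dataset" (train split only) or a
# plain list of list(image, label).
as_sample_list <- function(dataset) {
  if (inherits(dataset, "synthetic_dataset"))
    dataset$samples[dataset$split == "train"]
  else dataset
}

# Attention-guided augmentation under `model`: object crop and part crops
# of `img`, with the boxes that produced them.
build_aug_streams <- function(model, img, config, raw_cache = NULL) {
  fwd <- raw_cache %||% tiny_cnn_forward(model, img, keep_cache = TRUE)
  amap <- compute_attention_map(fwd$features)
  mask <- binarize(amap, attention_threshold(amap))
  d <- dim(img)
  box <- tryCatch(
    map_box_to_image(largest_component_bbox(mask), dim(amap), d[1:2]),
    attnkd_empty_mask = function(e) bbox(0L, 0L, d[2], d[1]))
  obj <- crop_and_resize(img, box, config$object_size)
  parts <- list()
  if (config$top_n > 0L) {
    ofwd <- tiny_cnn_forward(model, obj)
    oamap <- compute_attention_map(ofwd$features)
    sizes <- default_window_sizes(dim(oamap), config$window_fracs)
    sel <- select_part_windows(
      propose_part_windows(oamap, sizes, config$stride),
      max_iou = config$max_iou, top_n = config$top_n)
    if (nrow(sel) > 0L)
      parts <- lapply(seq_len(nrow(sel)), function(i) {
        pb <- map_box_to_image(bbox(sel$x0[i], sel$y0[i], sel$x1[i], sel$y1[i]),
                               dim(oamap), dim(obj)[1:2])
        crop_and_resize(obj, pb, config$part_size)
      })
  }
  list(raw_fwd = fwd, object_box = box, object = obj, parts = parts)
}

#' One epoch of multi-branch teacher training
#'
#' For each image: forward the (augmented) raw image, derive the object
#' crop and part crops from the model's own attention, forward each
#' branch, and take one SGD step per mini-batch on the summed branch
#' cross-entropies (mean over the batch). Box coordinates are a
#' non-differentiable spatial selection; gradients flow through crop
#' contents only.
#'
#' @param model A [tiny_cnn()].
#' @param dataset A `"synthetic_dataset"` or list of `list(image, label)`.
#' @param config A [train_config()].
#' @param epoch 1-based epoch index (sets the learning rate).
#' @param vel Optional momentum state from the previous epoch.
#' @return A list: `model` (updated), `vel`, and `record` -- epoch, mean
#'   `l_r`, `l_o`, `l_p`, `l_total`, `lr`, `train_accuracy` (fraction of
#'   object-branch predictions that were correct).
#' @export
teacher_train_epoch <- function(model, dataset, config, epoch = 1L,
                                vel = NULL) {
  samples <- as_sample_list(dataset)
  n <- length(samples)
  if (n == 0L) stop_invalid("empty dataset")
  vel <- vel %||% zero_like(model$params)
  lr <- lr_schedule(config, epoch)
  order <- sample.int(n)
  losses <- matrix(0, n, 4)
  correct <- logical(n)
  pos <- 1L
  for (start in seq(1L, n, by = config$batch_size)) {
    idx <- order[start:min(start + config$batch_size - 1L, n)]
    gacc <- zero_like(model$params)
    for (i in idx) {
      s <- samples[[i]]
      img <- s$image
      if (any(dim(img)[1:2] != config$raw_size))
        img <- resize_image(img, config$raw_size, config$raw_size)
      if (config$augment) img <- augment_image(img)
      aug <- build_aug_streams(model, img, config)
      fwd_o <- tiny_cnn_forward(model, aug$object, keep_cache = TRUE)
      fwd_p <- lapply(aug$parts, tiny_cnn_forward, model = model,
                      keep_cache = TRUE)
      bundle <- teacher_total_loss(
        softmax_t(aug$raw_fwd$logits, 1), softmax_t(fwd_o$logits, 1),
        lapply(fwd_p, function(f) softmax_t(f$logits, 1)), s$label)
      losses[pos, ] <- c(bundle$l_r, bundle$l_o, bundle$l_p, bundle$l_total)
      correct[pos] <- which.max(fwd_o$logits) - 1L == s$label
      pos <- pos + 1L
      for (f in c(list(aug$raw_fwd, fwd_o), fwd_p))
        gacc <- add_grads(gacc, tiny_cnn_backward(
          model, f$cache, ce_grad(f$logits, s$label)))
    }
    gacc <- lapply(gacc, `/`, length(idx))
    st <- sgd_step(model$params, gacc, vel, lr, config$momentum,
                   config$weight_decay)
    model$params <- st$params
    vel <- st$vel
  }
  record <- list(epoch = epoch, l_r = mean(losses[, 1]), l_o = mean(losses[, 2]),
                 l_p = mean(losses[, 3]), l_total = mean(losses[, 4]),
                 lr = lr, train_accuracy = mean(correct))
  list(model = model, vel = vel, record = record)
}

#' Train a teacher model
#'
#' Runs [teacher_train_epoch()] for `config$epochs` epochs under
#' `config$seed`.
#'
#' @inheritParams teacher_train_epoch
#' @return A list: `model` (trained) and `history`, a data frame of epoch
#'   records.
#' @export
train_teacher <- function(model, dataset, config) {
  set.seed(config$seed)
  vel <- NULL
  history <- vector("list", config$epochs)
  for (e in seq_len(config$epochs)) {
    out <- teacher_train_epoch(model, dataset, config, epoch = e, vel = vel)
    model <- out$model
    vel <- out$vel
    history[[e]] <- as.data.frame(out$record)
  }
  list(model = model, history = do.call(rbind, history))
}

#' One epoch of student distillation
#'
#' Five image streams per sample: the augmented raw image, the object and
#' part crops under the (frozen) teacher's attention, and the object and
#' part crops under the student's own attention -- the two backbones
#' attend differently, so their crops differ. Both models predict every
#' stream; the student's loss sums per-stream hard cross-entropy and the
#' per-stream decoupled (or classical, per `config$soft_mode`)
#' distillation loss against the teacher's logits on the same stream. Only
#' the student takes gradient steps.
#'
#' @param student,teacher [tiny_cnn()] models with the same class count;
#'   the teacher is used in inference mode only.
#' @inheritParams teacher_train_epoch
#' @return A list: `student`, `vel`, and `record` with mean `l_hard`,
#'   `l_soft`, `l_total`, diagnostic means `tckd_mean`, `nckd_mean`,
#'   `teacher_pt_mean`, `lr`, and `train_accuracy` (student object-crop
#'   predictions).
#' @export
student_distill_epoch <- function(student, teacher, dataset, config,
                                  epoch = 1L, vel = NULL) {
  if (student$spec$num_classes != teacher$spec$num_classes)
    stop_invalid("teacher and student class counts differ")
  samples <- as_sample_list(dataset)
  n <- length(samples)
  if (n == 0L) stop_invalid("empty dataset")
  vel <- vel %||% zero_like(student$params)
  lr <- lr_schedule(config, epoch)
  order <- sample.int(n)
  recs <- matrix(0, n, 6)
  correct <- logical(n)
  pos <- 1L
  for (start in seq(1L, n, by = config$batch_size)) {
    idx <- order[start:min(start + config$batch_size - 1L, n)]
    gacc <- zero_like(student$params)
    for (i in idx) {
      s <- samples[[i]]
      img <- s$image
      if (any(dim(img)[1:2] != config$raw_size))
        img <- resize_image(img, config$raw_size, config$raw_size)
      if (config$augment) img <- augment_image(img)
      t_aug <- build_aug_streams(teacher, img, config)
      s_aug <- build_aug_streams(student, img, config)
      stream_imgs <- c(list(img), list(t_aug$object), t_aug$parts,
                       list(s_aug$object), s_aug$parts)
      streams <- vector("list", length(stream_imgs))
      for (k in seq_along(stream_imgs)) {
        sf <- if (k == 1L) s_aug$raw_fwd else
          tiny_cnn_forward(student, stream_imgs[[k]], keep_cache = TRUE)
        zt <- if (k == 1L) t_aug$raw_fwd$logits else
          tiny_cnn_forward(teacher, stream_imgs[[k]])$logits
        streams[[k]] <- list(z_student = sf$logits, z_teacher = zt,
                             label = s$label)
        dz <- ce_grad(sf$logits, s$label)
        if (config$soft_mode != "none")
          dz <- dz + dkd_grad_student(zt, sf$logits, s$label, T = config$T,
                                      alpha = config$alpha,
                                      soft_mode = config$soft_mode)
        gacc <- add_grads(gacc, tiny_cnn_backward(student, sf$cache, dz))
        if (k == 3L + length(t_aug$parts))  # student-attention object stream
          correct[pos] <- which.max(sf$logits) - 1L == s$label
      }
      bundle <- student_total_loss(streams, T = config$T, alpha = config$alpha,
                                   soft_mode = config$soft_mode)
      recs[pos, ] <- c(bundle$l_hard, bundle$l_soft, bundle$l_total,
                       bundle$tckd_mean, bundle$nckd_mean,
                       if (is.na(bundle$teacher_pt_mean)) 0 else
                         bundle$teacher_pt_mean)
      pos <- pos + 1L
    }
    gacc <- lapply(gacc, `/`, length(idx))
    st <- sgd_step(student$params, gacc, vel, lr, config$momentum,
                   config$weight_decay)
    student$params <- st$params
    vel <- st$vel
  }
  record <- list(epoch = epoch, l_hard = mean(recs[, 1]),
                 l_soft = mean(recs[, 2]), l_total = mean(recs[, 3]),
                 tckd_mean = mean(recs[, 4]), nckd_mean = mean(recs[, 5]),
                 teacher_pt_mean = mean(recs[, 6]), lr = lr,
                 train_accuracy = mean(correct))
  list(student = student, vel = vel, record = record)
}

#' Distill a student from a frozen teacher
#'
#' @inheritParams student_distill_epoch
#' @return A list: `student` (trained) and `history` data frame.
#' @export
distill_student <- function(student, teacher, dataset, config) {
  set.seed(config$seed)
  vel <- NULL
  history <- vector("list", config$epochs)
  for (e in seq_len(config$epochs)) {
    out <- student_distill_epoch(student, teacher, dataset, config,
                                 epoch = e, vel = vel)
    student <- out$student
    vel <- out$vel
    history[[e]] <- as.data.frame(out$record)
  }
  list(student = student, history = do.call(rbind, history))
}

#' Localization-recognition prediction
#'
#' Forward the raw image to localize the object via attention, crop and
#' resample the object region, and classify the crop; the object-crop
#' prediction is the final prediction. Part branches are not used at test
#' time.
#'
#' @param model A classifier backbone.
#' @param image `(H, W, 3)` array.
#' @param object_size Side of the resampled object crop.
#' @return A list: `label` (0-based argmax), `probs` (softmax at T = 1),
#'   `object_box` (the attention-derived [bbox()]).
#' @export
predict_image <- function(model, image, object_size = 64L) {
  box <- localize_object(image, model)
  logits <- classify(model, crop_and_resize(image, box, object_size))
  probs <- softmax_t(logits, 1)
  list(label = which.max(logits) - 1L, probs = probs, object_box = box)
}

#' Write an epoch history to CSV
#'
#' @param history Data frame of epoch records.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_history_csv <- function(history, file) {
  write.csv(history, file, row.names = FALSE)
  invisible(file)
}

#' Save and load model checkpoints
#'
#' Checkpoints bundle the weights, the configuration, and the epoch.
#'
#' @param model A model object.
#' @param config A [train_config()].
#' @param epoch Epoch index the checkpoint corresponds to.
#' @param file Path (RDS).
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` a list
#'   with `model`, `config`, `epoch`.
#' @export
save_checkpoint <- function(model, config, epoch, file) {
  saveRDS(list(model = model, config = config, epoch = epoch), file)
  invisible(file)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(file) readRDS(file)
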