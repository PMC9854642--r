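# Small shared fixtures for the training loops
make_tiny_task <- function(n_classes = 3L, n_samples = 12L, seed = 21L,
                           image_size = 32L) {
  gen_dataset(fixture_params(image_size = image_size, n_classes = n_classes,
                             n_samples = n_samples, seed = seed))
}
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(raw_size = 32L, object_size = 32L, part_size = 16L, epochs = 2L,
         lr_milestones = integer(0)),
    list(...))
  do.call(tiny_train_config, args)
}

test_that("learning-rate schedule drops by gamma exactly at milestones", {
  cfg <- train_config(epochs = 120L, lr0 = 0.001,
                      lr_milestones = c(60L, 100L), lr_gamma = 0.1)
  lrs <- vapply(1:120, function(e) lr_schedule(cfg, e), 0)
  expect_equal(unique(lrs[1:59]), 0.001)
  expect_equal(unique(lrs[60:99]), 0.001 * 0.1)
  expect_equal(unique(lrs[100:120]), 0.001 * 0.01)
  expect_equal(lrs, cfg$lr0 * cfg$lr_gamma^vapply(
    1:120, function(e) sum(e >= cfg$lr_milestones), 0))
})

test_that("zero learning rate leaves parameters untouched", {
  ds <- make_tiny_task()
  cfg <- tiny_cfg(seed = 1L)
  cfg$lr0 <- 1e-300  # smallest admissible stand-in for a zero step
  m <- tiny_cnn(3, seed = 2)
  set.seed(1)
  out <- teacher_train_epoch(m, ds, cfg)
  for (nm in names(m$params))
    expect_equal(out$model$params[[nm]], m$params[[nm]], tolerance = 1e-12)

  st <- tiny_cnn_student(3, seed = 3)
  set.seed(1)
  out2 <- student_distill_epoch(st, m, ds, cfg)
  for (nm in names(st$params))
    expect_equal(out2$student$params[[nm]], st$params[[nm]], tolerance = 1e-12)
})

test_that("fixed seeds make whole training runs bit-reproducible", {
  ds <- make_tiny_task()
  cfg <- tiny_cfg(seed = 5L, epochs = 2L)
  r1 <- train_teacher(tiny_cnn(3, seed = 9), ds, cfg)
  r2 <- train_teacher(tiny_cnn(3, seed = 9), ds, cfg)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$history, r2$history)

  d1 <- distill_student(tiny_cnn_student(3, seed = 4), r1$model, ds, cfg)
  d2 <- distill_student(tiny_cnn_student(3, seed = 4), r2$model, ds, cfg)
  expect_identical(d1$student$params, d2$student$params)
})

test_that("teacher weights are bit-identical before and after distillation", {
  ds <- make_tiny_task()
  cfg <- tiny_cfg(seed = 6L)
  teacher <- tiny_cnn(3, seed = 10)
  before <- teacher$params
  invisible(distill_student(tiny_cnn_student(3, seed = 2), teacher, ds, cfg))
  expect_identical(teacher$params, before)
})

test_that("disabling the part branch empties l_p and the part streams", {
  ds <- make_tiny_task()
  cfg <- tiny_cfg(seed = 3L, top_n = 0L, epochs = 1L)
  out <- teacher_train_epoch(tiny_cnn(3, seed = 2), ds, cfg)
  expect_equal(out$record$l_p, 0)
  expect_equal(out$record$l_total, out$record$l_r + out$record$l_o,
               tolerance = 1e-12)
})

test_that("identical student and teacher give zero soft loss", {
  ds <- make_tiny_task()
  cfg <- tiny_cfg(seed = 8L, epochs = 1L)
  cfg$lr0 <- 1e-300
  m <- tiny_cnn(3, seed = 12)
  out <- student_distill_epoch(m, m, ds, cfg)
  expect_lt(out$record$l_soft, 1e-9)
})

test_that("teacher training improves accuracy on a small synthetic task", {
  ds <- make_tiny_task(n_classes = 3L, n_samples = 18L, seed = 33L,
                       image_size = 48L)
  cfg <- tiny_train_config(raw_size = 48L, object_size = 48L, part_size = 24L,
                           epochs = 12L, lr_milestones = c(9L), lr0 = 0.01,
                           seed = 2L)
  res <- train_teacher(tiny_cnn(3, seed = 7), ds, cfg)
  expect_gt(tail(res$history$train_accuracy, 1),
            res$history$train_accuracy[1])
  expect_gt(tail(res$history$train_accuracy, 1), 0.5)
  expect_lt(tail(res$history$l_total, 1), res$history$l_total[1])
})

test_that("prediction is localization-then-recognition and deterministic", {
  m <- tiny_cnn(3, seed = 14)
  img <- random_image(32, 32, seed = 15)
  p1 <- predict_image(m, img, object_size = 32L)
  p2 <- predict_image(m, img, object_size = 32L)
  expect_identical(p1, p2)
  expect_equal(p1$label, which.max(p1$probs) - 1L)
  expect_s3_class(p1$object_box, "bbox")

  # constant-logit model: prediction invariant to localization
  m0 <- tiny_cnn(3, seed = 14)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "Wfc"))
    m0$params[[nm]] <- m0$params[[nm]] * 0
  m0$params$bfc <- c(0.1, 0.9, 0.2)
  expect_equal(predict_image(m0, img, 32L)$label, 1L)
  expect_equal(predict_image(m0, random_image(32, 32, 16), 32L)$label, 1L)
})

test_that("checkpoints and history files round-trip", {
  cfg <- tiny_cfg(seed = 1L)
  m <- tiny_cnn(3, seed = 2)
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(m, cfg, 7L, tf)
  back <- load_checkpoint(tf)
  expect_identical(back$model$params, m$params)
  expect_equal(back$epoch, 7L)
  h <- data.frame(epoch = 1:2, l_total = c(1, 0.5))
  tc <- tempfile(fileext = ".csv")
  write_history_csv(h, tc)
  expect_equal(read.csv(tc), h)
})
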