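test_that("blob samples are reproducible and respect their ground truth", {
  fp <- fixture_params()
  s1 <- gen_blob_image(fp, seed = 5)
  s2 <- gen_blob_image(fp, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$image, gen_blob_image(fp, seed = 6)$image))

  # object box inside image, part boxes inside object box
  expect_lte(s1$object_box["x1"], fp$image_size)
  expect_lte(s1$object_box["y1"], fp$image_size)
  for (pb in s1$part_boxes) {
    expect_gte(pb["x0"], s1$object_box["x0"])
    expect_gte(pb["y0"], s1$object_box["y0"])
    expect_lte(pb["x1"], s1$object_box["x1"])
    expect_lte(pb["y1"], s1$object_box["y1"])
  }
  expect_true(all(s1$image >= 0 & s1$image <= 1))

  # noiseless, maximal-contrast object: intensity attention recovers the
  # box exactly at stride 1
  fp0 <- fixture_params(noise_sd = 0, signal_to_background = 100,
                        bg_level = 0.009, part_count = 0L)
  s0 <- gen_blob_image(fp0, seed = 3)
  expect_equal(iou(localize_object(s0$image, intensity_backbone(1L)),
                   s0$object_box), 1)
})

test_that("generated datasets are balanced, split, and seed-disjoint", {
  fp <- fixture_params(n_classes = 3L, n_samples = 30L, seed = 2)
  ds <- gen_dataset(fp)
  labs <- vapply(ds$samples, `[[`, 0L, "label")
  expect_equal(unname(table(labs)), rep(10L, 3), ignore_attr = TRUE)
  expect_equal(sum(ds$split == "train"), 15L)
  # per-class split balance
  for (k in 0:2)
    expect_equal(sum(ds$split[labs == k] == "train"), 5L)

  ds2 <- gen_dataset(fixture_params(n_classes = 3L, n_samples = 30L, seed = 3))
  hashes <- function(d) vapply(d$samples, function(s)
    paste(round(s$image[1:50], 8), collapse = ","), "")
  expect_equal(length(intersect(hashes(ds), hashes(ds2))), 0L)
})

test_that("logit pair batches hit the confident-teacher stress regime", {
  pairs <- gen_logit_pairs(C = 10, n = 400, seed = 3)
  expect_identical(pairs, gen_logit_pairs(C = 10, n = 400, seed = 3))
  pt <- vapply(pairs, function(p)
    oracle_softmax(p$z_teacher, 1)[p$target + 1], 0)
  expect_gt(sum(pt > 0.99), 50)
  expect_gt(sum(pt < 0.9), 50)  # and plenty of unconfident teachers too
})

test_that("oracle part crops are more class-informative than background", {
  # nearest-centroid classifier on mean RGB of oracle part crops beats the
  # same classifier on background (outside-object) crops
  fp <- fixture_params(n_classes = 4L, n_samples = 40L, seed = 9)
  ds <- gen_dataset(fp)
  feat <- function(img, box)
    vapply(1:3, function(ch) mean(crop_image(img, box)[, , ch]), 0)
  part_x <- t(vapply(ds$samples, function(s)
    feat(s$image, s$part_boxes[[1]]), numeric(3)))
  bg_box <- function(s) {
    if (s$object_box["x0"] >= 6) bbox(0, 0, 6, 6)
    else bbox(fp$image_size - 6, 0, fp$image_size, 6)
  }
  bg_x <- t(vapply(ds$samples, function(s) feat(s$image, bg_box(s)), numeric(3)))
  labs <- vapply(ds$samples, `[[`, 0L, "label")
  tr <- ds$split == "train"
  ncc_acc <- function(x) {
    cents <- lapply(0:3, function(k) colMeans(x[tr & labs == k, , drop = FALSE]))
    pred <- apply(x[!tr, , drop = FALSE], 1, function(v)
      which.min(vapply(cents, function(cn) sum((v - cn)^2), 0)) - 1L)
    mean(pred == labs[!tr])
  }
  expect_gt(ncc_acc(part_x), ncc_acc(bg_x))
})
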