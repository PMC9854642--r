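#' Parameters of the synthetic fixture generator
#'
#' The generator plants one bright textured ellipse (the "object") on a
#' noisy dark background and stamps `part_count` small two-color patterns
#' (the "parts") inside it. The part colors, not any global image
#' property, encode the class label, emulating the low inter-class-variance
#' regime of fine-grained recognition where discriminative information
#' lives in local part appearance. Ground-truth object and part boxes are
#' recorded with every sample.
#'
#' @param image_size Square image side in pixels (default 64, matching the
#'   desk-scale backbone; 448 works for integration runs).
#' @param n_classes Number of classes.
#' @param object_area_fraction Range of the ellipse area as a fraction of
#'   the image (default 0.2--0.4).
#' @param signal_to_background Ratio of object to background mean intensity
#'   (default 3).
#' @param bg_level Background mean intensity (default 0.25).
#' @param part_count Parts stamped inside each object.
#' @param noise_sd Gaussian noise standard deviation (default 0.08).
#' @param n_samples Dataset size for [gen_dataset()].
#' @param seed Master seed.
#' @return A list of class `"fixture_params"`.
#' @export
fixture_params <- function(image_size = 64L, n_classes = 5L,
                           object_area_fraction = c(0.2, 0.4),
                           signal_to_background = 3, bg_level = 0.25,
                           part_count = 3L, noise_sd = 0.08,
                           n_samples = 30L, seed = 1L) {
  stopifnot(image_size >= 16L, n_classes >= 2L,
            length(object_area_fraction) == 2L,
            all(object_area_fraction > 0), all(object_area_fraction < 0.8),
            signal_to_background >= 1, part_count >= 0L, noise_sd >= 0,
            n_samples >= n_classes)
  structure(list(image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 object_area_fraction = object_area_fraction,
                 signal_to_background = signal_to_background,
                 bg_level = bg_level, part_count = as.integer(part_count),
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "fixture_params")
}

# Two saturated part colors per class, fixed by the class index alone and
# evenly spaced on the color wheel so classes are distinct by construction.
class_part_colors <- function(label, n_classes) {
  hues <- ((label + c(0, 0.5)) / n_classes) %% 1
  lapply(hues, function(h)
    as.numeric(grDevices::col2rgb(grDevices::hsv(h, 1, 1)) / 255))
}

#' Generate one synthetic sample
#'
#' Regeneration from the same `(params, seed, label)` is bit-identical; the
#' RNG state of the caller is left untouched.
#'
#' @param params A [fixture_params()] list.
#' @param seed Integer seed for this sample.
#' @param label Optional 0-based class label; drawn uniformly if `NULL`.
#' @return A list of class `"synthetic_sample"`: `image` (`(S, S, 3)` array
#'   in `[0, 1]`), `label`, `object_box` ([bbox()]), `part_boxes` (list of
#'   [bbox()]), `seed`.
#' @export
gen_blob_image <- function(params, seed, label = NULL) {
  S <- params$image_size
  with_seed(seed, {
    if (is.null(label)) label <- sample.int(params$n_classes, 1L) - 1L
    img <- array(pmin(pmax(rnorm(S * S * 3, params$bg_level, params$noise_sd),
                           0), 1), c(S, S, 3L))
    # ellipse geometry: draw an area fraction, then semi-axes and center
    frac <- runif(1, params$object_area_fraction[1], params$object_area_fraction[2])
    area <- frac * S * S
    aspect <- runif(1, 0.7, 1.4)
    a <- sqrt(area * aspect / pi)   # semi-axis along x
    b <- area / (pi * a)
    amax <- S / 2 - 2
    if (a > amax) a <- amax
    if (b > amax) b <- amax
    if (a < 3 || b < 3) stop_invalid("object does not fit: semi-axes (",
                                     round(a, 1), ", ", round(b, 1), ")")
    cx <- runif(1, a + 1, S - a - 1)
    cy <- runif(1, b + 1, S - b - 1)
    xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # x of each column
    ys <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # y of each row
    inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    level <- min(params$bg_level * params$signal_to_background, 0.95)
    texture <- pmin(pmax(level * (1 + 0.12 * rnorm(sum(inside))), 0), 1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- texture
      img[, , ch] <- plane
    }
    rows <- which(apply(inside, 1, any))
    cols <- which(apply(inside, 2, any))
    object_box <- bbox(min(cols) - 1L, min(rows) - 1L, max(cols), max(rows))
    # parts: class-colored checker patches at class-specific angles
    part_boxes <- list()
    if (params$part_count > 0L) {
      colors <- class_part_colors(label, params$n_classes)
      side <- max(4L, as.integer(round(0.6 * min(a, b))))
      angles <- 2 * pi * (label / params$n_classes +
                            seq_len(params$part_count) / params$part_count)
      for (p in seq_len(params$part_count)) {
        px <- cx + 0.55 * a * cos(angles[p])
        py <- cy + 0.55 * b * sin(angles[p])
        x0 <- max(object_box["x0"], min(as.integer(round(px - side / 2)),
                                        object_box["x1"] - side))
        y0 <- max(object_box["y0"], min(as.integer(round(py - side / 2)),
                                        object_box["y1"] - side))
        pb <- bbox(x0, y0, x0 + side, y0 + side)
        half <- side %/% 2L
        for (ch in 1:3) {
          block <- img[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side), ch]
          checker <- matrix(colors[[1]][ch], side, side)
          checker[seq_len(half), (half + 1):side] <- colors[[2]][ch]
          checker[(half + 1):side, seq_len(half)] <- colors[[2]][ch]
          img[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side), ch] <- checker
        }
        part_boxes <- c(part_boxes, list(pb))
      }
    }
    structure(list(image = img, label = label, object_box = object_box,
                   part_boxes = part_boxes, seed = seed),
              class = "synthetic_sample")
  })
}

#' Generate a class-balanced synthetic dataset
#'
#' Labels are assigned round-robin, so classes are exactly balanced when
#' `n_samples` divides by `n_classes`; within each class, samples alternate
#' between the train and test split. Every sample's seed derives from the
#' master seed, so the whole dataset is reproducible bit-for-bit.
#'
#' @param params A [fixture_params()] list.
#' @return A list of class `"synthetic_dataset"`: `samples` (list of
#'   [gen_blob_image()] outputs), `split` (character vector), `params`.
#' @export
gen_dataset <- function(params) {
  n <- params$n_samples
  labels <- rep_len(0:(params$n_classes - 1L), n)
  seeds <- (as.numeric(params$seed) * 7919 + 1000L * seq_len(n)) %% 2147483647
  samples <- lapply(seq_len(n), function(i)
    gen_blob_image(params, seed = as.integer(seeds[i]), label = labels[i]))
  idx_in_class <- stats::ave(seq_len(n), labels, FUN = seq_along)
  split <- ifelse(idx_in_class %% 2L == 1L, "train", "test")
  structure(list(samples = samples, split = split, params = params),
            class = "synthetic_dataset")
}

#' Export a synthetic dataset in the CUB metadata layout
#'
#' Writes `images/<class>/<name>.png` plus the three metadata files
#' (`images.txt`, `image_class_labels.txt`, `train_test_split.txt`) with
#' 1-based image and class IDs, and the ground-truth boxes as JSON
#' (`ground_truth_boxes.json`).
#'
#' @param dataset A `"synthetic_dataset"`.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
export_cub_layout <- function(dataset, root) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$samples)
  lines_img <- lines_lab <- lines_split <- character(n)
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    s <- dataset$samples[[i]]
    cls_dir <- sprintf("%03d.class_%03d", s$label + 1L, s$label + 1L)
    dir.create(file.path(root, "images", cls_dir), showWarnings = FALSE)
    rel <- file.path(cls_dir, sprintf("img_%04d.png", i))
    write_image_file(s$image, file.path(root, "images", rel))
    lines_img[i] <- paste(i, rel)
    lines_lab[i] <- paste(i, s$label + 1L)
    lines_split[i] <- paste(i, if (dataset$split[i] == "train") 1L else 0L)
    gt[[i]] <- list(image_id = i,
                    object = as.list(unclass(s$object_box)),
                    parts = lapply(s$part_boxes, function(b) as.list(unclass(b))))
  }
  writeLines(lines_img, file.path(root, "images.txt"))
  writeLines(lines_lab, file.path(root, "image_class_labels.txt"))
  writeLines(lines_split, file.path(root, "train_test_split.txt"))
  jsonlite::write_json(gt, file.path(root, "ground_truth_boxes.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(root)
}

#' Generate random teacher/student logit pairs
#'
#' Teacher logits are heavy-tailed (Student-t, df 3) so that some teachers
#' are sharply peaked; in addition, one pair in four gets a large boost on
#' the target logit, driving the teacher's target probability above 0.99 --
#' the regime in which classical distillation suppresses non-target
#' knowledge. Student logits are Gaussian.
#'
#' @param C Number of classes (>= 2).
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @return A list of `n` lists with fields `z_teacher`, `z_student`,
#'   `target` (0-based).
#' @export
gen_logit_pairs <- function(C, n, seed = 1L) {
  stopifnot(C >= 2L, n >= 1L)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      target <- sample.int(C, 1L) - 1L
      zt <- stats::rt(C, df = 3) * 2.5
      if (i %% 4L == 0L) zt[target + 1L] <- max(zt) + runif(1, 8, 15)
      list(z_teacher = zt, z_student = rnorm(C, sd = 2), target = target)
    })
  })
}
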