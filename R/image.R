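#' Resize an image or matrix by separable resampling
#'
#' Bilinear (default) or nearest-neighbor resampling using the half-pixel
#' center convention: output pixel center `i + 0.5` (0-based) maps to source
#' coordinate `(i + 0.5) * in/out - 0.5`, clamped to the grid. Resampling is
#' separable, implemented as two small matrix products per channel.
#'
#' @param img A numeric matrix or `(H, W, C)` array.
#' @param out_h,out_w Output height and width (positive integers).
#' @param method `"bilinear"` or `"nearest"`.
#' @return The resized matrix/array.
#' @export
resize_image <- function(img, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (out_h < 1 || out_w < 1) stop_invalid("output size must be positive")
  was_matrix <- is.matrix(img)
  if (was_matrix) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  A <- resample_weights(d[1], out_h, method)
  B <- resample_weights(d[2], out_w, method)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% img[, , c] %*% t(B)
  if (was_matrix) out[, , 1L] else out
}

# n_out x n_in interpolation weight matrix for one axis.
resample_weights <- function(n_in, n_out, method) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    # nearest source pixel to the projected center (round half toward floor
    # so upscale by an integer factor replicates blocks exactly)
    idx <- pmin(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1, n_in)
    W[cbind(seq_len(n_out), idx)] <- 1
  } else {
    lo <- floor(src)
    hi <- pmin(lo + 1, n_in - 1)
    t <- src - lo
    W[cbind(seq_len(n_out), lo + 1)] <- W[cbind(seq_len(n_out), lo + 1)] + (1 - t)
    W[cbind(seq_len(n_out), hi + 1)] <- W[cbind(seq_len(n_out), hi + 1)] + t
  }
  W
}

#' Crop a box out of an image
#'
#' @param image `(H, W, C)` array or matrix.
#' @param box [bbox()] in image coordinates; must lie within the image.
#' @return The sub-image under `box`.
#' @export
crop_image <- function(image, box) {
  d <- dim(image)
  if (box["x1"] > d[2] || box["y1"] > d[1])
    stop_invalid("box exceeds image bounds")
  if (length(d) == 2L)
    image[(box["y0"] + 1L):box["y1"], (box["x0"] + 1L):box["x1"], drop = FALSE]
  else
    image[(box["y0"] + 1L):box["y1"], (box["x0"] + 1L):box["x1"], , drop = FALSE]
}

#' Crop a box and resample it to a fixed size
#'
#' This is the "deflationary transformation" used by the augmentation
#' pipeline: object crops are resampled to the object input size (448 at
#' full scale) and part crops to the part input size (224 at full scale).
#'
#' @inheritParams crop_image
#' @param out_size Scalar or `(h, w)` output size.
#' @param method Resampling method, see [resize_image()].
#' @return The cropped, resampled image.
#' @export
crop_and_resize <- function(image, box, out_size, method = "bilinear") {
  out_size <- rep_len(out_size, 2L)
  resize_image(crop_image(image, box), out_size[1], out_size[2], method)
}

#' Read and write images as (H, W, 3) arrays in [0, 1]
#'
#' PNG files via the png package; grayscale images are replicated to three
#' channels and any alpha channel is dropped.
#'
#' @param file Path to a PNG file.
#' @param image `(H, W, 3)` array with values in `[0, 1]`.
#' @return `read_image_file` returns the array; `write_image_file` the path,
#'   invisibly.
#' @export
read_image_file <- function(file) {
  img <- png::readPNG(file)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

#' @rdname read_image_file
#' @export
write_image_file <- function(image, file) {
  png::writePNG(pmin(pmax(image, 0), 1), file)
  invisible(file)
}

#' Render localization overlays
#'
#' Draws the object box in green and ranked part windows in red, yellow,
#' and blue (recycled beyond rank 3), mirroring the usual visualization of
#' attention-guided localization.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param object_box Optional [bbox()].
#' @param part_boxes Optional data frame of part windows ordered by rank
#'   (image coordinates).
#' @param file Optional PNG path; written when given.
#' @param lwd Border thickness in pixels.
#' @return The annotated image array, invisibly.
#' @export
render_overlay <- function(image, object_box = NULL, part_boxes = NULL,
                           file = NULL, lwd = 2L) {
  draw <- function(img, b, col) {
    x0 <- b["x0"] + 1L; x1 <- b["x1"]; y0 <- b["y0"] + 1L; y1 <- b["y1"]
    for (k in 0:(lwd - 1L)) {
      ys <- c(pmin(y0 + k, y1), pmax(y1 - k, y0))
      xs <- c(pmin(x0 + k, x1), pmax(x1 - k, x0))
      for (ch in 1:3) {
        img[ys, x0:x1, ch] <- col[ch]
        img[y0:y1, xs, ch] <- col[ch]
      }
    }
    img
  }
  cols <- list(red = c(1, 0, 0), yellow = c(1, 1, 0), blue = c(0, 0, 1))
  if (!is.null(object_box)) image <- draw(image, object_box, c(0, 1, 0))
  if (!is.null(part_boxes) && nrow(part_boxes) > 0L)
    for (i in seq_len(nrow(part_boxes)))
      image <- draw(image,
                    bbox(part_boxes$x0[i], part_boxes$y0[i],
                         part_boxes$x1[i], part_boxes$y1[i]),
                    cols[[(i - 1L) %% 3L + 1L]])
  if (!is.null(file)) write_image_file(image, file)
  invisible(image)
}
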