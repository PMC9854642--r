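#' Backbone contract
#'
#' A backbone is anything with a [forward_features()] method returning an
#' `(H', W', C)` post-activation feature stack and (for classifiers) a
#' [classify()] method returning class logits. The reference full-scale
#' pairing is a DenseNet121-class teacher and a ShuffleNetV2-class student
#' (see [arch_densenet121()] / [arch_shufflenet_v2_x10()] for their layer
#' tables); for desk-scale work the package ships a small trainable CNN.
#'
#' @param model A backbone object.
#' @param image `(H, W, C)` numeric array.
#' @param ... Method-specific arguments.
#' @return `forward_features`: the feature stack; `classify`: a numeric
#'   logit vector of length `num_classes`.
#' @name backbone
NULL

#' @rdname backbone
#' @export
forward_features <- function(model, image, ...) UseMethod("forward_features")

#' @rdname backbone
#' @export
classify <- function(model, image, ...) UseMethod("classify")

#' Small trainable convolutional backbone
#'
#' A three-block CNN (conv 3x3 / ReLU / 2x2 max-pool, output stride 8)
#' followed by global average pooling and a single fully connected head.
#' It accepts any input whose sides are multiples of 8 and is small enough
#' to train in seconds on synthetic fixtures, while exposing exactly the
#' same feature-stack/logit contract as a full-size backbone. Weights are
#' He-initialized from `seed`.
#'
#' @param num_classes Number of output classes (>= 2).
#' @param channels Integer vector of three block widths. The default
#'   `c(8, 12, 16)` is the "teacher" width; `tiny_cnn_student()` gives a
#'   roughly quarter-size student.
#' @param in_channels Input channels (3 for RGB).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"tiny_cnn"`.
#' @export
tiny_cnn <- function(num_classes, channels = c(8L, 12L, 16L), in_channels = 3L,
                     seed = 1L) {
  stopifnot(num_classes >= 2L, length(channels) == 3L)
  cs <- c(in_channels, as.integer(channels))
  params <- with_seed(seed, {
    p <- list()
    for (i in 1:3) {
      fan_in <- 9L * cs[i]
      p[[paste0("W", i)]] <- array(rnorm(fan_in * cs[i + 1], sd = sqrt(2 / fan_in)),
                                   c(3L, 3L, cs[i], cs[i + 1]))
      p[[paste0("b", i)]] <- numeric(cs[i + 1])
    }
    p$Wfc <- matrix(rnorm(cs[4] * num_classes, sd = sqrt(1 / cs[4])),
                    cs[4], num_classes)
    p$bfc <- numeric(num_classes)
    p
  })
  structure(list(params = params,
                 spec = list(name = "tiny_cnn",
                             feature_channels = cs[4],
                             output_stride = 8L,
                             num_classes = as.integer(num_classes),
                             channels = cs)),
            class = "tiny_cnn")
}

#' @rdname tiny_cnn
#' @export
tiny_cnn_student <- function(num_classes, seed = 1L) {
  tiny_cnn(num_classes, channels = c(4L, 6L, 8L), seed = seed)
}

# Full forward pass; with keep_cache = TRUE all intermediates needed by
# tiny_cnn_backward are retained.
tiny_cnn_forward <- function(model, image, keep_cache = FALSE) {
  p <- model$params
  d <- dim(image)
  if (length(d) != 3L || d[3] != dim(p$W1)[3])
    stop_invalid("expected an (H, W, ", dim(p$W1)[3], ") image, got (",
                 paste(d, collapse = ", "), ")")
  if (any(d[1:2] %% 8L != 0L))
    stop_invalid("image sides must be multiples of the output stride (8)")
  x <- image - 0.5  # center [0, 1] inputs
  cache <- list(input_dim = d)
  for (i in 1:3) {
    W <- p[[paste0("W", i)]]
    k <- dim(W)[1]
    cols <- im2col_cpp(x, k, 1L, (k - 1L) %/% 2L)
    pre <- cols %*% matrix(W, k * k * dim(W)[3], dim(W)[4])
    pre <- sweep(pre, 2L, p[[paste0("b", i)]], "+")
    hw <- dim(x)[1:2]
    a <- array(pmax(pre, 0), c(hw, dim(W)[4]))
    mp <- maxpool2_fwd_cpp(a)
    if (keep_cache) {
      cache[[paste0("cols", i)]] <- cols
      cache[[paste0("pre", i)]] <- pre
      cache[[paste0("dim", i)]] <- dim(a)
      cache[[paste0("idx", i)]] <- mp$idx
    }
    x <- mp$out
  }
  feat <- x  # (H/8, W/8, C) post-activation stack
  pooled <- apply(feat, 3L, mean)
  logits <- drop(pooled %*% p$Wfc) + p$bfc
  cache$feat_dim <- dim(feat)
  cache$pooled <- pooled
  list(features = feat, pooled = pooled, logits = logits,
       cache = if (keep_cache) cache)
}

#' @rdname backbone
#' @export
forward_features.tiny_cnn <- function(model, image, ...) {
  tiny_cnn_forward(model, image)$features
}

#' @rdname backbone
#' @export
classify.tiny_cnn <- function(model, image, ...) {
  tiny_cnn_forward(model, image)$logits
}

# Backpropagate d loss / d logits through the network; returns gradients in
# the same layout as model$params.
tiny_cnn_backward <- function(model, cache, dlogits) {
  p <- model$params
  g <- list()
  g$bfc <- dlogits
  g$Wfc <- outer(cache$pooled, dlogits)
  dpooled <- drop(p$Wfc %*% dlogits)
  fd <- cache$feat_dim
  dfeat <- array(rep(dpooled, each = fd[1] * fd[2]) / (fd[1] * fd[2]), fd)
  dx <- dfeat
  for (i in 3:1) {
    W <- p[[paste0("W", i)]]
    k <- dim(W)[1]
    adim <- cache[[paste0("dim", i)]]
    da <- maxpool2_bwd_cpp(dx, cache[[paste0("idx", i)]], adim[1], adim[2])
    dpre <- matrix(da, adim[1] * adim[2], adim[3]) *
      (cache[[paste0("pre", i)]] > 0)
    cols <- cache[[paste0("cols", i)]]
    g[[paste0("b", i)]] <- colSums(dpre)
    g[[paste0("W", i)]] <- array(crossprod(cols, dpre), dim(W))
    if (i > 1L) {
      dcols <- dpre %*% t(matrix(W, k * k * dim(W)[3], dim(W)[4]))
      indim <- c(cache[[paste0("dim", i - 1L)]][1:2] %/% 2L, dim(W)[3])
      dx <- col2im_cpp(dcols, indim[1], indim[2], indim[3], k, 1L,
                       (k - 1L) %/% 2L)
    }
  }
  g[names(p)]
}

#' Intensity backbone for attention diagnostics
#'
#' A parameter-free backbone whose single-channel feature stack is the image
#' brightness average-pooled by `stride` (default 2 px per cell). Its attention map is therefore
#' (approximately) the image intensity itself, which makes it the natural
#' probe for validating attention-based localization on fixtures whose
#' object is brighter than the background. It has no classifier head.
#'
#' @param stride Pooling factor in pixels per attention cell (default 2,
#'   which keeps box quantization error well below the localization
#'   tolerance on 64-px fixtures).
#' @return An object of class `"intensity_backbone"`.
#' @export
intensity_backbone <- function(stride = 2L) {
  structure(list(spec = list(name = "intensity", feature_channels = 1L,
                             output_stride = as.integer(stride))),
            class = "intensity_backbone")
}

#' @rdname backbone
#' @export
forward_features.intensity_backbone <- function(model, image, ...) {
  s <- model$spec$output_stride
  d <- dim(image)
  if (any(d[1:2] %% s != 0L))
    stop_invalid("image sides must be multiples of the backbone stride (", s, ")")
  gray <- if (length(d) == 3L) rowSums(image, dims = 2L) / d[3] else image
  ho <- d[1] %/% s; wo <- d[2] %/% s
  # average pool s x s blocks
  pooled <- matrix(colMeans(matrix(gray, s, ho * d[2])), ho, d[2])
  pooled <- t(matrix(colMeans(matrix(t(pooled), s, wo * ho)), wo, ho))
  array(pooled, c(ho, wo, 1L))
}

#' @rdname backbone
#' @export
classify.intensity_backbone <- function(model, image, ...) {
  stop_invalid("the intensity backbone has no classifier head")
}
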