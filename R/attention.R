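#' Sum a convolutional feature stack into a spatial attention map
#'
#' The attention map at each location is the sum of activations across all
#' channels of the backbone's final post-activation feature stack. High
#' values mark regions the network attends to and are the basis for both
#' object localization and key-part discovery.
#'
#' @param features A numeric array of dimension `(H, W, C)`: the feature
#'   stack, rows indexing y and columns x.
#' @return An `H x W` numeric matrix.
#' @export
compute_attention_map <- function(features) {
  if (is.matrix(features)) features <- array(features, c(dim(features), 1L))
  d <- dim(features)
  if (is.null(d) || length(d) != 3L || any(d < 1L) || !is.numeric(features))
    stop_invalid("features must be a non-empty numeric (H, W, C) array")
  rowSums(features, dims = 2L)
}

#' Mean-attention threshold
#'
#' The threshold separating object from background is the arithmetic mean of
#' all `H x W` attention values.
#'
#' @param map An attention-map matrix.
#' @return The scalar mean.
#' @export
attention_threshold <- function(map) {
  if (!is.matrix(map) || length(map) == 0)
    stop_invalid("map must be a non-empty matrix")
  mean(map)
}

#' Threshold an attention map into a binary object mask
#'
#' A cell is marked `TRUE` exactly where the attention value strictly
#' exceeds `theta`. With `theta` at the map mean, a constant map therefore
#' yields an all-`FALSE` mask; downstream callers fall back to the
#' full-image box in that case.
#'
#' @param map Attention-map matrix.
#' @param theta Finite numeric threshold.
#' @return A logical matrix of the same shape.
#' @export
binarize <- function(map, theta) {
  if (!is.finite(theta)) stop_invalid("theta must be finite")
  map > theta
}

# 8-connected component labeling by breadth-first search. Returns an integer
# matrix of labels (0 = background); label order follows column-major first
# contact, so results are deterministic.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  lab <- 0L
  queue <- integer(length(mask))
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    queue[1L] <- start
    qlen <- 1L
    while (qlen > 0L) {
      cur <- queue[qlen]; qlen <- qlen - 1L
      y <- ((cur - 1L) %% h) + 1L
      x <- ((cur - 1L) %/% h) + 1L
      for (dx in -1:1) for (dy in -1:1) {
        ny <- y + dy; nx <- x + dx
        if (ny < 1L || ny > h || nx < 1L || nx > w) next
        ni <- ny + (nx - 1L) * h
        if (mask[ni] && labels[ni] == 0L) {
          labels[ni] <- lab
          qlen <- qlen + 1L
          queue[qlen] <- ni
        }
      }
    }
  }
  labels
}

#' Bounding box of the largest connected mask component
#'
#' Components are 8-connected (diagonal neighbors join). Smaller components
#' -- typically background noise that survived thresholding -- are
#' discarded, and the tight box of the component with the most cells is
#' returned in 0-based, half-open map coordinates. Ties on size go to the
#' component first reached in column-major scan order.
#'
#' @param mask A logical matrix.
#' @return A [bbox()] in map coordinates.
#' @seealso [localize_object()] for the full pipeline with its
#'   empty-mask fallback.
#' @export
largest_component_bbox <- function(mask) {
  if (!is.matrix(mask)) stop_invalid("mask must be a logical matrix")
  if (!any(mask))
    stop(errorCondition("mask has no TRUE cells",
                        class = c("attnkd_empty_mask", "error")))
  labels <- label_components8(mask)
  sizes <- tabulate(labels)
  win <- which.max(sizes)  # first maximum = earliest label on ties
  cells <- which(labels == win, arr.ind = TRUE)
  bbox(min(cells[, "col"]) - 1L, min(cells[, "row"]) - 1L,
       max(cells[, "col"]), max(cells[, "row"]))
}

#' Mean attention inside a window
#'
#' @param map Attention-map matrix.
#' @param box A [bbox()] in map coordinates.
#' @return Sum of in-window values divided by the window area.
#' @export
window_mean_attention <- function(map, box) {
  if (box["x1"] > ncol(map) || box["y1"] > nrow(map))
    stop_invalid("box exceeds map bounds")
  mean(map[(box["y0"] + 1L):box["y1"], (box["x0"] + 1L):box["x1"], drop = FALSE])
}

#' Enumerate sliding-window part candidates
#'
#' Every placement of every window size on the stride grid becomes one
#' candidate, scored by its mean attention. Scores are computed with a
#' summed-area table, so enumeration is cheap even for dense strides.
#'
#' @param map Attention-map matrix.
#' @param window_sizes List of `(h, w)` integer pairs, or a single pair.
#'   Every size must fit inside the map.
#' @param stride Grid step in map cells (default 1, exhaustive).
#' @return A data frame with columns `x0, y0, x1, y1` (map coordinates),
#'   `mean_attention`, and `scale_id` (1-based index into `window_sizes`),
#'   ordered by scale, then row, then column.
#' @export
propose_part_windows <- function(map, window_sizes, stride = 1L) {
  if (!is.list(window_sizes)) window_sizes <- list(window_sizes)
  h <- nrow(map); w <- ncol(map)
  # summed-area table with a zero border for O(1) window sums
  sat <- matrix(0, h + 1L, w + 1L)
  sat[-1L, -1L] <- t(apply(apply(map, 2L, cumsum), 1L, cumsum))
  out <- vector("list", length(window_sizes))
  for (s in seq_along(window_sizes)) {
    wh <- window_sizes[[s]][1]; ww <- window_sizes[[s]][2]
    if (wh > h || ww > w)
      stop_invalid("window size (", wh, ", ", ww, ") exceeds map (", h, ", ", w, ")")
    y0 <- seq(0L, h - wh, by = stride)
    x0 <- seq(0L, w - ww, by = stride)
    g <- expand.grid(x0 = x0, y0 = y0)  # x fastest within each row band
    g <- g[order(g$y0, g$x0), , drop = FALSE]
    sums <- sat[cbind(g$y0 + wh + 1L, g$x0 + ww + 1L)] -
      sat[cbind(g$y0 + 1L, g$x0 + ww + 1L)] -
      sat[cbind(g$y0 + wh + 1L, g$x0 + 1L)] +
      sat[cbind(g$y0 + 1L, g$x0 + 1L)]
    out[[s]] <- data.frame(x0 = g$x0, y0 = g$y0,
                           x1 = g$x0 + ww, y1 = g$y0 + wh,
                           mean_attention = sums / (wh * ww),
                           scale_id = s)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Greedy non-overlapping selection of part windows
#'
#' Candidates are visited in descending mean attention (ties broken by
#' ascending `scale_id`, `y0`, `x0`); a candidate is kept iff its IoU with
#' every window already kept is at most `max_iou`, stopping after `top_n`
#' selections. This suppresses repeated picks of the same region.
#'
#' @param candidates Data frame from [propose_part_windows()].
#' @param max_iou Maximum allowed IoU with already-selected windows
#'   (default 0.25).
#' @param top_n Maximum number of windows to keep (default 2).
#' @return The selected rows, ordered by non-increasing `mean_attention`.
#' @export
select_part_windows <- function(candidates, max_iou = 0.25, top_n = 2L) {
  if (max_iou < 0 || max_iou > 1) stop_invalid("max_iou must be in [0, 1]")
  if (top_n < 1L) stop_invalid("top_n must be >= 1")
  if (is.null(candidates) || nrow(candidates) == 0L) return(candidates)
  ord <- order(-candidates$mean_attention, candidates$scale_id,
               candidates$y0, candidates$x0)
  candidates <- candidates[ord, , drop = FALSE]
  kept <- integer(0)
  kept_boxes <- list()
  for (i in seq_len(nrow(candidates))) {
    b <- bbox(candidates$x0[i], candidates$y0[i],
              candidates$x1[i], candidates$y1[i])
    ok <- all(vapply(kept_boxes, function(k) iou(b, k) <= max_iou, logical(1)))
    if (ok) {
      kept <- c(kept, i)
      kept_boxes <- c(kept_boxes, list(b))
      if (length(kept) >= top_n) break
    }
  }
  res <- candidates[kept, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Localize the object in an image via its attention map
#'
#' Composes the attention pipeline: feature stack -> channel-sum attention
#' map -> mean threshold -> binary mask -> largest 8-connected component ->
#' box rescaled to image pixels. If thresholding leaves no cell (e.g. a
#' constant attention map), the full-image box is returned so the pipeline
#' never fails on degenerate inputs.
#'
#' @param image An `(H, W, 3)` numeric array in `[0, 1]`.
#' @param model A backbone with a [forward_features()] method.
#' @return A [bbox()] in image pixel coordinates.
#' @export
localize_object <- function(image, model) {
  amap <- compute_attention_map(forward_features(model, image))
  mask <- binarize(amap, attention_threshold(amap))
  ih <- dim(image)[1]; iw <- dim(image)[2]
  box <- tryCatch(largest_component_bbox(mask),
                  attnkd_empty_mask = function(e) NULL)
  if (is.null(box)) return(bbox(0L, 0L, iw, ih))
  map_box_to_image(box, dim(amap), c(ih, iw))
}

#' Default square window sizes as fractions of the attention-map side
#'
#' @param map_shape `(H, W)` of the attention map.
#' @param fracs Side fractions (default 1/2, 1/3, 1/4).
#' @return A list of `(h, w)` pairs, deduplicated, each at least 1 cell.
#' @export
default_window_sizes <- function(map_shape, fracs = c(1/2, 1/3, 1/4)) {
  side <- min(map_shape[1:2])
  sizes <- unique(pmax(1L, as.integer(round(side * fracs))))
  lapply(sizes, function(s) c(s, s))
}

#' Discover key-part windows in an (object) image
#'
#' Computes the attention map of `image` under `model`, enumerates sliding
#' windows with [propose_part_windows()], keeps the top windows with
#' [select_part_windows()], and rescales the kept boxes to image pixels.
#'
#' @inheritParams localize_object
#' @param window_sizes List of `(h, w)` pairs in map cells; default
#'   [default_window_sizes()] of the map.
#' @param stride,max_iou,top_n Passed to the proposal/selection steps.
#' @return A data frame in the [boxes_to_df()] box schema columns
#'   `x0, y0, x1, y1` (image coordinates) plus `mean_attention` and
#'   `scale_id`, ordered by rank.
#' @export
locate_part_windows <- function(image, model, window_sizes = NULL,
                                stride = 1L, max_iou = 0.25, top_n = 2L) {
  amap <- compute_attention_map(forward_features(model, image))
  if (is.null(window_sizes)) window_sizes <- default_window_sizes(dim(amap))
  cand <- propose_part_windows(amap, window_sizes, stride)
  sel <- select_part_windows(cand, max_iou = max_iou, top_n = top_n)
  if (nrow(sel) == 0L) return(sel)
  ih <- dim(image)[1]; iw <- dim(image)[2]
  for (i in seq_len(nrow(sel))) {
    b <- map_box_to_image(bbox(sel$x0[i], sel$y0[i], sel$x1[i], sel$y1[i]),
                          dim(amap), c(ih, iw))
    sel$x0[i] <- b["x0"]; sel$y0[i] <- b["y0"]
    sel$x1[i] <- b["x1"]; sel$y1[i] <- b["y1"]
  }
  sel
}
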