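#' Axis-aligned bounding box
#'
#' Boxes are stored in 0-based, half-open pixel coordinates: the box covers
#' columns `[x0, x1)` and rows `[y0, y1)`, with x increasing rightwards and
#' y downwards. Width is `x1 - x0` and height `y1 - y0`; both must be
#' positive.
#'
#' @param x0,y0 Integer coordinates of the top-left corner (inclusive).
#' @param x1,y1 Integer coordinates of the bottom-right corner (exclusive).
#' @return An object of class `"bbox"`: a named integer vector
#'   `c(x0, y0, x1, y1)`.
#' @examples
#' b <- bbox(3, 2, 4, 3)   # the single pixel at column 3, row 2
#' bbox_area(b)
#' @export
bbox <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (anyNA(v) || any(v != round(v)))
    stop_invalid("bbox coordinates must be integral, got (",
                 paste(v, collapse = ", "), ")")
  v <- as.integer(round(v))
  names(v) <- c("x0", "y0", "x1", "y1")
  if (v["x0"] < 0L || v["y0"] < 0L || v["x1"] <= v["x0"] || v["y1"] <= v["y0"])
    stop_invalid("degenerate bbox: need 0 <= x0 < x1 and 0 <= y0 < y1, got (",
                 paste(v, collapse = ", "), ")")
  structure(v, class = "bbox")
}

#' @rdname bbox
#' @param b A `bbox`.
#' @export
bbox_width <- function(b) unname(b["x1"] - b["x0"])

#' @rdname bbox
#' @export
bbox_height <- function(b) unname(b["y1"] - b["y0"])

#' @rdname bbox
#' @export
bbox_area <- function(b) as.numeric(bbox_width(b)) * bbox_height(b)

#' Intersection over union of two boxes
#'
#' @param a,b Boxes created with [bbox()].
#' @return The ratio of intersection area to union area, in `[0, 1]`.
#'   Disjoint boxes give 0; identical boxes give 1.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  iw <- max(0L, min(a["x1"], b["x1"]) - max(a["x0"], b["x0"]))
  ih <- max(0L, min(a["y1"], b["y1"]) - max(a["y0"], b["y0"]))
  inter <- as.numeric(iw) * ih
  if (inter == 0) return(0)
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

#' Rescale a box from attention-map coordinates to image coordinates
#'
#' Coordinates are multiplied by the per-axis ratio of image size to map
#' size; start coordinates are rounded down and end coordinates rounded up,
#' so the mapped box never loses area to rounding, then clipped to the image.
#'
#' @param box A [bbox()] in map coordinates.
#' @param map_shape,image_shape `(height, width)` pairs for the attention map
#'   and the target image.
#' @return A `bbox` in image pixel coordinates.
#' @examples
#' map_box_to_image(bbox(2, 3, 5, 6), c(14, 14), c(448, 448))
#' @export
map_box_to_image <- function(box, map_shape, image_shape) {
  if (length(map_shape) < 2 || length(image_shape) < 2 ||
      any(map_shape[1:2] <= 0) || any(image_shape[1:2] <= 0))
    stop_invalid("map_shape and image_shape must be positive (height, width)")
  if (box["x1"] > map_shape[2] || box["y1"] > map_shape[1])
    stop_invalid("box exceeds map_shape")
  sy <- image_shape[1] / map_shape[1]
  sx <- image_shape[2] / map_shape[2]
  bbox(max(0, floor(box["x0"] * sx)),
       max(0, floor(box["y0"] * sy)),
       min(image_shape[2], ceiling(box["x1"] * sx)),
       min(image_shape[1], ceiling(box["y1"] * sy)))
}

#' Export and import boxes as data frames, CSV, or JSON
#'
#' The interchange schema has one row per box with columns `image_id`,
#' `kind` (`"object"` or `"part"`), `x0`, `y0`, `x1`, `y1`, `score`.
#'
#' @param boxes A list of `bbox` objects, or for part windows a data frame
#'   with box columns and a `mean_attention` column.
#' @param image_id Identifier recorded with each row.
#' @param kind `"object"` or `"part"`.
#' @param scores Optional numeric scores (mean attention for parts).
#' @param df A data frame in the interchange schema.
#' @param file Path to write/read.
#' @return `boxes_to_df` returns the interchange data frame; the writers
#'   return the path invisibly; the readers return the data frame.
#' @export
boxes_to_df <- function(boxes, image_id = "", kind = "object", scores = NA_real_) {
  if (is.data.frame(boxes)) {
    scores <- if ("mean_attention" %in% names(boxes)) boxes$mean_attention else scores
    boxes <- lapply(seq_len(nrow(boxes)), function(i)
      bbox(boxes$x0[i], boxes$y0[i], boxes$x1[i], boxes$y1[i]))
  }
  if (inherits(boxes, "bbox")) boxes <- list(boxes)
  n <- length(boxes)
  data.frame(
    image_id = rep_len(image_id, n), kind = rep_len(kind, n),
    x0 = vapply(boxes, `[[`, 0L, "x0"), y0 = vapply(boxes, `[[`, 0L, "y0"),
    x1 = vapply(boxes, `[[`, 0L, "x1"), y1 = vapply(boxes, `[[`, 0L, "y1"),
    score = rep_len(as.numeric(scores), n),
    stringsAsFactors = FALSE)
}

#' @rdname boxes_to_df
#' @export
write_boxes_csv <- function(df, file) {
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname boxes_to_df
#' @export
read_boxes_csv <- function(file) read.csv(file, stringsAsFactors = FALSE)

#' @rdname boxes_to_df
#' @export
write_boxes_json <- function(df, file) {
  jsonlite::write_json(df, file, dataframe = "rows", digits = NA)
  invisible(file)
}

#' @rdname boxes_to_df
#' @export
read_boxes_json <- function(file) {
  as.data.frame(jsonlite::read_json(file, simplifyVector = TRUE))
}
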