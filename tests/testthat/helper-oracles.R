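# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check: plain loops, recursion, and textbook
# formulas only.

# channel sum by triple loop
oracle_attention_map <- function(features) {
  d <- dim(features)
  out <- matrix(0, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2]))
    for (c in seq_len(d[3])) out[y, x] <- out[y, x] + features[y, x, c]
  out
}

# recursive flood fill, 8-connected
oracle_label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fill <- function(y, x, lab) {
    stack <- list(c(y, x))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      y <- p[1]; x <- p[2]
      if (y < 1 || y > h || x < 1 || x > w) next
      if (!mask[y, x] || labels[y, x] != 0L) next
      labels[y, x] <<- lab
      for (dy in -1:1) for (dx in -1:1)
        if (dy != 0L || dx != 0L) stack[[length(stack) + 1L]] <- c(y + dy, x + dx)
    }
  }
  lab <- 0L
  for (x in seq_len(w)) for (y in seq_len(h))
    if (mask[y, x] && labels[y, x] == 0L) {
      lab <- lab + 1L
      fill(y, x, lab)
    }
  labels
}

# per-pixel bilinear resampling, half-pixel centers, double loop
oracle_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  out <- array(0, c(out_h, out_w, d[3]))
  for (i in seq_len(out_h)) for (j in seq_len(out_w)) {
    sy <- min(max((i - 0.5) * d[1] / out_h - 0.5, 0), d[1] - 1)
    sx <- min(max((j - 0.5) * d[2] / out_w - 0.5, 0), d[2] - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, d[1] - 1); x1 <- min(x0 + 1, d[2] - 1)
    ty <- sy - y0; tx <- sx - x0
    for (c in seq_len(d[3]))
      out[i, j, c] <-
        (1 - ty) * ((1 - tx) * img[y0 + 1, x0 + 1, c] + tx * img[y0 + 1, x1 + 1, c]) +
        ty * ((1 - tx) * img[y1 + 1, x0 + 1, c] + tx * img[y1 + 1, x1 + 1, c])
  }
  out
}

# greedy window selection written independently (vector scan, no bbox class)
oracle_select <- function(df, max_iou, top_n) {
  area <- function(r) (r$x1 - r$x0) * (r$y1 - r$y0)
  pair_iou <- function(a, b) {
    iw <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
    ih <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
    if (iw * ih == 0) return(0)
    iw * ih / (area(a) + area(b) - iw * ih)
  }
  df <- df[order(-df$mean_attention, df$scale_id, df$y0, df$x0), , drop = FALSE]
  chosen <- list()
  rows <- integer(0)
  for (i in seq_len(nrow(df))) {
    r <- as.list(df[i, ])
    if (all(vapply(chosen, function(k) pair_iou(r, k) <= max_iou, logical(1)))) {
      chosen[[length(chosen) + 1L]] <- r
      rows <- c(rows, i)
      if (length(rows) == top_n) break
    }
  }
  df[rows, , drop = FALSE]
}

# KL divergence by explicit summation over a probability table
oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  s
}

oracle_softmax <- function(z, temp) {
  e <- exp(z / temp - max(z / temp))
  e / sum(e)
}

# central-difference gradient of f at x
numerical_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + eps
    xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

random_image <- function(h = 32, w = 32, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}
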