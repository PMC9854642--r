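## Analytic model profiler.
##
## Architectures are described as flat layer tables (one row per conv / bn /
## fc layer) with an explicit `div` column: the downsampling factor of the
## layer's OUTPUT relative to the network input. Making the resolution
## explicit per layer keeps parallel branches (ShuffleNet units) and
## re-used resolutions (DenseNet blocks) honest, which a sequential
## stride-tracker gets wrong.
##
## Conventions (documented because published "FLOPs" columns rarely state
## theirs): param_count counts trainable scalars only (conv/fc weights and
## biases, batch-norm scale and shift; running statistics are buffers, not
## parameters). mac_count counts one multiply-accumulate per conv/linear
## multiply-add: k^2 * (C_in / groups) * C_out * H_out * W_out for a conv,
## C_in * C_out for a linear layer. Batch norm, pooling and activations
## contribute zero MACs.

arch_layer <- function(type, cin = NA, cout = NA, k = NA, groups = 1L,
                       bias = FALSE, div = NA, head = FALSE) {
  data.frame(type = type, cin = cin, cout = cout, k = k, groups = groups,
             bias = bias, div = div, head = head, stringsAsFactors = FALSE)
}

#' Layer table of ShuffleNetV2 x1.0
#'
#' The stock 1000-class network: a 24-channel stem, three stages of
#' channel-split units (output widths 116 / 232 / 464, with 4 / 8 / 4 units,
#' the first of each stage downsampling through two parallel branches), a
#' 1x1 conv to 1024 channels, and the fully connected head. Its parameter
#' count, 2,278,604 (2.28 M), matches the published reference
#' implementation exactly.
#'
#' @param num_classes Classifier width (default 1000, the stock head).
#' @return A data frame of layers consumable by [profile_architecture()].
#' @export
arch_shufflenet_v2_x10 <- function(num_classes = 1000L) {
  L <- list(arch_layer("conv", 3, 24, 3, div = 2),
            arch_layer("bn", cout = 24, div = 2))
  div <- 4  # after the stem max-pool
  ci <- 24
  for (stage in list(c(116, 4), c(232, 8), c(464, 4))) {
    co <- stage[1]; n <- stage[2]; bf <- co %/% 2L; od <- div * 2
    # downsampling unit: branch1 = DW 3x3 s2 + 1x1; branch2 = 1x1 (at the
    # incoming resolution), DW 3x3 s2, 1x1
    L <- c(L, list(
      arch_layer("conv", ci, ci, 3, groups = ci, div = od),
      arch_layer("bn", cout = ci, div = od),
      arch_layer("conv", ci, bf, 1, div = od),
      arch_layer("bn", cout = bf, div = od),
      arch_layer("conv", ci, bf, 1, div = div),
      arch_layer("bn", cout = bf, div = div),
      arch_layer("conv", bf, bf, 3, groups = bf, div = od),
      arch_layer("bn", cout = bf, div = od),
      arch_layer("conv", bf, bf, 1, div = od),
      arch_layer("bn", cout = bf, div = od)))
    # basic units: channel split, branch2 only (1x1, DW 3x3, 1x1 on co/2)
    for (i in seq_len(n - 1)) L <- c(L, list(
      arch_layer("conv", bf, bf, 1, div = od),
      arch_layer("bn", cout = bf, div = od),
      arch_layer("conv", bf, bf, 3, groups = bf, div = od),
      arch_layer("bn", cout = bf, div = od),
      arch_layer("conv", bf, bf, 1, div = od),
      arch_layer("bn", cout = bf, div = od)))
    ci <- co; div <- od
  }
  L <- c(L, list(arch_layer("conv", 464, 1024, 1, div = 32),
                 arch_layer("bn", cout = 1024, div = 32),
                 arch_layer("fc", 1024, num_classes, bias = TRUE, head = TRUE)))
  out <- do.call(rbind, L)
  attr(out, "name") <- "shufflenet_v2_x1.0"
  out
}

#' Layer table of DenseNet121
#'
#' Stem (7x7 conv, 64 channels), four dense blocks of 6 / 12 / 24 / 16
#' layers with growth rate 32 and bottleneck width 128, halving transitions
#' between blocks, a final batch norm, and a 1000-class head. The trunk
#' (all layers except the fully connected head) has 6,953,856 parameters
#' (6.95 M); with the head, 7,978,856.
#'
#' @inheritParams arch_shufflenet_v2_x10
#' @return A data frame of layers consumable by [profile_architecture()].
#' @export
arch_densenet121 <- function(num_classes = 1000L) {
  growth <- 32L; bottleneck <- 128L
  L <- list(arch_layer("conv", 3, 64, 7, div = 2),
            arch_layer("bn", cout = 64, div = 2))
  nf <- 64L; div <- 4
  blocks <- c(6L, 12L, 24L, 16L)
  for (b in seq_along(blocks)) {
    for (i in seq_len(blocks[b])) {
      L <- c(L, list(arch_layer("bn", cout = nf, div = div),
                     arch_layer("conv", nf, bottleneck, 1, div = div),
                     arch_layer("bn", cout = bottleneck, div = div),
                     arch_layer("conv", bottleneck, growth, 3, div = div)))
      nf <- nf + growth
    }
    if (b < length(blocks)) {
      L <- c(L, list(arch_layer("bn", cout = nf, div = div),
                     arch_layer("conv", nf, nf %/% 2L, 1, div = div)))
      nf <- nf %/% 2L; div <- div * 2
    }
  }
  L <- c(L, list(arch_layer("bn", cout = nf, div = div),
                 arch_layer("fc", nf, num_classes, bias = TRUE, head = TRUE)))
  out <- do.call(rbind, L)
  attr(out, "name") <- "densenet121"
  out
}

layer_params <- function(l) {
  switch(l$type,
         conv = l$k^2 * (l$cin / l$groups) * l$cout + if (isTRUE(l$bias)) l$cout else 0,
         bn = 2 * l$cout,
         fc = l$cin * l$cout + if (isTRUE(l$bias)) l$cout else 0,
         0)
}

layer_macs <- function(l, input_size) {
  switch(l$type,
         conv = l$k^2 * (l$cin / l$groups) * l$cout *
           (input_size[1] / l$div) * (input_size[2] / l$div),
         fc = l$cin * l$cout,
         0)
}

#' Profile an architecture layer table
#'
#' @param arch A layer table from [arch_densenet121()],
#'   [arch_shufflenet_v2_x10()], or built by hand.
#' @param input_size Scalar or `(h, w)` input resolution for the MAC count
#'   (default 448, the raw/object input size of the full-scale pipeline).
#' @return A list of class `"model_profile"`: `name`, `param_count`,
#'   `trunk_params`, `head_params`, `mac_count`, `input_size`. Layer types
#'   other than conv / bn / fc / pool count zero MACs with a warning.
#' @examples
#' p <- profile_architecture(arch_shufflenet_v2_x10())
#' round(p$param_count / 1e6, 2)  # 2.28
#' @export
profile_architecture <- function(arch, input_size = c(448L, 448L)) {
  input_size <- rep_len(input_size, 2L)
  known <- c("conv", "bn", "fc", "pool")
  if (any(!arch$type %in% known))
    warning("unsupported layer types counted as zero MACs: ",
            paste(unique(setdiff(arch$type, known)), collapse = ", "))
  params <- vapply(seq_len(nrow(arch)), function(i) layer_params(arch[i, ]), 0)
  macs <- vapply(seq_len(nrow(arch)), function(i) layer_macs(arch[i, ], input_size), 0)
  head <- arch$head
  structure(list(name = attr(arch, "name") %||% "custom",
                 param_count = sum(params),
                 trunk_params = sum(params[!head]),
                 head_params = sum(params[head]),
                 mac_count = sum(macs),
                 input_size = input_size),
            class = "model_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Profile a model object
#'
#' For the built-in [tiny_cnn()] the parameter count is the exact number of
#' trainable scalars in its weight arrays and the MAC count follows the
#' conv/linear convention described in [profile_architecture()].
#'
#' @param model A model object (currently [tiny_cnn()]).
#' @param input_size Scalar or `(h, w)` input size.
#' @return A `"model_profile"` list; see [profile_architecture()].
#' @export
profile_model <- function(model, input_size = c(64L, 64L)) {
  UseMethod("profile_model")
}

#' @export
profile_model.tiny_cnn <- function(model, input_size = c(64L, 64L)) {
  input_size <- rep_len(input_size, 2L)
  cs <- model$spec$channels
  n_classes <- model$spec$num_classes
  L <- list()
  div <- 1
  for (i in 1:3) {
    L <- c(L, list(arch_layer("conv", cs[i], cs[i + 1], 3, bias = TRUE,
                              div = div)))
    div <- div * 2
  }
  L <- c(L, list(arch_layer("fc", cs[4], n_classes, bias = TRUE, head = TRUE)))
  arch <- do.call(rbind, L)
  attr(arch, "name") <- model$spec$name
  prof <- profile_architecture(arch, input_size)
  # cross-check the table against the actual weight arrays
  stopifnot(prof$param_count == sum(vapply(model$params, length, 0L)))
  prof
}

#' @export
print.model_profile <- function(x, ...) {
  cat(sprintf("%s @ %dx%d: %s params (trunk %s, head %s), %.1f M MACs\n",
              x$name, x$input_size[1], x$input_size[2],
              format(x$param_count, big.mark = ","),
              format(x$trunk_params, big.mark = ","),
              format(x$head_params, big.mark = ","),
              x$mac_count / 1e6))
  invisible(x)
}

#' Write a profile report as JSON
#'
#' @param profile A `"model_profile"`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_profile_json <- function(profile, file) {
  jsonlite::write_json(
    list(name = profile$name, params = profile$param_count,
         trunk_params = profile$trunk_params, head_params = profile$head_params,
         macs = profile$mac_count, input_size = profile$input_size),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
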