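#' Read a CUB-200-2011-style dataset index
#'
#' Parses the three whitespace-separated metadata files `images.txt`
#' (`id path`), `image_class_labels.txt` (`id class`), and
#' `train_test_split.txt` (`id flag`, 1 = train, 0 = test), joins them on
#' the image ID, and remaps the 1-based file class IDs to contiguous
#' 0-based labels. Inconsistencies raise errors naming the offending file
#' and ID.
#'
#' @param root Directory containing the metadata files and the `images/`
#'   tree.
#' @param check_paths Verify every image file exists (default TRUE).
#' @return A data frame of class `"dataset_index"` with columns
#'   `image_id`, `image_path` (absolute), `label` (0-based), `split`
#'   (`"train"`/`"test"`); attribute `class_names` maps label -> name.
#' @export
read_cub_layout <- function(root, check_paths = TRUE) {
  parse2 <- function(fname) {
    path <- file.path(root, fname)
    if (!file.exists(path)) stop_invalid("missing metadata file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- regmatches(lines, regexpr("[ \t]+", lines), invert = TRUE)
    bad <- which(vapply(parts, length, 0L) != 2L)
    if (length(bad))
      stop_invalid(fname, " line ", bad[1], ": expected 'id value', got '",
                   lines[bad[1]], "'")
    data.frame(id = as.integer(vapply(parts, `[`, "", 1L)),
               value = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
  }
  imgs <- parse2("images.txt")
  labs <- parse2("image_class_labels.txt")
  splits <- parse2("train_test_split.txt")
  for (x in list(list(labs, "image_class_labels.txt"),
                 list(splits, "train_test_split.txt"))) {
    orphan <- setdiff(x[[1]]$id, imgs$id)
    if (length(orphan))
      stop_invalid(x[[2]], ": image id ", orphan[1], " absent from images.txt")
    missing <- setdiff(imgs$id, x[[1]]$id)
    if (length(missing))
      stop_invalid(x[[2]], ": no entry for image id ", missing[1])
  }
  labs <- labs[match(imgs$id, labs$id), ]
  splits <- splits[match(imgs$id, splits$id), ]
  class_ids <- as.integer(labs$value)
  uc <- sort(unique(class_ids))
  label <- match(class_ids, uc) - 1L
  class_names <- vapply(uc, function(k) {
    p <- dirname(imgs$value[class_ids == k][1])
    if (p == ".") as.character(k) else basename(p)
  }, "")
  out <- data.frame(image_id = imgs$id,
                    image_path = file.path(normalizePath(root), "images",
                                           imgs$value),
                    label = label,
                    split = ifelse(splits$value == "1", "train", "test"),
                    stringsAsFactors = FALSE)
  if (check_paths) {
    gone <- which(!file.exists(out$image_path))
    if (length(gone))
      stop_invalid("images.txt: file for image id ", out$image_id[gone[1]],
                   " not found: ", out$image_path[gone[1]])
  }
  attr(out, "class_names") <- class_names
  class(out) <- c("dataset_index", "data.frame")
  out
}

#' Read a class-per-folder dataset layout
#'
#' `root/<class>/<image>` with classes sorted lexicographically (C locale)
#' into labels 0, 1, ..., independent of the OS listing order. Files
#' without a PNG/JPEG extension are skipped with a warning.
#'
#' @param root Dataset root directory.
#' @return A `"dataset_index"` data frame as in [read_cub_layout()].
#' @export
read_folder_layout <- function(root) {
  if (!dir.exists(root)) stop_invalid("no such directory: ", root)
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old))
  Sys.setlocale("LC_COLLATE", "C")
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop_invalid("no class directories under ", root)
  recs <- list()
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]), full.names = TRUE))
    ok <- grepl("\\.(png|jpe?g)$", files, ignore.case = TRUE)
    if (any(!ok))
      warning("ignoring non-image files under ", classes[k], ": ",
              paste(basename(files[!ok]), collapse = ", "))
    files <- files[ok]
    if (length(files))
      recs[[k]] <- data.frame(image_path = normalizePath(files),
                              label = k - 1L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) stop_invalid("no images under ", root)
  out <- data.frame(image_id = seq_len(nrow(out)), out,
                    split = "train", stringsAsFactors = FALSE)
  attr(out, "class_names") <- classes
  class(out) <- c("dataset_index", "data.frame")
  out
}

#' Load the images of a dataset index
#'
#' @param index A `"dataset_index"`.
#' @param split Optional split filter (`"train"` or `"test"`).
#' @return A list of `list(image, label)` usable by the training loops.
#' @export
load_index_images <- function(index, split = NULL) {
  if (!is.null(split)) index <- index[index$split == split, , drop = FALSE]
  lapply(seq_len(nrow(index)), function(i)
    list(image = read_image_file(index$image_path[i]),
         label = index$label[i]))
}

#' Write and read a training configuration as YAML
#'
#' @param config A [train_config()].
#' @param file Path.
#' @return The path / the restored `"train_config"`.
#' @export
write_config_yaml <- function(config, file) {
  yaml::write_yaml(unclass(config), file, precision = 15L)
  invisible(file)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(file) {
  do.call(train_config, yaml::read_yaml(file))
}

#' Write a run manifest
#'
#' Records the full configuration, the seed, the package version, and the
#' output paths as JSON before a run starts, so the run can be reproduced
#' from the manifest alone.
#'
#' @param config A [train_config()].
#' @param out_dir Output directory of the run.
#' @param file Manifest path (default `manifest.json` in `out_dir`).
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(config, out_dir,
                               file = file.path(out_dir, "manifest.json")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = unclass(config), seed = config$seed,
         package_version = as.character(utils::packageVersion("attnkd")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         out_dir = out_dir),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
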