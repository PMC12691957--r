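# On-disk dialects.
#
# Images: 8-bit grayscale PNG, named {patient}_{pair}_{L|R}.png.
# Boxes: YOLO-style text (one "0 x_center y_center width height" line per
# box, normalised to [0, 1]) next to each image, plus a JSON manifest with
# pixel-coordinate boxes for the whole dataset.

#' Write / read YOLO-format box annotations
#'
#' @param b Box tibble (pixel coordinates).
#' @param path Text file path.
#' @param width,height Image dimensions used for normalisation.
#' @returns `read_yolo_boxes()` returns a box tibble.
#' @export
write_yolo_boxes <- function(b, path, width, height) {
  lines <- sprintf("0 %.6f %.6f %.6f %.6f",
                   (b$x + b$w / 2) / width, (b$y + b$h / 2) / height,
                   b$w / width, b$h / height)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_boxes
#' @export
read_yolo_boxes <- function(path, width, height) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_boxes())
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  boxes(x = m[, 2] * width - m[, 4] * width / 2,
        y = m[, 3] * height - m[, 5] * height / 2,
        w = m[, 4] * width, h = m[, 5] * height)
}

write_gray_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

#' Write a phantom dataset to disk
#'
#' Writes 8-bit grayscale PNGs (`{patient}_{pair}_{L|R}.png`), YOLO-style
#' annotation text files, and a JSON manifest (`manifest.json`) with
#' pixel-coordinate boxes.
#'
#' @param pairs List of `bilateral_pair` objects.
#' @param dir Output directory (created if missing).
#' @returns The manifest path, invisibly.
#' @export
write_pair_dataset <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(pairs, function(p) {
    entry <- list(pair_id = p$pair_id, patient_id = p$patient_id)
    for (side in c("left", "right")) {
      tag <- if (side == "left") "L" else "R"
      img <- pair_image(p, side)
      b <- pair_boxes(p, side)
      stem <- sprintf("%s_%s_%s", p$patient_id, p$pair_id, tag)
      write_gray_png(img, file.path(dir, paste0(stem, ".png")))
      write_yolo_boxes(b, file.path(dir, paste0(stem, ".txt")),
                       ncol(img), nrow(img))
      entry[[side]] <- list(file = paste0(stem, ".png"),
                            boxes = as.data.frame(b))
    }
    entry
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a phantom dataset written by [write_pair_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @returns List of `bilateral_pair` objects (without the pre-speckle base
#'   fields, which are not serialised).
#' @export
read_pair_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest, function(e) {
    get_side <- function(side) {
      img <- read_gray_png(file.path(dir, e[[side]]$file))
      bx <- dplyr::bind_rows(lapply(e[[side]]$boxes, tibble::as_tibble))
      if (nrow(bx) == 0) bx <- empty_boxes()
      list(img = img, boxes = bx)
    }
    l <- get_side("left"); r <- get_side("right")
    structure(list(left_image = l$img, right_image = r$img,
                   left_boxes = l$boxes, right_boxes = r$boxes,
                   left_base = NULL, right_base = NULL,
                   distractor_boxes = empty_boxes(),
                   patient_id = e$patient_id, pair_id = e$pair_id),
              class = "bilateral_pair")
  })
}

#' Serialise / load mined patch pairs
#'
#' Pairs are written as paired PNGs plus a CSV index
#' (`pair_id, side, center_x, center_y, label, index_file, reference_file`).
#'
#' @param mined Tibble from [mine_training_pairs()].
#' @param dir Output directory.
#' @returns `read_mined_pairs()` returns the mined-pair tibble.
#' @export
write_mined_pairs <- function(mined, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- mined[, c("pair_id", "side", "center_x", "center_y", "label")]
  idx$index_file <- sprintf("pair%05d_idx.png", seq_len(nrow(mined)))
  idx$reference_file <- sprintf("pair%05d_ref.png", seq_len(nrow(mined)))
  for (i in seq_len(nrow(mined))) {
    write_gray_png(mined$index_patch[[i]], file.path(dir, idx$index_file[i]))
    write_gray_png(mined$reference_patch[[i]],
                   file.path(dir, idx$reference_file[i]))
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_mined_pairs
#' @export
read_mined_pairs <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  out <- tibble::as_tibble(idx[, c("pair_id", "side", "center_x",
                                   "center_y", "label")])
  out$index_patch <- lapply(idx$index_file, function(f) {
    read_gray_png(file.path(dir, f))
  })
  out$reference_patch <- lapply(idx$reference_file, function(f) {
    read_gray_png(file.path(dir, f))
  })
  out
}

#' Save / load a model checkpoint
#'
#' Weights go to a single serialised file; the configuration to a JSON
#' sidecar next to it.
#'
#' @param model A `sonosym_detector` or `sonosym_scnn`.
#' @param path Checkpoint path (e.g. `model.rds`); the sidecar is
#'   `<path>.json`.
#' @returns `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$cfg
  jsonlite::write_json(
    list(class = class(model)[1], config = unclass(cfg)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised sections: `phantom`, `hog`, `detector`, `symmetry`, `filter`,
#' `cascade`; each is passed to the corresponding `*_config()` /
#' [phantom_params()] constructor, so omitted fields keep their defaults.
#'
#' @param path YAML file path.
#' @returns Named list of configuration objects.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  build <- function(section, ctor) {
    args <- y[[section]] %||% list()
    do.call(ctor, args)
  }
  list(phantom = build("phantom", phantom_params),
       hog = build("hog", hog_config),
       detector = build("detector", detector_config),
       symmetry = build("symmetry", symmetry_config),
       filter = build("filter", filter_config),
       cascade = build("cascade", cascade_config))
}

#' Write detections as JSON records
#'
#' One record per detection:
#' `{pair_id, side, x, y, w, h, confidence, stage}`.
#'
#' @param detections Tibble from [run_pipeline()].
#' @param path Output JSON path.
#' @export
write_detections_json <- function(detections, path) {
  jsonlite::write_json(detections, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
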