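# Contralateral reference localisation and training-pair mining.
#
# A candidate box on one side of a bilateral pair is compared against
# patches of the opposite side: the exact anatomical mirror of its centre
# plus three jittered mirrors, to absorb small probe-placement offsets. HOG
# matching picks the reference that best resembles the candidate's
# surroundings. Training pairs for the similarity filter are mined with a
# coarse sliding window over each hemifield (each side image).

#' Symmetry / reference-localisation configuration
#'
#' @param patch_size Side length of the square comparison patches (px).
#' @param jitter Magnitude of the mirror-centre jitter (px); the three
#'   jittered candidates use distinct non-zero offsets from
#'   `{-jitter, 0, +jitter}^2`.
#' @param mine_stride Stride of the training-time sliding window (px).
#' @param mirror_mode `"flip"` (anatomical horizontal mirroring, the
#'   default) or `"identity"` (sides already co-registered).
#' @param expand_margin Margin (px) by which a detection box is grown in all
#'   four directions to form the feature region; `NULL` grows the box to the
#'   patch size, clamped to at least 8 px of context.
#' @returns An object of class `symmetry_config`.
#' @export
symmetry_config <- function(patch_size = 128, jitter = 32, mine_stride = 64,
                            mirror_mode = c("flip", "identity"),
                            expand_margin = NULL) {
  mirror_mode <- match.arg(mirror_mode)
  structure(list(patch_size = as.integer(patch_size),
                 jitter = as.integer(jitter),
                 mine_stride = as.integer(mine_stride),
                 mirror_mode = mirror_mode,
                 expand_margin = expand_margin),
            class = "symmetry_config")
}

#' Mirror a box across the vertical midline of an image
#'
#' With `mode = "flip"`, `x' = width - x - w` (an involution); heights and
#' vertical positions are unchanged. With `mode = "identity"` the box is
#' returned as is.
#'
#' @param box Box tibble (any number of rows).
#' @param image_width Width of the image the box lives in (px).
#' @param mode `"flip"` or `"identity"`.
#' @returns Box tibble of the same shape.
#' @export
mirror_box <- function(box, image_width, mode = c("flip", "identity")) {
  mode <- match.arg(mode)
  if (mode == "identity") return(box)
  box$x <- image_width - box$x - box$w
  box
}

#' Crop a square patch centred at a point
#'
#' Out-of-image area is filled by symmetric reflection of the source pixels.
#'
#' @param image Grayscale matrix.
#' @param center `c(cx, cy)` in pixel coordinates.
#' @param size Patch side length (px); must satisfy
#'   `size <= 2 * min(dim(image))`.
#' @returns `size` x `size` matrix.
#' @export
crop_patch <- function(image, center, size) {
  if (size > 2 * min(dim(image))) {
    abort("Patch size exceeds twice the smallest image dimension.")
  }
  crop_matrix(image, center, size)
}

# The three jitter offsets: distinct non-zero draws from {-j, 0, +j}^2.
jitter_offsets <- function(jitter, seed) {
  grid <- expand.grid(dx = c(-jitter, 0, jitter), dy = c(-jitter, 0, jitter))
  grid <- grid[!(grid$dx == 0 & grid$dy == 0), , drop = FALSE]
  withr::with_seed(seed, grid[sample.int(nrow(grid), 3L), , drop = FALSE])
}

expand_margin_for <- function(box, cfg) {
  cfg$expand_margin %||% max((cfg$patch_size - max(box$w, box$h)) / 2, 8)
}

#' Contralateral reference candidates for a candidate box
#'
#' Builds the four patch pairs the similarity filter scores: the index-side
#' patch centred on the candidate box, stacked with (1) the patch at the
#' exact mirrored centre on the opposite side and (2-4) three jittered
#' mirrors at distinct non-zero offsets drawn without replacement from
#' `{-jitter, 0, +jitter}^2 \ {(0,0)}`.
#'
#' @param box One-row box tibble on the index side.
#' @param pair A `bilateral_pair`.
#' @param side Side the box lives on (`"left"` or `"right"`).
#' @param cfg A [symmetry_config()].
#' @param seed Seed for the jitter draw (fixed seed, fixed offsets).
#' @returns Tibble with 4 rows: `candidate` (1 = exact mirror), `offset_x`,
#'   `offset_y`, `ref_cx`, `ref_cy` and list-columns `index_patch`,
#'   `reference_patch` (each `patch_size` x `patch_size`).
#' @export
reference_candidates <- function(box, pair, side = c("left", "right"),
                                 cfg = symmetry_config(), seed = 1L) {
  side <- match.arg(side)
  idx_img <- pair_image(pair, side)
  ref_img <- pair_image(pair, other_side(side))
  ctr <- box_centers(box)[1, ]
  mbox <- mirror_box(box, ncol(idx_img), cfg$mirror_mode)
  mctr <- box_centers(mbox)[1, ]
  offs <- unname(rbind(c(0, 0), as.matrix(jitter_offsets(cfg$jitter, seed))))
  # the feature region is the box expanded in all four directions; for
  # boxes smaller than the patch the expansion IS the patch-size context,
  # for larger boxes the oversized crop is scaled back to the patch size
  margin <- expand_margin_for(box, cfg)
  crop_sz <- max(cfg$patch_size, 2 * round((max(box$w, box$h) + 2 * margin) / 2))
  rescale <- function(p) {
    if (nrow(p) == cfg$patch_size) p else
      resize_bilinear(p, cfg$patch_size, cfg$patch_size)
  }
  index_patch <- rescale(crop_patch(idx_img, ctr, crop_sz))
  tibble::tibble(
    candidate = seq_len(4L),
    offset_x = offs[, 1], offset_y = offs[, 2],
    ref_cx = mctr[1] + offs[, 1], ref_cy = mctr[2] + offs[, 2],
    index_patch = rep(list(index_patch), 4L),
    reference_patch = purrr::map2(.data$ref_cx, .data$ref_cy, function(cx, cy) {
      rescale(crop_reference(ref_img, c(cx, cy), crop_sz, cfg$mirror_mode))
    })
  )
}

#' Localise the contralateral reference centre by HOG matching
#'
#' Among the four candidate centres (exact mirror first, then the three
#' jitters) returns the one whose patch minimises the HOG descriptor
#' distance to the feature patch; ties are broken by candidate order.
#'
#' @param feature_patch Index-side patch (matrix).
#' @param contralateral_image Opposite-side image.
#' @param mirror_center `c(cx, cy)`: the exact mirrored centre.
#' @param cfg A [symmetry_config()].
#' @param hog_cfg A [hog_config()].
#' @param seed Seed for the jitter draw.
#' @returns List: `center` (best `c(cx, cy)`), `candidate` (index 1-4),
#'   `distances` (all four HOG distances). Under flip mirroring candidate
#'   patches are compared (and returned elsewhere) in the index side's
#'   orientation.
#' @export
refine_reference <- function(feature_patch, contralateral_image, mirror_center,
                             cfg = symmetry_config(), hog_cfg = hog_config(),
                             seed = 1L) {
  offs <- rbind(c(0, 0), as.matrix(jitter_offsets(cfg$jitter, seed)))
  d_feat <- hog_descriptor(feature_patch, hog_cfg)
  dists <- vapply(seq_len(4L), function(k) {
    ctr <- mirror_center + c(offs[k, 1], offs[k, 2])
    hog_distance(d_feat,
                 hog_descriptor(crop_reference(contralateral_image, ctr,
                                               cfg$patch_size,
                                               cfg$mirror_mode), hog_cfg))
  }, 0)
  best <- which.min(dists)  # which.min takes the first minimum: mirror wins ties
  list(center = mirror_center + c(offs[best, 1], offs[best, 2]),
       candidate = best, distances = dists)
}

# Crop a contralateral reference patch; under flip mirroring the crop is
# flipped back into the index side's orientation so that homologous
# structures land at the same within-patch coordinates.
crop_reference <- function(image, center, size, mirror_mode) {
  p <- crop_matrix(image, center, size)
  if (mirror_mode == "flip") p <- p[, ncol(p):1, drop = FALSE]
  p
}

window_overlaps_gt <- function(cx, cy, size, gt) {
  if (nrow(gt) == 0) return(FALSE)
  wbox <- boxes(cx - size / 2, cy - size / 2, size, size)
  any(iou_matrix(wbox, gt) > 0)
}

center_in_gt <- function(cx, cy, gt) {
  if (nrow(gt) == 0) return(FALSE)
  any(cx >= gt$x & cx < gt$x + gt$w & cy >= gt$y & cy < gt$y + gt$h)
}

#' Mine labelled patch pairs from a bilateral pair
#'
#' Slides a `patch_size` window at `mine_stride` over each side (index
#' side), localises its contralateral reference by HOG matching, and
#' labels: windows whose centre lies inside a ground-truth box while the
#' reference region touches no ground truth are *dissimilar* (+1); windows
#' touching no ground truth on either side are *similar* (-1); windows
#' overlapping ground truth on both sides, or touching a lesion without
#' containing its centre, are discarded as ambiguous. In addition to the
#' coarse grid, one anchored window is mined at the centre of every
#' ground-truth box - the configuration verification sees at inference -
#' so every pair with a unilateral lesion contributes dissimilar examples.
#'
#' @param pair A `bilateral_pair`.
#' @param cfg A [symmetry_config()].
#' @param hog_cfg A [hog_config()].
#' @param seed Seed driving the jitter draws (one per window).
#' @returns Tibble: `pair_id`, `side`, `center_x`, `center_y`,
#'   `ref_center_x`, `ref_center_y`, `label` (-1 similar / +1 dissimilar)
#'   and list-columns `index_patch`, `reference_patch`.
#' @export
mine_training_pairs <- function(pair, cfg = symmetry_config(),
                                hog_cfg = hog_config(), seed = 1L) {
  ps <- cfg$patch_size
  out <- list()
  win_id <- 0L
  for (side in c("left", "right")) {
    img <- pair_image(pair, side)
    ref_img <- pair_image(pair, other_side(side))
    gt_idx <- pair_boxes(pair, side)
    gt_ref <- pair_boxes(pair, other_side(side))
    cxs <- seq(ps / 2, ncol(img) - ps / 2, by = cfg$mine_stride)
    cys <- seq(ps / 2, nrow(img) - ps / 2, by = cfg$mine_stride)
    centers <- expand.grid(cx = cxs, cy = cys)
    if (nrow(gt_idx) > 0) {
      gc <- box_centers(gt_idx)
      centers <- rbind(centers, data.frame(cx = gc[, "cx"], cy = gc[, "cy"]))
    }
    for (wi in seq_len(nrow(centers))) {
      cx <- centers$cx[wi]; cy <- centers$cy[wi]
      win_id <- win_id + 1L
      wbox <- boxes(cx - ps / 2, cy - ps / 2, ps, ps)
      feat <- crop_patch(img, c(cx, cy), ps)
      mctr <- box_centers(mirror_box(wbox, ncol(img), cfg$mirror_mode))[1, ]
      ref <- refine_reference(feat, ref_img, mctr, cfg, hog_cfg,
                              seed = seed + win_id)
      ref_touch <- window_overlaps_gt(ref$center[1], ref$center[2], ps, gt_ref)
      idx_center_hit <- center_in_gt(cx, cy, gt_idx)
      idx_touch <- window_overlaps_gt(cx, cy, ps, gt_idx)
      label <- if (idx_center_hit && !ref_touch) {
        1L
      } else if (!idx_touch && !ref_touch) {
        -1L
      } else {
        NA_integer_
      }
      if (is.na(label)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        pair_id = pair$pair_id, side = side,
        center_x = cx, center_y = cy,
        ref_center_x = ref$center[1], ref_center_y = ref$center[2],
        label = label,
        index_patch = list(feat),
        reference_patch = list(crop_reference(ref_img, ref$center, ps,
                                              cfg$mirror_mode)))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(pair_id = character(), side = character(),
                          center_x = numeric(), center_y = numeric(),
                          ref_center_x = numeric(), ref_center_y = numeric(),
                          label = integer(), index_patch = list(),
                          reference_patch = list()))
  }
  dplyr::bind_rows(out)
}

#' Mine labelled patch pairs from a list of bilateral pairs
#'
#' @param pairs List of `bilateral_pair` objects.
#' @inheritParams mine_training_pairs
#' @returns Row-bound tibble of [mine_training_pairs()] results.
#' @export
mine_dataset_pairs <- function(pairs, cfg = symmetry_config(),
                               hog_cfg = hog_config(), seed = 1L) {
  dplyr::bind_rows(purrr::imap(pairs, function(p, i) {
    mine_training_pairs(p, cfg, hog_cfg, seed = seed + 1000L * i)
  }))
}
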