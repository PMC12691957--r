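# Lightweight anchor-based single-class detector.
#
# Head geometry: three detection heads at strides 8 / 16 / 32, three anchors
# per spatial location, and per anchor 4 box coordinates + 1 objectness
# score + 1 class logit. The backbone is a small strided conv net with one
# residual block; the cascade downstream is detector-agnostic, so the
# backbone is deliberately compact enough to train on CPU. Boxes are encoded
# YOLO-style: sigmoid cell offsets for the centre, log ratios to the anchor
# for width/height; the box loss is mean-squared error in that encoded
# space, objectness and class use binary cross-entropy on logits.

#' Detector configuration
#'
#' @param input_size Square network input in pixels; must be divisible by
#'   the largest stride. 544 is the faithful setting; 256 is a practical
#'   CPU-scale profile for the 256 x 256 phantoms.
#' @param strides Downsampling factor of each detection head.
#' @param anchors_per_level Anchors per spatial location (3).
#' @param anchor_sizes List (one per stride, ascending) of
#'   `anchors_per_level` x 2 matrices of anchor (w, h) in input pixels, or
#'   `NULL` to fit them by k-means on the training boxes.
#' @param n_classes Number of foreground classes (1: lesion vs background).
#' @param conf_floor Minimum confidence returned by [detect()].
#' @param nms_iou IoU threshold of greedy non-maximum suppression.
#' @param max_det Maximum detections kept per image after NMS.
#' @returns An object of class `detector_config`.
#' @export
detector_config <- function(input_size = 544,
                            strides = c(8, 16, 32),
                            anchors_per_level = 3,
                            anchor_sizes = NULL,
                            n_classes = 1,
                            conf_floor = 0.001,
                            nms_iou = 0.45,
                            max_det = 100) {
  strides <- sort(as.integer(strides))
  if (input_size %% max(strides) != 0) {
    abort("input_size must be divisible by the largest stride.")
  }
  if (is.null(anchor_sizes)) {
    anchor_sizes <- default_anchor_sizes(strides, input_size)
  }
  structure(list(input_size = as.integer(input_size), strides = strides,
                 anchors_per_level = as.integer(anchors_per_level),
                 anchor_sizes = anchor_sizes,
                 n_classes = as.integer(n_classes),
                 conf_floor = conf_floor, nms_iou = nms_iou,
                 max_det = as.integer(max_det)),
            class = "detector_config")
}

default_anchor_sizes <- function(strides, input_size) {
  lapply(seq_along(strides), function(l) {
    base <- strides[l] * 2.5 * input_size / 256
    rbind(c(base, base), c(base * 1.4, base * 0.8), c(base * 0.8, base * 1.4))
  })
}

#' Number of prediction channels per detection head
#'
#' Each anchor predicts 4 box coordinates, 1 objectness score and
#' `n_classes` class logits, so a head emits
#' `anchors_per_level * (5 + n_classes)` channels.
#'
#' @param cfg A [detector_config()].
#' @returns Integer channel count (18 for the default 3 anchors, 1 class).
#' @export
head_channels <- function(cfg) {
  cfg$anchors_per_level * (4L + 1L + cfg$n_classes)
}

#' Fit anchor sizes by k-means over ground-truth boxes
#'
#' Clusters the (w, h) of the supplied boxes into
#' `anchors_per_level * length(strides)` groups and assigns them to levels
#' by ascending area (small anchors to the finest stride).
#'
#' @param wh Two-column matrix of box widths/heights in network-input pixels.
#' @param cfg A [detector_config()].
#' @returns List of per-level anchor matrices, as in `detector_config()`.
#' @export
anchors_from_boxes <- function(wh, cfg) {
  k <- cfg$anchors_per_level * length(cfg$strides)
  if (nrow(wh) < k) return(cfg$anchor_sizes)
  km <- kmeans(wh, centers = k, nstart = 5, iter.max = 50)
  centers <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  lapply(seq_along(cfg$strides), function(l) {
    centers[seq.int((l - 1) * cfg$anchors_per_level + 1,
                    l * cfg$anchors_per_level), , drop = FALSE]
  })
}

#' Build an untrained detector model
#'
#' @param cfg A [detector_config()].
#' @returns An object of class `sonosym_detector` holding the parameters and
#'   the configuration. A forward pass yields one grid per stride of shape
#'   `(input/stride, input/stride, head_channels(cfg))`.
#' @export
build_detector <- function(cfg = detector_config()) {
  nch <- head_channels(cfg)
  params <- list(
    c1 = conv_init(3, 3, 1, 12),
    c2 = conv_init(3, 3, 12, 20),
    c3 = conv_init(3, 3, 20, 32),
    r3 = resblock_init(32),
    c4 = conv_init(3, 3, 32, 40),
    c5 = conv_init(3, 3, 40, 48),
    h8 = conv_init(3, 3, 32, nch),
    h16 = conv_init(3, 3, 40, nch),
    h32 = conv_init(3, 3, 48, nch)
  )
  structure(list(params = params, cfg = cfg), class = "sonosym_detector")
}

det_forward <- function(model, x) {
  p <- model$params
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  c1 <- conv_fwd(x, p$c1, stride = 2L); a1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(a1$y, p$c2, stride = 2L); a2 <- relu_fwd(c2$y)
  c3 <- conv_fwd(a2$y, p$c3, stride = 2L); a3 <- relu_fwd(c3$y)
  r3 <- resblock_fwd(a3$y, p$r3)
  c4 <- conv_fwd(r3$y, p$c4, stride = 2L); a4 <- relu_fwd(c4$y)
  c5 <- conv_fwd(a4$y, p$c5, stride = 2L); a5 <- relu_fwd(c5$y)
  h8 <- conv_fwd(r3$y, p$h8, stride = 1L)
  h16 <- conv_fwd(a4$y, p$h16, stride = 1L)
  h32 <- conv_fwd(a5$y, p$h32, stride = 1L)
  list(grids = list(h8$y, h16$y, h32$y),
       cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, a3 = a3,
                    r3 = r3, c4 = c4, a4 = a4, c5 = c5, a5 = a5,
                    h8 = h8, h16 = h16, h32 = h32))
}

det_backward <- function(model, cache, dgrids) {
  p <- model$params
  g <- list()
  bh8 <- conv_bwd(dgrids[[1]], p$h8, cache$h8$cache)
  bh16 <- conv_bwd(dgrids[[2]], p$h16, cache$h16$cache)
  bh32 <- conv_bwd(dgrids[[3]], p$h32, cache$h32$cache)
  g$h8 <- list(W = bh8$dW, b = bh8$db)
  g$h16 <- list(W = bh16$dW, b = bh16$db)
  g$h32 <- list(W = bh32$dW, b = bh32$db)

  da5 <- relu_bwd(bh32$dx, cache$a5$cache)
  b5 <- conv_bwd(da5, p$c5, cache$c5$cache)
  g$c5 <- list(W = b5$dW, b = b5$db)
  da4 <- relu_bwd(b5$dx + bh16$dx, cache$a4$cache)
  b4 <- conv_bwd(da4, p$c4, cache$c4$cache)
  g$c4 <- list(W = b4$dW, b = b4$db)
  br3 <- resblock_bwd(b4$dx + bh8$dx, p$r3, cache$r3$cache)
  g$r3 <- br3$grads
  da3 <- relu_bwd(br3$dx, cache$a3$cache)
  b3 <- conv_bwd(da3, p$c3, cache$c3$cache)
  g$c3 <- list(W = b3$dW, b = b3$db)
  da2 <- relu_bwd(b3$dx, cache$a2$cache)
  b2 <- conv_bwd(da2, p$c2, cache$c2$cache)
  g$c2 <- list(W = b2$dW, b = b2$db)
  da1 <- relu_bwd(b2$dx, cache$a1$cache)
  b1 <- conv_bwd(da1, p$c1, cache$c1$cache)
  g$c1 <- list(W = b1$dW, b = b1$db)
  g
}

# ---- box encoding ----------------------------------------------------------

#' Encode a ground-truth box to its anchor representation
#'
#' @param box One-row box tibble (network-input coordinates).
#' @param anchor Anchor (w, h) in pixels.
#' @param stride Stride of the head the anchor belongs to.
#' @returns List with grid cell `(i, j)` (1-based row/col) and raw logits
#'   `t = c(tx, ty, tw, th)` such that [decode_box()] recovers the box.
#' @export
encode_box <- function(box, anchor, stride) {
  cx <- box$x + box$w / 2
  cy <- box$y + box$h / 2
  j <- floor(cx / stride); i <- floor(cy / stride)
  ox <- clamp(cx / stride - j, 1e-4, 1 - 1e-4)
  oy <- clamp(cy / stride - i, 1e-4, 1 - 1e-4)
  list(i = as.integer(i) + 1L, j = as.integer(j) + 1L,
       t = c(qlogis(ox), qlogis(oy),
             log(box$w / anchor[1]), log(box$h / anchor[2])),
       off = c(ox, oy, log(box$w / anchor[1]), log(box$h / anchor[2])))
}

#' Decode raw logits at a grid cell back to a box
#'
#' @param t Raw predictions `c(tx, ty, tw, th)`.
#' @param i,j 1-based grid cell (row, col).
#' @inheritParams encode_box
#' @returns One-row box tibble in network-input coordinates.
#' @export
decode_box <- function(t, i, j, anchor, stride) {
  cx <- (j - 1 + plogis(t[1])) * stride
  cy <- (i - 1 + plogis(t[2])) * stride
  w <- anchor[1] * exp(clamp(t[3], -6, 6))
  h <- anchor[2] * exp(clamp(t[4], -6, 6))
  boxes(cx - w / 2, cy - h / 2, w, h)
}

# Assign GT boxes to anchors: best shape-IoU anchor across all levels plus
# every anchor with shape-IoU > 0.5. Returns a data frame of assignments.
assign_anchors <- function(gt, cfg) {
  all_anchors <- do.call(rbind, cfg$anchor_sizes)
  na <- cfg$anchors_per_level
  out <- list()
  for (gi in seq_len(nrow(gt))) {
    ious <- wh_iou(c(gt$w[gi], gt$h[gi]), all_anchors)
    chosen <- union(which.max(ious), which(ious > 0.5))
    for (a in chosen) {
      level <- (a - 1L) %/% na + 1L
      ai <- (a - 1L) %% na + 1L
      enc <- encode_box(gt[gi, ], cfg$anchor_sizes[[level]][ai, ],
                        cfg$strides[level])
      gh <- cfg$input_size %/% cfg$strides[level]
      if (enc$i < 1 || enc$i > gh || enc$j < 1 || enc$j > gh) next
      out[[length(out) + 1L]] <- data.frame(
        gt = gi, level = level, a = ai, i = enc$i, j = enc$j,
        ox = enc$off[1], oy = enc$off[2], tw = enc$off[3], th = enc$off[4])
    }
  }
  if (length(out) == 0) return(NULL)
  asg <- do.call(rbind, out)
  asg[!duplicated(asg[, c("level", "a", "i", "j")]), , drop = FALSE]
}

# Per-image loss and head gradients. Returns loss components and the three
# dL/d(grid) arrays.
det_loss <- function(grids, gt, cfg, w_obj_pos = 5, w_box = 10) {
  na <- cfg$anchors_per_level
  npred <- 5L + cfg$n_classes
  asg <- if (nrow(gt) > 0) assign_anchors(gt, cfg) else NULL
  n_all <- sum(vapply(grids, function(gr) prod(dim(gr)[1:2]) * na, 0))
  n_pos <- if (is.null(asg)) 0L else nrow(asg)

  dgrids <- vector("list", 3L)
  l_obj <- 0; l_box <- 0; l_cls <- 0
  for (l in 1:3) {
    gr <- grids[[l]]
    gh <- dim(gr)[1]; gw <- dim(gr)[2]
    pr <- array(gr, c(gh, gw, npred, na))  # channel layout: anchor-major
    # channels are stored (a-1)*npred + k; array() above splits k fastest
    tobj <- array(0, c(gh, gw, na))
    wobj <- array(1, c(gh, gw, na))
    dgr <- array(0, dim(gr))
    rows <- if (!is.null(asg)) which(asg$level == l) else integer()
    zobj <- pr[, , 5L, , drop = FALSE]
    dim(zobj) <- c(gh, gw, na)
    for (r in rows) {
      i <- asg$i[r]; j <- asg$j[r]; a <- asg$a[r]
      tobj[i, j, a] <- 1
      wobj[i, j, a] <- w_obj_pos
      tvec <- c(asg$ox[r], asg$oy[r], asg$tw[r], asg$th[r])
      z <- pr[i, j, 1:4, a]
      sxy <- plogis(z[1:2])
      d <- c(sxy - tvec[1:2], z[3:4] - tvec[3:4])
      l_box <- l_box + sum(d^2)
      dz <- c(2 * d[1:2] * sxy * (1 - sxy), 2 * d[3:4]) * w_box / max(1, n_pos)
      base <- (a - 1L) * npred
      for (k in 1:4) dgr[i, j, base + k] <- dgr[i, j, base + k] + dz[k]
    }
    # objectness and lesion-vs-background logit are both supervised densely
    # (the class channel would otherwise drift on background and inflate
    # the decoded confidence = sigmoid(obj) * sigmoid(cls))
    sobj <- plogis(zobj)
    bce <- -(tobj * log(pmax(sobj, 1e-12)) +
               (1 - tobj) * log(pmax(1 - sobj, 1e-12)))
    l_obj <- l_obj + sum(wobj * bce)
    dobj <- wobj * (sobj - tobj) / n_all
    zcls <- pr[, , 6L, , drop = FALSE]
    dim(zcls) <- c(gh, gw, na)
    scls <- plogis(zcls)
    l_cls <- l_cls + sum(wobj * -(tobj * log(pmax(scls, 1e-12)) +
                                    (1 - tobj) * log(pmax(1 - scls, 1e-12))))
    dcls <- wobj * (scls - tobj) / n_all
    for (a in seq_len(na)) {
      dgr[, , (a - 1L) * npred + 5L] <- dgr[, , (a - 1L) * npred + 5L] +
        dobj[, , a]
      dgr[, , (a - 1L) * npred + 6L] <- dgr[, , (a - 1L) * npred + 6L] +
        dcls[, , a]
    }
    dgrids[[l]] <- dgr
  }
  list(loss = (l_obj + l_cls) / n_all + w_box * l_box / max(1, n_pos),
       dgrids = dgrids, n_pos = n_pos)
}

# ---- letterboxing ----------------------------------------------------------

letterbox <- function(img, size, fill = 0.5) {
  h <- nrow(img); w <- ncol(img)
  scale <- min(size / h, size / w)
  nh <- round(h * scale); nw <- round(w * scale)
  resized <- resize_bilinear(img, nh, nw)
  out <- matrix(fill, size, size)
  py <- (size - nh) %/% 2; px <- (size - nw) %/% 2
  out[(py + 1):(py + nh), (px + 1):(px + nw)] <- resized
  list(img = out, scale = scale, pad_x = px, pad_y = py)
}

letterbox_boxes <- function(b, lb) {
  b$x <- b$x * lb$scale + lb$pad_x
  b$y <- b$y * lb$scale + lb$pad_y
  b$w <- b$w * lb$scale
  b$h <- b$h * lb$scale
  b
}

unletterbox_boxes <- function(b, lb) {
  b$x <- (b$x - lb$pad_x) / lb$scale
  b$y <- (b$y - lb$pad_y) / lb$scale
  b$w <- b$w / lb$scale
  b$h <- b$h / lb$scale
  b
}

# ---- training --------------------------------------------------------------

#' Train the detector on bilateral phantom pairs
#'
#' Each side image of every pair is an independent training image
#' (lesion-free sides act as pure background). Anchor sizes are refit by
#' k-means on the training boxes unless `cfg$anchor_sizes` was set
#' explicitly and `refit_anchors = FALSE`.
#'
#' @param dataset List of `bilateral_pair` objects.
#' @param cfg A [detector_config()].
#' @param epochs Training epochs.
#' @param seed Integer seed; fixed seed gives an identical loss trace.
#' @param lr Adam learning rate.
#' @param refit_anchors Refit anchors by k-means on the dataset boxes?
#' @returns An object of class `detector_fit` with elements `model`
#'   (a `sonosym_detector`) and `loss_trace` (tibble: epoch, loss).
#' @export
train_detector <- function(dataset, cfg = detector_config(), epochs = 30,
                           seed = 1L, lr = 1e-3, refit_anchors = TRUE) {
  if (length(dataset) == 0) abort("Cannot train a detector on an empty dataset.")
  set.seed(seed)

  samples <- list()
  for (pair in dataset) {
    for (side in c("left", "right")) {
      lb <- letterbox(pair_image(pair, side), cfg$input_size)
      samples[[length(samples) + 1L]] <-
        list(img = lb$img, gt = letterbox_boxes(pair_boxes(pair, side), lb))
    }
  }

  if (refit_anchors) {
    wh <- do.call(rbind, lapply(samples, function(s) cbind(s$gt$w, s$gt$h)))
    if (!is.null(wh) && nrow(wh) > 0) {
      cfg$anchor_sizes <- anchors_from_boxes(wh, cfg)
    }
  }

  model <- build_detector(cfg)
  opt <- adam_init(model$params)
  trace <- numeric(epochs)
  skipped <- 0L
  for (ep in seq_len(epochs)) {
    # step decay: settle the objectness map in the last third of training
    lr_ep <- lr * if (ep > 2 * epochs / 3) 0.2 else 1
    ord <- sample.int(length(samples))
    total <- 0
    for (s in ord) {
      smp <- samples[[s]]
      fwd <- det_forward(model, smp$img)
      ls <- det_loss(fwd$grids, smp$gt, cfg)
      if (nrow(smp$gt) > 0 && ls$n_pos == 0) {
        skipped <- skipped + 1L
        next
      }
      total <- total + ls$loss
      grads <- det_backward(model, fwd$cache, ls$dgrids)
      st <- adam_step(model$params, grads, opt, lr = lr_ep)
      model$params <- st$params
      opt <- st$opt
    }
    trace[ep] <- total / length(samples)
    if (any(!is.finite(trace[ep]))) abort("Non-finite detector loss.")
  }
  if (skipped > 0) {
    warn(sprintf("%d image(s) had no assignable positive anchors and were skipped.",
                 skipped))
  }
  structure(list(model = model,
                 loss_trace = tibble::tibble(epoch = seq_len(epochs),
                                             loss = trace),
                 seed = seed, n_images = length(samples)),
            class = "detector_fit")
}

#' @export
print.detector_fit <- function(x, ...) {
  cat(sprintf("<detector_fit: %d images, %d epochs, final loss %.4f>\n",
              x$n_images, nrow(x$loss_trace), tail(x$loss_trace$loss, 1)))
  invisible(x)
}

# ---- inference -------------------------------------------------------------

decode_grids <- function(grids, cfg, conf_floor) {
  na <- cfg$anchors_per_level
  npred <- 5L + cfg$n_classes
  out <- list()
  for (l in seq_along(grids)) {
    gr <- grids[[l]]
    gh <- dim(gr)[1]; gw <- dim(gr)[2]
    pr <- array(gr, c(gh, gw, npred, na))
    for (a in seq_len(na)) {
      conf <- plogis(pr[, , 5L, a]) * plogis(pr[, , 6L, a])
      hits <- which(conf >= conf_floor, arr.ind = TRUE)
      if (nrow(hits) == 0) next
      anchor <- cfg$anchor_sizes[[l]][a, ]
      stride <- cfg$strides[l]
      i <- hits[, 1]; j <- hits[, 2]
      cx <- (j - 1 + plogis(pr[cbind(i, j, 1L, a)])) * stride
      cy <- (i - 1 + plogis(pr[cbind(i, j, 2L, a)])) * stride
      bw <- anchor[1] * exp(clamp(pr[cbind(i, j, 3L, a)], -6, 6))
      bh <- anchor[2] * exp(clamp(pr[cbind(i, j, 4L, a)], -6, 6))
      out[[length(out) + 1L]] <- tibble::tibble(
        x = cx - bw / 2, y = cy - bh / 2, w = bw, h = bh,
        confidence = conf[cbind(i, j)], level = l)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), w = numeric(),
                          h = numeric(), confidence = numeric(),
                          level = integer()))
  }
  dplyr::bind_rows(out)
}

#' Run the detector on one grayscale image
#'
#' The image is letterboxed to the network input size; decoded boxes are
#' mapped back to original pixel coordinates, clipped to the image, and
#' reduced by greedy NMS.
#'
#' @param model A `sonosym_detector` (typically `fit$model`).
#' @param image Grayscale matrix in \[0, 1\].
#' @param conf_floor Minimum confidence to return (defaults to the config).
#' @returns Tibble of detections (`x`, `y`, `w`, `h`, `confidence`,
#'   `level`), sorted by descending confidence.
#' @export
detect <- function(model, image, conf_floor = NULL) {
  cfg <- model$cfg
  conf_floor <- conf_floor %||% cfg$conf_floor
  if (conf_floor >= 1) {
    return(decode_grids(list(), cfg, conf_floor))
  }
  lb <- letterbox(image, cfg$input_size)
  fwd <- det_forward(model, lb$img)
  det <- decode_grids(fwd$grids, cfg, conf_floor)
  det <- dplyr::arrange(det, dplyr::desc(.data$confidence))
  det <- nms(det, cfg$nms_iou)
  det <- head(det, cfg$max_det %||% 100L)
  if (nrow(det) == 0) return(det)
  out <- unletterbox_boxes(det, lb)
  x2 <- pmin(out$x + out$w, ncol(image))
  y2 <- pmin(out$y + out$h, nrow(image))
  out$x <- pmax(out$x, 0)
  out$y <- pmax(out$y, 0)
  out$w <- x2 - out$x
  out$h <- y2 - out$y
  out <- out[out$w > 0 & out$h > 0, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$confidence))
}

#' Greedy non-maximum suppression
#'
#' @param detections Detection tibble sorted by descending confidence.
#' @param iou_threshold Boxes with IoU above this to an already-kept box are
#'   suppressed.
#' @returns The kept subset, original order preserved. Idempotent.
#' @export
nms <- function(detections, iou_threshold) {
  n <- nrow(detections)
  if (n <= 1) return(detections)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < n) {
      rest <- which(alive & seq_len(n) > i)
      if (length(rest) > 0) {
        ious <- iou(detections[i, c("x", "y", "w", "h")],
                    detections[rest, c("x", "y", "w", "h")])
        alive[rest[ious > iou_threshold]] <- FALSE
      }
    }
  }
  detections[keep, , drop = FALSE]
}
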