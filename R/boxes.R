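# Bounding-box conventions used throughout the package:
#   * boxes live in tibbles with numeric columns x, y, w, h
#   * (x, y) is the top-left corner, 0-based; the box covers the half-open
#     region [x, x + w) x [y, y + h) in pixel coordinates
#   * images are matrices indexed [row, col] = [y + 1, x + 1]

#' Construct a tibble of bounding boxes
#'
#' @param x,y Top-left corner (0-based pixel coordinates).
#' @param w,h Box width and height in pixels (must be positive).
#' @returns A tibble with columns `x`, `y`, `w`, `h`.
#' @export
#' @examples
#' boxes(x = c(10, 40), y = c(5, 20), w = 20, h = 10)
boxes <- function(x = numeric(), y = numeric(), w = numeric(), h = numeric()) {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        w = as.numeric(w), h = as.numeric(h))
  if (nrow(out) > 0 && any(out$w <= 0 | out$h <= 0)) {
    abort("Box widths and heights must be positive.")
  }
  out
}

empty_boxes <- function() boxes()

box_centers <- function(b) {
  cbind(cx = b$x + b$w / 2, cy = b$y + b$h / 2)
}

#' Intersection-over-union between two sets of boxes
#'
#' Vectorised pairwise IoU. `iou()` is the scalar/row-wise form used by the
#' matching and NMS routines; `iou_matrix()` returns the full cross matrix.
#'
#' @param a,b Box tibbles (see [boxes()]); `iou()` recycles single rows.
#' @returns `iou()`: numeric vector in \[0, 1\]. `iou_matrix()`: an
#'   `nrow(a)` x `nrow(b)` matrix.
#' @export
#' @examples
#' iou(boxes(0, 0, 2, 2), boxes(1, 0, 2, 2)) # 2/6
iou <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L) b <- b[rep(1L, n), ]
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  uni <- a$w * a$h + b$w * b$h - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' @rdname iou
#' @export
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(), nrow(a), nrow(b)))
  }
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) out[, j] <- iou(a, b[j, ])
  out
}

clip_boxes <- function(b, width, height) {
  x2 <- pmin(b$x + b$w, width)
  y2 <- pmin(b$y + b$h, height)
  b$x <- pmax(b$x, 0)
  b$y <- pmax(b$y, 0)
  b$w <- x2 - b$x
  b$h <- y2 - b$y
  b[b$w > 0 & b$h > 0, , drop = FALSE]
}

# Shape-only IoU between (w, h) pairs as if concentric; used for anchor
# assignment.
wh_iou <- function(wh_a, wh_b) {
  iw <- pmin(wh_a[1], wh_b[, 1])
  ih <- pmin(wh_a[2], wh_b[, 2])
  inter <- iw * ih
  inter / (wh_a[1] * wh_a[2] + wh_b[, 1] * wh_b[, 2] - inter)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Symmetric (edge-repeating) reflection of 1-based indices into [1, n].
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j))
}

# size x size crop centred at `center` = c(cx, cy) in pixel coordinates;
# out-of-image area filled by symmetric reflection.
crop_matrix <- function(image, center, size) {
  x0 <- round(center[1] - size / 2)
  y0 <- round(center[2] - size / 2)
  rows <- reflect_index(seq.int(y0 + 1L, y0 + size), nrow(image))
  cols <- reflect_index(seq.int(x0 + 1L, x0 + size), ncol(image))
  image[rows, cols, drop = FALSE]
}

# Bilinear resize of a matrix to (out_h, out_w), pixel-centre aligned.
resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  ry <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  rx <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  y0 <- clamp(floor(ry), 0, in_h - 1); x0 <- clamp(floor(rx), 0, in_w - 1)
  y1 <- pmin(y0 + 1, in_h - 1);        x1 <- pmin(x0 + 1, in_w - 1)
  wy <- clamp(ry - y0, 0, 1);          wx <- clamp(rx - x0, 0, 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c2 <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  wxm <- matrix(wx, nrow = out_h, ncol = out_w, byrow = TRUE)
  wym <- matrix(wy, nrow = out_h, ncol = out_w)
  top <- a * (1 - wxm) + b * wxm
  bot <- c2 * (1 - wxm) + d * wxm
  top * (1 - wym) + bot * wym
}
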