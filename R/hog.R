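# Histogram of Oriented Gradients.
#
# Classic dense HOG: centered-difference gradients without pre-smoothing,
# orientations folded to [0, 180) when unsigned, trilinear (2 spatial x 1
# orientation) soft-binning of gradient magnitude into cell histograms,
# 2x2-cell blocks at one-cell stride, L2-Hys block normalisation
# (L2-normalise, clip, re-L2-normalise). Used here both as the matching
# descriptor that localises contralateral reference regions and as an
# optional per-pixel gradient-energy channel.

#' HOG configuration
#'
#' @param cell Cell size in pixels, `c(h, w)`.
#' @param block Block size in cells, `c(h, w)`.
#' @param bins Number of orientation bins.
#' @param signed Use the full 0-360 degree orientation range? The default
#'   (`FALSE`) folds orientations to \[0, 180).
#' @param block_norm Block normalisation scheme; only `"L2-Hys"` is
#'   implemented.
#' @param hys_clip Clipping value applied between the two L2 normalisations.
#' @returns An object of class `hog_config`.
#' @export
hog_config <- function(cell = c(8, 8), block = c(2, 2), bins = 9,
                       signed = FALSE, block_norm = "L2-Hys",
                       hys_clip = 0.2) {
  if (length(cell) == 1L) cell <- rep(cell, 2L)
  if (length(block) == 1L) block <- rep(block, 2L)
  stopifnot(bins >= 2, all(cell > 0), all(block > 0))
  block_norm <- match.arg(block_norm, "L2-Hys")
  structure(list(cell = as.integer(cell), block = as.integer(block),
                 bins = as.integer(bins), signed = signed,
                 block_norm = block_norm, hys_clip = hys_clip),
            class = "hog_config")
}

# Reflection-pad an image so its dimensions are multiples of the cell size.
pad_to_cells <- function(img, cell) {
  ph <- (cell[1] - nrow(img) %% cell[1]) %% cell[1]
  pw <- (cell[2] - ncol(img) %% cell[2]) %% cell[2]
  if (ph == 0 && pw == 0) return(img)
  rows <- reflect_index(seq_len(nrow(img) + ph), nrow(img))
  cols <- reflect_index(seq_len(ncol(img) + pw), ncol(img))
  img[rows, cols, drop = FALSE]
}

# Cell histogram array (ncy x ncx x bins) with trilinear soft binning.
hog_cell_histograms <- function(img, cfg) {
  img <- pad_to_cells(img, cfg$cell)
  h <- nrow(img); w <- ncol(img)
  ncy <- h %/% cfg$cell[1]; ncx <- w %/% cfg$cell[2]

  # Centered differences with replicated edges.
  gx <- img[, c(2:w, w), drop = FALSE] - img[, c(1, 1:(w - 1)), drop = FALSE]
  gy <- img[c(2:h, h), , drop = FALSE] - img[c(1, 1:(h - 1)), , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  range_deg <- if (cfg$signed) 360 else 180
  ang <- ang %% range_deg

  bw <- range_deg / cfg$bins
  ob <- ang / bw - 0.5
  o0 <- floor(ob)
  wo <- ob - o0                       # weight of the upper orientation bin
  bin0 <- (as.vector(o0) %% cfg$bins) + 1L
  bin1 <- (bin0 %% cfg$bins) + 1L

  # Spatial soft binning against cell centres (pixel centres at idx - 0.5).
  py <- matrix(seq_len(h) - 0.5, h, w)
  px <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  uy <- py / cfg$cell[1] - 0.5
  ux <- px / cfg$cell[2] - 0.5
  cy0 <- floor(uy); cx0 <- floor(ux)
  wy <- uy - cy0;   wx <- ux - cx0

  hist <- numeric(ncy * ncx * cfg$bins)
  magv <- as.vector(mag)
  cy0v <- as.vector(cy0); cx0v <- as.vector(cx0)
  wyv <- as.vector(wy);   wxv <- as.vector(wx)
  wov <- as.vector(wo)

  add <- function(ci, cj, b, wgt) {
    keep <- ci >= 0 & ci < ncy & cj >= 0 & cj < ncx & wgt > 0
    if (!any(keep)) return()
    idx <- ci[keep] + cj[keep] * ncy + (b[keep] - 1L) * ncy * ncx + 1L
    acc <- rowsum(wgt[keep], idx)
    ii <- as.integer(rownames(acc))
    hist[ii] <<- hist[ii] + acc[, 1]
  }
  for (dy in 0:1) for (dx in 0:1) {
    wsp <- magv *
      (if (dy == 0) 1 - wyv else wyv) *
      (if (dx == 0) 1 - wxv else wxv)
    add(cy0v + dy, cx0v + dx, bin0, wsp * (1 - wov))
    add(cy0v + dy, cx0v + dx, bin1, wsp * wov)
  }
  array(hist, c(ncy, ncx, cfg$bins))
}

l2hys <- function(v, clip) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(v * 0)
  v <- pmin(v / n, clip)
  n2 <- sqrt(sum(v^2))
  if (n2 < 1e-12) return(v * 0)
  v / n2
}

# All block sub-vectors as the columns of one matrix (blocks scanned
# row-major; within a block, cells row-major, bins fastest), then L2-Hys
# applied column-wise.
block_matrix <- function(hist, cfg) {
  ncy <- dim(hist)[1]; ncx <- dim(hist)[2]; bins <- dim(hist)[3]
  bh <- cfg$block[1]; bw <- cfg$block[2]
  by <- ncy - bh + 1L; bx <- ncx - bw + 1L
  if (by < 1 || bx < 1) abort("Image smaller than one HOG block.")
  parts <- vector("list", bh * bw)
  k <- 0L
  for (ci in seq_len(bh)) for (cj in seq_len(bw)) {
    k <- k + 1L
    sub <- hist[ci:(ci + by - 1L), cj:(cj + bx - 1L), , drop = FALSE]
    parts[[k]] <- matrix(aperm(sub, c(3, 2, 1)), nrow = bins)
  }
  M <- do.call(rbind, parts)
  # reorder rows so cells appear row-major with bins consecutive
  # (parts are already stacked in (ci, cj) row-major order)
  list(M = M, by = by, bx = bx, bins = bins, bh = bh, bw = bw)
}

l2hys_columns <- function(M, clip) {
  norms <- sqrt(colSums(M^2))
  nz <- norms >= 1e-12
  M[, nz] <- M[, nz, drop = FALSE] / rep(norms[nz], each = nrow(M))
  M[, !nz] <- 0
  M <- pmin(M, clip)
  norms2 <- sqrt(colSums(M^2))
  nz2 <- norms2 >= 1e-12
  M[, nz2] <- M[, nz2, drop = FALSE] / rep(norms2[nz2], each = nrow(M))
  M[, !nz2] <- 0
  M
}

#' HOG descriptor of a grayscale patch
#'
#' Blocks are scanned row-major (down first, then across) at one-cell
#' stride; within a block, cells are scanned row-major and each cell
#' contributes its `bins` histogram entries. Each block sub-vector is
#' L2-Hys-normalised independently.
#'
#' @param img Grayscale matrix (values on any affine scale; the descriptor
#'   is invariant to additive offsets). Dimensions not multiple of the cell
#'   size are reflection-padded.
#' @param cfg A [hog_config()].
#' @returns Numeric descriptor vector of length
#'   `n_blocks_y * n_blocks_x * prod(block) * bins`.
#' @export
hog_descriptor <- function(img, cfg = hog_config()) {
  hist <- hog_cell_histograms(img, cfg)
  bm <- block_matrix(hist, cfg)
  M <- l2hys_columns(bm$M, cfg$hys_clip)
  # columns are blocks in (i, j) row-major order already; concatenate
  as.vector(M)
}

#' Per-pixel HOG gradient-energy map
#'
#' For each cell, the L2 norm of its block-normalised histogram is averaged
#' over every block containing the cell; the per-cell energies are upsampled
#' to pixel resolution by nearest neighbour and rescaled to \[0, 1\]
#' (an all-zero map stays zero).
#'
#' @inheritParams hog_descriptor
#' @returns Matrix of the same size as `img`.
#' @export
hog_map <- function(img, cfg = hog_config()) {
  hist <- hog_cell_histograms(img, cfg)
  ncy <- dim(hist)[1]; ncx <- dim(hist)[2]
  bm <- block_matrix(hist, cfg)
  M <- l2hys_columns(bm$M, cfg$hys_clip)
  energy <- matrix(0, ncy, ncx)
  count <- matrix(0, ncy, ncx)
  k <- 0L
  for (ci in seq_len(bm$bh)) for (cj in seq_len(bm$bw)) {
    rows <- (k * bm$bins + 1L):((k + 1L) * bm$bins)
    k <- k + 1L
    cell_norms <- sqrt(colSums(M[rows, , drop = FALSE]^2))
    # columns are blocks (i, j) row-major: j fastest
    grid <- matrix(cell_norms, nrow = bm$bx, ncol = bm$by)
    yi <- ci:(ci + bm$by - 1L); xj <- cj:(cj + bm$bx - 1L)
    energy[yi, xj] <- energy[yi, xj] + t(grid)
    count[yi, xj] <- count[yi, xj] + 1
  }
  energy <- ifelse(count > 0, energy / pmax(count, 1), 0)
  up <- energy[rep(seq_len(ncy), each = cfg$cell[1]),
               rep(seq_len(ncx), each = cfg$cell[2]), drop = FALSE]
  up <- up[seq_len(nrow(img)), seq_len(ncol(img)), drop = FALSE]
  if (max(up) > 0) up <- up / max(up)
  up
}

#' Euclidean distance between two HOG descriptors
#'
#' @param a,b Descriptor vectors of equal length.
#' @returns Non-negative scalar; zero iff the descriptors are equal.
#' @export
hog_distance <- function(a, b) {
  if (length(a) != length(b)) abort("Descriptor lengths differ.")
  sqrt(sum((a - b)^2))
}
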