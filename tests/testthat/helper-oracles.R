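# Independent reference implementations used as oracles. These are written
# as literal, loop-based transcriptions of the definitions and share no code
# with the package's vectorised paths.

# Naive HOG: per-pixel loops, trilinear soft binning, L2-Hys blocks.
naive_hog <- function(img, cell = 8, bins = 9, clip = 0.2) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(h %% cell == 0, w %% cell == 0)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (y in 1:h) for (x in 1:w) {
    xm <- max(1, x - 1); xp <- min(w, x + 1)
    ym <- max(1, y - 1); yp <- min(h, y + 1)
    gx[y, x] <- img[y, xp] - img[y, xm]
    gy[y, x] <- img[yp, x] - img[ym, x]
  }
  ncy <- h / cell; ncx <- w / cell
  hist <- array(0, c(ncy, ncx, bins))
  bw <- 180 / bins
  for (y in 1:h) for (x in 1:w) {
    m <- sqrt(gx[y, x]^2 + gy[y, x]^2)
    if (m == 0) next
    a <- (atan2(gy[y, x], gx[y, x]) * 180 / pi) %% 180
    ob <- a / bw - 0.5
    b0 <- floor(ob); wo <- ob - b0
    bin0 <- (b0 %% bins) + 1; bin1 <- (bin0 %% bins) + 1
    uy <- (y - 0.5) / cell - 0.5; ux <- (x - 0.5) / cell - 0.5
    c0y <- floor(uy); c0x <- floor(ux)
    wy <- uy - c0y; wx <- ux - c0x
    for (dy in 0:1) for (dx in 0:1) {
      ci <- c0y + dy; cj <- c0x + dx
      if (ci < 0 || ci >= ncy || cj < 0 || cj >= ncx) next
      wsp <- m * (if (dy == 0) 1 - wy else wy) * (if (dx == 0) 1 - wx else wx)
      hist[ci + 1, cj + 1, bin0] <- hist[ci + 1, cj + 1, bin0] + wsp * (1 - wo)
      hist[ci + 1, cj + 1, bin1] <- hist[ci + 1, cj + 1, bin1] + wsp * wo
    }
  }
  desc <- c()
  for (i in 1:(ncy - 1)) for (j in 1:(ncx - 1)) {
    v <- c(hist[i, j, ], hist[i, j + 1, ], hist[i + 1, j, ], hist[i + 1, j + 1, ])
    n <- sqrt(sum(v^2))
    if (n >= 1e-12) {
      v <- pmin(v / n, clip)
      n2 <- sqrt(sum(v^2))
      v <- if (n2 >= 1e-12) v / n2 else v * 0
    } else v <- v * 0
    desc <- c(desc, v)
  }
  desc
}

# Brute-force all-point-interpolated AP for a fixed ranking of per-image
# predictions: correctness flags in rank order plus the number of GT boxes.
naive_ap <- function(correct, n_gt) {
  if (n_gt == 0 || length(correct) == 0) return(0)
  tp <- cumsum(correct)
  prec <- tp / seq_along(correct)
  rec <- tp / n_gt
  ap <- 0; prev <- 0
  for (k in seq_along(rec)) {
    if (rec[k] > prev) {
      ap <- ap + (rec[k] - prev) * max(prec[k:length(prec)])
      prev <- rec[k]
    }
  }
  ap
}

# Weighted-harmonic-mean F-beta, written out as the harmonic mean.
naive_fbeta <- function(p, r, beta) {
  if (p == 0 && r == 0) return(0)
  wp <- 1 / (1 + beta^2)
  wr <- beta^2 / (1 + beta^2)
  1 / (wp / p + wr / r)
}

# Cohen's kappa from an explicit 2x2 contingency table.
naive_kappa_from_table <- function(both_pos, both_neg, only1, only2) {
  n <- both_pos + both_neg + only1 + only2
  po <- (both_pos + both_neg) / n
  p1 <- (both_pos + only1) / n
  p2 <- (both_pos + only2) / n
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  (po - pe) / (1 - pe)
}
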