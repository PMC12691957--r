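# Compact CNN engine.
#
# Tensors are plain R arrays of dim c(H, W, C). Convolutions are computed by
# im2col + BLAS matrix multiplication; backward passes are hand-derived.
# Index matrices for im2col are cached per (input-shape, kernel, stride)
# signature. Everything is deterministic given the R RNG state.

.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(h, w, cin, kh, kw, stride) {
  key <- paste(h, w, cin, kh, kw, stride, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  ho <- (h - kh) %/% stride + 1L
  wo <- (w - kw) %/% stride + 1L
  oi <- rep(seq_len(ho), times = wo)            # output row (fastest)
  oj <- rep(seq_len(wo), each = ho)             # output col
  base_r <- (oi - 1L) * stride                  # 0-based top row of field
  base_c <- (oj - 1L) * stride
  npos <- ho * wo
  k <- kh * kw * cin
  idx <- matrix(0L, npos, k)
  q <- 0L
  for (c3 in seq_len(cin)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    q <- q + 1L
    idx[, q] <- (base_r + di) + (base_c + dj - 1L) * h + (c3 - 1L) * h * w
  }
  out <- list(idx = idx, ho = ho, wo = wo, k = k)
  .im2col_cache[[key]] <- out
  out
}

zero_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

conv_init <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  list(W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout),
       kh = as.integer(kh), kw = as.integer(kw),
       cin = as.integer(cin), cout = as.integer(cout))
}

conv_fwd <- function(x, lay, stride = 1L, pad = 1L) {
  xp <- zero_pad(x, pad)
  d <- dim(xp)
  ii <- im2col_indices(d[1], d[2], d[3], lay$kh, lay$kw, stride)
  xcol <- matrix(xp[ii$idx], nrow(ii$idx), ii$k)
  y <- xcol %*% lay$W
  y <- y + rep(lay$b, each = nrow(y))
  list(y = array(y, c(ii$ho, ii$wo, lay$cout)),
       cache = list(xcol = xcol, dpad = d, ii = ii, stride = stride,
                    pad = pad, din = dim(x)))
}

conv_bwd <- function(dy, lay, cache) {
  dym <- matrix(dy, prod(dim(dy)[1:2]), lay$cout)
  dW <- crossprod(cache$xcol, dym)
  db <- colSums(dym)
  dxcol <- dym %*% t(lay$W)
  dxp <- numeric(prod(cache$dpad))
  idx <- cache$ii$idx
  for (q in seq_len(ncol(idx))) {
    iq <- idx[, q]
    dxp[iq] <- dxp[iq] + dxcol[, q]
  }
  dxp <- array(dxp, cache$dpad)
  p <- cache$pad
  dx <- if (p > 0L) {
    dxp[(p + 1):(p + cache$din[1]), (p + 1):(p + cache$din[2]), , drop = FALSE]
  } else dxp
  dim(dx) <- cache$din
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  y <- pmax(x, 0)
  list(y = y, cache = x > 0)
}
relu_bwd <- function(dy, cache) dy * cache

dense_init <- function(nin, nout) {
  list(W = matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}
dense_fwd <- function(v, lay) {
  list(y = as.vector(v %*% lay$W + lay$b), cache = v)
}
dense_bwd <- function(dy, lay, cache) {
  list(dv = as.vector(lay$W %*% dy),
       dW = outer(as.vector(cache), dy), db = dy)
}

gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  list(y = colMeans(m), cache = d)
}
gap_bwd <- function(dy, cache) {
  d <- cache
  array(rep(dy / (d[1] * d[2]), each = d[1] * d[2]), d)
}

# Global max pooling; the gradient flows to the (first) argmax per channel.
gmp_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  am <- max.col(t(m), ties.method = "first")
  list(y = m[cbind(am, seq_len(d[3]))], cache = list(d = d, am = am))
}
gmp_bwd <- function(dy, cache) {
  d <- cache$d
  out <- matrix(0, d[1] * d[2], d[3])
  out[cbind(cache$am, seq_len(d[3]))] <- dy
  array(out, d)
}

# Pre-activation residual block: x + conv2(relu(conv1(relu(x)))).
resblock_init <- function(ch) {
  list(conv1 = conv_init(3, 3, ch, ch), conv2 = conv_init(3, 3, ch, ch))
}
resblock_fwd <- function(x, blk) {
  a <- relu_fwd(x)
  c1 <- conv_fwd(a$y, blk$conv1)
  a2 <- relu_fwd(c1$y)
  c2 <- conv_fwd(a2$y, blk$conv2)
  list(y = x + c2$y, cache = list(a = a$cache, c1 = c1$cache,
                                  a2 = a2$cache, c2 = c2$cache))
}
resblock_bwd <- function(dy, blk, cache) {
  b2 <- conv_bwd(dy, blk$conv2, cache$c2)
  d2 <- relu_bwd(b2$dx, cache$a2)
  b1 <- conv_bwd(d2, blk$conv1, cache$c1)
  dx <- dy + relu_bwd(b1$dx, cache$a)
  list(dx = dx,
       grads = list(conv1 = list(W = b1$dW, b = b1$db),
                    conv2 = list(W = b2$dW, b = b2$db)))
}

# ---- Adam over arbitrarily nested parameter lists --------------------------
# Parameters are any nested list whose leaves are named W / b numerics;
# gradients mirror the structure.

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p) && !is.null(p$W)) {
      list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
    } else if (is.list(p)) {
      lapply(p, walk)
    } else NULL
  }
  list(state = walk(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  opt$t <- opt$t + 1L
  t <- opt$t
  upd <- function(p, g, s) {
    if (is.list(p) && !is.null(p$W)) {
      if (is.null(g)) return(list(p = p, s = s))
      s$mW <- beta1 * s$mW + (1 - beta1) * g$W
      s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
      s$mb <- beta1 * s$mb + (1 - beta1) * g$b
      s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
      mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
      mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
      p$W <- p$W * (1 - lr * weight_decay) - lr * mhW / (sqrt(vhW) + eps)
      p$b <- p$b - lr * mhb / (sqrt(vhb) + eps)
      list(p = p, s = s)
    } else if (is.list(p)) {
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      list(p = p, s = s)
    } else list(p = p, s = s)
  }
  r <- upd(params, grads, opt$state)
  opt$state <- r$s
  list(params = r$p, opt = opt)
}

# Global L2 norm of a gradient structure, and norm clipping.
grad_norm <- function(g) {
  if (is.null(g)) return(0)
  if (is.list(g) && !is.null(g$W)) return(sqrt(sum(g$W^2) + sum(g$b^2)))
  sqrt(sum(vapply(g, function(x) grad_norm(x)^2, 0)))
}

grad_clip <- function(g, max_norm) {
  n <- grad_norm(g)
  if (n > max_norm) grad_scale(g, max_norm / n) else g
}

# Sum two gradient structures of identical shape (for gradient accumulation).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a) && !is.null(a$W)) {
    list(W = a$W + b$W, b = a$b + b$b)
  } else {
    out <- a
    for (nm in names(a)) out[[nm]] <- grad_add(a[[nm]], b[[nm]])
    out
  }
}

grad_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g) && !is.null(g$W)) return(list(W = g$W * s, b = g$b * s))
  lapply(g, grad_scale, s = s)
}

# Weighted average of two parameter structures, preserving layer metadata.
params_mix <- function(a, b, wa, wb) {
  if (is.list(a) && !is.null(a$W)) {
    a$W <- wa * a$W + wb * b$W
    a$b <- wa * a$b + wb * b$b
    return(a)
  }
  for (nm in names(a)) a[[nm]] <- params_mix(a[[nm]], b[[nm]], wa, wb)
  a
}
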