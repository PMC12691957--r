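# Siamese-style similarity filter (S-CNN).
#
# A candidate patch and its contralateral reference are stacked along the
# channel dimension (2 channels in `gray_pair` mode; 4 in `grayhog_pair`
# mode where each patch also contributes its HOG energy map) and scored by
# a compact pre-activation residual network ending in a tanh unit:
# -1 = similar (the pattern exists on both sides: an artifact),
# +1 = dissimilar (unilateral: a genuine lesion). Training minimises the
# mean-squared error between the tanh output and the +/-1 labels.

#' Augmentation configuration for filter training
#'
#' @param rotation Max |rotation| in degrees.
#' @param scale Isotropic scale range `c(lo, hi)`.
#' @param photometric Max |multiplicative intensity jitter| as a fraction.
#' @param noise_sd Range of the Gaussian pixel-noise standard deviation.
#' @param channel_swap_p Probability of swapping the index and reference
#'   channels (with their HOG maps, if present).
#' @returns An object of class `augment_config`.
#' @export
augment_config <- function(rotation = 5, scale = c(0.9, 1.1),
                           photometric = 0.1, noise_sd = c(0.01, 0.02),
                           channel_swap_p = 0.5) {
  structure(list(rotation = rotation, scale = scale,
                 photometric = photometric, noise_sd = noise_sd,
                 channel_swap_p = channel_swap_p),
            class = "augment_config")
}

#' Similarity-filter configuration
#'
#' @param input_size Patch side length (128).
#' @param channel_mode `"gray_pair"` (index + reference grayscale, 2
#'   channels) or `"grayhog_pair"` (each patch with its HOG energy map,
#'   4 channels).
#' @param backbone_depth Number of residual blocks (one per resolution
#'   stage, cycled).
#' @param epochs Training epochs (the faithful schedule is 1000; CPU-scale
#'   runs use far fewer).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param augment An [augment_config()].
#' @param hog_cfg HOG settings for `grayhog_pair` mode.
#' @param stem_downsample Integer pooling factor applied to each channel
#'   before the first convolution (2 halves the resolution: cheaper and
#'   averages out part of the speckle; the patch contract stays
#'   `input_size`).
#' @param n_members Number of independently initialised networks trained
#'   and averaged (score-level ensemble); small CNNs fitted on a few
#'   hundred pairs vary noticeably across initialisations, and the
#'   two-member average is markedly more stable than any single run.
#' @param seed Integer seed.
#' @returns An object of class `filter_config`.
#' @export
filter_config <- function(input_size = 128,
                          channel_mode = c("gray_pair", "grayhog_pair"),
                          backbone_depth = 2, epochs = 25, batch_size = 8,
                          lr = 5e-4, augment = augment_config(),
                          hog_cfg = hog_config(), stem_downsample = 2,
                          n_members = 2, seed = 1L) {
  channel_mode <- match.arg(channel_mode)
  structure(list(input_size = as.integer(input_size),
                 channel_mode = channel_mode,
                 in_channels = if (channel_mode == "gray_pair") 2L else 4L,
                 backbone_depth = as.integer(backbone_depth),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 augment = augment, hog_cfg = hog_cfg,
                 stem_downsample = max(1L, as.integer(stem_downsample)),
                 n_members = max(1L, as.integer(n_members)),
                 seed = as.integer(seed)),
            class = "filter_config")
}

#' Build an untrained similarity network
#'
#' @param cfg A [filter_config()].
#' @returns An object of class `sonosym_scnn`; [score_pair()] maps a stacked
#'   patch pair to a single tanh-bounded scalar in \[-1, 1\].
#' @export
build_scnn <- function(cfg = filter_config()) {
  depth <- max(1L, cfg$backbone_depth)
  params <- list(
    c1 = conv_init(3, 3, cfg$in_channels, 12),
    r1 = resblock_init(12),
    c2 = conv_init(3, 3, 12, 24),
    r2 = resblock_init(24),
    c3 = conv_init(3, 3, 24, 32),
    c4 = conv_init(3, 3, 32, 32),
    fc = dense_init(32, 1)
  )
  # gentle start: near-zero initial scores keep the tanh out of saturation
  params$fc$W <- params$fc$W * 0.1
  structure(list(params = params, cfg = cfg, depth = depth),
            class = "sonosym_scnn")
}

scnn_forward <- function(model, x) {
  p <- model$params
  use_r1 <- model$depth >= 1L
  use_r2 <- model$depth >= 2L
  c1 <- conv_fwd(x, p$c1, stride = 2L); a1 <- relu_fwd(c1$y)
  r1 <- if (use_r1) resblock_fwd(a1$y, p$r1) else list(y = a1$y)
  c2 <- conv_fwd(r1$y, p$c2, stride = 2L); a2 <- relu_fwd(c2$y)
  r2 <- if (use_r2) resblock_fwd(a2$y, p$r2) else list(y = a2$y)
  c3 <- conv_fwd(r2$y, p$c3, stride = 2L); a3 <- relu_fwd(c3$y)
  c4 <- conv_fwd(a3$y, p$c4, stride = 2L); a4 <- relu_fwd(c4$y)
  # a localized contralateral mismatch must not be averaged away: half the
  # final channels are max-pooled, half mean-pooled
  gp <- list(mean = gap_fwd(a4$y[, , 1:16, drop = FALSE]),
             max = gmp_fwd(a4$y[, , 17:32, drop = FALSE]))
  fc <- dense_fwd(c(gp$mean$y, gp$max$y), p$fc)
  score <- tanh(fc$y)
  list(score = score,
       cache = list(c1 = c1, a1 = a1, r1 = r1, c2 = c2, a2 = a2, r2 = r2,
                    c3 = c3, a3 = a3, c4 = c4, a4 = a4, gp = gp, fc = fc,
                    score = score))
}

scnn_backward <- function(model, cache, dscore) {
  p <- model$params
  g <- list()
  dfc <- dscore * (1 - cache$score^2)
  bfc <- dense_bwd(dfc, p$fc, cache$fc$cache)
  g$fc <- list(W = bfc$dW, b = bfc$db)
  dv <- bfc$dv
  dmean <- gap_bwd(dv[1:16], cache$gp$mean$cache)
  dmax <- gmp_bwd(dv[17:32], cache$gp$max$cache)
  dgp <- array(0, dim(cache$a4$cache))
  dgp[, , 1:16] <- dmean
  dgp[, , 17:32] <- dmax
  da4 <- relu_bwd(dgp, cache$a4$cache)
  b4 <- conv_bwd(da4, p$c4, cache$c4$cache)
  g$c4 <- list(W = b4$dW, b = b4$db)
  da3 <- relu_bwd(b4$dx, cache$a3$cache)
  b3 <- conv_bwd(da3, p$c3, cache$c3$cache)
  g$c3 <- list(W = b3$dW, b = b3$db)
  dr2 <- b3$dx
  if (model$depth >= 2L) {
    br2 <- resblock_bwd(dr2, p$r2, cache$r2$cache)
    g$r2 <- br2$grads
    dr2 <- br2$dx
  }
  da2 <- relu_bwd(dr2, cache$a2$cache)
  b2 <- conv_bwd(da2, p$c2, cache$c2$cache)
  g$c2 <- list(W = b2$dW, b = b2$db)
  dr1 <- b2$dx
  if (model$depth >= 1L) {
    br1 <- resblock_bwd(dr1, p$r1, cache$r1$cache)
    g$r1 <- br1$grads
    dr1 <- br1$dx
  }
  da1 <- relu_bwd(dr1, cache$a1$cache)
  b1 <- conv_bwd(da1, p$c1, cache$c1$cache)
  g$c1 <- list(W = b1$dW, b = b1$db)
  g
}

# Stack a patch pair into the network input tensor. Channels are pooled by
# `stem_downsample` and standardised to zero mean / unit variance: the
# comparison is about spatial structure, not absolute echo level, and an
# unnormalised mean-dominated input conditions the ReLU stack badly.
stack_pair <- function(index_patch, reference_patch, cfg) {
  if (!all(dim(index_patch) == cfg$input_size) ||
      !all(dim(reference_patch) == cfg$input_size)) {
    abort("Patches do not match the configured input size.")
  }
  side <- cfg$input_size %/% cfg$stem_downsample
  prep <- function(p) {
    p <- resize_bilinear(p, side, side)
    (p - mean(p)) / (sd(p) + 1e-6)
  }
  if (cfg$channel_mode == "gray_pair") {
    array(c(prep(index_patch), prep(reference_patch)), c(side, side, 2L))
  } else {
    array(c(prep(index_patch), prep(hog_map(index_patch, cfg$hog_cfg)),
            prep(reference_patch), prep(hog_map(reference_patch, cfg$hog_cfg))),
          c(side, side, 4L))
  }
}

# Affine warp (rotation about the centre + isotropic scale), bilinear
# sampling with edge clamping.
warp_patch <- function(p, angle_deg, scale) {
  if (abs(angle_deg) < 1e-9 && abs(scale - 1) < 1e-9) return(p)
  h <- nrow(p); w <- ncol(p)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ys <- matrix(seq_len(h) - cy, h, w)
  xs <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  sx <- (cos(th) * xs + sin(th) * ys) / scale + cx
  sy <- (-sin(th) * xs + cos(th) * ys) / scale + cy
  x0 <- clamp(floor(sx), 1, w - 1); y0 <- clamp(floor(sy), 1, h - 1)
  wx <- clamp(sx - x0, 0, 1); wy <- clamp(sy - y0, 0, 1)
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0 + 1))
  i10 <- cbind(as.vector(y0 + 1), as.vector(x0))
  i11 <- cbind(as.vector(y0 + 1), as.vector(x0 + 1))
  v <- p[i00] * as.vector((1 - wx) * (1 - wy)) +
    p[i01] * as.vector(wx * (1 - wy)) +
    p[i10] * as.vector((1 - wx) * wy) +
    p[i11] * as.vector(wx * wy)
  matrix(v, h, w)
}

augment_pair <- function(index_patch, reference_patch, aug) {
  ang <- runif(1, -aug$rotation, aug$rotation)
  sc <- runif(1, aug$scale[1], aug$scale[2])
  gain <- 1 + runif(1, -aug$photometric, aug$photometric)
  nsd <- runif(1, aug$noise_sd[1], aug$noise_sd[2])
  f <- function(p) {
    p <- warp_patch(p, ang, sc) * gain
    clamp(p + matrix(rnorm(length(p), sd = nsd), nrow(p)), 0, 1)
  }
  out <- list(index = f(index_patch), reference = f(reference_patch))
  if (runif(1) < aug$channel_swap_p) {
    out <- list(index = out$reference, reference = out$index)
  }
  out
}

#' Train the similarity filter on mined patch pairs
#'
#' Minimises the mean-squared error between the tanh output and the +/-1
#' labels, with per-sample augmentation (rotation, scaling, photometric
#' jitter, Gaussian noise, random channel swap). A seeded patient-agnostic
#' validation split (25% of pairs, stratified by label) tracks per-class
#' accuracy.
#'
#' @param pairs Mined-pair tibble from [mine_training_pairs()] /
#'   [mine_dataset_pairs()]: needs `index_patch`, `reference_patch` and
#'   `label` (+1/-1) columns. Both labels must be present.
#' @param cfg A [filter_config()].
#' @returns An object of class `scnn_fit`: `model` (a `sonosym_scnn` for a
#'   single member, otherwise a `sonosym_scnn_ensemble` averaging the
#'   member scores; each member is either its best-epoch snapshot or its
#'   tail weight average, whichever has the better worst-class validation
#'   accuracy), `trace` (tibble: member, epoch, loss, val_acc_similar,
#'   val_acc_dissimilar), the validation row indices, and
#'   `decision_threshold`: the similarity threshold calibrated on the
#'   validation scores (maximising worst-class accuracy), for use as the
#'   cascade operating threshold.
#' @export
train_scnn <- function(pairs, cfg = filter_config()) {
  labs <- unique(pairs$label)
  if (!all(c(-1L, 1L) %in% labs)) {
    abort("Training set must contain both similar (-1) and dissimilar (+1) pairs.")
  }
  set.seed(cfg$seed)
  n <- nrow(pairs)
  val <- unlist(lapply(c(-1L, 1L), function(l) {
    idx <- which(pairs$label == l)
    sample(idx, max(1L, floor(0.25 * length(idx))))
  }))
  train <- setdiff(seq_len(n), val)

  members <- vector("list", cfg$n_members)
  traces <- vector("list", cfg$n_members)
  for (m in seq_len(cfg$n_members)) {
    set.seed(cfg$seed + 131L * (m - 1L))
    fit_m <- train_scnn_member(pairs, cfg, train, val)
    members[[m]] <- fit_m$model
    tr <- fit_m$trace
    tr$member <- m
    traces[[m]] <- tr
  }
  model <- if (cfg$n_members == 1L) members[[1L]] else {
    structure(list(members = members, cfg = cfg), class = "sonosym_scnn_ensemble")
  }

  truth <- pairs$label[val]
  scores_fin <- vapply(val, function(s) {
    score_pair(model, pairs$index_patch[[s]], pairs$reference_patch[[s]])
  }, 0)
  worst_acc <- function(scores, thr) {
    pred <- ifelse(scores >= thr, 1L, -1L)
    min(mean(pred[truth == -1L] == -1L), mean(pred[truth == 1L] == 1L))
  }
  # calibrate the decision threshold on the validation scores
  grid <- sort(unique(c(0, scores_fin)))
  thr_acc <- vapply(grid, function(t) worst_acc(scores_fin, t), 0)
  thr <- grid[which.max(thr_acc)]
  structure(list(model = model, trace = dplyr::bind_rows(traces),
                 decision_threshold = thr, val_idx = val,
                 n_train = length(train)),
            class = "scnn_fit")
}

#' @rdname score_pair
#' @export
score_pair.sonosym_scnn_ensemble <- function(model, index_patch,
                                             reference_patch) {
  mean(vapply(model$members, function(m) {
    score_pair(m, index_patch, reference_patch)
  }, 0))
}

train_scnn_member <- function(pairs, cfg, train, val) {
  model <- build_scnn(cfg)
  opt <- adam_init(model$params)
  trace <- vector("list", cfg$epochs)
  pos_t <- intersect(train, which(pairs$label == 1L))
  neg_t <- intersect(train, which(pairs$label == -1L))
  m_half <- ceiling(length(train) / 2)
  best <- list(score = -Inf, params = model$params, epoch = NA_integer_)
  swa <- NULL; swa_n <- 0L
  swa_start <- ceiling(2 * cfg$epochs / 3)
  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- cfg$lr * if (ep > 2 * cfg$epochs / 3) 0.2 else 1
    # class-balanced epoch: mined sets are heavily similar-dominated
    ord <- sample(c(sample(pos_t, m_half, replace = length(pos_t) < m_half),
                    sample(neg_t, m_half, replace = length(neg_t) < m_half)))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      grads <- NULL
      for (s in bt) {
        ap <- augment_pair(pairs$index_patch[[s]], pairs$reference_patch[[s]],
                           cfg$augment)
        x <- stack_pair(ap$index, ap$reference, cfg)
        fwd <- scnn_forward(model, x)
        err <- fwd$score - pairs$label[s]
        ep_loss <- ep_loss + err^2
        g <- scnn_backward(model, fwd$cache, 2 * err / length(bt))
        grads <- grad_add(grads, g)
      }
      st <- adam_step(model$params, grad_clip(grads, 5), opt, lr = lr_ep,
                      weight_decay = 1e-4)
      model$params <- st$params
      opt <- st$opt
    }
    scores <- vapply(val, function(s) {
      score_pair(model, pairs$index_patch[[s]], pairs$reference_patch[[s]])
    }, 0)
    truth <- pairs$label[val]
    acc_cls <- function(l, thr = 0) {
      k <- truth == l
      pred <- ifelse(scores >= thr, 1L, -1L)
      if (!any(k)) NA_real_ else mean(pred[k] == l)
    }
    trace[[ep]] <- tibble::tibble(epoch = ep,
                                  loss = ep_loss / length(ord),
                                  val_acc_similar = acc_cls(-1L),
                                  val_acc_dissimilar = acc_cls(1L))
    bal <- min(acc_cls(-1L), acc_cls(1L), na.rm = TRUE)
    if (is.finite(bal) && bal >= best$score) {
      best <- list(score = bal, params = model$params, epoch = ep)
    }
    if (ep >= swa_start) {
      # tail weight averaging over the low-learning-rate phase
      swa <- if (is.null(swa)) model$params else
        params_mix(swa, model$params, swa_n / (swa_n + 1), 1 / (swa_n + 1))
      swa_n <- swa_n + 1L
    }
  }

  val_scores_for <- function(params) {
    m <- model; m$params <- params
    vapply(val, function(s) {
      score_pair(m, pairs$index_patch[[s]], pairs$reference_patch[[s]])
    }, 0)
  }
  truth <- pairs$label[val]
  worst_acc <- function(scores, thr) {
    pred <- ifelse(scores >= thr, 1L, -1L)
    min(mean(pred[truth == -1L] == -1L), mean(pred[truth == 1L] == 1L))
  }
  # candidate final models: best single epoch vs the tail average
  cand <- list(best = best$params)
  if (!is.null(swa)) cand$swa <- swa
  cand_scores <- lapply(cand, val_scores_for)
  cand_acc <- vapply(cand_scores, worst_acc, 0, thr = 0)
  pick <- names(which.max(cand_acc))
  model$params <- cand[[pick]]
  list(model = model, trace = dplyr::bind_rows(trace))
}

#' @export
print.scnn_fit <- function(x, ...) {
  last <- tail(x$trace, 1)
  cat(sprintf(
    "<scnn_fit: %d train pairs, %d member(s), threshold %.3f, val acc sim %.2f / dis %.2f>\n",
    x$n_train, max(c(1, x$trace$member)), x$decision_threshold,
    last$val_acc_similar, last$val_acc_dissimilar))
  invisible(x)
}

#' Score one patch pair
#'
#' @param model A scoring model; the shipped method is for `sonosym_scnn`
#'   (typically `fit$model`), but any object with a `score_pair` method can
#'   stand in as the verification stage.
#' @param index_patch,reference_patch Matrices of the configured patch size.
#' @returns Similarity score in \[-1, 1\]; negative = similar (bilateral
#'   pattern), positive = dissimilar (unilateral pattern).
#' @export
score_pair <- function(model, index_patch, reference_patch) {
  UseMethod("score_pair")
}

#' @rdname score_pair
#' @export
score_pair.sonosym_scnn <- function(model, index_patch, reference_patch) {
  x <- stack_pair(index_patch, reference_patch, model$cfg)
  scnn_forward(model, x)$score
}

#' Classify a similarity score
#'
#' @param score Scalar in \[-1, 1\].
#' @param decision_threshold Scores `>=` this are dissimilar (the boundary
#'   goes to dissimilar, preserving recall).
#' @returns `"similar"` or `"dissimilar"`.
#' @export
classify <- function(score, decision_threshold = 0) {
  ifelse(score >= decision_threshold, "dissimilar", "similar")
}
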