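test_that("head channel count follows anchors * (4 + 1 + classes)", {
  expect_equal(head_channels(detector_config()), 18L)
  expect_equal(head_channels(detector_config(anchors_per_level = 1)), 6L)
  expect_equal(head_channels(detector_config(anchors_per_level = 3,
                                             n_classes = 2)), 21L)
  for (a in 1:4) for (k in 1:3) {
    cfg <- detector_config(anchors_per_level = a, n_classes = k)
    expect_equal(head_channels(cfg), a * (5L + k))
  }
})

test_that("forward grids have the configured shapes and channel counts", {
  set.seed(1)
  for (size in c(256L, 544L)) {
    cfg <- detector_config(input_size = size)
    model <- build_detector(cfg)
    fwd <- sonosym:::det_forward(model, matrix(0.5, size, size))
    dims <- lapply(fwd$grids, dim)
    expect_equal(dims[[1]][1:2], rep(size / 8L, 2))
    expect_equal(dims[[2]][1:2], rep(size / 16L, 2))
    expect_equal(dims[[3]][1:2], rep(size / 32L, 2))
    for (d in dims) expect_equal(d[3], head_channels(cfg))
  }
  expect_error(detector_config(input_size = 200), "divisible")
})

test_that("box encode/decode round-trips within 1e-4 px", {
  set.seed(2)
  cfg <- detector_config(input_size = 256)
  for (k in 1:50) {
    level <- sample(1:3, 1)
    stride <- cfg$strides[level]
    anchor <- cfg$anchor_sizes[[level]][sample(1:3, 1), ]
    b <- boxes(runif(1, 0, 200), runif(1, 0, 200),
               runif(1, 5, 50), runif(1, 5, 50))
    enc <- encode_box(b, anchor, stride)
    dec <- decode_box(enc$t, enc$i, enc$j, anchor, stride)
    expect_lt(max(abs(unlist(dec) - unlist(b))), 1e-4)
  }
})

test_that("greedy NMS suppresses overlaps and is idempotent", {
  one <- tibble::tibble(x = 10, y = 10, w = 20, h = 20, confidence = 0.9)
  expect_equal(nrow(nms(one, 0.5)), 1)

  dup <- tibble::tibble(x = c(10, 10), y = c(10, 10), w = 20, h = 20,
                        confidence = c(0.9, 0.8))
  kept <- nms(dup, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  # A overlaps B with IoU 2/3 > 0.5 (20x20 boxes offset by 5 px in x:
  # inter 15*20 = 300, union 500); C disjoint
  abc <- tibble::tibble(x = c(10, 15, 100), y = 10, w = 20, h = 20,
                        confidence = c(0.9, 0.8, 0.7))
  kept <- nms(abc, 0.5)
  expect_equal(kept$x, c(10, 100))
  expect_identical(nms(kept, 0.5), kept)
})

test_that("anchor k-means assigns small clusters to fine strides", {
  set.seed(3)
  wh <- rbind(matrix(runif(40, 10, 20), 20, 2),
              matrix(runif(40, 40, 60), 20, 2),
              matrix(runif(40, 90, 120), 20, 2))
  anch <- anchors_from_boxes(wh, detector_config(input_size = 256))
  areas <- vapply(anch, function(a) mean(a[, 1] * a[, 2]), 0)
  expect_true(all(diff(areas) > 0))
})

test_that("training is deterministic and rejects an empty dataset", {
  expect_error(train_detector(list(), detector_config(input_size = 256)),
               "empty")
  ds <- generate_dataset(2, 1, phantom_params(n_lesions = 1,
                                              n_distractors = 0, seed = 71))
  cfg <- detector_config(input_size = 128)
  f1 <- train_detector(ds, cfg, epochs = 2, seed = 9)
  f2 <- train_detector(ds, cfg, epochs = 2, seed = 9)
  expect_equal(f1$loss_trace, f2$loss_trace)
  expect_true(all(is.finite(f1$loss_trace$loss)))
})

test_that("training reduces the loss on the phantom dataset", {
  fit <- get_detector_fit()
  expect_lt(tail(fit$loss_trace$loss, 1), fit$loss_trace$loss[1])
  g <- glance(fit)
  expect_equal(g$head_channels, 18L)
  expect_equal(g$n_images, 60L)
})

test_that("detections are sorted, bounded and honour the confidence floor", {
  fit <- get_detector_fit()
  img <- get_test_pairs()[[1]]$left_image
  expect_equal(nrow(detect(fit$model, img, conf_floor = 1.0)), 0)
  d <- detect(fit$model, img, conf_floor = 0.01)
  expect_true(all(diff(d$confidence) <= 0))
  expect_true(all(d$confidence >= 0.01))
  expect_true(all(d$x >= 0 & d$y >= 0 &
                    d$x + d$w <= ncol(img) & d$y + d$h <= nrow(img)))
})

test_that("a single high-contrast lesion is found near the top rank", {
  fit <- get_detector_fit()
  p <- generate_pair(phantom_params(n_lesions = 1, n_distractors = 0,
                                    lesion_contrast = 0.6,
                                    lesion_axes_range = c(16, 24),
                                    seed = 314))
  side <- if (nrow(p$left_boxes) > 0) "left" else "right"
  img <- if (side == "left") p$left_image else p$right_image
  gt <- if (side == "left") p$left_boxes else p$right_boxes
  d <- detect(fit$model, img, conf_floor = 0.01)
  expect_gt(nrow(d), 0)
  expect_gt(max(iou(d[1, c("x", "y", "w", "h")], gt)), 0.3)
})
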