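mk_dets <- function(conf) {
  n <- length(conf)
  tibble::tibble(x = seq(10, by = 40, length.out = n), y = 10,
                 w = 30, h = 30, confidence = conf, level = 1L)
}

test_that("routing follows the half-open interval conventions", {
  rt <- route(mk_dets(c(0.005, 0.15, 0.20)), cascade_config())
  expect_equal(rt$suppressed$confidence, 0.005)
  expect_equal(rt$forwarded$confidence, 0.15)
  expect_equal(rt$accepted$confidence, 0.20)
  # boundary cases: exactly T1 is forwarded, exactly T2 accepted
  rt2 <- route(mk_dets(c(0.01, 0.1999999)), cascade_config())
  expect_equal(nrow(rt2$forwarded), 2)
})

test_that("routing partitions the input exactly", {
  set.seed(1)
  for (k in 1:20) {
    d <- mk_dets(runif(sample(0:30, 1)))
    rt <- route(d, cascade_config())
    expect_equal(nrow(rt$suppressed) + nrow(rt$forwarded) + nrow(rt$accepted),
                 nrow(d))
    recombined <- dplyr::bind_rows(rt)
    expect_setequal(recombined$confidence, d$confidence)
  }
})

test_that("raising T1 never increases the surviving detections", {
  set.seed(2)
  d <- mk_dets(runif(50))
  t1s <- seq(0, 0.19, by = 0.01)
  surv <- vapply(t1s, function(t1) {
    rt <- route(d, cascade_config(T1 = t1))
    nrow(rt$forwarded) + nrow(rt$accepted)
  }, 0)
  expect_true(all(diff(surv) <= 0))
})

test_that("invalid threshold configurations are rejected", {
  expect_error(cascade_config(T1 = 0.3, T2 = 0.2), "T1")
  expect_error(cascade_config(T1 = 0.2, T2 = 0.2), "T1")
  expect_error(cascade_config(T2 = 1.5), "T1")
})

test_that("verification keeps unilateral and drops bilateral patterns", {
  # deterministic speckle-free bilateral scene (flip-symmetric striations):
  # clean HOG matching and exact mock verdicts
  pair <- crafted_bilateral_scene()
  scorer <- mock_scorer(margin = 0.03)
  img_w <- ncol(pair$left_image)
  for (side in c("left", "right")) {
    gt <- if (side == "left") pair$left_boxes else pair$right_boxes
    db <- pair$distractor_boxes
    if (side == "right" && nrow(db) > 0) db$x <- img_w - db$x - db$w
    cand <- dplyr::bind_rows(gt, db)
    if (nrow(cand) == 0) next
    cand$confidence <- 0.1
    kept <- verify(cand, pair, side, scorer, cfg = cascade_config())
    # ground-truth lesions survive, bilateral distractors are eliminated
    if (nrow(gt) > 0) expect_true(all(gt$x %in% kept$x))
    if (nrow(db) > 0) expect_false(any(db$x %in% kept$x))
  }
  empty <- verify(mk_dets(numeric()), pair, "left", scorer)
  expect_equal(nrow(empty), 0)
})

test_that("the pipeline merges accepted and verified detections only", {
  fit <- get_detector_fit()
  sfit <- get_scnn_fit()
  pair <- get_test_pairs()[[2]]
  cfg <- cascade_config(decision_threshold = sfit$decision_threshold)
  final <- run_pipeline(pair, fit$model, sfit$model, cfg)
  expect_true(all(final$confidence >= cfg$T1))
  expect_true(all(final$stage %in% c("accepted", "verified")))
  # the cascade never invents boxes: every output is among the raw
  # detections of its side at floor T1
  for (side in unique(final$side)) {
    raw <- detect(fit$model, sonosym:::pair_image(pair, side),
                  conf_floor = cfg$T1)
    out <- final[final$side == side, ]
    expect_true(all(out$confidence %in% raw$confidence))
    # directly accepted rows are exactly the raw detections at or above T2
    expect_setequal(out$confidence[out$stage == "accepted"],
                    raw$confidence[raw$confidence >= cfg$T2])
  }
})

test_that("an illustrative crafted scene reproduces the 60% low-confidence cut", {
  # 7 detections at T1: 2 at or above T2 (accepted outright), 5 forwarded;
  # 2 of the forwarded sit on genuine unilateral lesions, 3 on bilateral
  # look-alikes, so verification removes 3 of 5 (60%) of the low-confidence
  # candidates
  pair <- crafted_bilateral_scene()
  les <- list(c(50, 60), c(200, 60))
  bil <- list(c(60, 180), c(128, 200), c(190, 140))
  centers <- do.call(rbind, c(les, bil, list(c(90, 90), c(160, 90))))
  dets <- tibble::tibble(x = centers[, 1] - 15, y = centers[, 2] - 12,
                         w = 30, h = 24,
                         confidence = c(0.15, 0.12, 0.1, 0.08, 0.05,
                                        0.5, 0.3))
  cfg <- cascade_config()
  rt <- route(dets, cfg)
  expect_equal(nrow(rt$accepted), 2)
  expect_equal(nrow(rt$forwarded), 5)
  kept <- verify(rt$forwarded, pair, "left", mock_scorer(margin = 0.03),
                 cfg = cfg)
  expect_equal(nrow(kept), 2)
  expect_equal(1 - nrow(kept) / nrow(rt$forwarded), 0.6)
})
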