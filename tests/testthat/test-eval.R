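test_that("IoU matches closed forms", {
  a <- boxes(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, boxes(10, 10, 2, 2)), 0)
  expect_equal(iou(a, boxes(1, 0, 2, 2)), 2 / 6)
  expect_equal(iou(boxes(0, 0, 4, 2), boxes(2, 0, 4, 2)), 4 / 12)
})

test_that("greedy matching is one-to-one in confidence order", {
  gts <- boxes(c(0, 50), c(0, 0), 10, 10)
  perfect <- dplyr::mutate(gts, confidence = c(0.9, 0.8))
  m <- match_detections(perfect, gts)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 0, 0))

  none <- match_detections(perfect[0, ], boxes(0, 0, 10, 10))
  expect_equal(c(none$tp, none$fp, none$fn), c(0, 0, 1))

  # two predictions on one GT: only the higher-confidence one matches
  two <- tibble::tibble(x = c(0, 1), y = 0, w = 10, h = 10,
                        confidence = c(0.9, 0.8))
  m2 <- match_detections(two, boxes(0, 0, 10, 10))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
  expect_equal(m2$matched_pairs$pred, 1L)
})

test_that("precision and recall handle the degenerate conventions", {
  expect_equal(precision_recall(list(tp = 2, fp = 5, fn = 0)),
               c(precision = 2 / 7, recall = 1))
  expect_warning(pr <- precision_recall(list(tp = 0, fp = 0, fn = 3)),
                 "precision")
  expect_equal(pr, c(precision = 0, recall = 0))
  pr2 <- precision_recall(list(tp = 19, fp = 2, fn = 4))
  expect_equal(round(pr2[["precision"]], 3), 0.905)
  expect_equal(round(pr2[["recall"]], 3), 0.826)
})

test_that("fbeta equals the weighted harmonic mean on random inputs", {
  set.seed(1)
  for (k in 1:1000) {
    p <- runif(1); r <- runif(1); b <- runif(1, 0.2, 5)
    expect_equal(fbeta(p, r, b), naive_fbeta(p, r, b), tolerance = 1e-12)
  }
  x <- runif(5)
  for (b in c(0.5, 1, 2)) expect_equal(fbeta(x, x, b), x)
  expect_equal(fbeta(0, 0, 2), 0)
})

test_that("average precision follows all-point interpolation", {
  gts <- tibble::tibble(image = "a", x = 0, y = 0, w = 10, h = 10)
  hit <- tibble::tibble(image = "a", x = 0, y = 0, w = 10, h = 10,
                        confidence = 0.9)
  miss <- tibble::tibble(image = "a", x = 50, y = 50, w = 10, h = 10,
                         confidence = 0.95)
  expect_equal(average_precision(hit, gts), 1)
  expect_equal(average_precision(miss, gts), 0)
  # first-ranked wrong, second right: AP = 0.5
  expect_equal(average_precision(dplyr::bind_rows(miss, hit), gts), 0.5)
})

test_that("AP agrees with brute force on every ranking of few predictions", {
  # one image, 3 GT boxes, predictions hitting {T, T, F, F, T, F} in all
  # possible confidence orders
  gts <- tibble::tibble(image = "a", x = c(0, 100, 200), y = 0, w = 10, h = 10)
  pred_boxes <- tibble::tibble(
    x = c(0, 100, 400, 500, 200, 600), y = 0, w = 10, h = 10)
  correct <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  perms <- list(1:6, 6:1, c(3, 1, 4, 2, 5, 6), c(5, 4, 3, 2, 1, 6),
                c(2, 5, 1, 3, 6, 4), c(4, 6, 3, 5, 1, 2))
  for (ord in perms) {
    preds <- pred_boxes[ord, ]
    preds$image <- "a"
    preds$confidence <- seq(0.9, 0.4, length.out = 6)
    expect_equal(average_precision(preds, gts),
                 naive_ap(correct[ord], 3))
  }
})

test_that("cv_summary reproduces a fold-mean exactly", {
  s <- cv_summary(c(0.3853, 0.3882, 0.4262, 0.4069, 0.3965))
  expect_equal(round(s$mean, 4), 0.4006)
  expect_equal(s$n_folds, 5)
})

test_that("patient-level folds partition patients and respect the hold-out", {
  set.seed(2)
  pairs_df <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", 1:20), times = sample(2:8, 20, TRUE)))
  sp <- kfold_split(pairs_df, k = 5, holdout_pairs = 15, seed = 3)
  expect_equal(sort(unique(sp$patient_id)), sort(unique(pairs_df$patient_id)))
  expect_false(any(duplicated(sp$patient_id)))
  hold <- sp[sp$role == "holdout", ]
  expect_gte(sum(hold$n_pairs), 15)
  dev <- sp[sp$role == "dev", ]
  expect_true(all(!is.na(dev$fold)))
  expect_true(all(is.na(hold$fold)))
  expect_equal(sort(unique(dev$fold)), 1:5)
  # same seed, same split; 10 dev patients over 5 folds -> 2 each
  sp2 <- kfold_split(pairs_df, k = 5, holdout_pairs = 15, seed = 3)
  expect_identical(sp, sp2)
  sp10 <- kfold_split(tibble::tibble(patient_id = sprintf("P%02d", 1:10)),
                      k = 5, seed = 1)
  expect_true(all(table(sp10$fold) == 2))
  expect_error(kfold_split(tibble::tibble(patient_id = c("a", "b")), k = 5),
               "folds")
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  rec <- tibble::tibble(patient_id = sprintf("p%d", 1:6),
                        tp = 2, fp = 1, fn = 1)
  prec_fn <- function(tp, fp, fn) if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  ci1 <- bootstrap_ci(rec, prec_fn, B = 200, seed = 5)
  ci2 <- bootstrap_ci(rec, prec_fn, B = 200, seed = 5)
  expect_identical(ci1, ci2)
  # identical patients: the interval collapses to the point
  expect_equal(unname(ci1), c(2 / 3, 2 / 3))
  expect_error(bootstrap_ci(rec[1, ], prec_fn), "two patients")
})

test_that("bootstrap interval contains the point estimate on mixed records", {
  set.seed(6)
  rec <- tibble::tibble(patient_id = sprintf("p%d", 1:12),
                        tp = rpois(12, 3), fp = rpois(12, 2),
                        fn = rpois(12, 1))
  rec_fn <- function(tp, fp, fn) if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  ci <- bootstrap_ci(rec, rec_fn, B = 500, seed = 7)
  point <- rec_fn(sum(rec$tp), sum(rec$fp), sum(rec$fn))
  expect_lte(ci[["low"]], point)
  expect_gte(ci[["high"]], point)
})

test_that("Cohen's kappa matches hand arithmetic and chance behaviour", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # table: both+ 20, both- 15, rater1-only 5, rater2-only 10
  r1 <- c(rep(1, 20), rep(0, 15), rep(1, 5), rep(0, 10))
  r2 <- c(rep(1, 20), rep(0, 15), rep(0, 5), rep(1, 10))
  expect_equal(cohen_kappa(r1, r2), naive_kappa_from_table(20, 15, 5, 10))
  # independent raters with 0.5 marginals: kappa near zero on average
  set.seed(8)
  ks <- replicate(200, cohen_kappa(rbinom(400, 1, 0.5), rbinom(400, 1, 0.5)))
  expect_lt(abs(mean(ks)), 0.02)
  expect_error(cohen_kappa(c(1, 1), c(0, 0, 0)))
})

test_that("Fleiss' kappa behaves at unanimity, chance, and degeneracy", {
  unan <- rbind(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0))
  expect_equal(fleiss_kappa(unan), 1)
  set.seed(9)
  rand <- matrix(rbinom(5 * 400, 1, 0.5), nrow = 5)
  expect_lt(abs(fleiss_kappa(rand)), 0.05)
  expect_error(fleiss_kappa(matrix(1, 4, 10)), "constant")
  # for two readers it points the same way as Cohen's kappa
  set.seed(10)
  for (k in 1:20) {
    base <- rbinom(100, 1, 0.5)
    r2 <- ifelse(runif(100) < 0.8, base, 1 - base)
    m <- rbind(base, r2)
    ck <- cohen_kappa(base, r2)
    fk <- fleiss_kappa(m)
    if (abs(ck) > 0.05) expect_equal(sign(fk), sign(ck))
  }
})

test_that("metrics_report pools counts and brackets the point estimates", {
  set.seed(20)
  rec <- tibble::tibble(patient_id = sprintf("p%d", 1:10),
                        tp = rpois(10, 4), fp = rpois(10, 2),
                        fn = rpois(10, 2))
  rep_tbl <- metrics_report(rec, map50 = 0.4, B = 300, seed = 3)
  expect_setequal(rep_tbl$metric, c("precision", "recall", "f1", "f2", "map50"))
  p <- sum(rec$tp) / sum(rec$tp + rec$fp)
  r <- sum(rec$tp) / sum(rec$tp + rec$fn)
  expect_equal(rep_tbl$value[rep_tbl$metric == "precision"], p)
  expect_equal(rep_tbl$value[rep_tbl$metric == "f2"], fbeta(p, r, 2))
  core <- rep_tbl[rep_tbl$metric != "map50", ]
  expect_true(all(core$ci_low <= core$value & core$value <= core$ci_high))
})

test_that("macro averaging over readers uses the averaged operating point", {
  pr <- tibble::tibble(precision = c(0.4, 0.6), recall = c(0.8, 0.6))
  out <- macro_average_readers(pr)
  expect_equal(out$precision, 0.5)
  expect_equal(out$recall, 0.7)
  expect_equal(out$f1, fbeta(0.5, 0.7, 1))
})

test_that("threshold sweeps re-threshold stored detections consistently", {
  set.seed(11)
  gts <- tibble::tibble(image = rep(c("a", "b"), each = 2),
                        x = c(0, 100, 0, 100), y = 0, w = 20, h = 20)
  hits <- dplyr::mutate(gts, confidence = runif(4, 0.3, 0.9))
  fps <- tibble::tibble(image = sample(c("a", "b"), 30, TRUE),
                        x = runif(30, 150, 220), y = runif(30, 40, 200),
                        w = 15, h = 15, confidence = runif(30, 0.001, 0.6))
  dets <- dplyr::bind_rows(hits, fps)
  grid <- c(0.001, 0.01, 0.05, 0.1, 0.2)
  sw <- threshold_sweep(dets, gts, grid)
  base <- sw[!sw$filtered, ]
  # recall is non-increasing in T1 for the unfiltered detector
  expect_true(all(diff(base$recall) <= 1e-12))
  # T1 = T2: the forwarded set is empty, so filtering changes nothing
  sw2 <- threshold_sweep(dets, gts, 0.2, T2_fixed = 0.2,
                         filter_fn = function(d) rep(FALSE, nrow(d)))
  expect_equal(sw2$precision[1], sw2$precision[2])
  expect_equal(sw2$recall[1], sw2$recall[2])
  # a filter that drops every forwarded false positive raises precision
  keep_truth <- dets$confidence %in% hits$confidence
  sw3 <- threshold_sweep(dets, gts, 0.01, filter_fn = function(d) {
    d$confidence %in% hits$confidence
  })
  expect_gte(sw3$precision[sw3$filtered], sw3$precision[!sw3$filtered])
})
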