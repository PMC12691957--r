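# Evaluation protocol: greedy IoU matching, precision/recall/F-beta,
# all-point-interpolated average precision, patient-level k-fold splits,
# stratified patient bootstrap, inter-reader kappa statistics, and
# operating-point sweeps over the cascade's forwarding threshold.

#' Match predictions to ground truth by IoU
#'
#' Greedy one-to-one matching: predictions are visited in order of
#' descending confidence and each claims the still-unclaimed ground-truth
#' box of highest IoU, provided that IoU reaches the threshold. Unmatched
#' predictions are false positives; unmatched ground truth, false
#' negatives.
#'
#' @param preds Detection tibble with `x`, `y`, `w`, `h` and (optionally)
#'   `confidence`; sorted internally by descending confidence.
#' @param gts Ground-truth box tibble.
#' @param iou_threshold Minimum IoU for a match (0.5 by default).
#' @returns List of class `match_result`: counts `tp`, `fp`, `fn` and a
#'   tibble `matched_pairs` (`pred`, `gt`, `iou`).
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  if (!is.null(preds$confidence)) {
    ord <- order(-preds$confidence)
  } else {
    ord <- seq_len(nrow(preds))
  }
  claimed <- logical(nrow(gts))
  matches <- list()
  for (p in ord) {
    if (nrow(gts) == 0) break
    ious <- iou(preds[p, c("x", "y", "w", "h")], gts)
    ious[claimed] <- -1
    g <- which.max(ious)
    if (length(g) == 1 && ious[g] >= iou_threshold) {
      claimed[g] <- TRUE
      matches[[length(matches) + 1L]] <-
        tibble::tibble(pred = p, gt = g, iou = ious[g])
    }
  }
  mp <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(pred = integer(), gt = integer(), iou = numeric())
  structure(list(tp = nrow(mp), fp = nrow(preds) - nrow(mp),
                 fn = nrow(gts) - nrow(mp), matched_pairs = mp),
            class = "match_result")
}

#' Precision and recall from a match result
#'
#' Degenerate cases: precision is 0 (with a warning) when there are no
#' predictions; recall is 0 when there is no ground truth.
#'
#' @param m A `match_result` or any list with `tp`, `fp`, `fn`.
#' @returns Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(m) {
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else {
    warn("No predictions: precision defined as 0.")
    0
  }
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  c(precision = p, recall = r)
}

#' F-beta score
#'
#' `(1 + beta^2) * p * r / (beta^2 * p + r)`; beta = 2 weighs recall four
#' times as heavily as precision. Returns 0 when both inputs are 0.
#'
#' @param p,r Precision and recall in \[0, 1\].
#' @param beta Recall weight.
#' @returns F-beta in \[0, 1\].
#' @export
fbeta <- function(p, r, beta = 1) {
  ifelse(p + r == 0, 0, (1 + beta^2) * p * r / (beta^2 * p + r))
}

#' Average precision with all-point interpolation
#'
#' Predictions are pooled over images, ranked by confidence, and matched
#' greedily at the IoU threshold; AP is the area under the interpolated
#' precision-recall curve (at each recall level, the maximum precision at
#' any recall at least as large). With a single class, mAP equals AP.
#'
#' @param preds Detection tibble with a `confidence` column and an `image`
#'   column identifying the image each prediction belongs to.
#' @param gts Ground-truth tibble with the same `image` column.
#' @param iou_threshold Matching threshold.
#' @returns AP in \[0, 1\].
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5) {
  n_gt <- nrow(gts)
  if (n_gt == 0) return(0)
  if (nrow(preds) == 0) return(0)
  preds <- preds[order(-preds$confidence), , drop = FALSE]
  claimed <- rep(FALSE, n_gt)
  tp <- numeric(nrow(preds))
  for (k in seq_len(nrow(preds))) {
    g_idx <- which(gts$image == preds$image[k] & !claimed)
    if (length(g_idx) > 0) {
      ious <- iou(preds[k, c("x", "y", "w", "h")], gts[g_idx, ])
      best <- which.max(ious)
      if (ious[best] >= iou_threshold) {
        claimed[g_idx[best]] <- TRUE
        tp[k] <- 1
      }
    }
  }
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  # all-point interpolation: running max of precision from the right
  prec_i <- rev(cummax(rev(prec)))
  ap <- 0
  prev_r <- 0
  for (k in seq_along(rec)) {
    if (rec[k] > prev_r) {
      ap <- ap + (rec[k] - prev_r) * prec_i[k]
      prev_r <- rec[k]
    }
  }
  ap
}

#' Summarise per-fold cross-validation metrics
#'
#' @param values Numeric vector of per-fold metric values (or a tibble with
#'   a `value` column).
#' @returns One-row tibble: `mean`, `sd`, `n_folds`.
#' @export
cv_summary <- function(values) {
  if (is.data.frame(values)) values <- values$value
  tibble::tibble(mean = mean(values), sd = sd(values),
                 n_folds = length(values))
}

#' Patient-level k-fold split with an a-priori hold-out
#'
#' Hold-out patients are removed first (greedily chosen, seeded, until
#' their pair counts reach `holdout_pairs`), the remaining (development)
#' patients are shuffled into `k` folds, and within each fold patients are
#' flagged ~80/20 train/validation. All pairs of a patient stay together.
#'
#' @param pairs_df Tibble with one row per bilateral pair and a
#'   `patient_id` column.
#' @param k Number of folds.
#' @param holdout_pairs Approximate number of pairs to reserve as hold-out.
#' @param seed Integer seed.
#' @returns Tibble: `patient_id`, `n_pairs`, `role`
#'   (`"holdout"`/`"dev"`), `fold` (`NA` for hold-out), `dev_split`
#'   (`"train"`/`"val"` within the fold, `NA` for hold-out).
#' @export
kfold_split <- function(pairs_df, k = 5, holdout_pairs = 0, seed = 1L) {
  counts <- dplyr::count(pairs_df, .data$patient_id, name = "n_pairs")
  withr::with_seed(seed, {
    counts <- counts[sample.int(nrow(counts)), , drop = FALSE]
    cum <- cumsum(counts$n_pairs)
    n_hold <- if (holdout_pairs > 0) which(cum >= holdout_pairs)[1] else 0L
    if (is.na(n_hold)) abort("holdout_pairs exceeds the number of pairs.")
    hold <- counts$patient_id[seq_len(n_hold)]
    dev <- counts$patient_id[setdiff(seq_len(nrow(counts)), seq_len(n_hold))]
    if (length(dev) < k) abort("Not enough development patients for k folds.")
    fold <- rep(seq_len(k), length.out = length(dev))
    dev_split <- ifelse(runif(length(dev)) < 0.8, "train", "val")
    dplyr::bind_rows(
      tibble::tibble(patient_id = hold, role = "holdout",
                     fold = NA_integer_, dev_split = NA_character_),
      tibble::tibble(patient_id = dev, role = "dev", fold = fold,
                     dev_split = dev_split)
    ) |>
      dplyr::left_join(counts, by = "patient_id") |>
      dplyr::select(dplyr::all_of(c("patient_id", "n_pairs", "role",
                                    "fold", "dev_split")))
  })
}

#' Stratified patient-level bootstrap confidence interval
#'
#' Patients are resampled with replacement within lesion-positive and
#' lesion-negative strata (a patient is positive when `tp + fn > 0`); the
#' metric is recomputed from the pooled tp/fp/fn of each resample and a
#' percentile interval returned. Resamples on which the metric is
#' undefined (`NA`) are redrawn.
#'
#' @param records Tibble with one row per patient: `patient_id`, `tp`,
#'   `fp`, `fn`.
#' @param metric_fn Function of `(tp, fp, fn)` returning a scalar (or `NA`
#'   when undefined).
#' @param B Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @returns Named vector `c(low, high)`.
#' @export
bootstrap_ci <- function(records, metric_fn, B = 10000, level = 0.95,
                         seed = 1L) {
  if (nrow(records) < 2) abort("Need at least two patients to bootstrap.")
  pos <- which(records$tp + records$fn > 0)
  neg <- setdiff(seq_len(nrow(records)), pos)
  withr::with_seed(seed, {
    stats <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        take <- c(if (length(pos)) sample(pos, length(pos), replace = TRUE),
                  if (length(neg)) sample(neg, length(neg), replace = TRUE))
        v <- metric_fn(sum(records$tp[take]), sum(records$fp[take]),
                       sum(records$fn[take]))
        if (!is.na(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 100 * B) abort("Metric undefined on almost all resamples.")
      }
      stats[b] <- v
    }
    if (redrawn > 0) {
      warn(sprintf("%d undefined resample(s) redrawn.", redrawn))
    }
    alpha <- (1 - level) / 2
    ci <- quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7)
    c(low = ci[1], high = ci[2])
  })
}

#' Cohen's kappa for two binary raters
#'
#' `(p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' products. When `p_e = 1`, defined as 1 if the observed agreement is also
#' perfect, otherwise an error.
#'
#' @param r1,r2 Equal-length binary (0/1 or logical) vectors.
#' @returns Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) >= 1)
  r1 <- as.integer(as.logical(r1)); r2 <- as.integer(as.logical(r2))
  n <- length(r1)
  po <- mean(r1 == r2)
  pe <- mean(r1) * mean(r2) + (1 - mean(r1)) * (1 - mean(r2))
  if (abs(1 - pe) < 1e-12) {
    if (abs(1 - po) < 1e-12) return(1)
    abort("Chance agreement is 1 but observed agreement is not; kappa undefined.")
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for a panel of raters on binary items
#'
#' @param ratings Reader x case binary matrix (rows = readers, columns =
#'   cases; complete, no missing cells).
#' @returns Kappa. Errors when every rater gives the same rating to every
#'   item (agreement is undefined).
#' @export
fleiss_kappa <- function(ratings) {
  stopifnot(is.matrix(ratings), nrow(ratings) >= 2)
  if (any(is.na(ratings))) abort("Ratings matrix must be complete.")
  n_r <- nrow(ratings)
  pos <- colSums(ratings != 0)
  neg <- n_r - pos
  p_i <- (pos * (pos - 1) + neg * (neg - 1)) / (n_r * (n_r - 1))
  p_bar <- mean(p_i)
  pj <- c(mean(pos / n_r), mean(neg / n_r))
  pe <- sum(pj^2)
  if (abs(1 - pe) < 1e-12) {
    abort("All raters constant on all items; Fleiss' kappa undefined.")
  }
  (p_bar - pe) / (1 - pe)
}

#' Assemble a metrics report with bootstrap confidence intervals
#'
#' Pools per-patient counts into point estimates of precision, recall, F1
#' and F2 and attaches patient-level stratified bootstrap percentile
#' intervals to each.
#'
#' @param records Tibble with one row per patient: `patient_id`, `tp`,
#'   `fp`, `fn`.
#' @param map50 Optional AP at IoU 0.5 to carry along (no interval).
#' @param B,level,seed Passed to [bootstrap_ci()].
#' @returns Tibble with one row per metric: `metric`, `value`, `ci_low`,
#'   `ci_high`.
#' @export
metrics_report <- function(records, map50 = NA_real_, B = 10000,
                           level = 0.95, seed = 1L) {
  tp <- sum(records$tp); fp <- sum(records$fp); fn <- sum(records$fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  fns <- list(
    precision = function(tp, fp, fn) if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = function(tp, fp, fn) if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    f1 = function(tp, fp, fn) {
      if (tp + fp == 0 || tp + fn == 0) return(NA_real_)
      fbeta(tp / (tp + fp), tp / (tp + fn), 1)
    },
    f2 = function(tp, fp, fn) {
      if (tp + fp == 0 || tp + fn == 0) return(NA_real_)
      fbeta(tp / (tp + fp), tp / (tp + fn), 2)
    })
  vals <- c(precision = p, recall = r,
            f1 = fbeta(p, r, 1), f2 = fbeta(p, r, 2))
  out <- purrr::imap(fns, function(f, nm) {
    ci <- bootstrap_ci(records, f, B = B, level = level, seed = seed)
    tibble::tibble(metric = nm, value = vals[[nm]],
                   ci_low = ci[["low"]], ci_high = ci[["high"]])
  })
  out <- dplyr::bind_rows(out)
  if (!is.na(map50)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "map50", value = map50,
      ci_low = NA_real_, ci_high = NA_real_))
  }
  out
}

#' Macro-average precision/recall over a reader panel
#'
#' @param per_reader Tibble with one row per reader: `precision`, `recall`.
#' @param beta F-score weights to report.
#' @returns One-row tibble with averaged precision/recall and F-scores of
#'   the averages.
#' @export
macro_average_readers <- function(per_reader, beta = c(1, 2)) {
  p <- mean(per_reader$precision); r <- mean(per_reader$recall)
  out <- tibble::tibble(precision = p, recall = r)
  for (b in beta) out[[paste0("f", b)]] <- fbeta(p, r, b)
  out
}

#' Sweep the forwarding threshold T1 at fixed T2
#'
#' Re-thresholds stored detections without re-running any model. For each
#' T1 in the grid, metrics are computed over all images after suppressing
#' detections below T1; when `filter_fn` is supplied, a second set of rows
#' additionally drops forwarded detections (`T1 <= confidence < T2`) that
#' `filter_fn` rejects.
#'
#' @param detections Tibble of raw detections: `image` (image/side
#'   identifier), `x`, `y`, `w`, `h`, `confidence`, and a stable `id`
#'   column (added if absent).
#' @param gts Ground-truth tibble with an `image` column.
#' @param T1_grid Numeric vector of T1 values.
#' @param T2_fixed The fixed accept threshold.
#' @param filter_fn Optional predicate: takes the forwarded-detection rows,
#'   returns a logical keep vector (the verification stage, precomputable).
#' @param iou_threshold Matching threshold.
#' @returns Tibble of class `sweep_table`: one row per (T1, filtered) with
#'   `precision`, `recall`, `f1`, `f2`.
#' @export
threshold_sweep <- function(detections, gts, T1_grid, T2_fixed = 0.20,
                            filter_fn = NULL, iou_threshold = 0.5) {
  if (!"id" %in% names(detections)) detections$id <- seq_len(nrow(detections))
  images <- unique(c(detections$image, gts$image))

  metrics_for <- function(dets) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (im in images) {
      m <- match_detections(dets[dets$image == im, , drop = FALSE],
                            gts[gts$image == im, , drop = FALSE],
                            iou_threshold)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    tibble::tibble(precision = p, recall = r,
                   f1 = fbeta(p, r, 1), f2 = fbeta(p, r, 2))
  }

  filter_keep <- NULL
  if (!is.null(filter_fn)) {
    filter_keep <- filter_fn(detections)
    stopifnot(length(filter_keep) == nrow(detections))
  }

  rows <- list()
  for (t1 in T1_grid) {
    base <- detections[detections$confidence >= t1, , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      dplyr::bind_cols(tibble::tibble(T1 = t1, filtered = FALSE),
                       metrics_for(base))
    if (!is.null(filter_keep)) {
      keep <- detections$confidence >= t1 &
        (detections$confidence >= T2_fixed | filter_keep)
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(T1 = t1, filtered = TRUE),
                         metrics_for(detections[keep, , drop = FALSE]))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_table", class(out))
  out
}
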