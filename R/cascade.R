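# Hierarchical decision policy.
#
# Detections are routed by confidence: below T1 suppressed, in [T1, T2)
# forwarded to contralateral verification, at or above T2 accepted
# directly. Forwarded candidates are scored against their four
# contralateral reference patches by the similarity filter; only candidates
# judged dissimilar from the opposite side survive. The final output is
# the union of directly accepted and verified detections - the cascade
# never invents boxes.

#' Cascade configuration
#'
#' @param T1 Suppression threshold: detections with confidence `< T1` are
#'   discarded (default 0.01).
#' @param T2 Direct-accept threshold: detections with confidence `>= T2`
#'   bypass verification (default 0.20). Requires `0 <= T1 < T2 <= 1`.
#' @param aggregation How the four candidate references feed the filter:
#'   `"best_reference"` (default) scores only the HOG-closest reference -
#'   the reference localisation step selects a single reference box, and
#'   that is also the configuration the filter is trained on;
#'   `"all_dissimilar"` keeps a candidate iff every reference scores
#'   dissimilar (strictest, trades recall for precision); `"majority"`
#'   requires at least 3 of 4.
#' @param decision_threshold Similarity-score threshold passed to
#'   [classify()].
#' @param mirror_mode Passed to the symmetry stage.
#' @param seed Seed for the jitter draws during verification.
#' @returns An object of class `cascade_config`.
#' @export
cascade_config <- function(T1 = 0.01, T2 = 0.20,
                           aggregation = c("best_reference", "all_dissimilar",
                                           "majority"),
                           decision_threshold = 0,
                           mirror_mode = c("flip", "identity"),
                           seed = 1L) {
  aggregation <- match.arg(aggregation)
  mirror_mode <- match.arg(mirror_mode)
  if (!(T1 >= 0 && T1 < T2 && T2 <= 1)) {
    abort("Cascade thresholds must satisfy 0 <= T1 < T2 <= 1.")
  }
  structure(list(T1 = T1, T2 = T2, aggregation = aggregation,
                 decision_threshold = decision_threshold,
                 mirror_mode = mirror_mode, seed = as.integer(seed)),
            class = "cascade_config")
}

#' Route detections by confidence
#'
#' Partitions detections into `suppressed` (`confidence < T1`), `forwarded`
#' (`T1 <= confidence < T2`) and `accepted` (`confidence >= T2`).
#'
#' @param detections Detection tibble with a `confidence` column.
#' @param cfg A [cascade_config()].
#' @returns List of three tibbles `suppressed`, `forwarded`, `accepted`
#'   that exactly partition the input.
#' @export
route <- function(detections, cfg = cascade_config()) {
  stopifnot(all(detections$confidence >= 0 & detections$confidence <= 1))
  list(
    suppressed = detections[detections$confidence < cfg$T1, , drop = FALSE],
    forwarded = detections[detections$confidence >= cfg$T1 &
                             detections$confidence < cfg$T2, , drop = FALSE],
    accepted = detections[detections$confidence >= cfg$T2, , drop = FALSE]
  )
}

#' Verify forwarded detections against contralateral references
#'
#' For each forwarded detection, the four contralateral patch pairs are
#' built ([reference_candidates()]) and scored by the similarity filter;
#' the detection is kept according to `cfg$aggregation`: by default the
#' HOG-closest reference decides (a genuine lesion should not resemble its
#' localised contralateral reference).
#'
#' @param forwarded Detection tibble (the `forwarded` element of [route()]).
#' @param pair The `bilateral_pair` the detections come from.
#' @param side Side the detections live on.
#' @param scnn_model A trained `sonosym_scnn`.
#' @param sym_cfg A [symmetry_config()].
#' @param cfg A [cascade_config()].
#' @param hog_cfg A [hog_config()] (used by the `best_reference` rule).
#' @returns The kept subset of `forwarded`, with a `min_score` column (the
#'   smallest of the aggregated similarity scores).
#' @export
verify <- function(forwarded, pair, side, scnn_model,
                   sym_cfg = symmetry_config(), cfg = cascade_config(),
                   hog_cfg = hog_config()) {
  if (nrow(forwarded) == 0) {
    out <- forwarded
    out$min_score <- numeric(0)
    return(out)
  }
  sym_cfg$mirror_mode <- cfg$mirror_mode
  keep <- logical(nrow(forwarded))
  min_score <- numeric(nrow(forwarded))
  for (i in seq_len(nrow(forwarded))) {
    cand <- reference_candidates(forwarded[i, ], pair, side, sym_cfg,
                                 seed = cfg$seed + i)
    scores <- purrr::map2_dbl(cand$index_patch, cand$reference_patch,
                              function(a, b) score_pair(scnn_model, a, b))
    dis <- classify(scores, cfg$decision_threshold) == "dissimilar"
    keep[i] <- switch(cfg$aggregation,
      all_dissimilar = all(dis),
      best_reference = {
        d_feat <- hog_descriptor(cand$index_patch[[1]], hog_cfg)
        dists <- vapply(cand$reference_patch, function(rp) {
          hog_distance(d_feat, hog_descriptor(rp, hog_cfg))
        }, 0)
        dis[which.min(dists)]
      },
      majority = sum(dis) >= 3L)
    min_score[i] <- min(scores)
  }
  out <- forwarded[keep, , drop = FALSE]
  out$min_score <- min_score[keep]
  out
}

#' Run the full two-stage pipeline on one bilateral pair
#'
#' Each side is detected independently; detections are routed, forwarded
#' candidates are verified against the opposite side, and the final output
#' per side is `accepted` plus the verified survivors (suppressed
#' detections are never returned).
#'
#' @param pair A `bilateral_pair`.
#' @param detector_model A trained `sonosym_detector`.
#' @param scnn_model A trained `sonosym_scnn`.
#' @param cfg A [cascade_config()].
#' @param sym_cfg A [symmetry_config()].
#' @param hog_cfg A [hog_config()].
#' @returns Tibble of final detections with columns `pair_id`, `side`,
#'   `x`, `y`, `w`, `h`, `confidence`, `stage` (`"accepted"` or
#'   `"verified"`).
#' @export
run_pipeline <- function(pair, detector_model, scnn_model,
                         cfg = cascade_config(),
                         sym_cfg = symmetry_config(),
                         hog_cfg = hog_config()) {
  out <- list()
  for (side in c("left", "right")) {
    det <- detect(detector_model, pair_image(pair, side), conf_floor = cfg$T1)
    rt <- route(det, cfg)
    kept <- verify(rt$forwarded, pair, side, scnn_model, sym_cfg, cfg, hog_cfg)
    acc <- rt$accepted
    if (nrow(acc) > 0) acc$stage <- "accepted"
    if (nrow(kept) > 0) kept$stage <- "verified"
    kept$min_score <- NULL
    res <- dplyr::bind_rows(acc, kept)
    if (nrow(res) > 0) {
      res$pair_id <- pair$pair_id
      res$side <- side
      out[[side]] <- res
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(pair_id = character(), side = character(),
                          x = numeric(), y = numeric(), w = numeric(),
                          h = numeric(), confidence = numeric(),
                          stage = character()))
  }
  dplyr::bind_rows(out) |>
    dplyr::select(dplyr::all_of(c("pair_id", "side", "x", "y", "w", "h",
                                  "confidence")), dplyr::everything())
}
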