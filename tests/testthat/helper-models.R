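# Shared, lazily-built fixtures. Training runs are the expensive part of
# the suite, so one detector fit and one filter fit are built on first use
# and reused by every test that needs a trained model. All sizes are
# CPU-scale study conditions: 256 x 256 phantoms, 30 training pairs,
# 30 held-out test pairs from disjoint patients.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

train_phantom_params <- function() {
  phantom_params(n_lesions = 2, n_distractors = 2, seed = 100)
}

test_phantom_params <- function() {
  phantom_params(n_lesions = 2, n_distractors = 2, seed = 999)
}

get_train_pairs <- function() {
  fixture("train_pairs", function() {
    generate_dataset(15, 2, train_phantom_params())
  })
}

get_test_pairs <- function() {
  fixture("test_pairs", function() {
    generate_dataset(15, 2, test_phantom_params())
  })
}

get_detector_fit <- function() {
  fixture("detector_fit", function() {
    train_detector(get_train_pairs(), detector_config(input_size = 256),
                   epochs = 60, seed = 1)
  })
}

get_mined_pairs <- function() {
  fixture("mined_pairs", function() {
    # the detector's training pairs plus mining-only pairs from additional
    # patients: the filter needs a few hundred labelled patch pairs
    extra <- generate_dataset(12, 2, phantom_params(n_lesions = 2,
                                                    n_distractors = 2,
                                                    seed = 5100))
    mine_dataset_pairs(c(get_train_pairs(), extra), seed = 42)
  })
}

get_scnn_fit <- function() {
  fixture("scnn_fit", function() {
    train_scnn(get_mined_pairs(), filter_config(seed = 5))
  })
}

# A deterministic stand-in scorer for cascade-logic tests: dissimilar iff
# the index-side patch centre is markedly darker than the reference centre.
mock_scorer <- function(margin = 0.02) {
  structure(list(margin = margin), class = "mock_scorer")
}

score_pair.mock_scorer <- function(model, index_patch, reference_patch) {
  ctr <- function(p) {
    n <- nrow(p)
    lo <- floor(n / 3); hi <- ceiling(2 * n / 3)
    mean(p[lo:hi, lo:hi])
  }
  d <- ctr(reference_patch) - ctr(index_patch)
  tanh(50 * (d - model$margin))
}
registerS3method("score_pair", "mock_scorer", score_pair.mock_scorer,
                 envir = asNamespace("sonosym"))


# A deterministic, speckle-free bilateral scene for cascade-logic tests:
# flip-symmetric striated background, two unilateral lesions on the left
# (ground truth) and three bilateral look-alike stamps (distractors).
crafted_bilateral_scene <- function() {
  base <- matrix(0.5, 256, 256) +
    0.1 * sin(2 * pi * matrix(seq_len(256), 256, 256) / 12)
  stamp <- function(im, cx, cy) {
    m <- sonosym:::ellipse_mask(nrow(im), ncol(im), cx, cy, 14, 11, 0)
    im * (1 - 0.5 * m)
  }
  les <- list(c(50, 60), c(200, 60))                  # unilateral, left only
  bil <- list(c(60, 180), c(128, 200), c(190, 140))   # on both sides
  img <- base
  for (p0 in c(les, bil)) img <- stamp(img, p0[1], p0[2])
  right <- base
  for (p0 in bil) right <- stamp(right, ncol(right) - p0[1], p0[2])
  structure(list(
    left_image = img, right_image = right,
    left_boxes = boxes(vapply(les, `[`, 0, 1) - 15,
                       vapply(les, `[`, 0, 2) - 12, 30, 24),
    right_boxes = boxes(),
    distractor_boxes = boxes(vapply(bil, `[`, 0, 1) - 15,
                             vapply(bil, `[`, 0, 2) - 12, 30, 24),
    patient_id = "craft", pair_id = "craft"), class = "bilateral_pair")
}
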