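test_that("identical parameters and seed give bit-identical pairs", {
  p1 <- generate_pair(phantom_params(seed = 17))
  p2 <- generate_pair(phantom_params(seed = 17))
  expect_identical(p1, p2)
  p3 <- generate_pair(phantom_params(seed = 18))
  expect_false(identical(p1$left_image, p3$left_image))
})

test_that("lesion count zero gives empty ground truth on both sides", {
  p <- generate_pair(phantom_params(n_lesions = 0, n_distractors = 0, seed = 2))
  expect_equal(nrow(p$left_boxes), 0)
  expect_equal(nrow(p$right_boxes), 0)
})

test_that("pair geometry and parameter validation hold", {
  p <- generate_pair(phantom_params(seed = 4))
  expect_identical(dim(p$left_image), dim(p$right_image))
  expect_true(all(p$left_image >= 0 & p$left_image <= 1))
  for (side in c("left", "right")) {
    b <- pair_boxes <- if (side == "left") p$left_boxes else p$right_boxes
    if (nrow(b) > 0) {
      expect_true(all(b$x >= 0 & b$y >= 0 &
                        b$x + b$w <= ncol(p$left_image) &
                        b$y + b$h <= nrow(p$left_image)))
    }
  }
  expect_error(phantom_params(n_lesions = 6), "n_lesions")
  expect_error(phantom_params(lesion_contrast = 1.2), "lesion_contrast")
  expect_error(phantom_params(image_size = 128), "256")
})

test_that("lesions are hypoechoic relative to the mirrored lesion-free side", {
  p <- generate_pair(phantom_params(n_lesions = 3, lesion_contrast = 0.5,
                                    side_offset_sd = 2, n_distractors = 0,
                                    seed = 11))
  w <- ncol(p$left_image)
  for (side in c("left", "right")) {
    b <- if (side == "left") p$left_boxes else p$right_boxes
    img <- if (side == "left") p$left_image else p$right_image
    oth <- if (side == "left") p$right_image else p$left_image
    for (i in seq_len(nrow(b))) {
      m <- mirror_box(b[i, ], w)
      region <- function(im, bb) {
        im[(floor(bb$y) + 1):ceiling(bb$y + bb$h),
           (floor(bb$x) + 1):ceiling(bb$x + bb$w)]
      }
      expect_lt(mean(region(img, b[i, ])), mean(region(oth, m)))
    }
  }
})

test_that("lesion interiors are darker than their local surround across seeds", {
  contrast_margin <- function(img, b) {
    # central part of the box (the bounding-box corners of a rotated
    # ellipse lie outside the lesion) against a surrounding ring
    rows <- (floor(b$y + 0.25 * b$h) + 1):ceiling(b$y + 0.75 * b$h)
    cols <- (floor(b$x + 0.25 * b$w) + 1):ceiling(b$x + 0.75 * b$w)
    brows <- (floor(b$y) + 1):ceiling(b$y + b$h)
    bcols <- (floor(b$x) + 1):ceiling(b$x + b$w)
    ring_rows <- pmax(1, min(brows) - 15):pmin(nrow(img), max(brows) + 15)
    ring_cols <- pmax(1, min(bcols) - 15):pmin(ncol(img), max(bcols) + 15)
    ring <- img[ring_rows, ring_cols]
    box_px <- img[brows, bcols]
    outer_mean <- (sum(ring) - sum(box_px)) / (length(ring) - length(box_px))
    outer_mean - mean(img[rows, cols])
  }
  speckled_ok <- 0L; n_lesions <- 0L
  for (s in 1:100) {
    p <- generate_pair(phantom_params(n_lesions = 1, n_distractors = 0,
                                      seed = 1000 + s))
    for (side in c("left", "right")) {
      b <- if (side == "left") p$left_boxes else p$right_boxes
      img <- if (side == "left") p$left_image else p$right_image
      pre <- if (side == "left") p$left_pre else p$right_pre
      for (i in seq_len(nrow(b))) {
        n_lesions <- n_lesions + 1L
        # deterministic contrast before speckle: strict, every lesion
        expect_gt(contrast_margin(pre, b[i, ]), 0)
        if (contrast_margin(img, b[i, ]) > 0) speckled_ok <- speckled_ok + 1L
      }
    }
  }
  # on the observable image multiplicative speckle can occasionally
  # outshine a small lesion; the contrast must still hold almost always
  expect_gte(speckled_ok / n_lesions, 0.97)
})

test_that("base anatomy is an exact mirror when the inter-side offset is zero", {
  p <- generate_pair(phantom_params(side_offset_sd = 0, n_lesions = 0,
                                    n_distractors = 0, seed = 3))
  expect_equal(p$right_base, p$left_base[, ncol(p$left_base):1])
  # speckled images themselves are independent realisations
  expect_false(isTRUE(all.equal(p$right_image,
                                p$left_image[, ncol(p$left_image):1])))
})

test_that("generate_dataset partitions pairs by patient and honours counts", {
  params <- phantom_params(n_lesions = 1, n_distractors = 0, seed = 9)
  ds <- generate_dataset(10, 2, params)
  expect_length(ds, 20)
  expect_length(unique(vapply(ds, function(p) p$patient_id, "")), 10)
  expect_length(unique(vapply(ds, function(p) p$pair_id, "")), 20)
  # uneven per-patient counts (the clinical 559-pairs-from-86-patients
  # layout is this same mechanism at larger counts)
  ds2 <- generate_dataset(3, c(3, 1, 2), params)
  expect_length(ds2, 6)
  tab <- table(vapply(ds2, function(p) p$patient_id, ""))
  expect_equal(as.integer(tab[order(names(tab))]), c(3, 1, 2))
})

test_that("impossible lesion placement raises an explicit error", {
  cramped <- phantom_params(n_lesions = 5, n_distractors = 0,
                            lesion_axes_range = c(60, 64), seed = 30)
  expect_error(generate_pair(cramped), "retries")
})

test_that("a five-lesion pair carries five boxes across the two sides", {
  p <- generate_pair(phantom_params(n_lesions = 5, n_distractors = 0,
                                    seed = 21))
  expect_equal(nrow(p$left_boxes) + nrow(p$right_boxes), 5)
})

test_that("lesion_mask covers exactly the box interiors", {
  p <- generate_pair(phantom_params(n_lesions = 0, n_distractors = 0, seed = 5))
  expect_equal(sum(lesion_mask(p, "left")), 0)
  # integer-coordinate boxes: mask area equals the summed box areas
  p$left_boxes <- boxes(x = c(10, 100), y = c(20, 150), w = c(30, 12),
                        h = c(14, 40))
  expect_equal(sum(lesion_mask(p, "left")), 30 * 14 + 12 * 40)
})
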