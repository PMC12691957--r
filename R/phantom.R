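# Bilateral speckle-phantom simulator.
#
# The generator emulates the statistical structure that the symmetry-aware
# cascade relies on: a smooth anatomical background shared (mirrored) between
# the two sides of a bilateral acquisition, striated hyperechoic bands over
# hypoechoic muscle, fully developed multiplicative speckle that is
# *independent* per side, a small random inter-side translation standing in
# for probe-placement differences, and focal hypoechoic lesions with
# interrupted striation placed on exactly one side. Optional bilateral
# "distractors" are hypoechoic look-alikes stamped at mirrored positions on
# BOTH sides and excluded from the ground truth; they exist to give the
# similarity filter genuine true negatives.

#' Phantom generator parameters
#'
#' @param image_size Integer vector `c(H, W)` in pixels; at least 256 x 256.
#' @param n_lesions Number of unilateral lesions per pair (0 to 5).
#' @param lesion_axes_range Range `c(min, max)` of ellipse semi-axes (px).
#' @param lesion_contrast Fraction in (0, 1) by which lesion interior
#'   intensity is reduced relative to the surrounding tissue.
#' @param side_offset_sd Standard deviation (px) of the random integer
#'   translation between the two sides' shared anatomy.
#' @param striation_period Vertical period (px) of the hyperechoic bands.
#' @param speckle_scale Gaussian correlation length (px) of the speckle.
#' @param n_distractors Number of *bilateral* hypoechoic look-alike pairs
#'   (present at mirrored positions on both sides, excluded from ground
#'   truth).
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @returns An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(256, 256),
                           n_lesions = 2,
                           lesion_axes_range = c(10, 24),
                           lesion_contrast = 0.45,
                           side_offset_sd = 4,
                           striation_period = 12,
                           speckle_scale = 2.5,
                           n_distractors = 2,
                           seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  stopifnot(length(image_size) == 2L)
  if (any(image_size < 256)) abort("image_size must be at least 256 x 256.")
  if (n_lesions < 0 || n_lesions > 5) {
    abort("n_lesions must be between 0 and 5.")
  }
  if (lesion_contrast <= 0 || lesion_contrast >= 1) {
    abort("lesion_contrast must lie strictly in (0, 1).")
  }
  structure(list(image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 lesion_axes_range = as.numeric(lesion_axes_range),
                 lesion_contrast = lesion_contrast,
                 side_offset_sd = side_offset_sd,
                 striation_period = striation_period,
                 speckle_scale = speckle_scale,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Dense row-normalised Gaussian smoothing matrix with reflected boundary.
gauss_smooth_operator <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k / rowSums(k)
}

gauss_smooth <- function(m, sigma) {
  ar <- gauss_smooth_operator(nrow(m), sigma)
  ac <- gauss_smooth_operator(ncol(m), sigma)
  ar %*% m %*% t(ac)
}

# Integer translation with edge replication.
translate_matrix <- function(m, dx, dy) {
  rows <- clamp(seq_len(nrow(m)) - dy, 1, nrow(m))
  cols <- clamp(seq_len(ncol(m)) - dx, 1, ncol(m))
  m[rows, cols, drop = FALSE]
}

# Soft interior mask of a rotated ellipse; ~1 inside, 0 outside, smooth
# transition over about 2 px at the boundary.
ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  xs <- matrix(seq_len(w) - 0.5 - cx, nrow = h, ncol = w, byrow = TRUE)
  ys <- matrix(seq_len(h) - 0.5 - cy, nrow = h, ncol = w)
  u <- (xs * cos(theta) + ys * sin(theta)) / a
  v <- (-xs * sin(theta) + ys * cos(theta)) / b
  r <- sqrt(u^2 + v^2)
  edge <- 2 / min(a, b)
  clamp((1 - r) / edge + 0.5, 0, 1)
}

# Axis-aligned bounding half-extents of a rotated ellipse.
ellipse_extent <- function(a, b, theta) {
  c(sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

# Rayleigh-like speckle field: envelope of low-pass-filtered complex Gaussian
# noise, normalised to unit mean.
speckle_field <- function(h, w, scale) {
  re <- gauss_smooth(matrix(rnorm(h * w), h, w), scale)
  im <- gauss_smooth(matrix(rnorm(h * w), h, w), scale)
  env <- sqrt(re^2 + im^2)
  env / mean(env)
}

place_ellipse <- function(h, w, axes_range, existing, max_tries = 100) {
  margin <- 8
  for (k in seq_len(max_tries)) {
    a <- runif(1, axes_range[1], axes_range[2])
    b <- runif(1, axes_range[1], axes_range[2])
    theta <- runif(1, 0, pi)
    ext <- ellipse_extent(a, b, theta)
    if (2 * ext[1] + 2 * margin >= w || 2 * ext[2] + 2 * margin >= h) next
    cx <- runif(1, ext[1] + margin, w - ext[1] - margin)
    cy <- runif(1, ext[2] + margin, h - ext[2] - margin)
    bb <- boxes(cx - ext[1], cy - ext[2], 2 * ext[1], 2 * ext[2])
    if (nrow(existing) > 0 && any(iou(bb, existing) > 0)) next
    return(list(cx = cx, cy = cy, a = a, b = b, theta = theta, box = bb))
  }
  abort("Could not place a lesion after bounded retries; reduce n_lesions or lesion size.")
}

#' Generate one synthetic bilateral ultrasound-like image pair
#'
#' The right side's base anatomy is the horizontal mirror of the left side's,
#' shifted by a random integer translation (probe-placement jitter), and each
#' side receives independent speckle. Lesions are hypoechoic ellipses with
#' locally interrupted striation, each placed on exactly one randomly chosen
#' side; their tight axis-aligned bounding boxes form the ground truth.
#' Bilateral distractors (if requested) appear at mirrored positions on both
#' sides and are *not* in the ground truth.
#'
#' @param params A [phantom_params()] object.
#' @param patient_id,pair_id Identifiers stored on the pair.
#' @returns An object of class `bilateral_pair`: a list with `left_image`,
#'   `right_image` (matrices in \[0, 1\]), `left_boxes`, `right_boxes`
#'   (box tibbles), `left_base`, `right_base` (the pre-speckle, pre-lesion
#'   anatomy fields), `left_pre`, `right_pre` (pre-speckle with lesions
#'   applied; both intermediates are kept for inspection and testing),
#'   `distractor_boxes`, `patient_id` and `pair_id`.
#' @export
generate_pair <- function(params, patient_id = "P001", pair_id = "S001") {
  stopifnot(inherits(params, "phantom_params"))
  withr::with_seed(params$seed, generate_pair_impl(params, patient_id, pair_id))
}

generate_pair_impl <- function(params, patient_id, pair_id) {
  h <- params$image_size[1]; w <- params$image_size[2]

  # Shared smooth anatomy + wavy striation bands (left-side frame).
  g <- gauss_smooth(matrix(rnorm(h * w), h, w), w / 12)
  g <- g / max(abs(g))
  anat_l <- 0.45 + 0.12 * g
  warp <- 6 * g
  rows <- matrix(seq_len(h), h, w)
  stri_l <- sin(2 * pi * (rows + warp) / params$striation_period)

  # Mirror + integer translation for the right side.
  dx <- as.integer(round(rnorm(1, 0, params$side_offset_sd)))
  dy <- as.integer(round(rnorm(1, 0, params$side_offset_sd)))
  anat_r <- translate_matrix(anat_l[, w:1, drop = FALSE], dx, dy)
  stri_r <- translate_matrix(stri_l[, w:1, drop = FALSE], dx, dy)

  base_l <- clamp(anat_l + 0.15 * stri_l, 0.02, 0.98)
  base_r <- clamp(anat_r + 0.15 * stri_r, 0.02, 0.98)

  # Lesions: hypoechoic, striation-interrupting, one side each.
  dark_l <- matrix(0, h, w); dark_r <- matrix(0, h, w)
  gt <- list(left = empty_boxes(), right = empty_boxes())
  for (i in seq_len(params$n_lesions)) {
    side <- if (runif(1) < 0.5) "left" else "right"
    existing <- dplyr::bind_rows(gt$left, gt$right)
    les <- place_ellipse(h, w, params$lesion_axes_range, existing)
    m <- ellipse_mask(h, w, les$cx, les$cy, les$a, les$b, les$theta)
    if (side == "left") dark_l <- pmax(dark_l, m) else dark_r <- pmax(dark_r, m)
    gt[[side]] <- dplyr::bind_rows(gt[[side]], les$box)
  }

  # Bilateral distractors: same hypoechoic stamp at mirrored positions.
  distr <- empty_boxes()
  for (i in seq_len(params$n_distractors)) {
    # Keep distractors clear of GT lesions in both frames (the right-side
    # stamp sits at the mirrored, shifted position).
    gt_right_in_left <- gt$right
    if (nrow(gt_right_in_left) > 0) {
      gt_right_in_left$x <- w - gt_right_in_left$x - gt_right_in_left$w
    }
    existing <- dplyr::bind_rows(gt$left, gt_right_in_left, distr)
    d <- place_ellipse(h, w, params$lesion_axes_range, existing)
    m_l <- ellipse_mask(h, w, d$cx, d$cy, d$a, d$b, d$theta)
    m_r <- translate_matrix(m_l[, w:1, drop = FALSE], dx, dy)
    dark_l <- pmax(dark_l, m_l)
    dark_r <- pmax(dark_r, m_r)
    distr <- dplyr::bind_rows(distr, d$box)
  }

  ct <- params$lesion_contrast
  pre_l <- clamp(anat_l * (1 - ct * dark_l) + 0.15 * stri_l * (1 - dark_l), 0.02, 0.98)
  pre_r <- clamp(anat_r * (1 - ct * dark_r) + 0.15 * stri_r * (1 - dark_r), 0.02, 0.98)

  img_l <- clamp(pre_l * speckle_field(h, w, params$speckle_scale), 0, 1)
  img_r <- clamp(pre_r * speckle_field(h, w, params$speckle_scale), 0, 1)

  structure(list(left_image = img_l, right_image = img_r,
                 left_boxes = gt$left, right_boxes = gt$right,
                 left_base = base_l, right_base = base_r,
                 left_pre = pre_l, right_pre = pre_r,
                 distractor_boxes = distr,
                 patient_id = patient_id, pair_id = pair_id),
            class = "bilateral_pair")
}

#' @export
print.bilateral_pair <- function(x, ...) {
  cat(sprintf("<bilateral_pair %s/%s: %dx%d, %d left + %d right lesion box(es)>\n",
              x$patient_id, x$pair_id, nrow(x$left_image), ncol(x$left_image),
              nrow(x$left_boxes), nrow(x$right_boxes)))
  invisible(x)
}

pair_image <- function(pair, side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") pair$left_image else pair$right_image
}

pair_boxes <- function(pair, side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") pair$left_boxes else pair$right_boxes
}

other_side <- function(side) if (side == "left") "right" else "left"

#' Generate a multi-patient phantom dataset
#'
#' @param n_patients Number of patients (>= 1).
#' @param pairs_per_patient Either a single count or a vector of per-patient
#'   counts of length `n_patients`.
#' @param params A [phantom_params()] object; per-pair seeds are derived
#'   deterministically from `params$seed`.
#' @param dir Optional directory: when given, images and annotations are
#'   written there via [write_pair_dataset()].
#' @returns A list of `bilateral_pair` objects.
#' @export
generate_dataset <- function(n_patients, pairs_per_patient, params, dir = NULL) {
  stopifnot(n_patients >= 1)
  counts <- if (length(pairs_per_patient) == 1L) {
    rep(as.integer(pairs_per_patient), n_patients)
  } else {
    stopifnot(length(pairs_per_patient) == n_patients)
    as.integer(pairs_per_patient)
  }
  idx <- 0L
  out <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (s in seq_len(counts[p])) {
      idx <- idx + 1L
      pp <- params
      pp$seed <- as.integer((params$seed + 7919 * idx) %% .Machine$integer.max)
      out[[idx]] <- generate_pair(pp, patient_id = pid,
                                  pair_id = sprintf("%s_S%03d", pid, s))
    }
  }
  if (!is.null(dir)) write_pair_dataset(out, dir)
  out
}

#' Binary ground-truth mask of one side of a pair
#'
#' Union of the ground-truth box interiors, mainly for assertions and
#' visual checks.
#'
#' @param pair A `bilateral_pair`.
#' @param side `"left"` or `"right"`.
#' @returns A 0/1 matrix of the image size.
#' @export
lesion_mask <- function(pair, side = c("left", "right")) {
  side <- match.arg(side)
  img <- pair_image(pair, side)
  b <- pair_boxes(pair, side)
  m <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(b))) {
    rows <- max(1, floor(b$y[i]) + 1):min(nrow(img), ceiling(b$y[i] + b$h[i]))
    cols <- max(1, floor(b$x[i]) + 1):min(ncol(img), ceiling(b$x[i] + b$w[i]))
    m[rows, cols] <- 1
  }
  m
}
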