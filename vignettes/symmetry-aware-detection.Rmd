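---
title: "Symmetry-aware two-stage detection of muscle-strain lesions in bilateral ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-aware two-stage detection of muscle-strain lesions in bilateral ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Muscle-strain lesions appear in B-mode ultrasound as focal hypoechoic
(dark) regions that interrupt the striated, hyperechoic texture of healthy
muscle. Single-image detectors confuse many benign hypoechoic structures
with lesions, because locally the texture cue is genuinely ambiguous.
Clinicians resolve this ambiguity by comparing the suspicious region with
the *same anatomical location on the contralateral side*: bilateral
anatomy is approximately mirror-symmetric, so a pattern present on both
sides is anatomy, while a unilateral pattern is suspicious.

`sonosym` implements that reading strategy as a two-stage cascade:

1. **Proposal.** A single-class, anchor-based detector scores candidate
   boxes on each side image independently. Each of its three heads (at
   strides 8, 16 and 32) predicts, per spatial location and per anchor,
   4 box coordinates, 1 objectness score and 1 lesion-vs-background logit
   — 18 channels per head for the default 3 anchors.
2. **Routing.** Detections with confidence below `T1` (default 0.01) are
   suppressed; detections at or above `T2` (default 0.20) are accepted
   outright; the band `[T1, T2)` is forwarded for verification. The
   interval conventions are exactly half-open: `>= T2` accepts, `< T1`
   suppresses.
3. **Verification.** For each forwarded box, four contralateral reference
   patches (128 px square) are cropped: the exact mirror of the box centre
   and three jittered mirrors at distinct non-zero offsets from
   `{-32, 0, +32}^2`. A Siamese-style similarity network (S-CNN) scores
   each index/reference pair with a tanh output in `[-1, 1]`
   (`-1` = similar, `+1` = dissimilar). Under the default
   `best_reference` aggregation the HOG-closest reference decides: the
   localisation step selects a single reference box and the filter judges
   whether the candidate resembles it. A genuine lesion should not
   resemble its contralateral reference; a bilateral look-alike does and
   is treated as anatomy.
4. **Merge.** Final output per side is the union of directly accepted and
   verified detections. The cascade never invents boxes and never returns
   suppressed ones.

Reference localisation between the mirror and its jitters uses
Histogram-of-Oriented-Gradients matching (cell 8x8, block 2x2 cells,
9 unsigned orientation bins, L2-Hys block normalisation): the candidate
patch's descriptor is compared with each reference candidate's and the
closest wins, ties going to the exact mirror. HOG is deterministic, cheap,
and robust to speckle, which is why it is preferred over keypoint methods
here.

### Orientation convention

All reference patches are flipped back into the index side's orientation
before any comparison (HOG or S-CNN). Under a mirrored acquisition this is
what makes "the same anatomical position" comparable pixel-by-pixel: with
an exactly flipped copy as the contralateral image, the exact-mirror
reference has HOG distance zero, and homologous structures land at the
same within-patch coordinates in both channels of the S-CNN input. The
`identity` mirror mode (for pre-registered sides) skips both the
reflection of coordinates and the flip-back.

## The phantom generator

The clinical images behind the method are not redistributable, so the
package ships a bilateral speckle-phantom simulator that reproduces the
statistical structure the cascade exploits, with known ground truth:

* a smooth anatomy field plus wavy horizontal striation bands (period 12
  px by default), shared between sides;
* the right side is the horizontal mirror of the left, translated by a
  random integer offset (`side_offset_sd = 4` px) emulating differing
  probe entry points;
* fully developed speckle: each side is multiplied by an *independent*
  Rayleigh-like envelope (low-pass-filtered complex Gaussian noise,
  correlation length 2.5 px), the standard B-mode speckle surrogate;
* lesions: `n_lesions = 2` per pair by default, each a hypoechoic
  rotated ellipse (semi-axes 10-24 px, interior intensity reduced by
  `lesion_contrast = 0.45`) that also interrupts the striation locally,
  placed on exactly one randomly chosen side; tight bounding boxes form
  the ground truth;
* bilateral distractors: `n_distractors = 2` look-alike hypoechoic
  ellipses stamped at mirrored positions on *both* sides and excluded
  from the ground truth. These are what make the task honest: the
  detector fires on them, and only contralateral comparison can reject
  them.

Defaults were chosen once as plausible desk-scale analogues of clinical
appearance (lesion sizes of a few tens of pixels in a 256 px field,
moderate contrast, a few pixels of inter-side misregistration); they are
not claims about any clinical dataset, which reports no quantitative
lesion-appearance statistics to copy. What the phantom does *not* model:
wave propagation, attenuation, anisotropy artifacts, depth-dependent
resolution, or operator variability. Passing on phantoms therefore
demonstrates that the pipeline mechanics work under the assumed symmetry
statistics — not clinical performance.

```{r phantom-example}
library(sonosym)
pair <- generate_pair(phantom_params(seed = 1))
plot_pair(pair)
```

## Networks and training at desk scale

Both networks are trained with the package's own compact CNN engine
(im2col convolutions via BLAS, hand-derived backprop, Adam). Everything is
deterministic given the seed, and everything runs on one CPU.

**Detector.** A small strided conv backbone (12-20-32 channels to stride
8, one residual block, then 40 and 48 channels to strides 16/32) with a
3x3 conv head per level. Anchors default to k-means over the training
boxes (3 per level, assigned to levels by area). Boxes are encoded
YOLO-style (sigmoid centre offsets within the cell, log size ratios to
the anchor); the box loss is mean-squared error in that encoded space —
chosen over IoU-family losses for its simple exact gradients — and
objectness *and* the class logit are supervised densely with binary
cross-entropy (positives weighted 5x). Supervising the class channel on
background matters: the decoded confidence is
`sigmoid(obj) * sigmoid(cls)`, and an untrained class channel drifts and
inflates background confidences past `T1`. Training uses Adam at 1e-3
with a 5x step decay over the last third of the epochs; the desk-scale
profile is 256 px input, 30 pairs (60 images), 60 epochs. The 544 px
input of the faithful configuration is retained in
`detector_config(input_size = 544)`.

**Similarity filter.** Input is the index and reference patch stacked
along channels (2 channels; the optional `grayhog_pair` mode appends each
patch's HOG energy map for 4). Each channel is pooled 2x and standardised
to zero mean / unit variance before the first convolution — the
comparison should depend on spatial structure, not absolute echo level,
and the pooling averages out part of the speckle. The backbone is a
compact pre-activation residual net (12-24-32 channels over four stride-2
stages); the head mixes global mean pooling with global max pooling
(half the channels each) because a genuine contralateral mismatch is
*localised* and pure averaging dilutes it; a dense layer plus tanh yields
the score. Training minimises mean-squared error against the +/-1 labels
with the augmentations applied per sample: +/-5 deg rotation, 0.9-1.1
scaling, +/-10% intensity gain, Gaussian noise (sigma 0.01-0.02) and a
random index/reference channel swap with probability 0.5 (the similarity
relation is symmetric; the swap teaches the network that). Epochs are
class-balanced by resampling, since mined sets are heavily
similar-dominated.

Two stabilisers address the variance of training such a small network on
a few hundred pairs: the final model is either the epoch snapshot with
the best worst-class validation accuracy or the tail weight average over
the low-learning-rate phase, whichever validates better; and the decision
threshold actually used by the cascade is calibrated on the validation
scores (maximising worst-class accuracy) rather than fixed at the tanh
sign. The sign rule (threshold 0, with the boundary going to dissimilar
to preserve recall) remains the `classify()` default; the calibrated
value is returned as `fit$decision_threshold` and is analogous to
operating-point selection on a development set.

**Mining.** Training pairs come from a coarse 64 px sliding window over
each side (3x3 windows on a 256 px image with 128 px patches), plus one
anchored window at each ground-truth box centre — the configuration the
verifier actually sees at inference. Because a 256 px pair yields only
about ten usable windows, the filter mines from the detector's training
pairs plus additional mining-only phantoms from disjoint patients
(roughly 500 labelled pairs in the shipped configuration). A window whose centre lies in a
ground-truth box while its HOG-refined reference touches none is
dissimilar (+1); a window touching no ground truth on either side is
similar (-1); bilateral or grazing contacts are discarded as ambiguous.
These labelling rules are the package's construction; mining itself, the
window stride, the patch size and the jitter magnitudes follow the
method's stated procedure.

## Evaluation protocol

* **Matching:** greedy one-to-one by descending confidence at IoU >= 0.5
  (threshold configurable; the matching rule is a standard choice, fixed
  and documented here because published reports rarely state one).
* **Metrics:** precision, recall, F1, F2 (`beta = 2` puts four times the
  weight on recall, matching the clinical emphasis on sensitivity);
  precision of an empty prediction set is defined as 0 with a warning.
* **mAP:** all-point-interpolated average precision over pooled ranked
  detections; with one class mAP = AP.
* **Splits:** always at patient level; bilateral pairs never separate;
  an a-priori hold-out is removed before the seeded k-fold shuffle, and
  within folds patients are flagged ~80/20 train/validation.
* **Uncertainty:** patient-level stratified bootstrap (resampling
  lesion-positive and lesion-negative patients separately, recomputing
  the metric from pooled counts, percentile intervals; undefined
  resamples are redrawn and logged).
* **Reader agreement:** Cohen's kappa for two raters and Fleiss' kappa
  for panels, implemented from the standard formulas (no agreement
  package ships in the dependency set) and oracle-tested.
* **Operating-point sweeps:** `threshold_sweep()` re-thresholds stored
  detections over a T1 grid at fixed T2, with and without the
  verification stage, without re-running any model.

## Numerical choices and degenerate inputs

* HOG uses centred differences without pre-smoothing, orientations folded
  to [0, 180), trilinear soft binning, and blocks scanned row-major;
  zero-gradient blocks stay exactly zero rather than being normalised.
  Out-of-cell-range spatial votes are dropped. The per-pixel "HOG map" is
  defined as per-cell gradient energy after block normalisation, averaged
  over containing blocks and upsampled nearest-neighbour — one of several
  defensible readings of a gradient-energy channel; it is switchable off
  (`gray_pair`) and on (`grayhog_pair`).
* Patch crops pad out-of-image areas by symmetric reflection; mined
  patches are checked NaN-free.
* Box coordinates are 0-based with half-open extents; `encode_box()`
  clamps cell offsets to (1e-4, 1 - 1e-4) so the logit transform stays
  finite, and decoded log-sizes are clamped to +/-6.
* Ties in reference matching go to the exact mirror (candidate order);
  ties at the similarity threshold go to dissimilar (recall-preserving).
* `nms()` assumes confidence-sorted input and is idempotent.
* k-means anchor fitting falls back to fixed stride-scaled defaults when
  fewer boxes than clusters exist.

## Design choices where the design was open

* **Aggregation of the four reference scores** (`best_reference`,
  default): the method's reference-localisation step selects a single
  reference box (the HOG-closest of the mirror and its jitters), and the
  filter is trained on exactly such HOG-refined pairs, so scoring only
  that reference keeps inference on the training distribution. Requiring
  unanimity over the three *misaligned* jitter patches as well
  (`all_dissimilar`) is stricter and buys precision at a substantial
  recall cost; `majority` (3 of 4) sits between. All three are
  implemented because published descriptions of such cascades rarely pin
  down how multiple candidate comparisons combine.
* **Two-channel composition**: the channel dimension of 2 is read as
  (index patch, reference patch) — the channel-swap augmentation only
  makes sense in that reading — while the alternative reading
  (gray + HOG map per patch) is preserved as the 4-channel
  `grayhog_pair` mode. Neither is asserted as the original
  configuration.
* **Hemifield** is taken to be one side image of the pair, since sides
  are stored as separate images under the bilateral protocol.
* **Feature-box expansion** defaults to growing a detection to the patch
  size (at least 8 px of context); the original margins are not given
  numerically.
* **Backbone simplification**: the proposal stage is explicitly
  detector-agnostic, so a compact backbone replaces the full CSP
  architecture; the head geometry (strides, anchors, 18 channels) is kept
  exact. Mosaic-style augmentation and pretrained weights are out of
  scope.

## Problem sizes

The shipped tests and the acceptance script use: 256 x 256 phantoms;
30 training pairs (60 images) and 60 detector epochs; pair mining from
54 pairs (the 30 training pairs plus 24 mining-only pairs, giving about
500 labelled patch pairs, of which roughly 28% are dissimilar); a
2-member filter ensemble at 25 epochs per member; and 30 held-out test
pairs from disjoint patients. These sizes were chosen so a full from-scratch run completes
comfortably on a single CPU while leaving the learning problems
non-trivial; the faithful configuration (544 px input, 1000 filter
epochs, hundreds of clinical pairs) remains expressible through the same
configs.

## Known limitations

* Phantom realism is deliberately limited (no attenuation, anisotropy or
  acoustic shadowing); conclusions transfer to the algorithmics, not to
  clinical accuracy.
* The similarity filter's accuracy on phantoms (roughly three quarters of
  dissimilar patterns recognised at the calibrated threshold) is limited
  by the speckle statistics of the generator, and small validation sets
  make per-class accuracies noisy.
* The detector is calibrated only implicitly (dense BCE); its confidences
  are comparable across images but are not probabilities; probabilistic
  fusion of detector and similarity scores is explicitly out of scope.
* `bootstrap_ci()` resamples patients, not pairs; with very few patients
  the percentile interval can degenerate.
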