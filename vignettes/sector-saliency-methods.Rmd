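---
title: "Evaluating CNN saliency maps on optic-disc sectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating CNN saliency maps on optic-disc sectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Convolutional classifiers of optic-nerve-head photographs can detect
glaucoma well, but they are black boxes. Pixel-attribution ("saliency")
methods promise an explanation: a per-pixel relevance field for the class
the model predicts. Whether such maps are *clinically interpretable* is a
different question. Glaucoma has an anatomical reading — the neuroretinal
rim thins sector by sector, earliest in the temporal-inferior and
temporal-superior regions — so a natural evaluation is to project each
saliency map onto the standard angular sectors of the optic disc and ask,
across a whole test set, *which sectors the model's explanations actually
point at*, and whether the attribution methods themselves survive basic
sanity checks.

This package implements that evaluation end to end at desk scale: a
synthetic fundus generator with a known discriminative signal, a small
fully inspectable CNN satisfying the differentiable-model contract that
the attribution methods require, nine attribution algorithms, the sector
discretization metric, a global sector-relevance probability, Spearman
agreement analyses, and the two randomization sanity checks.

## The discretization metric

Given an image $I$, a model $f$ and a saliency map $S = S_I^f(p)$ over
pixels $p$, the map is first binarized by thresholding at a fraction
$\tau$ of its maximum:

$$M_{sal}(p) = \mathbf{1}\left[S(p) \ge \tau \cdot \max_p S(p)\right],
\qquad \tau = 0.75,$$

and then converted to a seven-component sector score

$$S_d(sec) = \frac{|M_{sec} \cap M_{sal}|}{|M_{sal}|},
\qquad sec \in \{N, NI, TI, T, TS, NS, B\},$$

where $M_{sec}$ are binary sector masks that partition the image: the six
anatomical disc sectors plus the background $B$ (everything outside the
disc). Because the masks partition the image the scores sum to 1, and
because the threshold is relative the scores are invariant to positive
rescaling of the map. The maximizing pixel is always retained, so
$|M_{sal}| > 0$; a constant map triggers a warning and retains every
pixel (the thresholding rule admits this degenerate case). All
correlation and relevance analyses operate on these 7-vectors, not on raw
pixels: per collection of $n$ images the analysis vector has $7n$
elements (e.g. 1036 for a 148-image test set).

## Sector geometry

Angular spans are measured from the temporal horizontal axis of the disc,
increasing toward superior, and follow the standard clinical
sectorization of the optic nerve head: temporal 90° ([315°, 45°)),
temporal superior 40°, nasal superior 40°, nasal 110°, nasal inferior
40°, temporal inferior 40°. An equal-width 60° tiling is available as an
alternative (`sector_scheme(style = "equal")`). Spans are half-open so
the tiling is pixel-exact. Each disc pixel is assigned by the angle of
its raster offset to the disc-ellipse center, with no ellipse-axis
normalization — the generated discs are near-circular, and this is the
simplest reproducible convention.

Laterality matters: for a left eye (OS) the sector layout is the
horizontal mirror of the right eye (OD). The implementation computes the
angle in an anatomical frame whose temporal axis flips with laterality,
which makes the mirroring property an identity rather than a special
case; the tests verify that OS masks equal mirrored OD masks exactly.
Which image side is temporal for OD is a single configuration shared by
the generator and the mask builder (`temporal_side_od`, default
`"left"`), so the metric is self-consistent whichever anatomical
convention is preferred. Sector wedges span the whole disc including the
cup by default; a rim-only variant (`rim_only = TRUE`) restricts the six
sectors to the disc-minus-cup annulus and assigns cup pixels to the
background so the seven masks still partition the image.

## The synthetic data generator

The study conditions are fixed by `generator_config()` defaults, chosen
once on domain grounds:

| parameter | default | rationale |
|---|---|---|
| `image_size` | 32 px | disc-centered crop at desk scale |
| `disc_radius_range` | 10–13 px | disc fills most of the crop, as in disc-centered photography |
| `healthy_cdr_range` | (0.25, 0.45) | clinically typical healthy cup-to-disc ratios |
| `glaucoma_cdr_range` | (0.60, 0.80) | CDR above 0.6 is the classic glaucoma sign |
| `texture_noise_sd` | 0.03 | visible low-frequency background texture |
| `vessel_count` | 4 | dark curvilinear distractors |
| `laterality_probability` | 0.5 | equal mix of right and left eyes |

Images preserve the intensity ordering that drives real disc photography
(cup brightest, then disc rim, then the orange-red background). The
discriminative structure is parametric and known: with disjoint CDR
ranges, a threshold on the measured CDR separates the classes perfectly,
so a trained classifier has a recoverable signal to use. Sector-localized
rim loss is modelled by displacing the glaucomatous cup center toward the
configured sector's mid-angle by `rim_loss_strength` times the rim width
(disc minus cup semi-axis); this plants a spatially localized class
difference whose recovery by the attribution pipeline can be tested. The
cup mask is clipped to the disc, so containment holds pixel-exactly by
construction.

What the generator does *not* emulate: vessel trees with realistic
branching, peripapillary atrophy, illumination gradients, camera noise,
and the sheer variability of real retinographs. Passing tests on this
data show that the *pipeline* is correct and that the metric recovers
planted signals; they say nothing about how informative saliency maps
are on clinical images.

## The toy classifier

No deep-learning framework is part of this package's dependency stack;
instead the package ships a compact CNN written directly in R (im2col
convolutions evaluated as BLAS matrix products, explicit backward pass):
two 3×3 same-padding convolutions with ReLU, a 2×2 average pool between
them, global average pooling and a two-unit dense head. This is the
smallest architecture that satisfies the full model contract the
attribution methods need — input gradients (plain and guided-ReLU),
activations and gradients at a designated convolutional (CAM) layer,
deterministic inference, and seeded reinitialization — and every
intermediate quantity is inspectable, which makes the oracle tests
(naive loop-based chain rule, finite differences) possible.

Training uses mini-batch Adam on the cross-entropy (defaults: learning
rate 3e-3, 30 epochs, batch 16). Inputs are centered by subtracting 0.5
inside the forward pass: with positive-only intensities the first-layer
weight gradients are strongly correlated and optimization is poorly
conditioned; the constant shift fixes that without changing input
gradients. These defaults converge to near-perfect training balanced
accuracy across initialization seeds at the 200-image scale; larger
learning rates occasionally kill every ReLU in the CAM layer early in
training (a dying-ReLU collapse), which is why the default is
conservative.

## The nine attribution methods

All methods explain the model's **predicted** class for the image at
hand (correct or not) and return a single-channel map aligned to the
input. Where a method differentiates the model, the default score is the
pre-softmax logit (`score_view = "logit"`), avoiding vanishing gradients
at saturated softmax outputs; the probability view is available. The
3-channel gradient or attribution is collapsed to one channel last;
the default reduction is the maximum of absolute values across channels
(`max_abs`), with `mean_abs` and `sum_then_abs` as alternatives covering
the signed-versus-absolute ambiguity inherent in gradient maps.

- **Grad** — raw input gradient.
- **GBack** — guided backpropagation: negative upstream gradients are
  zeroed at every ReLU.
- **SGrad / SGrad2 / VGrad** — SmoothGrad family: N = 25 noisy
  replicates with Gaussian noise of sd 0.15 × the input dynamic range
  (the method's original recommendation); mean, mean-of-squares, or
  variance aggregation, per channel, before reduction. The population
  variance is used, so a single replicate gives an identically zero
  VGrad map (with a warning). With zero noise SGrad reproduces Grad bit
  for bit (the aggregation short-circuits, avoiding the (N·G)/N
  round-off).
- **IGrad** — integrated gradients with a black baseline and 50 steps by
  default (white and uniform-random baselines available); a midpoint
  Riemann sum is used, and the signed per-channel attributions are kept
  so the completeness identity (attributions summing to the score
  difference from the baseline) can be verified — it holds within 1% at
  256 steps on the toy model.
- **Occl** — occlusion: a uniform square (side ⌈min(H, W)/14⌉, stride
  half the side, filled with the per-image mean intensity by default) is
  slid over the image; a final anchor is appended when the stride does
  not reach the border, so every pixel is covered. Each pixel's saliency
  is the mean score drop over the windows covering it. Values can be
  negative (occlusion can raise the score); the thresholding step always
  retains the argmax pixel, which keeps the discretization well defined
  even for all-negative maps.
- **GCam** — GradCAM at the last convolutional layer: channel weights
  are spatial means of the class-score gradients at that layer, the map
  is the ReLU of the weighted activation sum. Computed at native
  resolution (16×16 for the default architecture), retained in
  `$native`, and upsampled bilinearly (configurable to nearest) for the
  pixel-aligned discretization.
- **SCam** — ScoreCAM: gradient-free; each activation map is min-max
  normalized, upsampled, used to modulate the input, and the explained
  class's logit of that masked input is the channel weight (raw logits,
  no softmax over channels — the simplest reading of score-as-weight).
  Constant activation channels are skipped with a warning.

## Agreement analyses and sanity checks

Agreement between two collections of discrete maps over the same image
list is Spearman's rank correlation of their flattened score vectors
(average ranks for ties; two-sided p-value from the large-sample t
approximation, with no multiple-testing correction — raw correlations
are reported). `pairwise_agreement()` enumerates unordered pairs within
a group: methods within a model, folds within an architecture, or
architectures within a fold.

Two sanity checks give the baseline for what "low" correlation means:

- **Parameter randomization** — compare the trained model's discrete
  maps with those of freshly reinitialized copies (default 5
  replicates, one fresh initialization each, seed-exposed). High
  agreement means the method ignores the learned parameters.
- **Label randomization** — retrain with 50% of the training labels
  flipped and compare with the cleanly trained model. A method whose
  median absolute correlation reaches the discard threshold (default
  0.5, configurable) is flagged for exclusion; flagged methods (GBack
  and SCam in the motivating study) are excluded from the default
  agreement and relevance method lists in the pipeline, overridably.

The global relevance metric is the probability, over a test set, that a
sector holds the top discrete score, grouped by the model's *predicted*
class (not the true label), with a pooled "both" row; ties are broken by
the canonical sector order (N, NI, TI, T, TS, NS, B), a measure-zero
event for float scores but necessary for determinism. When pooling
across folds each image is weighted equally.

## Numerical choices and degenerate inputs

- Pixel centers at integer (row, col) coordinates, origin top-left;
  half-open angular arcs make the sector tiling exact.
- Tie-breaking: `which.max` order = canonical sector order.
- Thresholding a constant map retains every pixel, with a warning.
- An empty saliency mask cannot arise from the thresholding rule (the
  argmax is always retained) and is guarded with an error for custom
  masks.
- Spearman on a constant vector is undefined and reported as `NA` with
  a warning rather than silently zero.
- The generator rejects overlapping CDR ranges unless a rim-loss sector
  provides the class signal; training rejects single-class inputs and
  architectures whose input is not even-sized (the pooling stage).
- All stochastic components (generator, training shuffles and
  initialization, SmoothGrad noise, random baselines, splits, label
  flips, reinitialization) consume explicit seeds; every operation is a
  pure function of its inputs and seed.

## Problem sizes

The package's own analyses and tests run at deliberately small scale,
chosen as the smallest sizes at which the studied effects are visible:
32×32 images, 200 training images (100 per class), 150-image test sets
for the randomization analyses, 5 reinitialization replicates, and
5-seed replication for the planted-signal study. The pipeline's default
configuration (80 images, 9 methods, 3 sanity replicates) runs end to
end in a few minutes on one core.

For the planted-signal study (equal CDR ranges, rim loss toward the
temporal-inferior sector at strength 0.7 as the sole class difference)
the default training recipe underfits — the cup-displacement cue is
subtler than a CDR gap — so that study trains with 12 filters per layer
for 60 epochs, a choice made on training-convergence grounds alone
(balanced accuracy 0.7–0.96 across seeds). With a model that has
actually learned the displacement, the occlusion-method relevance table
concentrates the glaucoma-predicted mass on the temporal-inferior and
neighbouring sectors, recovering the planted signal.

## Known limitations

- The toy CNN is not a VGG/ResNet-scale model; conclusions about *which*
  saliency methods agree on real fundus data do not transfer. What does
  transfer is the metric's machinery and its verified properties.
- At this scale the parameter-randomization baseline behaves differently
  for the two families of methods. Gradient-based maps (Grad, SGrad,
  SGrad2, VGrad, and largely IGrad) decorrelate from their trained
  counterparts under reinitialization, as they should. Occlusion and
  GradCAM do not decorrelate as strongly: on tiny disc-centered images
  the bright cup and disc dominate the forward response of *any*
  network, trained or not, so score-drop and activation-weighted maps of
  a random network concentrate on much the same sectors as the trained
  one. The randomization test still ranks methods sensibly, but its
  absolute correlation level is inflated by this image-driven structure
  and should be read relative to the desk-scale setting, not as a
  property of the methods on clinical-scale models.
- GradCAM at a GAP head has analytically constant channel weights per
  class (the dense weights), so on this architecture GCam is a fixed
  nonnegative combination of CAM activations; this is a property of the
  architecture, not of the implementation.
- The 8-bit PNG round trip quantizes intensities to 1/255; analyses that
  reload written datasets inherit that quantization.
- Sector geometry assumes a well-defined disc center; annotations given
  as masks use the mask centroid.
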