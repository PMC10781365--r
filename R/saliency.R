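#' Configuration shared by the attribution methods
#'
#' @param score_view `"logit"` (default, pre-softmax score of the explained
#'   class) or `"probability"` (softmax output). Logits avoid vanishing
#'   gradients when the softmax saturates.
#' @param channel_reduction How the 3-channel gradient/attribution is
#'   collapsed to one channel, applied last: `"max_abs"` (default),
#'   `"mean_abs"`, or `"sum_then_abs"`.
#' @param sg_samples Number of noisy replicates N for the SmoothGrad family.
#' @param sg_noise_sd Noise standard deviation as a fraction of the input
#'   dynamic range (max - min).
#' @param ig_baseline Integrated-gradients baseline: `"black"`, `"white"`,
#'   or `"uniform_random"`.
#' @param ig_steps Number of interpolation points of the Riemann sum.
#' @param occl_patch Occlusion square side in pixels; `NULL` means
#'   `ceiling(min(H, W) / 14)`.
#' @param occl_stride Occlusion stride; `NULL` means `ceiling(patch / 2)`.
#' @param occl_fill Fill intensity of the occluding square; `NULL` means the
#'   per-image mean intensity.
#' @param cam_upsampling `"bilinear"` (default) or `"nearest"`: how native
#'   CAM maps are brought to image resolution.
#' @param seed Integer seed for the stochastic methods (SmoothGrad noise,
#'   random IG baseline).
#' @return An object of class `saliency_config`.
#' @export
saliency_config <- function(score_view = c("logit", "probability"),
                            channel_reduction = c("max_abs", "mean_abs",
                                                  "sum_then_abs"),
                            sg_samples = 25L, sg_noise_sd = 0.15,
                            ig_baseline = c("black", "white",
                                            "uniform_random"),
                            ig_steps = 50L,
                            occl_patch = NULL, occl_stride = NULL,
                            occl_fill = NULL,
                            cam_upsampling = c("bilinear", "nearest"),
                            seed = 1L) {
  stopifnot(sg_samples >= 1, sg_noise_sd >= 0, ig_steps >= 1)
  structure(list(score_view = match.arg(score_view),
                 channel_reduction = match.arg(channel_reduction),
                 sg_samples = as.integer(sg_samples),
                 sg_noise_sd = sg_noise_sd,
                 ig_baseline = match.arg(ig_baseline),
                 ig_steps = as.integer(ig_steps),
                 occl_patch = occl_patch, occl_stride = occl_stride,
                 occl_fill = occl_fill,
                 cam_upsampling = match.arg(cam_upsampling),
                 seed = as.integer(seed)),
            class = "saliency_config")
}

#' Abbreviations of the nine attribution methods
#' @return Character vector: Grad, GBack, SGrad, SGrad2, VGrad, IGrad,
#'   Occl, GCam, SCam.
#' @export
saliency_methods <- function() {
  c("Grad", "GBack", "SGrad", "SGrad2", "VGrad", "IGrad", "Occl",
    "GCam", "SCam")
}

new_saliency_map <- function(values, method, target_class,
                             native = NULL, extra = list()) {
  if (!all(is.finite(values))) {
    stop("non-finite values in ", method, " saliency map", call. = FALSE)
  }
  out <- c(list(values = values, method = method,
                target_class = target_class,
                native_resolution = if (is.null(native)) dim(values) else
                  dim(native),
                native = native),
           extra)
  structure(out, class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency_map [%s] %dx%d, target class %s, range [%.3g, %.3g]\n",
              x$method, nrow(x$values), ncol(x$values),
              as.character(x$target_class), min(x$values), max(x$values)))
  invisible(x)
}

channel_reduce <- function(G, how) {
  switch(how,
         max_abs = pmax(abs(G[, , 1]), abs(G[, , 2]), abs(G[, , 3])),
         mean_abs = (abs(G[, , 1]) + abs(G[, , 2]) + abs(G[, , 3])) / 3,
         sum_then_abs = abs(G[, , 1] + G[, , 2] + G[, , 3]))
}

# The class every method explains: the model's inferred class for this
# image, whether correct or not.
explained_class <- function(model, img) {
  which.max(stats::predict(model, img, type = "logit")[1, ])
}

#' Gradient (Grad) saliency map
#'
#' Channel-reduced gradient of the selected class score with respect to the
#' input pixels.
#'
#' @param model A model adapter (see [toy_cnn()]).
#' @param image Image array or `fundus_sample`.
#' @param config A [saliency_config()].
#' @return A `saliency_map`.
#' @export
grad_map <- function(model, image, config = saliency_config()) {
  img <- as_image_array(image)
  cls <- explained_class(model, img)
  G <- input_gradient(model, img, cls, view = config$score_view)
  new_saliency_map(channel_reduce(G, config$channel_reduction), "Grad", cls)
}

#' Guided Backpropagation (GBack) saliency map
#'
#' As [grad_map()], but negative gradients are zeroed at every ReLU during
#' backpropagation, which suppresses noise in the map.
#'
#' @inheritParams grad_map
#' @return A `saliency_map`.
#' @export
guided_backprop_map <- function(model, image, config = saliency_config()) {
  if (!supports_guided(model)) {
    stop("model adapter does not support the guided ReLU override",
         call. = FALSE)
  }
  img <- as_image_array(image)
  cls <- explained_class(model, img)
  G <- input_gradient(model, img, cls, view = config$score_view,
                      guided = TRUE)
  new_saliency_map(channel_reduce(G, config$channel_reduction), "GBack", cls)
}

#' SmoothGrad family (SGrad, SGrad2, VGrad) saliency maps
#'
#' Adds Gaussian noise to the image, recomputes the gradient, and repeats N
#' times. `mode = "mean"` averages the gradients (SGrad), `"squared"`
#' averages the squared gradients (SGrad2), `"variance"` takes their
#' per-pixel variance (VGrad). Aggregation happens per channel, before the
#' channel reduction. With zero noise the mean mode equals the plain
#' gradient exactly.
#'
#' @inheritParams grad_map
#' @param mode `"mean"`, `"squared"` or `"variance"`.
#' @return A `saliency_map` with method SGrad, SGrad2 or VGrad.
#' @export
smoothgrad_map <- function(model, image, config = saliency_config(),
                           mode = c("mean", "squared", "variance")) {
  mode <- match.arg(mode)
  smoothgrad_family(model, image, config, mode)[[1]]
}

# Core of the SmoothGrad family: one seeded noise loop serves all requested
# modes, so computing the three variants together costs one loop while each
# map is bit-identical to its standalone computation (same seed, same
# draws).
smoothgrad_family <- function(model, image, config, modes) {
  img <- as_image_array(image)
  cls <- explained_class(model, img)
  N <- config$sg_samples
  d <- dim(img)
  method_of <- c(mean = "SGrad", squared = "SGrad2", variance = "VGrad")
  if ("variance" %in% modes && N == 1) {
    warning("VarGrad with a single sample is identically zero")
  }
  sd_abs <- config$sg_noise_sd * (max(img) - min(img))
  if (sd_abs == 0) {
    # all noise draws coincide with the input: aggregate in closed form so
    # the zero-noise limit reproduces the plain gradient bit for bit
    G <- input_gradient(model, img, cls, view = config$score_view)
    aggs <- list(mean = G, squared = G^2, variance = array(0, d))
  } else {
    s1 <- array(0, d); s2 <- array(0, d)
    withr_seed(config$seed, {
      for (i in seq_len(N)) {
        xi <- img + array(stats::rnorm(length(img), 0, sd_abs), d)
        G <- input_gradient(model, xi, cls, view = config$score_view)
        s1 <- s1 + G
        s2 <- s2 + G^2
      }
    })
    aggs <- list(mean = s1 / N, squared = s2 / N,
                 variance = pmax(s2 / N - (s1 / N)^2, 0))
  }
  if (N == 1) aggs$variance <- array(0, d)
  out <- lapply(modes, function(mode) {
    new_saliency_map(channel_reduce(aggs[[mode]],
                                    config$channel_reduction),
                     method_of[[mode]], cls)
  })
  names(out) <- method_of[modes]
  out
}

#' Integrated Gradients (IGrad) saliency map
#'
#' Averages the gradient along the straight path from a baseline image to
#' the input (midpoint Riemann sum with `ig_steps` points) and multiplies by
#' the input-minus-baseline difference. The signed per-channel attributions
#' are kept in the result (`$signed`) so the completeness identity
#' `sum(attributions) = score(input) - score(baseline)` can be checked;
#' the map itself is the channel-reduced attribution.
#'
#' @inheritParams grad_map
#' @return A `saliency_map` with extra fields `signed` (H x W x 3 array)
#'   and `score_delta`.
#' @export
integrated_gradients_map <- function(model, image,
                                     config = saliency_config()) {
  img <- as_image_array(image)
  cls <- explained_class(model, img)
  d <- dim(img)
  baseline <- switch(config$ig_baseline,
                     black = array(0, d),
                     white = array(1, d),
                     uniform_random = withr_seed(config$seed,
                       array(stats::runif(prod(d)), d)))
  stopifnot(all(dim(baseline) == d))
  diff <- img - baseline
  avg <- array(0, d)
  m <- config$ig_steps
  for (i in seq_len(m)) {
    alpha <- (i - 0.5) / m
    avg <- avg + input_gradient(model, baseline + alpha * diff, cls,
                                view = config$score_view)
  }
  attr_signed <- (avg / m) * diff
  sc <- function(x) stats::predict(model, x, type = if (config$score_view ==
    "logit") "logit" else "probability")[1, cls]
  delta <- unname(sc(img) - sc(baseline))
  new_saliency_map(channel_reduce(attr_signed, config$channel_reduction),
                   "IGrad", cls,
                   extra = list(signed = attr_signed, score_delta = delta))
}

occlusion_anchors <- function(len, patch, stride) {
  a <- seq(1L, len - patch + 1L, by = stride)
  if (a[length(a)] != len - patch + 1L) a <- c(a, len - patch + 1L)
  a
}

#' Occlusion (Occl) saliency map
#'
#' Slides a uniform square over the image; each window's contribution is the
#' drop in the explained-class score when that window is filled with a
#' constant. The per-pixel saliency is the mean contribution over all
#' windows covering the pixel.
#'
#' @inheritParams grad_map
#' @return A `saliency_map` (values may be negative: occluding a pixel can
#'   raise the score).
#' @export
occlusion_map <- function(model, image, config = saliency_config()) {
  img <- as_image_array(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  patch <- config$occl_patch %||% ceiling(min(H, W) / 14)
  stride <- config$occl_stride %||% ceiling(patch / 2)
  if (patch < 1 || patch > min(H, W)) stop("invalid occlusion patch size",
                                           call. = FALSE)
  if (stride < 1 || stride > patch) {
    stop("occlusion stride must be in [1, patch] so every pixel is covered",
         call. = FALSE)
  }
  fill <- config$occl_fill %||% mean(img)
  cls <- explained_class(model, img)
  type <- if (config$score_view == "logit") "logit" else "probability"
  base <- stats::predict(model, img, type = type)[1, cls]
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (r in occlusion_anchors(H, patch, stride)) {
    for (cc in occlusion_anchors(W, patch, stride)) {
      occ <- img
      occ[r:(r + patch - 1L), cc:(cc + patch - 1L), ] <- fill
      s <- stats::predict(model, occ, type = type)[1, cls]
      acc[r:(r + patch - 1L), cc:(cc + patch - 1L)] <-
        acc[r:(r + patch - 1L), cc:(cc + patch - 1L)] + (base - s)
      cnt[r:(r + patch - 1L), cc:(cc + patch - 1L)] <-
        cnt[r:(r + patch - 1L), cc:(cc + patch - 1L)] + 1
    }
  }
  new_saliency_map(acc / cnt, "Occl", cls)
}

#' Upsample a single-channel map to a target size
#'
#' @param mat Numeric matrix (native map).
#' @param H,W Target dimensions.
#' @param method `"nearest"` or `"bilinear"`.
#' @return Numeric H x W matrix.
#' @export
upsample_map <- function(mat, H, W, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(mat); w <- ncol(mat)
  if (h == H && w == W) return(mat)
  # map output pixel centers onto input coordinates
  ri <- (seq_len(H) - 0.5) * h / H + 0.5
  ci <- (seq_len(W) - 0.5) * w / W + 0.5
  if (method == "nearest") {
    return(mat[pmin(pmax(round(ri), 1), h), pmin(pmax(round(ci), 1), w)])
  }
  r0 <- pmin(pmax(floor(ri), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(ci), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  top <- mat[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    mat[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  bot <- mat[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    mat[r1, c1, drop = FALSE] * outer(fr, fc)
  top + bot
}

#' GradCAM (GCam) saliency map
#'
#' Channel weights are the spatial means of the class-score gradients at the
#' designated convolutional (CAM) layer; the map is the ReLU of the weighted
#' sum of that layer's activation maps, computed at native resolution and
#' upsampled to the image size. The native map is retained in `$native`.
#'
#' @inheritParams grad_map
#' @return A `saliency_map` with non-negative values.
#' @export
gradcam_map <- function(model, image, config = saliency_config()) {
  img <- as_image_array(image)
  cls <- explained_class(model, img)
  A <- cam_activations(model, img)
  G <- cam_gradients(model, img, cls, view = config$score_view)
  wts <- apply(G, 3, mean)
  native <- pmax(apply(sweep(A, 3, wts, `*`), c(1, 2), sum), 0)
  vals <- upsample_map(native, dim(img)[1], dim(img)[2],
                       config$cam_upsampling)
  new_saliency_map(pmax(vals, 0), "GCam", cls, native = native)
}

#' ScoreCAM (SCam) saliency map
#'
#' Gradient-free CAM: each activation map of the CAM layer is min-max
#' normalized, upsampled, and used to mask the input; the explained-class
#' score of the masked input is the channel weight. The map is the ReLU of
#' the weighted activation sum, upsampled as in [gradcam_map()]. Constant
#' activation channels are skipped with a warning (their normalization is
#' undefined).
#'
#' @inheritParams grad_map
#' @return A `saliency_map` with non-negative values.
#' @export
scorecam_map <- function(model, image, config = saliency_config()) {
  img <- as_image_array(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  cls <- explained_class(model, img)
  A <- cam_activations(model, img)
  type <- if (config$score_view == "logit") "logit" else "probability"
  nch <- dim(A)[3]
  native <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(nch)) {
    Ak <- A[, , k]
    rng <- max(Ak) - min(Ak)
    if (rng <= .Machine$double.eps) {
      warning("ScoreCAM: skipping constant activation channel ", k)
      next
    }
    Mk <- upsample_map((Ak - min(Ak)) / rng, H, W, config$cam_upsampling)
    masked <- img * array(rep(Mk, dim(img)[3]), dim(img))
    s <- stats::predict(model, masked, type = type)[1, cls]
    native <- native + s * Ak
  }
  native <- pmax(native, 0)
  vals <- upsample_map(native, H, W, config$cam_upsampling)
  new_saliency_map(pmax(vals, 0), "SCam", cls, native = native)
}

#' Compute a saliency map by method abbreviation
#'
#' @inheritParams grad_map
#' @param method One of [saliency_methods()].
#' @return A `saliency_map`.
#' @export
compute_saliency <- function(model, image, method,
                             config = saliency_config()) {
  method <- match.arg(method, saliency_methods())
  switch(method,
         Grad = grad_map(model, image, config),
         GBack = guided_backprop_map(model, image, config),
         SGrad = smoothgrad_map(model, image, config, "mean"),
         SGrad2 = smoothgrad_map(model, image, config, "squared"),
         VGrad = smoothgrad_map(model, image, config, "variance"),
         IGrad = integrated_gradients_map(model, image, config),
         Occl = occlusion_map(model, image, config),
         GCam = gradcam_map(model, image, config),
         SCam = scorecam_map(model, image, config))
}
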