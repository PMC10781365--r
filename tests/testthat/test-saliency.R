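test_that("zero-noise SmoothGrad equals the plain gradient exactly", {
  m <- shared_model()
  img <- shared_dataset()$samples[[3]]
  cfg <- saliency_config(sg_noise_sd = 0, sg_samples = 7L)
  expect_identical(smoothgrad_map(m, img, cfg, "mean")$values,
                   grad_map(m, img, cfg)$values)
})

test_that("single-sample VarGrad is identically zero with a warning", {
  m <- shared_model()
  img <- shared_dataset()$samples[[3]]
  cfg <- saliency_config(sg_samples = 1L)
  expect_warning(v <- smoothgrad_map(m, img, cfg, "variance"),
                 "identically zero")
  expect_true(all(v$values == 0))
})

test_that("single-sample zero-noise SmoothGrad Squared is the squared raw gradient", {
  m <- shared_model()
  s <- shared_dataset()$samples[[4]]
  cfg <- saliency_config(sg_samples = 1L, sg_noise_sd = 0)
  got <- smoothgrad_map(m, s, cfg, "squared")$values
  cls <- which.max(predict(m, s, type = "logit")[1, ])
  G2 <- input_gradient(m, s$image, cls, view = "logit")^2
  expect_equal(got, pmax(abs(G2[, , 1]), abs(G2[, , 2]), abs(G2[, , 3])),
               tolerance = 1e-12)
})

test_that("integrated gradients are exact for a linear model and vanish on the baseline", {
  set.seed(7)
  w1 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  w2 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  lm <- make_linear_model(w1, w2)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  cfg <- saliency_config(ig_baseline = "black", ig_steps = 4L)
  out <- integrated_gradients_map(lm, x, cfg)
  cls <- which.max(predict(lm, x, type = "logit")[1, ])
  w <- if (cls == 1) w1 else w2
  expect_equal(out$signed, w * x, tolerance = 1e-10)   # w (x - 0)
  expect_equal(sum(out$signed), out$score_delta, tolerance = 1e-10)
  # input identical to the baseline: zero attribution everywhere
  zero <- integrated_gradients_map(lm, array(0, c(8, 8, 3)), cfg)
  expect_true(all(zero$values == 0))
})

test_that("integrated-gradients completeness holds on the trained CNN", {
  m <- shared_model()
  cfg <- saliency_config(ig_baseline = "black", ig_steps = 256L)
  for (i in c(2, 103)) {
    out <- integrated_gradients_map(m, shared_dataset()$samples[[i]], cfg)
    expect_lte(abs(sum(out$signed) - out$score_delta),
               0.01 * abs(out$score_delta))
  }
})

test_that("occlusion matches the per-window closed form of a linear model", {
  set.seed(8)
  w1 <- array(rnorm(8 * 8 * 3, sd = .3), c(8, 8, 3))
  w2 <- array(rnorm(8 * 8 * 3, sd = .3), c(8, 8, 3))
  lm <- make_linear_model(w1, w2)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  fill <- 0.25
  cfg <- saliency_config(occl_patch = 4L, occl_stride = 2L,
                         occl_fill = fill)
  got <- occlusion_map(lm, x, cfg)$values
  cls <- which.max(predict(lm, x, type = "logit")[1, ])
  w <- if (cls == 1) w1 else w2
  # oracle: per-pixel mean over windows covering it, each window's
  # contribution being sum_{p in window} w_p (x_p - fill)
  anchors <- c(1, 3, 5)
  acc <- matrix(0, 8, 8); cnt <- matrix(0, 8, 8)
  for (r in anchors) for (cc in anchors) {
    rows <- r:(r + 3); cols <- cc:(cc + 3)
    contrib <- sum(w[rows, cols, ] * (x[rows, cols, ] - fill))
    acc[rows, cols] <- acc[rows, cols] + contrib
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  expect_equal(got, acc / cnt, tolerance = 1e-10)
})

test_that("occlusion equals exhaustive window enumeration on the CNN", {
  m8 <- toy_cnn(c(8L, 8L, 3L), filters = c(3L, 3L), seed = 23L)
  set.seed(9)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  cfg <- saliency_config(occl_patch = 4L, occl_stride = 2L, occl_fill = 0.5)
  got <- occlusion_map(m8, x, cfg)$values
  cls <- which.max(predict(m8, x, type = "logit")[1, ])
  base <- predict(m8, x, type = "logit")[1, cls]
  acc <- matrix(0, 8, 8); cnt <- matrix(0, 8, 8)
  for (r in c(1, 3, 5)) for (cc in c(1, 3, 5)) {
    occ <- x
    occ[r:(r + 3), cc:(cc + 3), ] <- 0.5
    d <- base - predict(m8, occ, type = "logit")[1, cls]
    acc[r:(r + 3), cc:(cc + 3)] <- acc[r:(r + 3), cc:(cc + 3)] + d
    cnt[r:(r + 3), cc:(cc + 3)] <- cnt[r:(r + 3), cc:(cc + 3)] + 1
  }
  expect_equal(got, acc / cnt, tolerance = 1e-12)
  expect_error(occlusion_map(m8, x, saliency_config(occl_patch = 2L,
                                                    occl_stride = 3L)),
               "stride")
})

test_that("GradCAM is the ReLU-weighted activation sum, upsampled", {
  m <- shared_model()
  s <- shared_dataset()$samples[[5]]
  out <- gradcam_map(m, s)
  cls <- which.max(predict(m, s, type = "logit")[1, ])
  A <- cam_activations(m, s$image)
  # with global average pooling the channel weights are the dense weights
  # divided by the number of CAM positions
  alpha <- m$weights$W3[cls, ] / prod(dim(A)[1:2])
  native <- pmax(apply(sweep(A, 3, alpha, `*`), c(1, 2), sum), 0)
  expect_equal(out$native, native, tolerance = 1e-12)
  expect_equal(out$values,
               upsample_map(native, 32, 32, "bilinear"), tolerance = 1e-12)
  expect_true(all(out$values >= 0))
  expect_equal(out$native_resolution, c(16, 16))
})

test_that("nearest upsampling of a 2x2 native map gives four constant blocks", {
  up <- upsample_map(matrix(c(1, 3, 2, 4), 2, 2), 8, 8, "nearest")
  expect_true(all(up[1:4, 1:4] == 1))
  expect_true(all(up[5:8, 1:4] == 3))
  expect_true(all(up[1:4, 5:8] == 2))
  expect_true(all(up[5:8, 5:8] == 4))
})

test_that("ScoreCAM equals a brute-force loop over masked-input scores", {
  m <- shared_model()
  s <- shared_dataset()$samples[[6]]
  out <- suppressWarnings(scorecam_map(m, s))  # dead channels may warn
  cls <- which.max(predict(m, s, type = "logit")[1, ])
  A <- cam_activations(m, s$image)
  native <- matrix(0, 16, 16)
  for (k in seq_len(dim(A)[3])) {
    Ak <- A[, , k]
    rng <- max(Ak) - min(Ak)
    if (rng <= .Machine$double.eps) next
    Mk <- upsample_map((Ak - min(Ak)) / rng, 32, 32, "bilinear")
    masked <- s$image * array(rep(Mk, 3), c(32, 32, 3))
    native <- native + predict(m, masked, type = "logit")[1, cls] * Ak
  }
  native <- pmax(native, 0)
  expect_equal(out$native, native, tolerance = 1e-10)
  expect_true(all(out$values >= 0))
})

test_that("saliency maps explain the predicted class, not the true label", {
  m <- shared_model()
  s <- shared_dataset()$samples[[7]]
  s_relabel <- s
  s_relabel$label <- setdiff(c("healthy", "glaucoma"), s$label)
  for (meth in c("Grad", "IGrad", "GCam")) {
    expect_identical(compute_saliency(m, s, meth)$values,
                     compute_saliency(m, s_relabel, meth)$values)
  }
})

test_that("guided backprop needs the override and is vacuous without ReLUs", {
  set.seed(11)
  w1 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  lm <- make_linear_model(w1, -w1)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_identical(guided_backprop_map(lm, x)$values,
                   grad_map(lm, x)$values)
  attr(lm, "supports_guided") <- FALSE
  expect_error(guided_backprop_map(lm, x), "guided")
})

test_that("the shared SmoothGrad-family loop is bit-identical to standalone calls", {
  m <- shared_model()
  s <- shared_dataset()$samples[[9]]
  cfg <- saliency_config(sg_samples = 6L, seed = 19L)
  fam <- sectorsal:::smoothgrad_family(m, s, cfg,
                                       c("mean", "squared", "variance"))
  expect_identical(fam$SGrad$values, smoothgrad_map(m, s, cfg, "mean")$values)
  expect_identical(fam$SGrad2$values,
                   smoothgrad_map(m, s, cfg, "squared")$values)
  expect_identical(fam$VGrad$values,
                   smoothgrad_map(m, s, cfg, "variance")$values)
  # and discretize_model (which uses the shared loop) matches per-method maps
  masks <- shared_mask_sets(2)
  colls <- discretize_model(m, shared_dataset()$samples[1:2], masks,
                            c("SGrad", "Grad", "VGrad"), cfg)
  d_direct <- discretize_saliency(smoothgrad_map(m,
    shared_dataset()$samples[[1]], cfg, "mean"), masks[[1]])
  expect_equal(unclass(colls$SGrad$maps[[1]]), unclass(d_direct))
})

test_that("stochastic saliency maps are reproducible under a fixed seed", {
  m <- shared_model()
  s <- shared_dataset()$samples[[8]]
  cfg <- saliency_config(sg_samples = 5L, seed = 13L,
                         ig_baseline = "uniform_random", ig_steps = 5L)
  expect_identical(smoothgrad_map(m, s, cfg, "mean")$values,
                   smoothgrad_map(m, s, cfg, "mean")$values)
  expect_identical(integrated_gradients_map(m, s, cfg)$values,
                   integrated_gradients_map(m, s, cfg)$values)
})
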