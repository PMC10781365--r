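test_that("vectorized forward pass matches a naive loop implementation", {
  set.seed(42)
  m <- toy_cnn(c(8L, 8L, 3L), filters = c(3L, 4L), seed = 13L)
  for (i in 1:3) {
    X <- array(runif(8 * 8 * 3), c(8, 8, 3))
    nf <- naive_forward(m, X)
    expect_equal(predict(m, X, type = "logit")[1, ], nf$logits,
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(as.vector(cam_activations(m, X)), as.vector(nf$A2),
                 tolerance = 1e-10)
  }
})

test_that("input gradients match the naive chain rule, plain and guided", {
  set.seed(43)
  m <- toy_cnn(c(8L, 8L, 3L), filters = c(3L, 4L), seed = 17L)
  for (view in c("logit", "probability")) {
    for (cls in 1:2) {
      X <- array(runif(8 * 8 * 3), c(8, 8, 3))
      expect_equal(input_gradient(m, X, cls, view = view),
                   naive_input_gradient(m, X, cls, view = view),
                   tolerance = 1e-10)
      expect_equal(input_gradient(m, X, cls, view = view, guided = TRUE),
                   naive_input_gradient(m, X, cls, view = view,
                                        guided = TRUE),
                   tolerance = 1e-10)
    }
  }
})

test_that("input gradients agree with central finite differences", {
  m <- shared_model()
  ds <- shared_dataset()
  img <- ds$samples[[1]]$image
  for (view in c("logit", "probability")) {
    g <- input_gradient(m, img, 2L, view = view)
    fwd_score <- function(x) predict(m, x, type = if (view == "logit")
      "logit" else "probability")[1, 2]
    set.seed(99)
    probes <- cbind(sample(dim(img)[1], 10, TRUE),
                    sample(dim(img)[2], 10, TRUE),
                    sample(3, 10, TRUE))
    eps <- 1e-5
    for (k in seq_len(nrow(probes))) {
      p <- probes[k, ]
      xp <- img; xp[p[1], p[2], p[3]] <- xp[p[1], p[2], p[3]] + eps
      xm <- img; xm[p[1], p[2], p[3]] <- xm[p[1], p[2], p[3]] - eps
      fd <- unname((fwd_score(xp) - fwd_score(xm)) / (2 * eps))
      expect_equal(g[p[1], p[2], p[3]], fd, tolerance = 1e-3)
    }
  }
})

test_that("training on a separable synthetic set reaches high balanced accuracy", {
  ds <- shared_dataset()
  m <- shared_model()
  ba <- balanced_accuracy(predicted_classes(m, ds$samples),
                          ds$manifest$label)
  expect_gte(ba, 0.9)
  expect_equal(nrow(m$log), m$hyperparams$epochs)  # training curve logged
  expect_lt(m$log$loss[nrow(m$log)], m$log$loss[1])
})

test_that("training is deterministic and rejects degenerate inputs", {
  ds <- shared_dataset()
  idx <- c(1:8, 101:108)
  hp <- list(epochs = 4L)
  m1 <- train_toy_model(ds$samples[idx], ds$manifest$label[idx], hp,
                        seed = 5L)
  m2 <- train_toy_model(ds$samples[idx], ds$manifest$label[idx], hp,
                        seed = 5L)
  expect_identical(m1$weights, m2$weights)
  probe <- ds$samples[c(20, 120)]
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_error(train_toy_model(ds$samples[1:10],
                               rep("healthy", 10), hp), "both classes")
  expect_error(train_toy_model(ds$samples[c(1, 101)],
                               c("healthy", "glaucoma"), hp),
               "two samples per class")
})

test_that("reinitialization yields a fresh deterministic untrained copy", {
  m <- shared_model()
  r1 <- reinitialize(m, seed = 77L)
  r2 <- reinitialize(m, seed = 77L)
  r3 <- reinitialize(m, seed = 78L)
  expect_identical(r1$weights, r2$weights)
  expect_false(identical(r1$weights, r3$weights))
  expect_false(identical(r1$weights, m$weights))
  expect_false(r1$trained)
  expect_identical(r1$arch, m$arch)
  probe <- shared_dataset()$samples[[1]]
  expect_identical(predict(r1, probe), predict(r2, probe))
})

test_that("CAM-layer accessors return correctly shaped tensors", {
  m <- shared_model()
  img <- shared_dataset()$samples[[1]]$image
  A <- cam_activations(m, img)
  G <- cam_gradients(m, img, 1L)
  expect_equal(dim(A), c(16, 16, 8))
  expect_equal(dim(G), dim(A))
  expect_true(all(A >= 0))            # post-ReLU activations
  expect_true(all(is.finite(G)))
})
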