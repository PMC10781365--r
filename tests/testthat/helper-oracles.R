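# Independent oracles and shared fixtures for the test suite.

# ---- naive loop-based CNN (independent re-derivation of the forward and
# backward passes used to validate the vectorized implementation) ----

naive_conv <- function(X, W, b) {
  H <- dim(X)[1]; Wd <- dim(X)[2]; Cin <- dim(X)[3]; Cout <- dim(W)[4]
  out <- array(0, c(H, Wd, Cout))
  for (i in seq_len(H)) for (j in seq_len(Wd)) for (f in seq_len(Cout)) {
    s <- b[f]
    for (di in 0:2) for (dj in 0:2) {
      ii <- i + di - 1L; jj <- j + dj - 1L
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
        for (c in seq_len(Cin)) s <- s + X[ii, jj, c] * W[di + 1, dj + 1, c, f]
      }
    }
    out[i, j, f] <- s
  }
  out
}

naive_forward <- function(model, X) {
  w <- model$weights
  X <- X - 0.5                       # same input centering as the model
  Z1 <- naive_conv(X, w$W1, w$b1)
  A1 <- pmax(Z1, 0)
  H <- dim(X)[1]; Wd <- dim(X)[2]
  h <- H / 2; wd <- Wd / 2
  P1 <- array(0, c(h, wd, dim(A1)[3]))
  for (i in seq_len(h)) for (j in seq_len(wd)) {
    P1[i, j, ] <- (A1[2 * i - 1, 2 * j - 1, ] + A1[2 * i, 2 * j - 1, ] +
                   A1[2 * i - 1, 2 * j, ] + A1[2 * i, 2 * j, ]) / 4
  }
  Z2 <- naive_conv(P1, w$W2, w$b2)
  A2 <- pmax(Z2, 0)
  g <- apply(A2, 3, mean)
  logits <- as.vector(w$W3 %*% g + w$b3)
  p <- exp(logits - max(logits)); p <- p / sum(p)
  list(Z1 = Z1, A1 = A1, P1 = P1, Z2 = Z2, A2 = A2, g = g,
       logits = logits, probs = p)
}

naive_conv_backward_input <- function(dZ, W, Hin, Win) {
  Cin <- dim(W)[3]; Cout <- dim(W)[4]
  dX <- array(0, c(Hin, Win, Cin))
  for (i in seq_len(dim(dZ)[1])) for (j in seq_len(dim(dZ)[2])) {
    for (f in seq_len(Cout)) {
      v <- dZ[i, j, f]
      if (v == 0) next
      for (di in 0:2) for (dj in 0:2) {
        ii <- i + di - 1L; jj <- j + dj - 1L
        if (ii >= 1 && ii <= Hin && jj >= 1 && jj <= Win) {
          for (c in seq_len(Cin)) {
            dX[ii, jj, c] <- dX[ii, jj, c] + v * W[di + 1, dj + 1, c, f]
          }
        }
      }
    }
  }
  dX
}

naive_input_gradient <- function(model, X, class_idx,
                                 view = "logit", guided = FALSE) {
  w <- model$weights
  fwd <- naive_forward(model, X)
  e <- c(0, 0); e[class_idx] <- 1
  dlogits <- if (view == "logit") e else
    fwd$probs[class_idx] * (e - fwd$probs)
  dg <- as.vector(t(w$W3) %*% dlogits)
  h <- dim(fwd$A2)[1]; wd <- dim(fwd$A2)[2]
  dA2 <- array(0, dim(fwd$A2))
  for (k in seq_along(dg)) dA2[, , k] <- dg[k] / (h * wd)
  dZ2 <- dA2 * (fwd$Z2 > 0)
  if (guided) dZ2 <- dZ2 * (dA2 > 0)
  dP1 <- naive_conv_backward_input(dZ2, w$W2, h, wd)
  H <- dim(X)[1]; Wd <- dim(X)[2]
  dA1 <- array(0, dim(fwd$A1))
  for (i in seq_len(h)) for (j in seq_len(wd)) {
    for (a in 0:1) for (b in 0:1) {
      dA1[2 * i - a, 2 * j - b, ] <- dP1[i, j, ] / 4
    }
  }
  dZ1 <- dA1 * (fwd$Z1 > 0)
  if (guided) dZ1 <- dZ1 * (dA1 > 0)
  naive_conv_backward_input(dZ1, w$W1, H, Wd)
}

# ---- linear mock model adapter (closed-form oracles) ----

make_linear_model <- function(weights1, weights2, bias = c(0, 0)) {
  m <- structure(list(W = list(weights1, weights2), b = bias),
                 class = "mock_linear")
  attr(m, "supports_guided") <- TRUE    # no ReLUs: the override is vacuous
  m
}

predict.mock_linear <- function(object, images, type = "probability", ...) {
  if (!is.list(images) || inherits(images, "fundus_sample")) {
    images <- list(images)
  }
  out <- t(vapply(images, function(im) {
    if (inherits(im, "fundus_sample")) im <- im$image
    z <- c(sum(object$W[[1]] * im), sum(object$W[[2]] * im)) + object$b
    if (type == "logit") z else { p <- exp(z - max(z)); p / sum(p) }
  }, numeric(2)))
  colnames(out) <- c("healthy", "glaucoma")
  out
}

input_gradient.mock_linear <- function(model, image, class_idx,
                                       view = "logit", guided = FALSE,
                                       ...) {
  view <- match.arg(view, c("logit", "probability"))
  if (inherits(image, "fundus_sample")) image <- image$image
  if (view == "logit") return(model$W[[class_idx]])
  p <- predict.mock_linear(model, image, "probability")[1, ]
  e <- c(0, 0); e[class_idx] <- 1
  d <- p[class_idx] * (e - p)
  d[1] * model$W[[1]] + d[2] * model$W[[2]]
}

.S3method("predict", "mock_linear", predict.mock_linear)
.S3method("input_gradient", "mock_linear", input_gradient.mock_linear)

# ---- shared fixtures (built once per test run) ----

.shared <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.shared$ds)) {
    .shared$ds <- generate_dataset(generator_config(seed = 101L), 100L)
  }
  .shared$ds
}

shared_model <- function() {
  if (is.null(.shared$model)) {
    ds <- shared_dataset()
    .shared$model <- train_toy_model(ds$samples, ds$manifest$label,
                                     seed = 301L)
  }
  .shared$model
}

shared_mask_sets <- function(n = NULL) {
  ds <- shared_dataset()
  if (is.null(.shared$masks)) {
    shape <- dim(ds$samples[[1]]$image)[1:2]
    .shared$masks <- lapply(ds$annotations, build_sector_masks,
                            image_shape = shape, scheme = sector_scheme())
  }
  if (is.null(n)) .shared$masks else .shared$masks[seq_len(n)]
}

random_annotation <- function(shape, laterality = "OD") {
  ctr <- shape / 2 + stats::runif(2, -2, 2)
  rd <- stats::runif(1, shape[1] / 4, shape[1] / 2.5)
  disc_cup_annotation(
    disc = list(center = ctr, semi_axes = c(rd, rd * stats::runif(1, .85, 1)),
                rotation = stats::runif(1, 0, 180)),
    cup = list(center = ctr, semi_axes = 0.5 * c(rd, rd),
               rotation = 0),
    laterality = laterality)
}
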