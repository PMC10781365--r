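## A compact, fully inspectable convolutional network.
##
## Architecture: conv 3x3 (F1 filters, same padding) -> ReLU -> 2x2 average
## pool -> conv 3x3 (F2 filters, same padding) -> ReLU  [the CAM layer]
## -> global average pool -> dense (2 logits) -> softmax.
##
## Convolutions are evaluated as im2col gathers followed by a single BLAS
## matrix product; the backward pass is written out explicitly so that input
## gradients, CAM-layer gradients and the guided-ReLU backward rule are all
## available to the attribution methods.

.conv_cache <- new.env(parent = emptyenv())

# im2col index matrix: rows = H*W output positions (row index fastest),
# columns = the 9*C taps (kernel offset fastest within each input channel),
# values = linear indices into the zero-padded (H+2) x (W+2) x C array.
conv_indices <- function(H, W, C) {
  key <- paste(H, W, C, sep = ":")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  Hp <- H + 2L
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  B <- matrix(0L, H * W, 9L)
  for (q in 1:9) {
    di <- (q - 1L) %% 3L
    dj <- (q - 1L) %/% 3L
    B[, q] <- (i + di) + (j + dj - 1L) * Hp
  }
  plane <- Hp * (W + 2L)
  full <- matrix(0L, H * W, 9L * C)
  for (c in seq_len(C)) {
    full[, (c - 1L) * 9L + (1:9)] <- B + (c - 1L) * plane
  }
  out <- list(B = B, full = full, plane = plane)
  .conv_cache[[key]] <- out
  out
}

pad_array <- function(X) {
  d <- dim(X)
  Xp <- array(0, d + c(2L, 2L, 0L))
  Xp[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- X
  Xp
}

# Scatter-add of a column matrix back onto a padded image (col2im).
col2im <- function(dcol, H, W, Cin) {
  idx <- conv_indices(H, W, Cin)
  acc <- matrix(0, (H + 2L) * (W + 2L), Cin)
  sel <- 9L * (seq_len(Cin) - 1L)
  for (q in 1:9) {
    rows <- idx$B[, q]
    acc[rows, ] <- acc[rows, ] + dcol[, q + sel, drop = FALSE]
  }
  array(acc, c(H + 2L, W + 2L, Cin))[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

new_cnn_weights <- function(arch) {
  list(W1 = he_init(c(3, 3, arch$C, arch$F1), 9 * arch$C),
       b1 = numeric(arch$F1),
       W2 = he_init(c(3, 3, arch$F1, arch$F2), 9 * arch$F1),
       b2 = numeric(arch$F2),
       W3 = matrix(stats::rnorm(2 * arch$F2, sd = sqrt(2 / arch$F2)),
                   2, arch$F2),
       b3 = numeric(2))
}

#' Construct an untrained toy CNN
#'
#' @param input_shape Length-3 integer (H, W, channels); H and W must be
#'   even (a single 2x2 pooling stage sits between the conv layers).
#' @param filters Length-2 integer: filters in the two convolutional layers;
#'   the second layer is the CAM layer.
#' @param seed Integer seed for the weight initialization.
#' @param classes Class labels, length 2, in the order of the output units.
#' @return An object of class `toy_cnn`.
#' @export
toy_cnn <- function(input_shape, filters = c(8L, 8L), seed = 1L,
                    classes = c("healthy", "glaucoma")) {
  stopifnot(length(input_shape) == 3, input_shape[1] %% 2 == 0,
            input_shape[2] %% 2 == 0, length(filters) == 2,
            length(classes) == 2)
  arch <- list(H = as.integer(input_shape[1]), W = as.integer(input_shape[2]),
               C = as.integer(input_shape[3]), F1 = as.integer(filters[1]),
               F2 = as.integer(filters[2]))
  weights <- withr_seed(seed, new_cnn_weights(arch))
  structure(list(arch = arch, weights = weights, classes = classes,
                 seed = as.integer(seed), trained = FALSE, log = NULL),
            class = "toy_cnn")
}

as_image_array <- function(x, arch = NULL) {
  if (inherits(x, "fundus_sample")) x <- x$image
  stopifnot(is.array(x), length(dim(x)) == 3)
  if (!is.null(arch)) stopifnot(all(dim(x) == c(arch$H, arch$W, arch$C)))
  x
}

cnn_forward <- function(model, X) {
  a <- model$arch; w <- model$weights
  idx1 <- conv_indices(a$H, a$W, a$C)
  # center intensities: zero-mean inputs condition the first-layer weight
  # gradients; input gradients are unaffected by the constant shift
  Xp <- pad_array(X - 0.5)
  Xcol1 <- matrix(Xp[idx1$full], a$H * a$W, 9L * a$C)
  Z1 <- Xcol1 %*% matrix(w$W1, 9L * a$C, a$F1)
  Z1 <- Z1 + rep(w$b1, each = nrow(Z1))
  A1 <- pmax(Z1, 0)
  A1a <- array(A1, c(a$H, a$W, a$F1))
  o1 <- seq(1L, a$H, 2L); o2 <- seq(1L, a$W, 2L)
  P1 <- (A1a[o1, o2, , drop = FALSE] + A1a[o1 + 1L, o2, , drop = FALSE] +
         A1a[o1, o2 + 1L, , drop = FALSE] +
         A1a[o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
  h <- a$H %/% 2L; wd <- a$W %/% 2L
  idx2 <- conv_indices(h, wd, a$F1)
  Pp <- pad_array(P1)
  Xcol2 <- matrix(Pp[idx2$full], h * wd, 9L * a$F1)
  Z2 <- Xcol2 %*% matrix(w$W2, 9L * a$F1, a$F2)
  Z2 <- Z2 + rep(w$b2, each = nrow(Z2))
  A2 <- pmax(Z2, 0)
  g <- colMeans(A2)
  logits <- as.vector(w$W3 %*% g + w$b3)
  p <- exp(logits - max(logits)); p <- p / sum(p)
  list(X = X, Xcol1 = Xcol1, Z1 = Z1, Xcol2 = Xcol2, Z2 = Z2, A2 = A2,
       g = g, logits = logits, probs = p, h = h, wd = wd)
}

# Upstream logit-space gradient for the requested score view.
score_dlogits <- function(fwd, class_idx, view) {
  e <- c(0, 0); e[class_idx] <- 1
  if (view == "logit") e else fwd$probs[class_idx] * (e - fwd$probs)
}

# Backward pass to the input. `guided` applies the guided-backpropagation
# ReLU rule (zero out negative upstream gradients at every ReLU).
cnn_backward_input <- function(model, fwd, dlogits, guided = FALSE) {
  a <- model$arch; w <- model$weights
  hw <- fwd$h * fwd$wd
  dg <- as.vector(t(w$W3) %*% dlogits)
  dA2 <- matrix(dg / hw, hw, a$F2, byrow = TRUE)
  dZ2 <- dA2 * (fwd$Z2 > 0)
  if (guided) dZ2 <- dZ2 * (dA2 > 0)
  dPcol <- dZ2 %*% t(matrix(w$W2, 9L * a$F1, a$F2))
  dP1 <- col2im(dPcol, fwd$h, fwd$wd, a$F1)
  dA1a <- dP1[rep(seq_len(fwd$h), each = 2L),
              rep(seq_len(fwd$wd), each = 2L), , drop = FALSE] / 4
  dA1 <- matrix(dA1a, a$H * a$W, a$F1)
  dZ1 <- dA1 * (fwd$Z1 > 0)
  if (guided) dZ1 <- dZ1 * (dA1 > 0)
  dXcol <- dZ1 %*% t(matrix(w$W1, 9L * a$C, a$F1))
  col2im(dXcol, a$H, a$W, a$C)
}

# Backward pass to the weights (for training). Returns gradients in the same
# shapes as the weight list.
cnn_backward_weights <- function(model, fwd, dlogits) {
  a <- model$arch; w <- model$weights
  hw <- fwd$h * fwd$wd
  dW3 <- outer(dlogits, fwd$g)
  db3 <- dlogits
  dg <- as.vector(t(w$W3) %*% dlogits)
  dA2 <- matrix(dg / hw, hw, a$F2, byrow = TRUE)
  dZ2 <- dA2 * (fwd$Z2 > 0)
  dW2 <- t(fwd$Xcol2) %*% dZ2
  db2 <- colSums(dZ2)
  dPcol <- dZ2 %*% t(matrix(w$W2, 9L * a$F1, a$F2))
  dP1 <- col2im(dPcol, fwd$h, fwd$wd, a$F1)
  dA1a <- dP1[rep(seq_len(fwd$h), each = 2L),
              rep(seq_len(fwd$wd), each = 2L), , drop = FALSE] / 4
  dA1 <- matrix(dA1a, a$H * a$W, a$F1)
  dZ1 <- dA1 * (fwd$Z1 > 0)
  dW1 <- t(fwd$Xcol1) %*% dZ1
  db1 <- colSums(dZ1)
  list(W1 = array(dW1, dim(w$W1)), b1 = db1,
       W2 = array(dW2, dim(w$W2)), b2 = db2, W3 = dW3, b3 = db3)
}

#' Predict class scores for one or more images
#'
#' Inference is deterministic given fixed weights (there is no dropout or
#' batch statistics update).
#'
#' @param object A `toy_cnn`.
#' @param images A single image (H x W x C array or `fundus_sample`) or a
#'   list of them.
#' @param type `"probability"` (softmax) or `"logit"` (pre-softmax scores).
#' @param ... Unused.
#' @return Numeric matrix n x 2, columns named by the model's classes.
#' @export
predict.toy_cnn <- function(object, images, type = c("probability", "logit"),
                            ...) {
  type <- match.arg(type)
  if (!is.list(images) || inherits(images, "fundus_sample")) {
    images <- list(images)
  }
  out <- t(vapply(images, function(im) {
    fwd <- cnn_forward(object, as_image_array(im, object$arch))
    if (type == "logit") fwd$logits else fwd$probs
  }, numeric(2)))
  colnames(out) <- object$classes
  out
}

#' Gradient of a class score with respect to the input image
#'
#' @param model A model adapter (here, a `toy_cnn`).
#' @param image Image array or `fundus_sample`.
#' @param class_idx Output unit (1-based) whose score is differentiated.
#' @param view `"logit"` or `"probability"`: which score is differentiated.
#' @param guided If `TRUE`, apply the guided-backpropagation ReLU rule.
#' @param ... Passed to methods.
#' @return H x W x C gradient array.
#' @export
input_gradient <- function(model, image, class_idx,
                           view = c("logit", "probability"),
                           guided = FALSE, ...) {
  UseMethod("input_gradient")
}

#' @export
input_gradient.toy_cnn <- function(model, image, class_idx,
                                   view = c("logit", "probability"),
                                   guided = FALSE, ...) {
  view <- match.arg(view)
  fwd <- cnn_forward(model, as_image_array(image, model$arch))
  g <- cnn_backward_input(model, fwd,
                          score_dlogits(fwd, class_idx, view), guided)
  if (!all(is.finite(g))) stop("non-finite input gradient", call. = FALSE)
  g
}

#' Activations of the designated CAM layer
#' @inheritParams input_gradient
#' @return h x w x F array of post-ReLU activations of the last conv layer.
#' @export
cam_activations <- function(model, image, ...) UseMethod("cam_activations")

#' @export
cam_activations.toy_cnn <- function(model, image, ...) {
  fwd <- cnn_forward(model, as_image_array(image, model$arch))
  array(fwd$A2, c(fwd$h, fwd$wd, model$arch$F2))
}

#' Gradients of a class score at the CAM layer
#' @inheritParams input_gradient
#' @return h x w x F array: d(score)/d(activation) at the last conv layer.
#' @export
cam_gradients <- function(model, image, class_idx,
                          view = c("logit", "probability"), ...) {
  UseMethod("cam_gradients")
}

#' @export
cam_gradients.toy_cnn <- function(model, image, class_idx,
                                  view = c("logit", "probability"), ...) {
  view <- match.arg(view)
  fwd <- cnn_forward(model, as_image_array(image, model$arch))
  dlogits <- score_dlogits(fwd, class_idx, view)
  dg <- as.vector(t(model$weights$W3) %*% dlogits)
  hw <- fwd$h * fwd$wd
  array(matrix(dg / hw, hw, model$arch$F2, byrow = TRUE),
        c(fwd$h, fwd$wd, model$arch$F2))
}

#' Fresh untrained copy of a model with newly initialized weights
#' @param model A model adapter.
#' @param seed Integer seed for the new initialization.
#' @param ... Passed to methods.
#' @return A new adapter of the same architecture, untrained.
#' @export
reinitialize <- function(model, seed, ...) UseMethod("reinitialize")

#' @export
reinitialize.toy_cnn <- function(model, seed, ...) {
  model$weights <- withr_seed(seed, new_cnn_weights(model$arch))
  model$trained <- FALSE
  model$seed <- as.integer(seed)
  model$log <- NULL
  model
}

#' Does this adapter support the guided-backpropagation ReLU override?
#' @param model A model adapter.
#' @return Logical scalar.
#' @export
supports_guided <- function(model) UseMethod("supports_guided")

#' @export
supports_guided.toy_cnn <- function(model) TRUE

#' @export
supports_guided.default <- function(model) {
  isTRUE(attr(model, "supports_guided"))
}

#' Train the toy CNN on labelled images
#'
#' Minimizes the categorical cross-entropy with mini-batch Adam. Fixed seed
#' implies identical weights (initialization and shuffling are both seeded).
#'
#' @param samples List of images (`fundus_sample` or H x W x C arrays); at
#'   least two per class.
#' @param labels Character/factor vector of length `length(samples)` with
#'   exactly two classes.
#' @param hyperparams Optional list overriding `filters` (c(8, 8)),
#'   `lr` (0.003), `epochs` (30), `batch_size` (16).
#' @param seed Integer seed.
#' @return A trained `toy_cnn`; the per-epoch loss curve is in `$log`.
#' @export
train_toy_model <- function(samples, labels, hyperparams = list(),
                            seed = 1L) {
  labels <- as.character(labels)
  classes <- if (all(labels %in% c("healthy", "glaucoma")))
    c("healthy", "glaucoma") else sort(unique(labels))
  if (length(unique(labels)) < 2) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  if (any(table(factor(labels, classes)) < 2)) {
    stop("training requires at least two samples per class", call. = FALSE)
  }
  hp <- utils::modifyList(list(filters = c(8L, 8L), lr = 3e-3,
                               epochs = 30L, batch_size = 16L),
                          hyperparams)
  imgs <- lapply(samples, as_image_array)
  shp <- dim(imgs[[1]])
  y <- match(labels, classes)
  model <- toy_cnn(shp, hp$filters, seed = seed, classes = classes)
  n <- length(imgs)
  m <- lapply(model$weights, function(w) w * 0)   # Adam first moment
  v <- m                                          # Adam second moment
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  losses <- numeric(hp$epochs)
  withr_seed(seed + 1L, {
    for (ep in seq_len(hp$epochs)) {
      perm <- sample(n)
      ep_loss <- 0
      for (start in seq(1, n, by = hp$batch_size)) {
        batch <- perm[start:min(start + hp$batch_size - 1, n)]
        acc <- NULL
        for (i in batch) {
          fwd <- cnn_forward(model, imgs[[i]])
          onehot <- c(0, 0); onehot[y[i]] <- 1
          ep_loss <- ep_loss - log(max(fwd$probs[y[i]], 1e-12))
          gr <- cnn_backward_weights(model, fwd, fwd$probs - onehot)
          acc <- if (is.null(acc)) gr else
            Map(function(a, b) a + b, acc, gr)
        }
        acc <- lapply(acc, function(g) g / length(batch))
        step <- step + 1
        for (nm in names(acc)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * acc[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * acc[[nm]]^2
          mh <- m[[nm]] / (1 - b1^step)
          vh <- v[[nm]] / (1 - b2^step)
          model$weights[[nm]] <- model$weights[[nm]] -
            hp$lr * mh / (sqrt(vh) + eps)
        }
      }
      losses[ep] <- ep_loss / n
    }
  })
  model$trained <- TRUE
  model$log <- data.frame(epoch = seq_len(hp$epochs), loss = losses)
  model$hyperparams <- hp
  model
}

#' Predicted class labels
#' @param model A model adapter.
#' @param images Image or list of images.
#' @return Character vector of predicted class labels (argmax of the score).
#' @export
predicted_classes <- function(model, images) {
  p <- stats::predict(model, images, type = "logit")
  colnames(p)[max.col(p, ties.method = "first")]
}

#' @export
print.toy_cnn <- function(x, ...) {
  a <- x$arch
  cat(sprintf("toy_cnn: %dx%dx%d input, conv(%d) -> pool -> conv(%d, CAM) -> GAP -> dense(2)\n",
              a$H, a$W, a$C, a$F1, a$F2))
  cat("classes:", paste(x$classes, collapse = ", "),
      "| trained:", x$trained, "\n")
  if (!is.null(x$log)) {
    cat(sprintf("final training loss: %.4f (%d epochs)\n",
                x$log$loss[nrow(x$log)], nrow(x$log)))
  }
  invisible(x)
}
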