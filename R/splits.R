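#' Stratified train/test split with k validation folds
#'
#' Holds out a class-stratified test set (per-class sizes rounded to the
#' nearest integer) and partitions the remaining ids into `k` folds, again
#' stratified by class, yielding `k` (train, validation) pairs.
#'
#' @param manifest Data frame with columns `sample_id` and `label`.
#' @param test_fraction Fraction of each class held out for testing.
#' @param k Number of cross-validation folds (>= 2).
#' @param seed Integer seed.
#' @return An object of class `split_spec`: list with `test_ids`, `folds`
#'   (list of k lists with `train_ids`, `validation_ids`) and `seed`.
#' @export
make_splits <- function(manifest, test_fraction = 0.2, k = 5L, seed = 1L) {
  stopifnot(nrow(manifest) > 0, test_fraction > 0, test_fraction < 1, k >= 2)
  ids <- manifest$sample_id
  labs <- as.character(manifest$label)
  cls <- sort(unique(labs))
  withr_seed(seed, {
    test_ids <- unlist(lapply(cls, function(cl) {
      pool <- ids[labs == cl]
      n_test <- round(test_fraction * length(pool))
      sample(pool, n_test)
    }), use.names = FALSE)
    rest <- setdiff(ids, test_ids)
    rest_labs <- labs[match(rest, ids)]
    if (any(table(rest_labs) < k)) {
      stop("k exceeds the number of non-test samples in some class",
           call. = FALSE)
    }
    fold_of <- integer(length(rest))
    for (cl in cls) {
      sel <- which(rest_labs == cl)
      fold_of[sel] <- sample(rep_len(seq_len(k), length(sel)))
    }
    folds <- lapply(seq_len(k), function(f) {
      list(train_ids = rest[fold_of != f], validation_ids = rest[fold_of == f])
    })
  })
  structure(list(test_ids = sort(test_ids), folds = folds,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Flip a fraction of binary class labels at random
#'
#' Used by the label randomization sanity check: exactly
#' `round(fraction * n)` labels, chosen uniformly at random, are switched
#' to the opposite class.
#'
#' @param labels Character/factor vector with exactly two distinct classes.
#' @param fraction Fraction of labels to flip, in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of the same length with flipped labels.
#' @export
randomize_labels <- function(labels, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("labels must have exactly two classes",
                             call. = FALSE)
  n_flip <- round(fraction * length(labels))
  withr_seed(seed, flip <- sample(length(labels), n_flip))
  labels[flip] <- ifelse(labels[flip] == cls[1], cls[2], cls[1])
  labels
}

#' Balanced accuracy
#'
#' The arithmetic mean of sensitivity (true-positive rate on the positive
#' class) and specificity (true-negative rate).
#'
#' @param predictions Predicted class labels.
#' @param truth True class labels; both classes must be present.
#' @param positive Which label counts as the positive class; defaults to
#'   `"glaucoma"` when present, otherwise the second sorted class.
#' @return Numeric scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(predictions, truth, positive = NULL) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  stopifnot(length(predictions) == length(truth), length(truth) > 0)
  cls <- sort(unique(truth))
  if (length(cls) != 2) {
    stop("both classes must be present in `truth`", call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- if ("glaucoma" %in% cls) "glaucoma" else cls[2]
  }
  negative <- setdiff(cls, positive)
  sens <- mean(predictions[truth == positive] == positive)
  spec <- mean(predictions[truth == negative] == negative)
  (sens + spec) / 2
}
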