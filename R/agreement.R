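#' Bundle per-image discrete saliency maps into an ordered collection
#'
#' A collection fixes the image list and its order so that two collections
#' over the same images can be compared element-wise after vectorization.
#'
#' @param maps List of `discrete_saliency`, one per image, in manifest
#'   order.
#' @param sample_ids Character vector of image ids (same order).
#' @param model_id,method,dataset_id Provenance strings.
#' @return An object of class `discrete_collection`.
#' @export
discrete_collection <- function(maps, sample_ids, model_id = NA_character_,
                                method = NA_character_,
                                dataset_id = NA_character_) {
  stopifnot(length(maps) == length(sample_ids), length(maps) > 0)
  structure(list(maps = maps, sample_ids = as.character(sample_ids),
                 model_id = model_id, method = method,
                 dataset_id = dataset_id),
            class = "discrete_collection")
}

#' Flatten a collection into one score vector
#'
#' Concatenates images in collection (manifest) order and, within each
#' image, the seven sector scores in canonical order; a collection over
#' `n` images yields a vector of length `7 * n` (148 test images give the
#' 1036-element vectors used throughout the agreement analyses).
#'
#' @param x A `discrete_collection`.
#' @return Numeric vector of length `7 * n_images`.
#' @export
to_vector <- function(x) {
  stopifnot(inherits(x, "discrete_collection"))
  as.vector(vapply(x$maps, function(d) unclass(d)[sector_ids()],
                   numeric(7)))
}

#' Spearman rank correlation with a large-sample p-value
#'
#' Pearson correlation of average ranks (the standard tie-aware Spearman
#' coefficient), with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value` and `n`. A constant input yields
#'   `rho = NA` with a warning.
#' @export
spearman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(a)))
  }
  ra <- rank(a); rb <- rank(b)
  rho <- stats::cor(ra, rb)
  n <- length(a)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

# Spearman between two collections over the same image list.
collection_spearman <- function(x, y) {
  if (!identical(x$sample_ids, y$sample_ids)) {
    stop("collections cover different image lists and cannot be compared",
         call. = FALSE)
  }
  spearman(to_vector(x), to_vector(y))
}

#' Pairwise Spearman agreement within a group of collections
#'
#' Computes the rank correlation for every unordered pair of collections
#' (all over the same image list), e.g. the 21 pairs of 7 saliency methods
#' on one model, pairs of folds within an architecture, or pairs of
#' architectures within a fold.
#'
#' @param collections Named list of `discrete_collection` (>= 2); names
#'   label the pair members in the output.
#' @return Data frame with one row per pair: `a`, `b`, `rho`, `p_value`,
#'   `n_elements`. A singleton group returns an empty data frame with a
#'   warning.
#' @export
pairwise_agreement <- function(collections) {
  nms <- names(collections) %||% as.character(seq_along(collections))
  if (length(collections) < 2) {
    warning("fewer than two collections: no pairs to compare")
    return(data.frame(a = character(0), b = character(0),
                      rho = numeric(0), p_value = numeric(0),
                      n_elements = integer(0)))
  }
  pairs <- utils::combn(seq_along(collections), 2)
  out <- apply(pairs, 2, function(ij) {
    s <- collection_spearman(collections[[ij[1]]], collections[[ij[2]]])
    data.frame(a = nms[ij[1]], b = nms[ij[2]], rho = s$rho,
               p_value = s$p_value, n_elements = s$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Five-number summary of agreement coefficients
#' @param results Data frame from [pairwise_agreement()] (or any data frame
#'   with a `rho` column), optionally grouped.
#' @param group Optional column name to group by.
#' @return Data frame with min, q1, median, q3, max of rho per group.
#' @export
agreement_summary <- function(results, group = NULL) {
  split_list <- if (is.null(group)) list(all = results) else
    split(results, results[[group]])
  out <- lapply(names(split_list), function(g) {
    r <- split_list[[g]]$rho
    data.frame(group = g, n_pairs = length(r),
               min = min(r), q1 = unname(stats::quantile(r, 0.25)),
               median = stats::median(r),
               q3 = unname(stats::quantile(r, 0.75)), max = max(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Discretize a test set under one model for several attribution methods
#'
#' Workhorse shared by the sanity checks, the agreement analyses and the
#' pipeline: computes, for each requested method, the sector-discretized
#' saliency map of every image under the given model.
#'
#' @param model A model adapter.
#' @param samples List of `fundus_sample` (or image arrays).
#' @param mask_sets List of `sector_mask_set`, one per sample (see
#'   [build_sector_masks()]).
#' @param methods Character vector of method abbreviations.
#' @param config A [saliency_config()].
#' @param tau Discretization threshold.
#' @param model_id Provenance string.
#' @return Named list (per method) of `discrete_collection`, with an
#'   attribute `predicted` holding the predicted class labels.
#' @export
discretize_model <- function(model, samples, mask_sets,
                             methods = saliency_methods(),
                             config = saliency_config(), tau = 0.75,
                             model_id = "model") {
  stopifnot(length(samples) == length(mask_sets))
  ids <- vapply(seq_along(samples), function(i) {
    if (inherits(samples[[i]], "fundus_sample")) samples[[i]]$sample_id
    else sprintf("img%03d", i)
  }, character(1))
  pred <- predicted_classes(model, samples)
  sg <- intersect(methods, c("SGrad", "SGrad2", "VGrad"))
  rest <- setdiff(methods, sg)
  mode_of <- c(SGrad = "mean", SGrad2 = "squared", VGrad = "variance")
  per_image <- lapply(seq_along(samples), function(i) {
    maps <- list()
    if (length(sg)) {                 # one shared noise loop for the family
      maps[sg] <- smoothgrad_family(model, samples[[i]], config,
                                    unname(mode_of[sg]))[sg]
    }
    for (m in rest) maps[[m]] <- compute_saliency(model, samples[[i]], m,
                                                  config)
    lapply(maps[methods], discretize_saliency, masks = mask_sets[[i]],
           tau = tau)
  })
  out <- lapply(methods, function(m) {
    discrete_collection(lapply(per_image, `[[`, m), ids,
                        model_id = model_id, method = m)
  })
  names(out) <- methods
  attr(out, "predicted") <- pred
  out
}

#' Model-parameter randomization sanity check
#'
#' Compares the sector-discretized saliency of a trained model against that
#' of freshly reinitialized (untrained) copies of the same architecture. A
#' saliency method that genuinely depends on the learned parameters should
#' show low rank correlation between the two; high correlation is grounds
#' for discarding the method.
#'
#' @param trained A trained model adapter supporting [reinitialize()].
#' @param samples,mask_sets Test images and their sector masks.
#' @param methods Method abbreviations to test.
#' @param config A [saliency_config()].
#' @param n_replicates Number of random reinitializations.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param tau Discretization threshold.
#' @return Data frame: `method`, `replicate`, `rho`, `p_value`,
#'   `n_elements`, with class `sanity_fragment` and attribute
#'   `test = "parameter_randomization"`.
#' @export
parameter_randomization_test <- function(trained, samples, mask_sets,
                                         methods = saliency_methods(),
                                         config = saliency_config(),
                                         n_replicates = 5L, seed = 1L,
                                         tau = 0.75) {
  ref <- discretize_model(trained, samples, mask_sets, methods, config,
                          tau, model_id = "trained")
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rnd <- reinitialize(trained, seed = seed + r)
    cur <- discretize_model(rnd, samples, mask_sets, methods, config, tau,
                            model_id = sprintf("random%02d", r))
    for (m in methods) {
      s <- collection_spearman(ref[[m]], cur[[m]])
      rows[[length(rows) + 1]] <- data.frame(method = m, replicate = r,
                                             rho = s$rho,
                                             p_value = s$p_value,
                                             n_elements = s$n,
                                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sanity_fragment", "data.frame")
  attr(out, "test") <- "parameter_randomization"
  out
}

#' Label randomization sanity check
#'
#' Retrains a same-architecture model after flipping a fraction (default
#' 50%) of the training labels and correlates its sector-discretized
#' saliency with the cleanly trained model's. High correlation means the
#' method is insensitive to what the model learned, which is grounds for
#' discarding it.
#'
#' @param trained A trained `toy_cnn` (its hyperparameters are reused).
#' @param train_samples,train_labels The original training data.
#' @param samples,mask_sets Test images and their sector masks.
#' @param methods Method abbreviations to test.
#' @param config A [saliency_config()].
#' @param fraction Fraction of labels to flip; 0 retrains on the untouched
#'   labels (a determinism check: the retrained model is identical).
#' @param seed Integer seed (label choice and retraining).
#' @param tau Discretization threshold.
#' @return Data frame as in [parameter_randomization_test()], attribute
#'   `test = "label_randomization"`. A final-epoch training loss above 0.6
#'   attaches a `convergence_warning` attribute.
#' @export
label_randomization_test <- function(trained, train_samples, train_labels,
                                     samples, mask_sets,
                                     methods = saliency_methods(),
                                     config = saliency_config(),
                                     fraction = 0.5, seed = 1L,
                                     tau = 0.75) {
  flipped <- if (fraction > 0) {
    randomize_labels(train_labels, fraction, seed = seed)
  } else as.character(train_labels)
  corrupted <- train_toy_model(train_samples, flipped,
                               hyperparams = trained$hyperparams %||% list(),
                               seed = trained$seed)
  ref <- discretize_model(trained, samples, mask_sets, methods, config,
                          tau, model_id = "clean")
  cur <- discretize_model(corrupted, samples, mask_sets, methods, config,
                          tau, model_id = "label_randomized")
  rows <- lapply(methods, function(m) {
    s <- collection_spearman(ref[[m]], cur[[m]])
    data.frame(method = m, replicate = 1L, rho = s$rho,
               p_value = s$p_value, n_elements = s$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sanity_fragment", "data.frame")
  attr(out, "test") <- "label_randomization"
  final_loss <- corrupted$log$loss[nrow(corrupted$log)]
  if (is.finite(final_loss) && final_loss > 0.6) {
    attr(out, "convergence_warning") <-
      sprintf("corrupted-label training loss %.3f", final_loss)
  }
  out
}

#' Assemble a sanity report with discard flags
#'
#' A method is flagged for discarding when the median absolute rank
#' correlation in its label-randomization results reaches the threshold
#' (default 0.5), i.e. its saliency maps barely change when the model is
#' trained on scrambled labels.
#'
#' @param param_fragment Result of [parameter_randomization_test()] (may be
#'   `NULL`).
#' @param label_fragment Result of [label_randomization_test()].
#' @param discard_threshold Median |rho| at or above which a method is
#'   flagged.
#' @return An object of class `sanity_report`: list with `parameter`,
#'   `label`, and a `flags` data frame (`method`, `median_abs_rho`,
#'   `discard`, `threshold`).
#' @export
sanity_report <- function(param_fragment = NULL, label_fragment,
                          discard_threshold = 0.5) {
  med <- tapply(abs(label_fragment$rho), label_fragment$method, stats::median)
  flags <- data.frame(method = names(med),
                      median_abs_rho = as.vector(med),
                      discard = as.vector(med) >= discard_threshold,
                      threshold = discard_threshold,
                      stringsAsFactors = FALSE)
  rownames(flags) <- NULL
  structure(list(parameter = param_fragment, label = label_fragment,
                 flags = flags),
            class = "sanity_report")
}

#' @export
print.sanity_report <- function(x, ...) {
  cat("Sanity report (label-randomization discard threshold",
      x$flags$threshold[1], "):\n")
  print(x$flags, row.names = FALSE)
  invisible(x)
}
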