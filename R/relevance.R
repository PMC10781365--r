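#' Sector holding the maximal discrete saliency score
#'
#' Ties are broken by the canonical sector order (N, NI, TI, T, TS, NS, B).
#'
#' @param d A `discrete_saliency` (or named numeric vector in canonical
#'   order).
#' @return Single sector id.
#' @export
argmax_sector <- function(d) {
  v <- unclass(d)[sector_ids()]
  sector_ids()[which.max(v)]
}

#' Global sector-relevance probabilities grouped by predicted class
#'
#' For every group (each predicted class, plus a pooled "both" row), the
#' probability assigned to a sector is the fraction of images in the group
#' whose top discrete saliency score falls in that sector.
#'
#' @param discrete_maps List of `discrete_saliency`, one per image.
#' @param predicted_classes Character vector, the model's predicted class
#'   for each map (same order).
#' @param classes Optional class-level ordering; defaults to
#'   `c("healthy", "glaucoma")` when applicable.
#' @return An object of class `relevance_table`: data.frame with columns
#'   `class`, `n_images` and one column per sector. A class with no images
#'   gets `NA` probabilities and `n_images = 0`.
#' @export
global_relevance <- function(discrete_maps, predicted_classes,
                             classes = NULL) {
  stopifnot(length(discrete_maps) > 0,
            length(discrete_maps) == length(predicted_classes))
  predicted_classes <- as.character(predicted_classes)
  if (is.null(classes)) {
    u <- unique(predicted_classes)
    classes <- if (all(u %in% c("healthy", "glaucoma")))
      c("healthy", "glaucoma") else sort(u)
  }
  tops <- vapply(discrete_maps, argmax_sector, character(1))
  one_row <- function(sel) {
    n <- sum(sel)
    p <- if (n == 0) rep(NA_real_, 7) else
      as.vector(table(factor(tops[sel], sector_ids()))) / n
    c(list(n_images = n), stats::setNames(as.list(p), sector_ids()))
  }
  rows <- c(list(both = one_row(rep(TRUE, length(tops)))),
            stats::setNames(lapply(classes, function(cl)
              one_row(predicted_classes == cl)), classes))
  out <- do.call(rbind, lapply(names(rows), function(nm)
    data.frame(class = nm, rows[[nm]], stringsAsFactors = FALSE)))
  class(out) <- c("relevance_table", "data.frame")
  out
}

#' @export
print.relevance_table <- function(x, digits = 4, ...) {
  cat("Global sector relevance (probability that a sector holds the top",
      "discrete saliency score):\n")
  y <- as.data.frame(x)
  y[sector_ids()] <- lapply(y[sector_ids()], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Format a relevance table as percentages
#' @param x A `relevance_table`.
#' @param digits Decimal places.
#' @return Data frame with sector columns in percent.
#' @export
relevance_as_percent <- function(x, digits = 2) {
  y <- as.data.frame(x)
  y[sector_ids()] <- lapply(y[sector_ids()], function(v) round(100 * v,
                                                               digits))
  y
}
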