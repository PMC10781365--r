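#' Canonical sector identifiers
#'
#' The six anatomical optic-disc sectors plus the background, in the fixed
#' canonical order used for all vectorization and tie-breaking:
#' nasal (N), nasal inferior (NI), temporal inferior (TI), temporal (T),
#' temporal superior (TS), nasal superior (NS), background (B).
#'
#' @return Character vector of length 7.
#' @export
sector_ids <- function() c("N", "NI", "TI", "T", "TS", "NS", "B")

#' Angular sector scheme for the optic disc
#'
#' Defines the half-open angular spans of the six disc sectors, measured in
#' degrees from the temporal horizontal axis of the disc, increasing toward
#' superior. The default follows the standard clinical sectorization of the
#' optic nerve head: temporal 90 deg, temporal superior 40, nasal superior 40,
#' nasal 110, nasal inferior 40, temporal inferior 40. An equal-width
#' 60-degree tiling is available as an alternative.
#'
#' @param style `"garway_heath"` (default) or `"equal"`.
#' @param temporal_side_od Which image side (`"left"` or `"right"`) is
#'   temporal for a right eye (OD); left eyes mirror automatically.
#' @param rim_only If `TRUE`, disc sectors cover only the neuroretinal rim
#'   (disc minus cup) and cup pixels are assigned to the background mask so
#'   the seven masks still partition the image.
#' @return An object of class `sector_scheme` with a `spans` matrix
#'   (columns `start`, `end`; rows the six disc sectors).
#' @export
sector_scheme <- function(style = c("garway_heath", "equal"),
                          temporal_side_od = c("left", "right"),
                          rim_only = FALSE) {
  style <- match.arg(style)
  temporal_side_od <- match.arg(temporal_side_od)
  spans <- if (style == "garway_heath") {
    rbind(N  = c(125, 235),
          NI = c(235, 275),
          TI = c(275, 315),
          T  = c(315, 45),    # wraps through 0
          TS = c(45, 85),
          NS = c(85, 125))
  } else {
    rbind(N  = c(150, 210),
          NI = c(210, 270),
          TI = c(270, 330),
          T  = c(330, 30),
          TS = c(30, 90),
          NS = c(90, 150))
  }
  colnames(spans) <- c("start", "end")
  structure(list(style = style, spans = spans,
                 temporal_side_od = temporal_side_od,
                 rim_only = rim_only),
            class = "sector_scheme")
}

#' Mid-angle of a disc sector
#' @param sector One of the six disc sector ids.
#' @param scheme A [sector_scheme()].
#' @return Angle in degrees in \[0, 360).
#' @export
sector_mid_angle <- function(sector, scheme = sector_scheme()) {
  sp <- scheme$spans[sector, ]
  width <- (sp["end"] - sp["start"]) %% 360
  unname((sp["start"] + width / 2) %% 360)
}

# TRUE where theta (degrees, [0,360)) lies in the half-open arc [start, end),
# with wrap-around through 0.
angle_in_span <- function(theta, start, end) {
  start <- start %% 360; end <- end %% 360
  if (start < end) theta >= start & theta < end
  else theta >= start | theta < end
}

# Anatomical angle (degrees from temporal axis, toward superior) of every
# pixel relative to `center`, given laterality. Vectorized over the image.
pixel_angles <- function(shape, center, laterality,
                         temporal_side_od = "left") {
  H <- shape[1]; W <- shape[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- cols - center[2]
  dy <- rows - center[1]
  sx <- if (temporal_side_od == "left") -1 else 1
  if (laterality == "OS") sx <- -sx
  xt <- sx * dx          # component along the temporal axis
  ys <- -dy              # component toward superior (up in the image)
  (atan2(ys, xt) * 180 / pi) %% 360
}

#' Build the seven sector masks for one annotated image
#'
#' Each disc pixel is assigned to exactly one of the six anatomical sectors
#' by the angle of its offset from the disc center; the background mask B is
#' the complement of the disc. For a left eye the assignment is the
#' horizontal mirror of the right-eye assignment.
#'
#' @param annotation A `disc_cup_annotation`.
#' @param image_shape Length-2 integer (rows, cols).
#' @param scheme A [sector_scheme()].
#' @return An object of class `sector_mask_set`: a named list of 7 logical
#'   masks (canonical order) with attributes `laterality` and `scheme`.
#' @export
build_sector_masks <- function(annotation, image_shape,
                               scheme = sector_scheme()) {
  stopifnot(inherits(annotation, "disc_cup_annotation"))
  disc <- annotation_mask(annotation, image_shape, "disc")
  if (!any(disc)) stop("degenerate disc annotation: empty disc region",
                       call. = FALSE)
  if (all(disc)) stop("disc region covers the whole image", call. = FALSE)
  center <- if (is.list(annotation$disc)) annotation$disc$center else {
    idx <- which(disc, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }
  theta <- pixel_angles(image_shape, center, annotation$laterality,
                        scheme$temporal_side_od)
  region <- disc
  bg <- !disc
  if (isTRUE(scheme$rim_only)) {
    cup <- annotation_mask(annotation, image_shape, "cup")
    region <- disc & !cup
    bg <- bg | cup
  }
  masks <- lapply(rownames(scheme$spans), function(sec) {
    sp <- scheme$spans[sec, ]
    region & angle_in_span(theta, sp["start"], sp["end"])
  })
  names(masks) <- rownames(scheme$spans)
  masks <- c(masks[setdiff(sector_ids(), "B")], list(B = bg))
  structure(masks[sector_ids()], class = "sector_mask_set",
            laterality = annotation$laterality, scheme = scheme$style)
}

#' Threshold a saliency map at a fraction of its maximum
#'
#' Retains pixels whose relevance reaches `tau` times the map maximum. The
#' maximizing pixel is always included, so the mask is never empty.
#' A constant map yields an all-ones mask (every pixel attains the maximum)
#' with a warning.
#'
#' @param S A `saliency_map` or a numeric matrix of finite values.
#' @param tau Threshold fraction, default 0.75.
#' @return Logical matrix, same shape as the map.
#' @export
threshold_saliency <- function(S, tau = 0.75) {
  v <- if (inherits(S, "saliency_map")) S$values else S
  stopifnot(is.matrix(v), all(is.finite(v)), tau > 0, tau <= 1)
  mx <- max(v)
  if (max(v) == min(v)) {
    warning("constant saliency map: threshold mask covers the whole image")
    return(matrix(TRUE, nrow(v), ncol(v)))
  }
  m <- v >= tau * mx
  m[which.max(v)] <- TRUE   # guard: argmax retained even if tau*max > max
  m
}

#' Discretize a saliency map onto the seven sectors
#'
#' The score of each sector is the fraction of above-threshold saliency
#' pixels that fall inside that sector's mask. Because the seven masks
#' partition the image, the scores sum to 1.
#'
#' @param S A `saliency_map` or numeric matrix.
#' @param masks A `sector_mask_set` (or named list of 7 logical masks in
#'   canonical order).
#' @param tau Threshold fraction passed to [threshold_saliency()].
#' @return An object of class `discrete_saliency`: named numeric vector of 7
#'   sector fractions with attributes `method`, `sample_id` and `tau`.
#' @export
discretize_saliency <- function(S, masks, tau = 0.75) {
  v <- if (inherits(S, "saliency_map")) S$values else S
  stopifnot(all(dim(v) == dim(masks[[1]])))
  msal <- threshold_saliency(v, tau)
  n_sal <- sum(msal)
  if (n_sal == 0) stop("empty saliency mask", call. = FALSE)
  scores <- vapply(sector_ids(), function(sec) sum(masks[[sec]] & msal),
                   numeric(1)) / n_sal
  structure(scores, class = "discrete_saliency",
            method = if (inherits(S, "saliency_map")) S$method else NA_character_,
            sample_id = attr(S, "sample_id") %||% NA_character_,
            tau = tau)
}

#' @export
print.discrete_saliency <- function(x, ...) {
  cat("Discrete saliency (tau = ", attr(x, "tau"), ", method = ",
      attr(x, "method"), "):\n", sep = "")
  print(round(stats::setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' Export a sector mask set as a 7-valued label matrix
#'
#' @param masks A `sector_mask_set`.
#' @return Integer matrix with values 1..7 following the canonical sector
#'   order (B = 7).
#' @export
sector_label_matrix <- function(masks) {
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(sector_ids())) lab[masks[[sector_ids()[i]]]] <- i
  lab
}
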