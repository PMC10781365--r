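#' Configuration for the synthetic fundus generator
#'
#' Defines the study conditions under which two-class optic-nerve-head images
#' are simulated. Healthy and glaucomatous eyes differ by the cup-to-disc
#' ratio (CDR) and, optionally, by a sector-localized displacement of the cup
#' that emulates uneven neuroretinal rim loss.
#'
#' @param image_size Side length in pixels of the square disc-centered image.
#' @param disc_radius_range Length-2 numeric, min/max disc semi-major axis in
#'   pixels.
#' @param healthy_cdr_range Length-2 numeric in (0,1), CDR range for the
#'   healthy class.
#' @param glaucoma_cdr_range Length-2 numeric in (0,1), CDR range for the
#'   glaucoma class. When `rim_loss_sector` is `NULL` the lower bound must be
#'   >= the healthy upper bound so the classes are separable by construction.
#' @param rim_loss_sector Optional sector id (one of `sector_ids()` except
#'   "B"): glaucomatous cups are displaced toward this sector's mid-angle.
#' @param rim_loss_strength Fraction in \[0,1\] of the rim width (disc minus
#'   cup semi-axis) by which the cup center is displaced.
#' @param texture_noise_sd Standard deviation (intensity units) of the
#'   background texture noise; 0 gives piecewise-constant images.
#' @param vessel_count Number of dark curvilinear vessels drawn from the disc
#'   center outward.
#' @param laterality_probability Probability that a sample is a right eye
#'   (OD); left eyes (OS) are horizontal mirrors.
#' @param seed Integer seed making generation fully deterministic.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(image_size = 32L,
                             disc_radius_range = c(10, 13),
                             healthy_cdr_range = c(0.25, 0.45),
                             glaucoma_cdr_range = c(0.60, 0.80),
                             rim_loss_sector = NULL,
                             rim_loss_strength = 0,
                             texture_noise_sd = 0.03,
                             vessel_count = 4L,
                             laterality_probability = 0.5,
                             seed = 1L) {
  stopifnot(image_size >= 32, length(disc_radius_range) == 2,
            disc_radius_range[1] <= disc_radius_range[2],
            disc_radius_range[2] < image_size / 2)
  check_cdr <- function(r, name) {
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || any(r >= 1) ||
        r[1] > r[2]) {
      stop("invalid ", name, ": must be within (0,1) with min <= max",
           call. = FALSE)
    }
  }
  check_cdr(healthy_cdr_range, "healthy_cdr_range")
  check_cdr(glaucoma_cdr_range, "glaucoma_cdr_range")
  if (is.null(rim_loss_sector) &&
      glaucoma_cdr_range[1] < healthy_cdr_range[2]) {
    stop("overlapping CDR ranges: glaucoma_cdr_range must lie above ",
         "healthy_cdr_range when no rim_loss_sector is set", call. = FALSE)
  }
  if (!is.null(rim_loss_sector)) {
    rim_loss_sector <- match.arg(rim_loss_sector,
                                 setdiff(sector_ids(), "B"))
  }
  stopifnot(rim_loss_strength >= 0, rim_loss_strength <= 1,
            texture_noise_sd >= 0, vessel_count >= 0,
            laterality_probability >= 0, laterality_probability <= 1)
  structure(list(image_size = as.integer(image_size),
                 disc_radius_range = as.numeric(disc_radius_range),
                 healthy_cdr_range = as.numeric(healthy_cdr_range),
                 glaucoma_cdr_range = as.numeric(glaucoma_cdr_range),
                 rim_loss_sector = rim_loss_sector,
                 rim_loss_strength = rim_loss_strength,
                 texture_noise_sd = texture_noise_sd,
                 vessel_count = as.integer(vessel_count),
                 laterality_probability = laterality_probability,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Rasterize an ellipse into a logical mask
#'
#' Pixel centers sit at integer (row, col) coordinates, origin top-left.
#'
#' @param shape Length-2 integer (rows, cols).
#' @param center Length-2 numeric (row, col) of the ellipse center.
#' @param semi_axes Length-2 numeric (a, b) semi-axes in pixels; `a` lies
#'   along the rotated x (column) axis.
#' @param rotation_deg Rotation in degrees, counter-clockwise in standard
#'   (x right, y up) orientation.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_ellipse <- function(shape, center, semi_axes, rotation_deg = 0) {
  H <- shape[1]; W <- shape[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  x <- cols - center[2]
  y <- -(rows - center[1])            # y increases upward
  th <- rotation_deg * pi / 180
  xr <- cos(th) * x + sin(th) * y
  yr <- -sin(th) * x + cos(th) * y
  (xr / semi_axes[1])^2 + (yr / semi_axes[2])^2 <= 1
}

#' Disc/cup annotation
#'
#' Holds the disc and cup regions anchoring the sector geometry, either as
#' ellipse parameter lists (`center`, `semi_axes`, `rotation`) or as logical
#' masks, plus the eye laterality.
#'
#' @param disc,cup Either a list with elements `center` (row, col),
#'   `semi_axes` (a, b) and `rotation` (degrees), or a logical matrix.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @return An object of class `disc_cup_annotation`.
#' @export
disc_cup_annotation <- function(disc, cup, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  chk <- function(r, name) {
    ok <- (is.list(r) && all(c("center", "semi_axes") %in% names(r))) ||
      (is.matrix(r) && is.logical(r))
    if (!ok) stop(name, " must be an ellipse list or a logical mask",
                  call. = FALSE)
    if (is.list(r) && is.null(r$rotation)) r$rotation <- 0
    r
  }
  structure(list(disc = chk(disc, "disc"), cup = chk(cup, "cup"),
                 laterality = laterality),
            class = "disc_cup_annotation")
}

#' Rasterize the disc or cup region of an annotation
#'
#' @param annotation A `disc_cup_annotation`.
#' @param shape Image shape (rows, cols).
#' @param which `"disc"` or `"cup"`. The cup mask is clipped to the disc so
#'   the containment invariant holds pixel-wise.
#' @return Logical matrix.
#' @export
annotation_mask <- function(annotation, shape, which = c("disc", "cup")) {
  which <- match.arg(which)
  get1 <- function(r) {
    if (is.matrix(r)) {
      stopifnot(all(dim(r) == shape))
      r
    } else {
      rasterize_ellipse(shape, r$center, r$semi_axes, r$rotation %||% 0)
    }
  }
  m <- get1(annotation[[which]])
  if (which == "cup") m <- m & get1(annotation$disc)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direction (drow, dcol) in image coordinates of an anatomical angle theta
# (degrees from the temporal axis, positive toward superior) for the given
# laterality. temporal_side gives which image side is temporal for OD.
anatomical_direction <- function(theta_deg, laterality,
                                 temporal_side_od = "left") {
  th <- theta_deg * pi / 180
  sx <- if (temporal_side_od == "left") -1 else 1
  if (laterality == "OS") sx <- -sx
  c(drow = -sin(th), dcol = sx * cos(th))
}

# Low-frequency texture field via separable box smoothing of white noise.
smooth_noise <- function(H, W, passes = 3L) {
  z <- matrix(stats::rnorm(H * W), H, W)
  k <- rep(1 / 5, 5)
  for (i in seq_len(passes)) {
    z <- apply(z, 2, function(v) stats::filter(v, k, circular = TRUE))
    z <- t(apply(z, 1, function(v) stats::filter(v, k, circular = TRUE)))
  }
  z / stats::sd(z)
}

# Draw one vessel as a jittered radial polyline from the disc center.
draw_vessel <- function(img, center, H, W) {
  ang <- stats::runif(1, 0, 2 * pi)
  curv <- stats::rnorm(1, 0, 0.6)
  len <- max(H, W)
  t <- seq(0, 1, length.out = 4 * len)
  a <- ang + curv * t
  r <- t * len * 0.75
  rr <- round(center[1] + r * sin(a))
  cc <- round(center[2] + r * cos(a))
  keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  idx <- unique(cbind(rr[keep], cc[keep]))
  col <- c(0.35, 0.08, 0.05)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

# Generate one sample in canonical OD frame, then mirror when OS.
synth_one <- function(config, label, laterality, sample_id) {
  H <- W <- config$image_size
  ctr <- c(H, W) / 2 + 0.5
  rd <- stats::runif(1, config$disc_radius_range[1],
                     config$disc_radius_range[2])
  ecc <- stats::runif(1, 0.9, 1)      # near-circular discs
  rot <- stats::runif(1, 0, 180)
  cdr_range <- if (label == "glaucoma") config$glaucoma_cdr_range else
    config$healthy_cdr_range
  cdr <- stats::runif(1, cdr_range[1], cdr_range[2])
  disc <- list(center = ctr, semi_axes = c(rd, rd * ecc), rotation = rot)
  cup_axes <- cdr * disc$semi_axes
  cup_center <- ctr
  if (!is.null(config$rim_loss_sector) && label == "glaucoma" &&
      config$rim_loss_strength > 0) {
    scheme <- sector_scheme()
    mid <- sector_mid_angle(config$rim_loss_sector, scheme)
    dir <- anatomical_direction(mid, "OD", scheme$temporal_side_od)
    shift <- config$rim_loss_strength * (min(disc$semi_axes) - min(cup_axes))
    cup_center <- ctr + shift * dir
  }
  cup <- list(center = cup_center, semi_axes = cup_axes, rotation = rot)

  base <- c(0.72, 0.35, 0.15)         # fundus background (orange-red)
  disc_col <- c(0.93, 0.63, 0.35)     # disc rim, brighter
  cup_col <- c(1.00, 0.85, 0.55)      # cup, brightest
  img <- array(rep(base, each = H * W), dim = c(H, W, 3))
  if (config$texture_noise_sd > 0) {
    tex <- config$texture_noise_sd *
      (0.7 * smooth_noise(H, W) + 0.3 * matrix(stats::rnorm(H * W), H, W))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tex
  }
  dmask <- rasterize_ellipse(c(H, W), disc$center, disc$semi_axes,
                             disc$rotation)
  cmask <- rasterize_ellipse(c(H, W), cup$center, cup$semi_axes,
                             cup$rotation) & dmask
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[dmask] <- disc_col[ch]
    plane[cmask] <- cup_col[ch]
    img[, , ch] <- plane
  }
  if (config$vessel_count > 0) {
    for (v in seq_len(config$vessel_count)) {
      img <- draw_vessel(img, ctr, H, W)
    }
  }
  img <- pmin(pmax(img, 0), 1)

  if (laterality == "OS") {
    img <- mirror_image(img)
    disc <- mirror_ellipse(disc, W)
    cup <- mirror_ellipse(cup, W)
  }
  ann <- disc_cup_annotation(disc, cup, laterality)
  sample <- structure(list(image = img, laterality = laterality,
                           label = label, sample_id = sample_id),
                      class = "fundus_sample")
  list(sample = sample, annotation = ann)
}

#' Mirror an image array horizontally
#' @param img H x W x C array or H x W matrix.
#' @return Array of the same shape with columns reversed.
#' @export
mirror_image <- function(img) {
  if (length(dim(img)) == 3) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  else img[, rev(seq_len(ncol(img))), drop = FALSE]
}

mirror_ellipse <- function(e, W) {
  list(center = c(e$center[1], W + 1 - e$center[2]),
       semi_axes = e$semi_axes,
       rotation = -(e$rotation %||% 0))
}

#' Mirror an annotation horizontally (flipping laterality)
#' @param annotation A `disc_cup_annotation`.
#' @param shape Image shape (rows, cols), needed to mirror coordinates.
#' @return The mirrored `disc_cup_annotation` with opposite laterality.
#' @export
mirror_annotation <- function(annotation, shape) {
  W <- shape[2]
  m1 <- function(r) if (is.matrix(r)) mirror_image(r) else mirror_ellipse(r, W)
  disc_cup_annotation(m1(annotation$disc), m1(annotation$cup),
                      if (annotation$laterality == "OD") "OS" else "OD")
}

#' Generate a synthetic two-class fundus dataset
#'
#' Produces `2 * n_per_class` disc-centered images with paired disc/cup
#' annotations. Glaucomatous samples have larger cup-to-disc ratio and,
#' when `rim_loss_sector` is set in the config, a cup displaced toward that
#' sector. Identical seeds give bit-identical output.
#'
#' @param config A [generator_config()].
#' @param n_per_class Number of samples per class (>= 1).
#' @return List with elements `samples` (list of `fundus_sample`),
#'   `annotations` (list of `disc_cup_annotation`, same order) and
#'   `manifest` (data.frame: sample_id, label, laterality).
#' @export
generate_dataset <- function(config, n_per_class) {
  stopifnot(inherits(config, "generator_config"), n_per_class >= 1)
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c("healthy", "glaucoma"), each = n_per_class)
  ids <- sprintf("s%04d_%s", seq_len(n), substr(labels, 1, 1))
  withr_seed(config$seed, {
    lateralities <- ifelse(stats::runif(n) < config$laterality_probability,
                           "OD", "OS")
    out <- vector("list", n)
    for (i in seq_len(n)) {
      out[[i]] <- synth_one(config, labels[i], lateralities[i], ids[i])
    }
  })
  list(samples = lapply(out, `[[`, "sample"),
       annotations = lapply(out, `[[`, "annotation"),
       manifest = data.frame(sample_id = ids, label = labels,
                             laterality = lateralities,
                             stringsAsFactors = FALSE))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Measured cup-to-disc ratio of an annotation
#'
#' Ratio of the square roots of rasterized cup and disc areas, an
#' area-equivalent diameter ratio usable as a classification feature.
#'
#' @param annotation A `disc_cup_annotation`.
#' @param shape Image shape (rows, cols).
#' @return Numeric scalar in \[0, 1\].
#' @export
measured_cdr <- function(annotation, shape) {
  d <- sum(annotation_mask(annotation, shape, "disc"))
  cu <- sum(annotation_mask(annotation, shape, "cup"))
  sqrt(cu / d)
}
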