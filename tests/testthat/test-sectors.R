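test_that("sector masks are pairwise disjoint and cover the image", {
  set.seed(31)
  for (i in 1:5) {
    ann <- random_annotation(c(32, 32),
                             laterality = sample(c("OD", "OS"), 1))
    masks <- build_sector_masks(ann, c(32, 32))
    total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    expect_true(all(total == 1L))     # disjoint AND covering
    disc <- annotation_mask(ann, c(32, 32), "disc")
    six <- Reduce(`|`, masks[setdiff(sector_ids(), "B")])
    expect_identical(six, disc)       # the six sectors tile the disc
    expect_identical(masks$B, !disc)
  }
})

test_that("sector assignment matches brute-force per-pixel angle classification", {
  ann <- disc_cup_annotation(
    disc = list(center = c(24.5, 24.5), semi_axes = c(20, 20), rotation = 0),
    cup = list(center = c(24.5, 24.5), semi_axes = c(8, 8), rotation = 0),
    laterality = "OD")
  scheme <- sector_scheme()
  masks <- build_sector_masks(ann, c(48, 48), scheme)
  spans <- scheme$spans
  counts <- stats::setNames(integer(7), sector_ids())
  for (r in 1:48) for (cc in 1:48) {
    dx <- cc - 24.5; dy <- r - 24.5
    if (dx^2 + dy^2 > 20^2) { counts["B"] <- counts["B"] + 1L; next }
    # OD, temporal side left: temporal axis points to -x, superior is -y
    th <- (atan2(-dy, -dx) * 180 / pi) %% 360
    for (sec in rownames(spans)) {
      s <- spans[sec, "start"]; e <- spans[sec, "end"]
      inside <- if (s < e) th >= s && th < e else th >= s || th < e
      if (inside) { counts[sec] <- counts[sec] + 1L; break }
    }
  }
  expect_identical(vapply(sector_ids(), function(s) sum(masks[[s]]),
                          integer(1)),
                   counts)
  # and every mask equals the per-pixel classification, not just counts
  expect_identical(sum(masks$T), counts[["T"]])
})

test_that("left-eye masks are the horizontal mirror of right-eye masks", {
  set.seed(33)
  ann_od <- random_annotation(c(32, 32), "OD")
  ann_os <- mirror_annotation(ann_od, c(32, 32))
  m_od <- build_sector_masks(ann_od, c(32, 32))
  m_os <- build_sector_masks(ann_os, c(32, 32))
  for (sec in sector_ids()) {
    expect_identical(m_os[[sec]], mirror_image(m_od[[sec]]))
  }
})

test_that("thresholding keeps pixels at or above 75% of the maximum", {
  S <- matrix(c(1.0, 0.8, 0.74, 0), 2, 2)
  expect_identical(as.vector(threshold_saliency(S, 0.75)),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_warning(m <- threshold_saliency(matrix(1, 3, 3)), "constant")
  expect_true(all(m))
  S2 <- matrix(runif(16), 4, 4)
  m1 <- threshold_saliency(S2, 1.0)
  expect_identical(which(m1), which.max(S2))
})

test_that("discretization equals brute-force pixel counting on random maps", {
  set.seed(35)
  for (rep in 1:5) {
    # a 3-region toy tiling: T, N and B partition a 16x16 image
    half <- matrix(FALSE, 16, 16)
    reg1 <- half; reg1[1:8, ] <- TRUE
    reg2 <- half; reg2[9:16, 1:8] <- TRUE
    reg3 <- !(reg1 | reg2)
    masks <- stats::setNames(rep(list(half), 7), sector_ids())
    masks$T <- reg1; masks$N <- reg2; masks$B <- reg3
    S <- matrix(runif(256), 16, 16)
    d <- discretize_saliency(S, masks, tau = 0.6)
    msal <- S >= 0.6 * max(S)
    expect_equal(d[["T"]], sum(reg1 & msal) / sum(msal))
    expect_equal(d[["N"]], sum(reg2 & msal) / sum(msal))
    expect_equal(d[["B"]], sum(reg3 & msal) / sum(msal))
    expect_equal(sum(d), 1, tolerance = 1e-9)
  }
})

test_that("discretization is invariant to positive rescaling of the map", {
  set.seed(36)
  ann <- random_annotation(c(32, 32))
  masks <- build_sector_masks(ann, c(32, 32))
  S <- matrix(runif(32 * 32), 32, 32)
  d1 <- discretize_saliency(S, masks)
  d2 <- discretize_saliency(37.5 * S, masks)
  expect_identical(unclass(d1), unclass(d2))
})

test_that("a saliency mask confined to one sector scores 1 there", {
  ann <- disc_cup_annotation(
    disc = list(center = c(16.5, 16.5), semi_axes = c(12, 12), rotation = 0),
    cup = list(center = c(16.5, 16.5), semi_axes = c(5, 5), rotation = 0),
    laterality = "OD")
  masks <- build_sector_masks(ann, c(32, 32))
  S <- matrix(0, 32, 32)
  S[which(masks$T)[1:4]] <- 1        # hot pixels strictly inside T
  d <- discretize_saliency(S, masks)
  expect_equal(d[["T"]], 1)
  expect_equal(sum(d), 1)
  # constant map scores each sector by its area fraction
  suppressWarnings(dc <- discretize_saliency(matrix(2, 32, 32), masks))
  expect_equal(dc[["B"]], sum(masks$B) / (32 * 32))
})

test_that("discretization is equivariant under horizontal mirroring", {
  set.seed(38)
  ann <- random_annotation(c(32, 32), "OD")
  masks_od <- build_sector_masks(ann, c(32, 32))
  S <- matrix(runif(32 * 32), 32, 32)
  d_od <- discretize_saliency(S, masks_od)
  ann_os <- mirror_annotation(ann, c(32, 32))
  masks_os <- build_sector_masks(ann_os, c(32, 32))
  d_os <- discretize_saliency(mirror_image(S), masks_os)
  expect_equal(unclass(d_od), unclass(d_os))
})

test_that("rim-only schemes assign cup pixels to the background", {
  ann <- disc_cup_annotation(
    disc = list(center = c(16.5, 16.5), semi_axes = c(12, 12), rotation = 0),
    cup = list(center = c(16.5, 16.5), semi_axes = c(6, 6), rotation = 0),
    laterality = "OD")
  masks <- build_sector_masks(ann, c(32, 32),
                              sector_scheme(rim_only = TRUE))
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_true(all(total == 1L))
  cup <- annotation_mask(ann, c(32, 32), "cup")
  expect_true(all(masks$B[cup]))
})

test_that("degenerate disc annotations are rejected", {
  ann <- disc_cup_annotation(disc = matrix(FALSE, 16, 16),
                             cup = matrix(FALSE, 16, 16), "OD")
  expect_error(build_sector_masks(ann, c(16, 16)), "degenerate")
})
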