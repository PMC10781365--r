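test_that("dataset generation is deterministic and correctly labelled", {
  cfg <- generator_config(seed = 7L)
  a <- generate_dataset(cfg, 10L)
  b <- generate_dataset(cfg, 10L)
  expect_identical(lapply(a$samples, `[[`, "image"),
                   lapply(b$samples, `[[`, "image"))
  expect_identical(a$manifest, b$manifest)
  expect_equal(sum(a$manifest$label == "healthy"), 10L)
  expect_equal(sum(a$manifest$label == "glaucoma"), 10L)
  expect_false(anyDuplicated(a$manifest$sample_id) > 0)
  expect_true(all(vapply(a$samples, function(s)
    all(is.finite(s$image)) && min(s$image) >= 0 && max(s$image) <= 1,
    logical(1))))
})

test_that("cup-to-disc ratios recovered from the rasterized masks respect the configured ranges", {
  cfg <- generator_config(healthy_cdr_range = c(0.2, 0.4),
                          glaucoma_cdr_range = c(0.6, 0.8),
                          vessel_count = 0L, texture_noise_sd = 0,
                          seed = 11L)
  ds <- generate_dataset(cfg, 25L)
  shape <- dim(ds$samples[[1]]$image)[1:2]
  cdr <- vapply(ds$annotations, measured_cdr, numeric(1), shape = shape)
  lab <- ds$manifest$label
  # area-equivalent diameter ratio from the masks, with rasterization slack
  expect_true(all(cdr[lab == "healthy"] > 0.2 - 0.05))
  expect_true(all(cdr[lab == "healthy"] < 0.4 + 0.05))
  expect_true(all(cdr[lab == "glaucoma"] > 0.6 - 0.05))
  expect_true(all(cdr[lab == "glaucoma"] < 0.8 + 0.05))
  # separability: a single CDR threshold classifies the set perfectly
  expect_true(max(cdr[lab == "healthy"]) < min(cdr[lab == "glaucoma"]))
})

test_that("zero-noise zero-vessel images are piecewise constant", {
  cfg <- generator_config(vessel_count = 0L, texture_noise_sd = 0,
                          seed = 3L)
  ds <- generate_dataset(cfg, 2L)
  for (s in ds$samples) {
    for (ch in 1:3) {
      expect_lte(length(unique(as.vector(s$image[, , ch]))), 3L)
    }
  }
})

test_that("rasterized cup is always contained in the disc", {
  cfg <- generator_config(rim_loss_sector = "TI", rim_loss_strength = 1,
                          healthy_cdr_range = c(0.4, 0.6),
                          glaucoma_cdr_range = c(0.4, 0.6), seed = 5L)
  ds <- generate_dataset(cfg, 15L)
  shape <- dim(ds$samples[[1]]$image)[1:2]
  for (a in ds$annotations) {
    disc <- annotation_mask(a, shape, "disc")
    cup <- annotation_mask(a, shape, "cup")
    expect_true(all(disc[cup]))
    expect_gt(sum(disc), 0)
  }
})

test_that("left-eye generation mirrors right-eye generation", {
  base <- list(seed = 21L, vessel_count = 2L)
  od <- generate_dataset(do.call(generator_config,
                                 c(base, laterality_probability = 1)), 5L)
  os <- generate_dataset(do.call(generator_config,
                                 c(base, laterality_probability = 0)), 5L)
  shape <- dim(od$samples[[1]]$image)[1:2]
  for (i in seq_along(od$samples)) {
    expect_identical(os$samples[[i]]$image,
                     mirror_image(od$samples[[i]]$image))
    expect_identical(annotation_mask(os$annotations[[i]], shape, "disc"),
                     mirror_image(annotation_mask(od$annotations[[i]],
                                                  shape, "disc")))
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(healthy_cdr_range = c(0.3, 0.7),
                                glaucoma_cdr_range = c(0.6, 0.8)),
               "overlapping")
  expect_error(generator_config(healthy_cdr_range = c(0, 0.4)),
               "healthy_cdr_range")
  expect_error(generator_config(glaucoma_cdr_range = c(0.6, 1.2)),
               "glaucoma_cdr_range")
  # overlapping ranges are allowed when a rim-loss signal separates classes
  expect_s3_class(generator_config(healthy_cdr_range = c(0.4, 0.6),
                                   glaucoma_cdr_range = c(0.4, 0.6),
                                   rim_loss_sector = "TI",
                                   rim_loss_strength = 0.5),
                  "generator_config")
})
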