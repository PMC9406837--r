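test_that("generation is bitwise reproducible for a fixed spec and seed", {
  spec <- synthetic_spec("separable", image_size = 32L, seed = 7L)
  a <- generate_dataset(spec, n_per_class = 1)
  b <- generate_dataset(spec, n_per_class = 1)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
  expect_identical(a$ids, b$ids)
})

test_that("degenerate generator settings give constant base-colour images", {
  params <- list(
    normal = list(base_color = c(200, 150, 180), blob_density = 0,
                  blob_radius_range = c(2, 4), texture_freq = 0,
                  texture_amp = 0, noise_sd = 0),
    malignant = list(base_color = c(140, 85, 150), blob_density = 0,
                     blob_radius_range = c(2, 4), texture_freq = 0,
                     texture_amp = 0, noise_sd = 0)
  )
  spec <- synthetic_spec(class_params = params, image_size = 16L, seed = 3L)
  ds <- generate_dataset(spec, 1)
  expect_equal(unique(as.numeric(ds$images[[1]][, , 1])), 200)
  expect_equal(unique(as.numeric(ds$images[[1]][, , 2])), 150)
  expect_equal(unique(as.numeric(ds$images[[2]][, , 3])), 150)
})

test_that("malignant preset is darker in the blue channel on average", {
  spec <- synthetic_spec("separable", image_size = 32L, seed = 11L)
  ds <- generate_dataset(spec, n_per_class = 100)
  blue_mean <- function(cl) {
    mean(sapply(ds$images[ds$labels == cl], function(im) mean(im[, , 3])))
  }
  expect_lt(blue_mean("malignant"), blue_mean("normal"))
})

test_that("invalid generator arguments are rejected", {
  spec <- synthetic_spec("separable", image_size = 16L)
  expect_error(generate_dataset(spec, 0), "positive")
  bad <- list(normal = list(base_color = c(1, 1, 1), blob_density = -1,
                            blob_radius_range = c(1, 2), texture_freq = 0,
                            noise_sd = 0),
              malignant = list(base_color = c(1, 1, 1), blob_density = 0,
                               blob_radius_range = c(1, 2), texture_freq = 0,
                               noise_sd = 0))
  expect_error(synthetic_spec(class_params = bad), "blob_density")
})

test_that("PNG write/read round-trip is lossless for integer images", {
  set.seed(1)
  img <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), dim = c(32, 32, 3))
  path <- tempfile(fileext = ".png")
  write_image(img, path)
  expect_equal(read_image(path), img, ignore_attr = TRUE)

  flat <- array(77, dim = c(8, 8, 3))
  path2 <- tempfile(fileext = ".png")
  write_image(flat, path2)
  expect_true(all(read_image(path2) == 77))
})

test_that("reading a nonexistent image fails with the path in the message", {
  expect_error(read_image("/no/such/file.png"), "/no/such/file.png")
})

test_that("manifest round-trip preserves images, ids and labels", {
  spec <- synthetic_spec("separable", image_size = 16L, seed = 2L)
  ds <- generate_dataset(spec, 2)
  dir <- tempfile()
  mf <- write_image_set(ds, dir)
  back <- read_image_set(mf)
  expect_equal(back$ids, ds$ids)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$images[[1]], ds$images[[1]], ignore_attr = TRUE)
})

test_that("wider base-colour separation widens the FCH centroid distance", {
  normal <- list(base_color = c(200, 150, 180), blob_density = 2,
                 blob_radius_range = c(2, 4), texture_freq = 2,
                 texture_amp = 4, noise_sd = 2)
  # hue gaps of ~10, 18 and 24 degrees: within the fuzzy-bin overlap range,
  # where centroid distance still responds to colour separation
  malignant_colors <- list(c(200, 150, 188), c(200, 150, 195), c(200, 150, 200))
  dist_fch <- sapply(malignant_colors, function(col) {
    mal <- normal
    mal$base_color <- col
    spec <- synthetic_spec(class_params = list(normal = normal, malignant = mal),
                           image_size = 24L, seed = 5L)
    ds <- generate_dataset(spec, 8)
    cent <- function(cl) {
      rowMeans(sapply(ds$images[ds$labels == cl], fch_features))
    }
    sqrt(sum((cent("normal") - cent("malignant"))^2))
  })
  expect_true(all(diff(dist_fch) > 0))
})
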