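test_that("mass-free configs give empty annotation and seeding is exact", {
  cfg <- phantom_config(n_slices = 4, height = 32, width = 32, n_masses = 0,
                        seed = 5)
  ph <- generate_phantom(cfg)
  expect_true(all(ph$annotation$mask == 0))
  expect_equal(nrow(ph$annotation$boxes), 0)

  cfg2 <- phantom_config(n_slices = 5, height = 48, width = 48,
                         n_masses = 2, mass_radius_range = c(3, 5), seed = 11)
  a <- generate_phantom(cfg2)
  b <- generate_phantom(cfg2)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$annotation$mask, b$annotation$mask)
})

test_that("flat-background noise follows the Poisson law (mean = variance)", {
  lambda <- 300
  cfg <- phantom_config(n_slices = 2, height = 100, width = 100,
                        n_masses = 0, background_smoothness = Inf,
                        photon_scale = lambda, seed = 3)
  v <- as.numeric(generate_phantom(cfg)$stack$voxels)
  expect_gte(length(v), 1e4)
  expect_lt(abs(mean(v) - lambda) / lambda, 0.05)
  expect_lt(abs(var(v) - lambda) / lambda, 0.05)
})

test_that("mask volume grows with the number of masses and stays in boxes", {
  fracs <- vapply(0:3, function(nm) {
    cfg <- phantom_config(n_slices = 8, height = 80, width = 80,
                          n_masses = nm, mass_radius_range = c(3, 5),
                          seed = 9)
    mean(generate_phantom(cfg)$annotation$mask)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))

  ph <- tiny_phantom(seed = 13, n_masses = 2)
  boxed <- mask_from_boxes(ph$annotation$boxes, dim(ph$annotation$mask))
  expect_true(all(boxed[ph$annotation$mask == 1] == 1))
})

test_that("site profiles define genuinely different acquisition conditions", {
  h1 <- phantom_config(site_profile = "H1")
  h2 <- phantom_config(site_profile = "H2")
  expect_false(h1$mass_contrast == h2$mass_contrast &&
               h1$photon_scale == h2$photon_scale &&
               h1$background_smoothness == h2$background_smoothness)
  expect_error(phantom_config(site_profile = "H9"), "site_profile")
})

test_that("impossible geometry is rejected with the offending parameter", {
  expect_error(generate_phantom(
    phantom_config(n_slices = 4, height = 20, width = 20, n_masses = 1,
                   mass_radius_range = c(8, 9))),
    "mass_radius_range")
  expect_error(phantom_config(mass_radius_range = c(5, 3)),
               "mass_radius_range")
  expect_error(phantom_config(photon_scale = 0), "photon_scale")
})

test_that("box rasterization uses inclusive 0-based bounds", {
  boxes <- data.frame(slice = 0L, x_min = 2L, y_min = 2L,
                      x_max = 4L, y_max = 4L)
  m <- mask_from_boxes(boxes, c(8, 8, 1))
  expect_equal(sum(m), 9)
  expect_equal(sum(mask_from_boxes(boxes[0, ], c(8, 8, 1))), 0)

  two <- rbind(boxes, data.frame(slice = 0L, x_min = 6L, y_min = 6L,
                                 x_max = 7L, y_max = 7L))
  expect_equal(sum(mask_from_boxes(two, c(8, 8, 1))), 9 + 4)
  bad <- data.frame(slice = 0L, x_min = 5L, y_min = 5L,
                    x_max = 9L, y_max = 9L)
  expect_error(mask_from_boxes(bad, c(8, 8, 1)), "bounds")
})
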