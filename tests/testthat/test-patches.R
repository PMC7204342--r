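test_that("grid extraction follows the stride arithmetic and labels", {
  stack <- structure(list(voxels = array(runif(64 * 64), c(64, 64, 1)),
                          pixel_spacing = 1, slice_spacing = 1),
                     class = "slice_stack")
  ps <- extract_patches(stack, NULL, patch_spec(32, 32, stride = 32))
  expect_length(ps$patches, 4)
  expect_equal(unname(ps$grid), c(2, 2))
  expect_true(all(ps$manifest$label == "nonmass"))

  # a patch fully inside the mask is a certain positive
  mask <- array(1L, c(64, 64, 1))
  ann <- structure(list(mask = mask, boxes = NULL), class = "mass_annotation")
  ps2 <- extract_patches(stack, ann, patch_spec(32, 32, stride = 32))
  expect_true(all(ps2$manifest$mass_fraction == 1))
  expect_true(all(ps2$manifest$label == "mass"))

  expect_error(extract_patches(stack, NULL, patch_spec(128, 128)),
               "larger than slice")
})

test_that("padded extraction tiles centre windows over every pixel", {
  ph <- tiny_phantom(seed = 31, n_slices = 3, hw = 48)
  ps <- extract_patches(ph$stack, ph$annotation,
                        patch_spec(28, 28, stride = 12), pad = 8)
  # centre windows: origin o in the padded slice supervises original rows
  # o..o+stride-1; their union must cover 1..48
  covered <- rep(FALSE, 48)
  for (o in unique(ps$manifest$row)) {
    rows <- o:(o + 11)
    covered[rows[rows <= 48]] <- TRUE
  }
  expect_true(all(covered))
  # padded mask carries no invented ground truth: total mass pixels in
  # patch targets of one slice >= mass pixels of that slice
  sl1 <- ps$patches[vapply(ps$patches, function(p) p$origin["slice"] == 1,
                           logical(1))]
  expect_gte(sum(vapply(sl1, function(p) sum(p$target), numeric(1))),
             sum(ph$annotation$mask[, , 1]))
})

test_that("epoch resampling balances classes reproducibly", {
  labels <- c(rep("mass", 10), rep("nonmass", 100))
  s <- epoch_sampler(labels, seed = 2)
  idx <- resample_epoch(s, 1)
  expect_length(idx, 20)
  expect_equal(sum(idx <= 10), 10)
  expect_identical(resample_epoch(s, 1), idx)
  expect_false(identical(resample_epoch(s, 2), idx))

  s3 <- epoch_sampler(c("mass", "mass", "mass", "nonmass", "nonmass",
                        "nonmass"), per_epoch_n = 3, seed = 5)
  draw <- resample_epoch(s3, 4)
  expect_setequal(draw[1:3], 1:3)
  expect_setequal(draw[4:6], 4:6)

  expect_error(epoch_sampler(rep("nonmass", 5)), "mass")
})

test_that("right-angle rotations form the 4-element group and keep labels", {
  ph <- tiny_phantom(seed = 33, n_slices = 3, hw = 48)
  ps <- extract_patches(ph$stack, ph$annotation, patch_spec(24, 24, 24))
  p <- ps$patches[[1]]
  rots <- augment_rotations(p)
  expect_length(rots, 4)
  expect_identical(rots[[1]]$pixels, p$pixels)
  r90 <- rots[[2]]$pixels
  for (i in 1:3) r90 <- dbtseg:::rot90(r90, 1)
  expect_identical(r90, p$pixels)
  for (r in rots) {
    expect_equal(sort(as.numeric(r$pixels)), sort(as.numeric(p$pixels)))
    expect_equal(r$mass_fraction, p$mass_fraction)
    expect_identical(r$label, p$label)
  }
  p$pixels <- p$pixels[, 1:10]
  expect_error(augment_rotations(p), "square")
})

test_that("patch specs validate their invariants", {
  expect_error(patch_spec(4, 4), ">= 8")
  expect_error(patch_spec(16, 16, stride = 0), "stride")
  expect_error(patch_spec(16, 16, mass_fraction_threshold = 2), "threshold")
})
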