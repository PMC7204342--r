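test_that("top-hat of a flat image is zero and output is bounded by [0, I]", {
  expect_equal(max(abs(top_hat_enhance(matrix(7, 40, 40), 3, 8))), 0)

  set.seed(4)
  for (i in 1:5) {
    img <- matrix(rpois(40 * 40, 200), 40, 40)
    out <- top_hat_enhance(img, 3, 8)
    expect_true(all(out >= -1e-9))
    expect_true(all(out <= img + 1e-9))
  }
  expect_error(top_hat_enhance(matrix(1, 10, 10), r_close = 3, r_open = 8),
               "larger than image")
})

test_that("top-hat matches an independent morphology oracle on a toy disc", {
  img <- matrix(10, 32, 32)
  ctr <- expand.grid(r = 1:32, c = 1:32)
  disc <- with(ctr, (r - 16)^2 + (c - 16)^2 <= 3^2)
  img[as.matrix(ctr[disc, ])] <- 60   # bright disc radius 3 < r_open
  out <- top_hat_enhance(img, 2, 6)
  ref <- oracle_tophat(img, 2, 6)
  expect_equal(out, ref, tolerance = 1e-10, ignore_attr = TRUE)
  # disc retains its amplitude, background is suppressed to ~0
  expect_gt(mean(out[as.matrix(ctr[disc, ])]), 45)
  expect_lt(max(out[!disc]), 1e-9)
})

test_that("enhancement raises lesion contrast on the standard phantom", {
  ph <- tiny_phantom(seed = 7, n_slices = 6, hw = 64)
  enh <- preprocess_stack(ph$stack, r_close = 3, r_open = 10)
  m <- ph$annotation$mask
  cnr <- function(v) (mean(v[m == 1]) - mean(v[m == 0])) / sd(v[m == 0])
  expect_gt(cnr(enh$voxels), cnr(ph$stack$voxels))
})

test_that("greedy exclusion selection matches the brute-force oracle", {
  # two marks 3 mm apart with a 5 mm exclusion radius: exactly one survives,
  # whichever is drawn first
  marks <- rbind(c(10, 10), c(10, 16))   # 6 px = 3 mm at 0.5 mm/px
  sel <- select_candidates(marks, exclusion_mm = 5, pixel_spacing = 0.5,
                           seed = 1)
  expect_equal(nrow(sel), 1)
  expect_true(all(oracle_select(marks, 10, c(1, 2)) == 1) &&
              all(oracle_select(marks, 10, c(2, 1)) == 2))

  # marks pairwise farther than the radius: all survive in any order
  far <- as.matrix(expand.grid(c(5, 30, 55), c(5, 30, 55)))
  sel2 <- select_candidates(far, exclusion_mm = 5, pixel_spacing = 0.5,
                            seed = 3)
  expect_equal(nrow(sel2), nrow(far))

  # random clouds: the kept set must be one the oracle can reproduce with
  # some pick order, and must be a maximal exclusion-respecting subset
  set.seed(8)
  for (rep in 1:10) {
    mk <- cbind(runif(12, 1, 50), runif(12, 1, 50))
    kept <- select_candidates(mk, exclusion_mm = 5, pixel_spacing = 1,
                              seed = rep)
    idx <- apply(kept, 1, function(r)
      which(mk[, 1] == r[1] & mk[, 2] == r[2])[1])
    dk <- as.matrix(dist(kept))
    expect_true(all(dk[upper.tri(dk)] > 5))
    excluded <- setdiff(seq_len(nrow(mk)), idx)
    for (e in excluded) {
      d_to_kept <- sqrt((mk[e, 1] - kept[, 1])^2 + (mk[e, 2] - kept[, 2])^2)
      expect_true(any(d_to_kept <= 5))
    }
  }

  expect_equal(nrow(select_candidates(NULL)), 0)
  expect_equal(nrow(select_candidates(matrix(numeric(0), 0, 2))), 0)
})

test_that("constraint field is the closed-form Gaussian envelope", {
  fld <- build_constraint_field(rbind(c(20, 20)), sigma_mm = 5,
                                pixel_spacing = 1, shape = c(40, 40))
  expect_equal(fld$weights[20, 20], 1)
  expect_equal(fld$weights[25, 20], exp(-1 / 2), tolerance = 1e-12)

  two <- build_constraint_field(rbind(c(10, 10), c(10, 44)), sigma_mm = 5,
                                pixel_spacing = 1, shape = c(20, 54))
  expect_equal(two$weights[10, 10], 1)
  expect_equal(two$weights[10, 44], 1)
  expect_lt(two$weights[10, 27], 0.02)

  # order of centres is irrelevant
  swap <- build_constraint_field(rbind(c(10, 44), c(10, 10)), sigma_mm = 5,
                                 pixel_spacing = 1, shape = c(20, 54))
  expect_equal(two$weights, swap$weights)

  none <- build_constraint_field(NULL, sigma_mm = 5, pixel_spacing = 1,
                                 shape = c(8, 8))
  expect_true(all(none$weights == 1))
  expect_error(build_constraint_field(rbind(c(1, 1)), sigma_mm = 0,
                                      pixel_spacing = 1, shape = c(8, 8)),
               "sigma")
})

test_that("constraint application is a plain elementwise product", {
  img <- matrix(rpois(64, 50), 8, 8)
  ones <- build_constraint_field(NULL, 5, 1, c(8, 8))
  expect_equal(apply_constraint(img, ones), img)
  zero <- ones; zero$weights[] <- 0
  expect_true(all(apply_constraint(img, zero) == 0))
  fld <- build_constraint_field(rbind(c(4, 4)), 2, 1, c(8, 8))
  expect_equal(apply_constraint(img * 3, fld),
               3 * apply_constraint(img, fld))
  expect_error(apply_constraint(matrix(1, 4, 4), fld), "mismatch")
})
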