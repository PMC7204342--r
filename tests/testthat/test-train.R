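make_train_fixture <- function(seed = 31) {
  ph <- tiny_phantom(seed = seed, n_slices = 3, hw = 48)
  pset <- extract_patches(ph$stack, ph$annotation,
                          patch_spec(28, 28, stride = 12), pad = 8)
  net <- build_unet(unet_spec(depth = 2, base_channels = 2))
  list(ph = ph, pset = pset, net = net)
}

test_that("training respects the epoch budget and is seed-reproducible", {
  fx <- make_train_fixture()
  cfg <- train_config(max_epochs = 2, augment = FALSE, per_epoch_n = 3,
                      seed = 5)
  m1 <- train_unet(fx$net, fx$pset, cfg)
  m2 <- train_unet(fx$net, fx$pset, cfg)
  expect_lte(length(m1$loss_trace), 2)
  expect_equal(m1$loss_trace, m2$loss_trace, tolerance = 1e-12)
  expect_identical(m1$params, m2$params)
  expect_true(all(m1$loss_trace >= 0 & m1$loss_trace <= 1))
})

test_that("an all-background dataset trains at the constant degenerate loss", {
  ph0 <- generate_phantom(phantom_config(n_slices = 3, height = 48,
                                         width = 48, n_masses = 0,
                                         seed = 4))
  ps <- extract_patches(ph0$stack, ph0$annotation,
                        patch_spec(28, 28, stride = 12), pad = 8)
  net <- build_unet(unet_spec(depth = 2, base_channels = 2))
  expect_warning(
    m <- train_unet(net, ps, train_config(max_epochs = 3, per_epoch_n = 4,
                                          augment = FALSE, seed = 1)),
    "single class")
  expect_equal(m$loss_trace, rep(1, 3))
})

test_that("prediction assembles a full probability volume with patch votes", {
  fx <- make_train_fixture()
  m <- train_unet(fx$net, fx$pset,
                  train_config(max_epochs = 2, augment = FALSE,
                               per_epoch_n = 3, seed = 5))
  pr <- predict_heatmap(m, fx$ph$stack)
  expect_equal(dim(pr$heatmap), dim(fx$ph$stack$voxels))
  expect_true(all(pr$heatmap >= 0 & pr$heatmap <= 1))
  expect_equal(pr$preds$p_nonmass + pr$preds$p_mass,
               rep(1, nrow(pr$preds)))
  expect_equal(nrow(pr$preds),
               prod(pr$grid) * dim(fx$ph$stack$voxels)[3])
  pr2 <- predict_heatmap(m, fx$ph$stack)
  expect_identical(pr$heatmap, pr2$heatmap)
})

test_that("patches below the network minimum are rejected", {
  fx <- make_train_fixture()
  small <- extract_patches(fx$ph$stack, fx$ph$annotation,
                           patch_spec(12, 12, stride = 12))
  expect_error(train_unet(fx$net, small, train_config(max_epochs = 1)),
               "inadmissible")
})

test_that("training configuration validates the recipe parameters", {
  expect_error(train_config(learning_rate = -1), "learning_rate")
  expect_error(train_config(max_epochs = 0), "max_epochs")
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 2e-4)
  expect_equal(cfg$max_epochs, 150L)
  expect_equal(cfg$beta, 1)
  expect_equal(cfg$batch_size, 1L)
})
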