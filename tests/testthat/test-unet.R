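test_that("default architecture has the canonical 23-layer census", {
  net <- build_unet(unet_spec())
  expect_equal(sum(net$census), 23)
  expect_equal(unname(net$census["conv3"]), 18)
  expect_equal(unname(net$census["upconv"]), 4)
  expect_equal(unname(net$census["conv1"]), 1)

  down <- net$layers[grepl("^down.*conv2$", net$layers$name), ]
  expect_equal(down$c_out, c(64, 128, 256, 512, 1024))
})

test_that("size map matches the layer-by-layer arithmetic oracle", {
  # independent oracle: walk the layer sequence explicitly
  oracle_size <- function(depth, n) {
    for (l in seq_len(depth - 1)) {
      n <- n - 2 - 2
      if (n < 2 || n %% 2 != 0) return(NA)
      n <- n / 2
    }
    n <- n - 4
    if (n < 1) return(NA)
    for (l in seq_len(depth - 1)) {
      n <- n * 2
      n <- n - 4
      if (n < 1) return(NA)
    }
    n
  }
  s5 <- unet_spec()
  expect_equal(unet_output_size(s5, 572), 388L)
  for (d in c(2, 3, 5)) {
    sp <- unet_spec(depth = d, base_channels = 4)
    got <- unet_output_size(sp, 8:600)
    want <- vapply(8:600, function(n) oracle_size(d, n), numeric(1))
    expect_equal(as.numeric(got), want)
  }
  expect_error(build_unet(unet_spec(depth = 1)), "depth")
})

test_that("forward pass yields per-pixel probability simplexes, deterministically", {
  spec <- unet_spec(depth = 2, base_channels = 2)
  net <- build_unet(spec)
  params <- unet_init(net, seed = 3)
  n <- net$min_input
  x <- matrix(runif(n * n), n, n)
  fw1 <- dbtseg:::unet_forward(net, params, x)
  fw2 <- dbtseg:::unet_forward(net, params, x)
  expect_identical(fw1$probs, fw2$probs)
  sums <- fw1$probs[, , 1] + fw1$probs[, , 2]
  expect_equal(sums, matrix(1, nrow(sums), ncol(sums)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(fw1$probs >= 0 & fw1$probs <= 1))
  expect_error(dbtseg:::unet_forward(net, params, matrix(0, 7, 7)),
               "minimum valid")
})

test_that("analytic network gradients agree with finite differences", {
  set.seed(9)
  spec <- unet_spec(depth = 2, base_channels = 2)
  net <- build_unet(spec)
  params <- unet_init(net, seed = 42)
  n <- net$min_input
  osz <- unet_output_size(spec, n)
  x <- matrix(runif(n * n), n, n)
  target <- matrix(rbinom(osz * osz, 1, 0.4), osz, osz)
  fw <- dbtseg:::unet_forward(net, params, x, keep_cache = TRUE)
  glog <- dbtseg:::loss_logit_grad(fw$probs, target, 1)
  grads <- dbtseg:::unet_backward(net, params, fw$cache, glog)
  eps <- 1e-6
  for (nm in c("down1_conv1", "down2_conv2", "up1", "exp1_conv2", "final")) {
    for (rep in 1:3) {
      i <- sample(length(params[[nm]]$w), 1)
      pp <- params
      pp[[nm]]$w[i] <- pp[[nm]]$w[i] + eps
      up <- fbeta_loss(dbtseg:::unet_forward(net, pp, x)$probs[, , 2], target)
      pp[[nm]]$w[i] <- pp[[nm]]$w[i] - 2 * eps
      dn <- fbeta_loss(dbtseg:::unet_forward(net, pp, x)$probs[, , 2], target)
      num <- (up - dn) / (2 * eps)
      expect_equal(grads[[nm]]$w[i], num, tolerance = 1e-4)
    }
  }
})

test_that("Xavier-normal initialization is seeded and zero-biased", {
  net <- build_unet(unet_spec(depth = 2, base_channels = 4))
  p1 <- unet_init(net, seed = 7)
  p2 <- unet_init(net, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(vapply(p1, function(l) all(l$b == 0), logical(1))))
  w <- p1$down1_conv1$w
  expect_equal(sd(w), sqrt(2 / (9 * 1 + 9 * 4)), tolerance = 0.5)
})
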