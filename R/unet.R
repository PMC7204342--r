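#' U-Net architecture parameters
#'
#' The classic valid-convolution (unpadded) encoder-decoder: a contracting
#' path of \code{depth} levels, each applying two 3x3 convolutions + ReLU and
#' (except at the bottom) 2x2 max pooling with stride 2, doubling the channel
#' count per level; an expansive path of 2x2 up-convolutions that halve the
#' channels, concatenation with the centre-cropped contracting feature map,
#' and two further 3x3 convolutions + ReLU; and a final 1x1 convolution onto
#' \code{n_classes} with a softmax head. At the default depth 5 / base 64
#' this yields exactly 23 convolutional layers (18 of 3x3, 4 up-convolutions,
#' 1 of 1x1).
#'
#' @param depth number of resolution levels including the bottleneck
#'   (default 5).
#' @param base_channels feature channels at the first level (default 64).
#' @param n_classes output classes (default 2: nonmass, mass).
#' @param in_channels input image channels (default 1, grayscale).
#' @return a \code{unet_spec}.
#' @export
unet_spec <- function(depth = 5L, base_channels = 64L, n_classes = 2L,
                      in_channels = 1L) {
  if (depth < 2) stop("depth must be >= 2")
  if (base_channels < 1) stop("base_channels must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 conv_kernel = 3L, pool = 2L, upconv_kernel = 2L),
            class = "unet_spec")
}

# Ordered layer plan: one row per convolutional layer with channel counts.
unet_plan <- function(spec) {
  d <- spec$depth
  ch <- spec$base_channels * 2^(seq_len(d) - 1L)
  rows <- list()
  add <- function(name, kind, cin, cout)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, kind = kind,
                                             c_in = cin, c_out = cout)
  cin <- spec$in_channels
  for (l in seq_len(d)) {
    add(paste0("down", l, "_conv1"), "conv3", cin, ch[l])
    add(paste0("down", l, "_conv2"), "conv3", ch[l], ch[l])
    cin <- ch[l]
  }
  for (l in seq(d - 1L, 1L)) {
    add(paste0("up", l), "upconv", ch[l + 1L], ch[l])
    add(paste0("exp", l, "_conv1"), "conv3", 2L * ch[l], ch[l])
    add(paste0("exp", l, "_conv2"), "conv3", ch[l], ch[l])
  }
  add("final", "conv1", ch[1], spec$n_classes)
  do.call(rbind, rows)
}

#' Build a U-Net network description
#'
#' Constructs the layer census and size arithmetic of the network without
#' allocating weights (see \code{\link{unet_init}} for that).
#'
#' @param spec a \code{\link{unet_spec}}.
#' @return a \code{unet} object with elements \code{spec}, \code{layers}
#'   (ordered layer table), \code{census} (layer counts by kind) and
#'   \code{min_input} (smallest admissible square input size).
#' @export
build_unet <- function(spec = unet_spec()) {
  layers <- unet_plan(spec)
  census <- table(layers$kind)
  net <- structure(list(spec = spec, layers = layers,
                        census = c(conv3 = unname(census["conv3"]),
                                   upconv = unname(census["upconv"]),
                                   conv1 = unname(census["conv1"])),
                        min_input = NA_integer_),
                   class = "unet")
  net$min_input <- unet_min_input(spec)
  net
}

#' @export
print.unet <- function(x, ...) {
  cat("U-Net (valid convolutions), depth", x$spec$depth,
      "- base", x$spec$base_channels, "channels\n")
  cat("  convolutional layers:", sum(x$census), "(",
      x$census[["conv3"]], "x 3x3,", x$census[["upconv"]],
      "x 2x2 up-conv,", x$census[["conv1"]], "x 1x1 )\n")
  cat("  minimum square input:", x$min_input, "px\n")
  invisible(x)
}

#' Input-to-output size arithmetic of the valid-convolution U-Net
#'
#' Each valid 3x3 convolution subtracts 2 per axis, each 2x2 pool halves
#' (requiring an even size), each up-convolution doubles. Returns \code{NA}
#' when the input size is inadmissible (an intermediate dimension would be
#' odd before pooling or below 1).
#'
#' @param spec a \code{\link{unet_spec}}.
#' @param input square input size in pixels (vectorized).
#' @return output size(s), \code{NA} where inadmissible.
#' @export
unet_output_size <- function(spec, input) {
  vapply(input, function(n) {
    d <- spec$depth
    for (l in seq_len(d - 1L)) {
      n <- n - 4L
      if (n < 2L || n %% 2L) return(NA_integer_)
      n <- n %/% 2L
    }
    n <- n - 4L                      # bottleneck convolutions
    if (n < 1L) return(NA_integer_)
    for (l in seq_len(d - 1L)) {
      n <- 2L * n - 4L               # up-convolution then two convolutions
      if (n < 1L) return(NA_integer_)
    }
    as.integer(n)
  }, integer(1))
}

#' @rdname unet_output_size
#' @export
unet_min_input <- function(spec) {
  for (n in 8:1000) if (!is.na(unet_output_size(spec, n))) return(as.integer(n))
  stop("no admissible input size found below 1000 px")
}

#' Initialize U-Net weights
#'
#' Kernel weights use the Xavier (Glorot) normal heuristic,
#' \eqn{sd = \sqrt{2/(fan_{in}+fan_{out})}} with fans counted over kernel
#' taps times channels; all biases start at zero.
#'
#' @param net a \code{\link{build_unet}} object.
#' @param seed RNG seed; initialization is reproducible.
#' @return named list of parameters (\code{w}, \code{b} per layer).
#' @export
unet_init <- function(net, seed = 1L) {
  with_seed(seed, {
    params <- list()
    for (i in seq_len(nrow(net$layers))) {
      ly <- net$layers[i, ]
      k <- switch(ly$kind, conv3 = 3L, conv1 = 1L, upconv = 2L)
      if (ly$kind == "upconv") {
        fan_in <- ly$c_in; fan_out <- 4L * ly$c_out
        w <- matrix(rnorm(ly$c_in * 4L * ly$c_out,
                          sd = sqrt(2 / (fan_in + fan_out))),
                    ly$c_in, 4L * ly$c_out)
      } else {
        fan_in <- k * k * ly$c_in; fan_out <- k * k * ly$c_out
        w <- matrix(rnorm(k * k * ly$c_in * ly$c_out,
                          sd = sqrt(2 / (fan_in + fan_out))),
                    k * k * ly$c_in, ly$c_out)
      }
      params[[ly$name]] <- list(w = w, b = numeric(ly$c_out), kind = ly$kind)
    }
    params
  })
}

relu <- function(x) relu_cube(x)

cat_channels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# Forward pass. Returns per-pixel class probabilities (softmax over the
# channel axis) and, when keep_cache, everything backward needs.
unet_forward <- function(net, params, x, keep_cache = FALSE) {
  spec <- net$spec
  d <- spec$depth
  x <- as_cube(x)
  if (is.na(unet_output_size(spec, dim(x)[1])) ||
      is.na(unet_output_size(spec, dim(x)[2])))
    stop("inadmissible input size ", dim(x)[1], "x", dim(x)[2],
         "; minimum valid square input is ", net$min_input)
  cache <- list(input = x)
  skips <- vector("list", d - 1L)
  h <- x
  for (l in seq_len(d)) {
    for (m in 1:2) {
      nm <- sprintf("down%d_conv%d", l, m)
      pre <- conv2d_forward(h, params[[nm]]$w, params[[nm]]$b, 3L, 3L)
      if (keep_cache) cache[[nm]] <- list(x = h, pre = pre)
      h <- relu(pre)
    }
    if (l < d) {
      skips[[l]] <- h
      mp <- maxpool2_forward(h)
      if (keep_cache) cache[[paste0("pool", l)]] <- list(idx = mp$idx,
                                                         dims = dim(h))
      h <- mp$y
    }
  }
  for (l in seq(d - 1L, 1L)) {
    nm <- paste0("up", l)
    if (keep_cache) cache[[nm]] <- list(x = h)
    h <- upconv2_forward(h, params[[nm]]$w, params[[nm]]$b)
    s <- center_crop(skips[[l]], dim(h)[1:2])
    if (keep_cache) cache[[paste0("cat", l)]] <-
      list(skip_dims = dim(skips[[l]]), n_skip = dim(s)[3])
    h <- cat_channels(s, h)
    for (m in 1:2) {
      nm <- sprintf("exp%d_conv%d", l, m)
      pre <- conv2d_forward(h, params[[nm]]$w, params[[nm]]$b, 3L, 3L)
      if (keep_cache) cache[[nm]] <- list(x = h, pre = pre)
      h <- relu(pre)
    }
  }
  if (keep_cache) cache$final <- list(x = h)
  logits <- conv2d_forward(h, params$final$w, params$final$b, 1L, 1L)
  # softmax over the class axis, numerically stabilized
  K <- dim(logits)[3]
  mx <- logits[, , 1]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, logits[, , k])
  ex <- exp(logits - as.vector(mx))
  tot <- ex[, , 1]
  for (k in seq_len(K)[-1]) tot <- tot + ex[, , k]
  probs <- ex / as.vector(tot)
  if (keep_cache) cache$skips <- skips
  list(probs = probs, logits = logits, cache = if (keep_cache) cache)
}

# Backward pass from the gradient w.r.t. the logits. Returns gradients in
# the same shape as params.
unet_backward <- function(net, params, cache, glogits) {
  d <- net$spec$depth
  grads <- list()
  bw <- conv2d_backward(cache$final$x, params$final$w, glogits, 1L, 1L)
  grads$final <- list(w = bw$gw, b = as.numeric(bw$gb))
  g <- bw$gx
  pending_skip <- vector("list", d - 1L)
  for (l in seq_len(d - 1L)) {                 # reverse of expansive order
    for (m in 2:1) {
      nm <- sprintf("exp%d_conv%d", l, m)
      g <- g * (cache[[nm]]$pre > 0)
      bw <- conv2d_backward(cache[[nm]]$x, params[[nm]]$w, g, 3L, 3L)
      grads[[nm]] <- list(w = bw$gw, b = as.numeric(bw$gb))
      g <- bw$gx
    }
    ct <- cache[[paste0("cat", l)]]
    n_skip <- ct$n_skip
    gskip <- g[, , seq_len(n_skip), drop = FALSE]
    gup <- g[, , -seq_len(n_skip), drop = FALSE]
    pending_skip[[l]] <- center_uncrop(gskip, ct$skip_dims)
    nm <- paste0("up", l)
    bw <- upconv2_backward(cache[[nm]]$x, params[[nm]]$w, gup)
    grads[[nm]] <- list(w = bw$gw, b = as.numeric(bw$gb))
    g <- bw$gx
  }
  for (l in seq(d, 1L)) {                      # reverse of contracting order
    if (l < d) {
      pl <- cache[[paste0("pool", l)]]
      g <- maxpool2_backward(g, pl$idx, pl$dims[1], pl$dims[2], pl$dims[3])
      g <- g + pending_skip[[l]]
    }
    for (m in 2:1) {
      nm <- sprintf("down%d_conv%d", l, m)
      g <- g * (cache[[nm]]$pre > 0)
      bw <- conv2d_backward(cache[[nm]]$x, params[[nm]]$w, g, 3L, 3L)
      grads[[nm]] <- list(w = bw$gw, b = as.numeric(bw$gb))
      g <- bw$gx
    }
  }
  grads
}
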