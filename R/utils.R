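#' @useDynLib dbtseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif quantile sd median setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a per-stage / per-epoch seed from a global seed. Keeps results in
# 32-bit integer range so set.seed() accepts them.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 131 + 17) %% 2147483629)
}

#' Rotate a matrix by a multiple of 90 degrees (counter-clockwise)
#'
#' @param m numeric matrix.
#' @param k number of quarter turns (0-3).
#' @return the rotated matrix.
#' @keywords internal
rot90 <- function(m, k = 1L) {
  k <- as.integer(k) %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

# Crop the spatial centre of a (H, W) or (H, W, C) array to size `target`
# (length-2). Margins must be even on both sides or split floor/ceil.
center_crop <- function(x, target) {
  d <- dim(x)
  mr <- d[1] - target[1]
  mc <- d[2] - target[2]
  stopifnot(mr >= 0, mc >= 0)
  r0 <- floor(mr / 2) + 1L
  c0 <- floor(mc / 2) + 1L
  if (length(d) == 2) {
    x[r0:(r0 + target[1] - 1L), c0:(c0 + target[2] - 1L), drop = FALSE]
  } else {
    x[r0:(r0 + target[1] - 1L), c0:(c0 + target[2] - 1L), , drop = FALSE]
  }
}

# Place `g` (H, W[, C]) into the spatial centre of a zero array of dims `d`.
center_uncrop <- function(g, d) {
  out <- array(0, d)
  dg <- dim(g)
  r0 <- floor((d[1] - dg[1]) / 2) + 1L
  c0 <- floor((d[2] - dg[2]) / 2) + 1L
  if (length(d) == 2) {
    out[r0:(r0 + dg[1] - 1L), c0:(c0 + dg[2] - 1L)] <- g
  } else {
    out[r0:(r0 + dg[1] - 1L), c0:(c0 + dg[2] - 1L), ] <- g
  }
  out
}

# Mirror-pad a matrix (reflection without repeating the edge pixel).
mirror_pad <- function(m, top, bottom, left, right) {
  refl <- function(n, before, after) {
    idx <- seq_len(n)
    pre <- if (before > 0) rev(seq_len(before) + 1L) else integer(0)
    post <- if (after > 0) n - seq_len(after) else integer(0)
    c(pmin(pmax(pre, 1L), n), idx, pmin(pmax(post, 1L), n))
  }
  m[refl(nrow(m), top, bottom), refl(ncol(m), left, right), drop = FALSE]
}

stack_dims <- function(stack) dim(stack$voxels)

is_binary_volume <- function(x) {
  is.array(x) && length(dim(x)) == 3 && all(x %in% c(0, 1))
}
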