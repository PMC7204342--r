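#' Patch extraction parameters
#'
#' @param patch_h,patch_w patch dimensions in pixels (>= 8).
#' @param stride grid stride in pixels (>= 1). A stride no larger than the
#'   patch size guarantees the grid covers every pixel.
#' @param mass_fraction_threshold fraction of mask-positive pixels at or
#'   above which a patch is labelled \code{"mass"}; default 0.05, so a patch
#'   clipped by a single boundary pixel still counts as background.
#' @return a \code{patch_spec} list.
#' @export
patch_spec <- function(patch_h = 128L, patch_w = 128L, stride = patch_h,
                       mass_fraction_threshold = 0.05) {
  if (patch_h < 8 || patch_w < 8) stop("patch dimensions must be >= 8")
  if (stride < 1) stop("stride must be >= 1")
  if (mass_fraction_threshold < 0 || mass_fraction_threshold > 1)
    stop("mass_fraction_threshold must lie in [0, 1]")
  structure(list(patch_h = as.integer(patch_h), patch_w = as.integer(patch_w),
                 stride = as.integer(stride),
                 mass_fraction_threshold = mass_fraction_threshold),
            class = "patch_spec")
}

#' Extract a regular grid of labelled axial patches from a stack
#'
#' Tiles every slice with \code{patch_h x patch_w} windows at the given
#' stride. Each patch records its origin, its fraction of mask-positive
#' pixels, its class label (\code{"mass"} iff the fraction reaches the
#' threshold), and the aligned mask crop used as the dense training target.
#'
#' @param stack a \code{slice_stack}.
#' @param annotation a \code{mass_annotation} (or \code{NULL} for unlabeled
#'   extraction; labels then default to \code{"nonmass"}).
#' @param spec a \code{\link{patch_spec}}.
#' @param pad optional mirror-pad margin in pixels (default 0). For training
#'   a valid-convolution network whose supervised output window is the patch
#'   centre, set \code{pad} to the network margin (input - output) / 2 and
#'   \code{stride} to the output size: slices are then mirror-padded so the
#'   centre windows tile every pixel, matching the prediction tiling. Masks
#'   are zero-padded (mirrored border pixels carry no ground truth).
#' @return a \code{patch_set}: list with \code{patches} (list of
#'   \code{dbt_patch}), \code{manifest} data frame (slice, row, col,
#'   grid_row, grid_col, label, mass_fraction) and \code{grid} = c(rows,
#'   cols) of the per-slice patch grid. Origins are coordinates in the
#'   (padded, when \code{pad > 0}) slice.
#' @export
extract_patches <- function(stack, annotation, spec, pad = 0L) {
  v <- stack$voxels
  d <- dim(v)
  if (spec$patch_h > d[1] + 2 * pad || spec$patch_w > d[2] + 2 * pad)
    stop("patch larger than slice (", spec$patch_h, "x", spec$patch_w,
         " vs ", d[1], "x", d[2], ")")
  mask <- if (is.null(annotation)) array(0L, d) else annotation$mask
  if (pad > 0L) {
    n_gr <- ceiling(d[1] / spec$stride)
    n_gc <- ceiling(d[2] / spec$stride)
    pb <- pad + n_gr * spec$stride - d[1] + (spec$patch_h - 2L * pad -
                                             spec$stride)
    pr <- pad + n_gc * spec$stride - d[2] + (spec$patch_w - 2L * pad -
                                             spec$stride)
    vp <- array(0, c(d[1] + pad + pb, d[2] + pad + pr, d[3]))
    mp <- array(0L, dim(vp))
    for (k in seq_len(d[3])) {
      vp[, , k] <- mirror_pad(v[, , k], pad, pb, pad, pr)
      mp[pad + seq_len(d[1]), pad + seq_len(d[2]), k] <- mask[, , k]
    }
    v <- vp; mask <- mp; d <- dim(v)
    r0 <- (seq_len(n_gr) - 1L) * spec$stride + 1L
    c0 <- (seq_len(n_gc) - 1L) * spec$stride + 1L
  } else {
    r0 <- seq(1L, d[1] - spec$patch_h + 1L, by = spec$stride)
    c0 <- seq(1L, d[2] - spec$patch_w + 1L, by = spec$stride)
  }
  patches <- vector("list", length(r0) * length(c0) * d[3])
  man <- vector("list", length(patches))
  n <- 0L
  for (k in seq_len(d[3]))
    for (gj in seq_along(c0))
      for (gi in seq_along(r0)) {
        n <- n + 1L
        rows <- r0[gi]:(r0[gi] + spec$patch_h - 1L)
        cols <- c0[gj]:(c0[gj] + spec$patch_w - 1L)
        px <- v[rows, cols, k]
        mk <- mask[rows, cols, k]
        mf <- mean(mk)
        lab <- if (mf >= spec$mass_fraction_threshold) "mass" else "nonmass"
        patches[[n]] <- structure(
          list(pixels = px, target = mk,
               origin = c(slice = k, row = r0[gi], col = c0[gj]),
               label = lab, mass_fraction = mf),
          class = "dbt_patch")
        man[[n]] <- data.frame(slice = k, row = r0[gi], col = c0[gj],
                               grid_row = gi, grid_col = gj, label = lab,
                               mass_fraction = mf)
      }
  structure(list(patches = patches, manifest = do.call(rbind, man),
                 grid = c(rows = length(r0), cols = length(c0))),
            class = "patch_set")
}

#' Balanced per-epoch patch sampler
#'
#' Clinical mass pixels are a small minority, so training draws the same
#' number of patches from each class pool at every epoch. The draw is
#' without replacement when the pool is large enough, with replacement
#' otherwise (so a tiny minority pool is oversampled rather than fatal).
#'
#' @param labels character vector of patch labels ("mass"/"nonmass").
#' @param per_epoch_n patches per class per epoch; default the minority pool
#'   size.
#' @param seed base seed; each epoch derives its own stream from it.
#' @return an \code{epoch_sampler}.
#' @export
epoch_sampler <- function(labels, per_epoch_n = NULL, seed = 1L) {
  pools <- split(seq_along(labels), factor(labels, c("mass", "nonmass")))
  for (cl in names(pools))
    if (!length(pools[[cl]]))
      stop("empty class pool: no '", cl, "' patches available")
  if (is.null(per_epoch_n)) per_epoch_n <- min(lengths(pools))
  structure(list(pools = pools, per_epoch_n = as.integer(per_epoch_n),
                 seed = as.integer(seed)),
            class = "epoch_sampler")
}

#' Draw one epoch's balanced patch indices
#'
#' @param sampler an \code{\link{epoch_sampler}}.
#' @param epoch epoch index (>= 1); the draw is reproducible given
#'   (seed, epoch) and differs across epochs.
#' @return integer vector of 2 * per_epoch_n patch indices (mass first).
#' @export
resample_epoch <- function(sampler, epoch) {
  with_seed(derive_seed(sampler$seed, paste0("epoch", epoch)), {
    unlist(lapply(sampler$pools, function(pool) {
      n <- sampler$per_epoch_n
      pool[sample.int(length(pool), n, replace = n > length(pool))]
    }), use.names = FALSE)
  })
}

#' Right-angle rotation augmentation of a patch
#'
#' Returns the four rotations (0, 90, 180, 270 degrees) of a square patch.
#' The dense training target, when present, is rotated identically; the
#' class label and mass fraction are invariant (rotation permutes pixels).
#' Translations are deliberately not offered: a translated patch is a
#' different patch with a possibly different label.
#'
#' @param patch a \code{dbt_patch}.
#' @return list of 4 \code{dbt_patch} objects.
#' @export
augment_rotations <- function(patch) {
  if (nrow(patch$pixels) != ncol(patch$pixels))
    stop("rotation augmentation requires square patches")
  lapply(0:3, function(k) {
    p <- patch
    p$pixels <- rot90(patch$pixels, k)
    if (!is.null(patch$target)) p$target <- rot90(patch$target, k)
    p$rotation <- 90L * k
    p
  })
}
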