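#' Top-hat contrast enhancement of a DBT slice
#'
#' Enhances candidate mass regions against background fibroglandular texture
#' with the morphological residue
#' \deqn{I_{tophat} = I - \min(\mathrm{open}(\mathrm{close}(I, s_c), s_o),\, I),}
#' where \eqn{s_c} and \eqn{s_o} are disc structuring elements. Closing with
#' a small disc bridges background texture; opening with a disc larger than a
#' mass removes the mass from the background estimate, so the residue keeps
#' mass-sized structures and suppresses everything larger. The output is
#' pixel-wise bounded by \eqn{[0, I]}.
#'
#' @param image 2D nonnegative intensity matrix.
#' @param r_close radius (px) of the closing disc; default 15.
#' @param r_open radius (px) of the opening disc; default 40. Should exceed
#'   the expected mass radius in pixels.
#' @return enhanced matrix of the same dimensions.
#' @export
top_hat_enhance <- function(image, r_close = 15L, r_open = 40L) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stop("top_hat_enhance expects nonnegative intensities")
  if (r_close < 1 || r_open < 1) stop("structuring element radii must be >= 1")
  if (2 * max(r_close, r_open) + 1 > min(dim(image)))
    stop("structuring element larger than image")
  kc <- EBImage::makeBrush(2L * as.integer(r_close) + 1L, shape = "disc")
  ko <- EBImage::makeBrush(2L * as.integer(r_open) + 1L, shape = "disc")
  # grayscale morphology operates in [0, 1]; rescaling commutes with
  # min/max filters, so normalize, transform, and scale back
  mx <- max(image)
  if (mx == 0) return(image * 0)
  im01 <- image / mx
  bg <- EBImage::opening(EBImage::closing(im01, kc), ko)
  out <- (im01 - pmin(bg, im01)) * mx
  out[out < 0] <- 0
  matrix(as.numeric(out), nrow(image), ncol(image))
}

#' Greedy exclusion-radius thinning of candidate mark locations
#'
#' Repeatedly draws one location uniformly at random from the remaining pool,
#' keeps it, and discards every pool location (itself included) within
#' \code{exclusion_mm} of it, until the pool is empty. This is the mark
#' selection step preceding construction of the constraint field: it spaces
#' candidate centres at least one exclusion radius apart.
#'
#' @param marks n x 2 matrix of (row, col) pixel locations (1-based).
#' @param exclusion_mm exclusion radius in mm (default 5).
#' @param pixel_spacing mm/px used to convert the radius to pixels.
#' @param seed RNG seed making the greedy order reproducible.
#' @return matrix of selected (row, col) locations, a subset of \code{marks}.
#' @export
select_candidates <- function(marks, exclusion_mm = 5, pixel_spacing = 1,
                              seed = 1L) {
  if (is.null(marks) || NROW(marks) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  marks <- as.matrix(marks)
  r_px <- exclusion_mm / pixel_spacing
  with_seed(seed, {
    pool <- seq_len(nrow(marks))
    keep <- integer(0)
    while (length(pool)) {
      pick <- pool[sample.int(length(pool), 1L)]
      keep <- c(keep, pick)
      d <- sqrt((marks[pool, 1] - marks[pick, 1])^2 +
                (marks[pool, 2] - marks[pick, 2])^2)
      pool <- pool[d > r_px]
    }
  })
  out <- marks[sort(keep), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Radial-basis constraint field around candidate centres
#'
#' Builds the multiplicative attenuation field: at pixel \eqn{p} the weight is
#' the maximum over centres \eqn{c} of the isotropic Gaussian
#' \eqn{\exp(-\|p-c\|^2_{mm} / (2\sigma^2))}, peak value 1 at each centre.
#' With no centres the field is all ones (no suppression).
#'
#' @param centers m x 2 matrix of (row, col) pixel locations.
#' @param sigma_mm RBF scale in mm (default 5).
#' @param pixel_spacing mm/px.
#' @param shape c(height, width) of the target slice.
#' @return a \code{constraint_field} list with \code{weights} matrix in
#'   [0, 1], \code{sigma_mm} and \code{centers}.
#' @export
build_constraint_field <- function(centers, sigma_mm = 5, pixel_spacing = 1,
                                   shape) {
  if (sigma_mm <= 0) stop("sigma_mm must be > 0")
  w <- matrix(1, shape[1], shape[2])
  if (!is.null(centers) && NROW(centers) > 0) {
    centers <- as.matrix(centers)
    w <- matrix(0, shape[1], shape[2])
    rr <- seq_len(shape[1]); cc <- seq_len(shape[2])
    for (i in seq_len(nrow(centers))) {
      d2 <- outer((rr - centers[i, 1])^2, rep(1, shape[2])) +
            outer(rep(1, shape[1]), (cc - centers[i, 2])^2)
      d2 <- d2 * pixel_spacing^2
      w <- pmax(w, exp(-d2 / (2 * sigma_mm^2)))
    }
  }
  structure(list(weights = w, sigma_mm = sigma_mm, centers = centers),
            class = "constraint_field")
}

#' Apply a constraint field to a slice
#'
#' Element-wise product of the image with the field's weights.
#'
#' @param image 2D matrix.
#' @param field a \code{constraint_field}.
#' @return attenuated image.
#' @export
apply_constraint <- function(image, field) {
  w <- if (inherits(field, "constraint_field")) field$weights else field
  if (!all(dim(image) == dim(w))) stop("shape mismatch between image and field")
  image * w
}

#' Default candidate marks: bright local maxima of the enhanced slice
#'
#' Pixels that equal the maximum of their 3x3 neighbourhood and exceed the
#' given intensity quantile of the slice.
#'
#' @param image 2D matrix (typically top-hat enhanced).
#' @param q quantile cut, default 0.99.
#' @return n x 2 matrix of (row, col) locations.
#' @export
find_candidate_marks <- function(image, q = 0.99) {
  thr <- quantile(image, q)
  if (thr <= 0) thr <- .Machine$double.eps
  locmax <- image == EBImage::dilate(image, matrix(1L, 3L, 3L)) & image >= thr
  which(locmax, arr.ind = TRUE)
}

#' Enhance a full stack slice-by-slice
#'
#' Runs the 2D enhancement chain on every slice: top-hat transform, candidate
#' mark detection (or user-supplied marks), greedy exclusion-radius
#' selection, RBF constraint field, multiplicative suppression.
#'
#' @param stack a \code{slice_stack}.
#' @param r_close,r_open disc radii (px) of the top-hat structuring elements.
#' @param sigma_mm RBF scale in mm.
#' @param exclusion_mm exclusion radius for candidate selection in mm.
#' @param marks optional list (one entry per slice) of (row, col) mark
#'   matrices; when \code{NULL}, marks default to bright local maxima of the
#'   enhanced slice.
#' @param seed RNG seed for the greedy selection.
#' @return a \code{slice_stack} of enhanced intensities.
#' @export
preprocess_stack <- function(stack, r_close = 15L, r_open = 40L,
                             sigma_mm = 5, exclusion_mm = 5, marks = NULL,
                             seed = 1L) {
  v <- stack$voxels
  out <- array(0, dim(v))
  for (k in seq_len(dim(v)[3])) {
    enh <- top_hat_enhance(v[, , k], r_close, r_open)
    mk <- if (is.null(marks)) find_candidate_marks(enh) else marks[[k]]
    sel <- select_candidates(mk, exclusion_mm, stack$pixel_spacing,
                             seed = derive_seed(seed, paste0("slice", k)))
    fld <- build_constraint_field(sel, sigma_mm, stack$pixel_spacing, dim(enh))
    out[, , k] <- apply_constraint(enh, fld)
  }
  structure(list(voxels = out, pixel_spacing = stack$pixel_spacing,
                 slice_spacing = stack$slice_spacing),
            class = "slice_stack")
}
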