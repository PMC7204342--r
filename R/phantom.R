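#' Phantom generation parameters
#'
#' Assembles the full parameter set for the synthetic DBT phantom generator.
#' A phantom emulates a reconstructed tomosynthesis slice stack: a smooth
#' textured fibroglandular background, a small number of low-contrast
#' ellipsoidal masses, and Poisson photon noise applied voxel-wise. Two named
#' site profiles (\code{"H1"}, \code{"H2"}) bundle contrast/texture/dose
#' presets so cross-site experiments have genuinely different source
#' distributions.
#'
#' @param n_slices number of reconstructed slices (clinical stacks carry
#'   50-80; the test-scale default is 12).
#' @param height,width slice dimensions in pixels.
#' @param pixel_spacing in-plane spacing in mm/px.
#' @param slice_spacing distance between slices in mm (default 1).
#' @param n_masses number of lesions to insert.
#' @param mass_radius_range ordered positive interval of in-plane lesion
#'   semi-axis lengths, in mm; the default 4-8 mm matches the 8-16 mm
#'   diameters typical of screening-detected masses. The through-plane
#'   semi-axis is drawn from the same range but capped by the stack
#'   thickness, so lesions in thin test stacks are oblate.
#' @param mass_contrast relative intensity lift of a lesion over the local
#'   background (e.g. 0.4 = 40\% brighter at the lesion core).
#' @param background_smoothness Gaussian correlation length of the background
#'   texture, in px; \code{Inf} gives a perfectly flat background.
#' @param photon_scale mean photon count of the background; the Poisson rate
#'   field is this scale times the (unit-mean) texture.
#' @param site_profile \code{"H1"}, \code{"H2"}, or \code{NULL} for explicit
#'   parameters. A profile overrides \code{mass_contrast},
#'   \code{background_smoothness} and \code{photon_scale}.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return a \code{phantom_config} list.
#' @export
phantom_config <- function(n_slices = 12L, height = 128L, width = 128L,
                           pixel_spacing = 0.5, slice_spacing = 1.0,
                           n_masses = 2L, mass_radius_range = c(4, 8),
                           mass_contrast = 0.4, background_smoothness = 8,
                           photon_scale = 400, site_profile = NULL,
                           seed = 1L) {
  if (!is.null(site_profile)) {
    preset <- switch(site_profile,
      H1 = list(mass_contrast = 0.40, background_smoothness = 8,
                photon_scale = 400),
      H2 = list(mass_contrast = 0.55, background_smoothness = 12,
                photon_scale = 250),
      stop("unknown site_profile: ", site_profile, " (use \"H1\" or \"H2\")"))
    mass_contrast <- preset$mass_contrast
    background_smoothness <- preset$background_smoothness
    photon_scale <- preset$photon_scale
  }
  cfg <- list(n_slices = as.integer(n_slices), height = as.integer(height),
              width = as.integer(width), pixel_spacing = pixel_spacing,
              slice_spacing = slice_spacing, n_masses = as.integer(n_masses),
              mass_radius_range = as.numeric(mass_radius_range),
              mass_contrast = mass_contrast,
              background_smoothness = background_smoothness,
              photon_scale = photon_scale,
              site_profile = site_profile, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_slices < 1L) stop("n_slices must be >= 1")
  if (cfg$pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  if (length(cfg$mass_radius_range) != 2 ||
      any(cfg$mass_radius_range <= 0) ||
      diff(cfg$mass_radius_range) < 0)
    stop("mass_radius_range must be a positive ordered interval")
  if (cfg$photon_scale <= 0) stop("photon_scale must be > 0")
  invisible(cfg)
}

# Unit-mean smooth random texture for one slice.
background_texture <- function(h, w, smoothness) {
  if (is.infinite(smoothness)) return(matrix(1, h, w))
  noise <- matrix(rnorm(h * w), h, w)
  r <- min(2L * ceiling(3 * smoothness) + 1L,
           2L * floor((min(h, w) - 1L) / 2L) + 1L)
  sm <- EBImage::gblur(noise, sigma = smoothness, radius = r)
  sm <- sm / stats::sd(sm) * 0.15
  pmax(1 + sm - mean(sm), 0.05)
}

#' Generate a synthetic DBT phantom with ground truth
#'
#' Builds a slice stack of Poisson photon counts over a textured background
#' with \code{n_masses} brighter ellipsoidal lesions (Gaussian-feathered
#' edges), together with the exact lesion mask and the per-slice 2D bounding
#' boxes that mimic the weak radiologist annotation of clinical DBT data.
#'
#' @param config a \code{\link{phantom_config}}.
#' @return a list with elements \code{stack} (class \code{slice_stack}:
#'   \code{voxels} array of dim (height, width, n_slices), spacings) and
#'   \code{annotation} (class \code{mass_annotation}: binary \code{mask}
#'   congruent with the stack and a \code{boxes} data frame with 0-based
#'   inclusive bounds \code{slice, x_min, y_min, x_max, y_max}, where x is the
#'   row coordinate and y the column coordinate).
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  cfg <- config
  h <- cfg$height; w <- cfg$width; ns <- cfg$n_slices
  r_px_max <- cfg$mass_radius_range[2] / cfg$pixel_spacing
  r_sl_min <- cfg$mass_radius_range[1] / cfg$slice_spacing
  if (cfg$n_masses > 0 && 2 * r_px_max + 4 >= min(h, w))
    stop("mass_radius_range too large for the volume: ",
         "a mass of in-plane radius ", cfg$mass_radius_range[2],
         " mm cannot fit inside ", h, "x", w, " at pixel_spacing ",
         cfg$pixel_spacing)
  # through-plane semi-axis cap: the lesion must fit the stack depth
  c_cap <- (ns - 2) / 2
  if (cfg$n_masses > 0 && c_cap < 0.5)
    stop("n_slices too small to contain a mass: need at least 3 slices")

  with_seed(cfg$seed, {
    rate <- array(0, c(h, w, ns))
    for (k in seq_len(ns))
      rate[, , k] <- background_texture(h, w, cfg$background_smoothness)

    mask <- array(0L, c(h, w, ns))
    for (m in seq_len(cfg$n_masses)) {
      a <- runif(1, cfg$mass_radius_range[1], cfg$mass_radius_range[2])
      b <- runif(1, cfg$mass_radius_range[1], cfg$mass_radius_range[2])
      cmm <- runif(1, cfg$mass_radius_range[1], cfg$mass_radius_range[2])
      a_px <- a / cfg$pixel_spacing; b_px <- b / cfg$pixel_spacing
      c_sl <- min(cmm / cfg$slice_spacing, c_cap)
      cx <- runif(1, a_px + 2, h - a_px - 1)
      cy <- runif(1, b_px + 2, w - b_px - 1)
      cz <- runif(1, 1 + c_sl * 0.5, ns - c_sl * 0.5)
      dr <- outer((seq_len(h) - cx) / a_px, rep(1, w))
      dc <- outer(rep(1, h), (seq_len(w) - cy) / b_px)
      for (k in seq_len(ns)) {
        dz <- (k - cz) / c_sl
        d <- sqrt(dr^2 + dc^2 + dz^2)
        inside <- d <= 1
        feather <- exp(-(pmax(d - 1, 0) / 0.15)^2)
        lift <- cfg$mass_contrast * ifelse(inside, 1, feather)
        rate[, , k] <- rate[, , k] * (1 + lift)
        mask[, , k] <- as.integer(mask[, , k] | inside)
      }
    }
    voxels <- array(as.numeric(rpois(length(rate),
                                     rate * cfg$photon_scale)),
                    dim = dim(rate))
  })

  stack <- structure(list(voxels = voxels,
                          pixel_spacing = cfg$pixel_spacing,
                          slice_spacing = cfg$slice_spacing),
                     class = "slice_stack")
  annotation <- structure(list(mask = mask, boxes = boxes_from_mask(mask)),
                          class = "mass_annotation")
  list(stack = stack, annotation = annotation)
}

# Per-slice bounding boxes of a 3D binary mask; 0-based inclusive bounds,
# x = row, y = column.
boxes_from_mask <- function(mask) {
  rows <- list()
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k]
    if (!any(sl > 0)) next
    # box each 2D connected region separately so disjoint masses on one
    # slice get separate weak labels
    lab <- EBImage::bwlabel(sl)
    for (id in seq_len(max(lab))) {
      idx <- which(lab == id, arr.ind = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        slice = k - 1L,
        x_min = min(idx[, 1]) - 1L, y_min = min(idx[, 2]) - 1L,
        x_max = max(idx[, 1]) - 1L, y_max = max(idx[, 2]) - 1L)
    }
  }
  if (!length(rows))
    return(data.frame(slice = integer(0), x_min = integer(0),
                      y_min = integer(0), x_max = integer(0),
                      y_max = integer(0)))
  do.call(rbind, rows)
}

#' Rasterize weak bounding-box annotation into a binary volume
#'
#' Boxes use the package-wide convention: 0-based inclusive pixel bounds in
#' (row, column) order, one box per slice entry.
#'
#' @param boxes data frame with columns \code{slice, x_min, y_min, x_max,
#'   y_max}.
#' @param shape volume dimensions \code{c(height, width, n_slices)}.
#' @return binary array of dimension \code{shape}.
#' @export
mask_from_boxes <- function(boxes, shape) {
  mask <- array(0L, shape)
  if (nrow(boxes) == 0) return(mask)
  if (any(boxes$x_min < 0 | boxes$y_min < 0 |
          boxes$x_max >= shape[1] | boxes$y_max >= shape[2] |
          boxes$slice < 0 | boxes$slice >= shape[3] |
          boxes$x_min > boxes$x_max | boxes$y_min > boxes$y_max))
    stop("box outside volume bounds or degenerate")
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    mask[(b$x_min + 1L):(b$x_max + 1L),
         (b$y_min + 1L):(b$y_max + 1L), b$slice + 1L] <- 1L
  }
  mask
}
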