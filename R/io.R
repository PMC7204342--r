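#' Write a slice stack to disk
#'
#' Two on-disk forms are supported. \code{format = "tiff"} writes a single
#' multi-page 16-bit TIFF; integer-valued stacks (e.g. phantom photon counts)
#' up to 65535 round-trip losslessly. \code{format = "jpeg"} writes a
#' directory of 8-bit JPEG slices named \code{slice_0000.jpg, ...} whose
#' lexicographic order is the slice order. Both forms carry a JSON sidecar
#' (\code{<path>.json} or \code{<dir>/metadata.json}) recording the min-max
#' rescale applied, so intensities are recoverable on read, plus the pixel
#' and slice spacings.
#'
#' @param stack a \code{slice_stack}.
#' @param path output file (tiff) or directory (jpeg).
#' @param format \code{"tiff"} or \code{"jpeg"}.
#' @param quality JPEG quality in (0, 1]; default 0.95.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, format = c("tiff", "jpeg"),
                        quality = 0.95) {
  format <- match.arg(format)
  v <- stack$voxels
  lossless <- all(v == round(v)) && max(v) <= 65535 && min(v) >= 0
  if (format == "tiff" && lossless) {
    offset <- 0; scale <- 65535
  } else {
    offset <- min(v); scale <- max(v) - min(v)
    if (scale == 0) scale <- 1
  }
  meta <- list(format = format, offset = offset, scale = scale,
               n_slices = dim(v)[3],
               pixel_spacing = stack$pixel_spacing,
               slice_spacing = stack$slice_spacing)
  scaled <- (v - offset) / scale
  if (format == "tiff") {
    pages <- lapply(seq_len(dim(v)[3]), function(k) scaled[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(dim(v)[3]))
      jpeg::writeJPEG(scaled[, , k],
                      file.path(path, sprintf("slice_%04d.jpg", k - 1L)),
                      quality = quality)
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a slice stack written by \code{\link{write_stack}}
#'
#' @param path a multi-page TIFF file or a directory of JPEG slices.
#' @return a \code{slice_stack}.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    metaf <- file.path(path, "metadata.json")
    if (!file.exists(metaf)) stop("missing sidecar metadata.json in ", path)
    meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
    files <- sort(list.files(path, pattern = "\\.jpe?g$", full.names = TRUE))
    if (!length(files)) stop("no JPEG slices found in ", path)
    pages <- lapply(files, function(f) {
      m <- jpeg::readJPEG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    })
  } else {
    metaf <- paste0(path, ".json")
    if (!file.exists(metaf)) stop("missing sidecar ", metaf)
    meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed slice shapes on read: slices are not congruent")
  v <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) v[, , k] <- pages[[k]]
  v <- v * meta$scale + meta$offset
  if (meta$format == "tiff" && meta$offset == 0 && meta$scale == 65535)
    v <- round(v)
  structure(list(voxels = v, pixel_spacing = meta$pixel_spacing,
                 slice_spacing = meta$slice_spacing),
            class = "slice_stack")
}

#' Write / read a binary mask volume as per-slice PNGs
#'
#' Slices are stored as 0/255 grayscale PNGs named \code{mask_0000.png, ...}.
#'
#' @param mask 3D binary array.
#' @param path output directory.
#' @return \code{path} invisibly (write); binary array (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_binary_volume(mask))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(dim(mask)[3]))
    png::writePNG(matrix(as.numeric(mask[, , k]), dim(mask)[1]),
                  file.path(path, sprintf("mask_%04d.png", k - 1L)))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  files <- sort(list.files(path, pattern = "^mask_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no mask PNGs found in ", path)
  pages <- lapply(files, png::readPNG)
  v <- array(0L, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) v[, , k] <- as.integer(pages[[k]] > 0.5)
  v
}

#' Write / read weak bounding-box annotation as CSV
#'
#' Column layout \code{slice,x_min,y_min,x_max,y_max}; 0-based inclusive
#' bounds, x = row, y = column.
#'
#' @param boxes box data frame.
#' @param path CSV path.
#' @export
write_boxes <- function(boxes, path) {
  write.csv(boxes[, c("slice", "x_min", "y_min", "x_max", "y_max")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes
#' @export
read_boxes <- function(path) read.csv(path)

#' Cache a patch set as a multi-page TIFF plus a CSV manifest
#'
#' Patch pixel data goes to \code{patches.tiff} (16-bit, min-max rescaled,
#' scale recorded in \code{cache.json}), targets to \code{targets.tiff},
#' and the manifest (origin, label, mass fraction) to \code{manifest.csv}.
#'
#' @param patch_set an \code{\link{extract_patches}} result.
#' @param path cache directory (created).
#' @return \code{path} invisibly (write); a \code{patch_set} (read).
#' @export
write_patch_cache <- function(patch_set, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  px <- lapply(patch_set$patches, `[[`, "pixels")
  lo <- min(vapply(px, min, numeric(1)))
  hi <- max(vapply(px, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(px, function(m) (m - lo) / scale),
                  file.path(path, "patches.tiff"), bits.per.sample = 16L,
                  reduce = FALSE)
  tiff::writeTIFF(lapply(patch_set$patches,
                         function(p) matrix(as.numeric(p$target),
                                            nrow(p$target))),
                  file.path(path, "targets.tiff"), bits.per.sample = 8L,
                  reduce = FALSE)
  write.csv(patch_set$manifest, file.path(path, "manifest.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            grid = as.list(patch_set$grid)),
                       file.path(path, "cache.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_patch_cache
#' @export
read_patch_cache <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "cache.json"),
                              simplifyVector = TRUE)
  px <- tiff::readTIFF(file.path(path, "patches.tiff"), all = TRUE)
  tg <- tiff::readTIFF(file.path(path, "targets.tiff"), all = TRUE)
  man <- read.csv(file.path(path, "manifest.csv"))
  patches <- lapply(seq_along(px), function(i) {
    structure(list(pixels = px[[i]] * meta$scale + meta$offset,
                   target = matrix(as.integer(tg[[i]] > 0.5), nrow(tg[[i]])),
                   origin = c(slice = man$slice[i], row = man$row[i],
                              col = man$col[i]),
                   label = man$label[i],
                   mass_fraction = man$mass_fraction[i]),
              class = "dbt_patch")
  })
  structure(list(patches = patches, manifest = man,
                 grid = c(rows = meta$grid$rows, cols = meta$grid$cols)),
            class = "patch_set")
}

#' Save / load a trained model checkpoint
#'
#' Weights and optimizer-free model state are serialized with R's native
#' format; a JSON sidecar records the architecture and training
#' configuration for inspection without deserializing.
#'
#' @param model a \code{unet_model}.
#' @param path checkpoint file (e.g. \code{model.rds}).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(spec = unclass(model$net$spec),
                            config = unclass(model$config),
                            norm_center = model$norm_center,
                            norm_scale = model$norm_scale,
                            epochs_run = length(model$loss_trace)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
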