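#' Threshold a probability heatmap into a binary volume
#'
#' A voxel is foreground iff its mass probability is at or above the
#' threshold.
#'
#' @param heatmap 3D array of probabilities in [0, 1].
#' @param threshold cut in [0, 1]; default 0.5.
#' @return 3D integer binary array.
#' @export
binarize <- function(heatmap, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  out <- array(0L, dim(heatmap))
  out[heatmap >= threshold] <- 1L
  out
}

#' Remove small connected clusters from a binary segmentation
#'
#' Small spurious clusters in the raw per-pixel segmentation are false
#' positives: connected components (26-connectivity in 3D by default) whose
#' voxel count is strictly less than \code{min_voxels} are set to
#' background; surviving clusters are untouched. The default of 50 voxels
#' is the volumetric false-positive cut of the reference pipeline.
#'
#' @param mask 3D binary array.
#' @param min_voxels minimum surviving cluster size (strict "less than"
#'   removal rule; a cluster of exactly \code{min_voxels} is kept).
#' @param connectivity 26 (default, includes diagonals) or 6 (faces only).
#' @return a \code{label_volume}: list with the filtered binary \code{mask}
#'   and a \code{cluster_table} data frame (cluster_id, voxels) of
#'   survivors, ids contiguous from 1.
#' @export
remove_small_clusters <- function(mask, min_voxels = 50L, connectivity = 26L) {
  if (!is_binary_volume(mask)) stop("input mask must be a 3D binary volume")
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  labels <- label_components_3d(mask, connectivity)
  out <- array(0L, dim(mask))
  keep_sizes <- integer(0)
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0])
    keep <- which(sizes >= min_voxels)
    relabel <- integer(length(sizes))
    relabel[keep] <- seq_along(keep)
    pos <- labels > 0
    out[pos] <- as.integer(relabel[labels[pos]] > 0)
    keep_sizes <- sizes[keep]
  }
  structure(list(mask = out,
                 cluster_table = data.frame(
                   cluster_id = seq_along(keep_sizes),
                   voxels = keep_sizes)),
            class = "label_volume")
}

# Label the connected components of a binary volume.
label_components_3d <- function(mask, connectivity = 26L) {
  lab <- label_components_26(array(mask > 0, dim(mask)),
                             as.integer(dim(mask)),
                             as.integer(connectivity))
  lab
}

#' Median-smooth the boundaries of a binary segmentation
#'
#' Applies a per-slice 2D median filter (for binary data, a majority vote
#' over the window) with edge replication at slice borders. Smooths jagged
#' mass boundaries and removes isolated single-pixel responses.
#'
#' @param mask 3D binary array.
#' @param window odd window size (default 3).
#' @return filtered 3D binary array.
#' @export
median_smooth <- function(mask, window = 3L) {
  if (!is_binary_volume(mask)) stop("input mask must be a 3D binary volume")
  if (window %% 2 == 0) stop("median filter window must be odd")
  binary_median_slices(array(as.integer(mask), dim(mask)),
                       as.integer(dim(mask)), as.integer(window))
}

#' Full postprocessing chain: threshold, size-filter, smooth
#'
#' @param heatmap 3D probability array.
#' @param threshold binarization cut (default 0.5).
#' @param min_voxels cluster size cut (default 50).
#' @param window median window (default 3).
#' @param connectivity cluster connectivity (default 26).
#' @return a \code{label_volume} whose \code{mask} is the final
#'   segmentation.
#' @export
postprocess_heatmap <- function(heatmap, threshold = 0.5, min_voxels = 50L,
                                window = 3L, connectivity = 26L) {
  m <- binarize(heatmap, threshold)
  lv <- remove_small_clusters(m, min_voxels, connectivity)
  lv$mask <- median_smooth(lv$mask, window)
  lv
}
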