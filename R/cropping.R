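#' Label connected components of a binary mask
#'
#' Deterministic flood-fill labeling; labels are assigned in scan order of
#' the first voxel met in each component. 2D masks support 4- or
#' 8-connectivity, 3D masks 6- or 26-connectivity. Defaults follow the
#' pipeline's conventions: full-neighbourhood connectivity (8 in 2D, 26 in
#' 3D).
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4 or 8 (2D); 6 or 26 (3D).
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 3L) 26L else 8L) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or 3D array")
  if (length(d) == 2L && !connectivity %in% c(4L, 8L))
    stop("2D connectivity must be 4 or 8")
  if (length(d) == 3L && !connectivity %in% c(6L, 26L))
    stop("3D connectivity must be 6 or 26")
  .cc_label(as.logical(mask), as.integer(d), as.integer(connectivity))
}

#' Threshold a volume into tooth foreground and background
#'
#' Applies one common, fixed gray-value threshold: a voxel is foreground when
#' its gray value is strictly greater than \code{threshold}. The default of
#' 25 (of 255) sits below dentin and above air/noise for typical 8-bit
#' micro-CT reconstructions; it is data-dependent and deliberately exposed.
#'
#' @param volume a [voxel_volume()].
#' @param threshold gray value in \code{[0, 255]}.
#' @return logical 3D array (the tooth mask).
#' @export
foreground_mask <- function(volume, threshold = 25) {
  stopifnot(inherits(volume, "voxel_volume"),
            threshold >= 0, threshold <= 255)
  volume$data > threshold
}

#' Remove small 3D connected components (speckles)
#'
#' Deletes every 26-connected component with a voxel count strictly below
#' \code{min_voxels}; components of exactly \code{min_voxels} voxels are
#' retained.
#'
#' @param mask logical 3D array.
#' @param min_voxels minimum surviving component volume (default 1000).
#' @return logical 3D array.
#' @export
remove_small_components_3d <- function(mask, min_voxels = 1000L) {
  stopifnot(length(dim(mask)) == 3L)
  labels <- label_components(mask, 26L)
  if (max(labels) == 0L) return(mask & FALSE)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_voxels)
  out <- array(labels %in% keep, dim = dim(mask))
  out
}

#' Bounding box of the largest connected component
#'
#' Returns the tight axis-aligned box of the 26-connected component with the
#' greatest voxel count, as half-open 0-based index intervals per axis in
#' (axial, row, column) order. Ties between equal-sized components are broken
#' toward the component with the smallest axial start.
#'
#' @param mask logical 3D array with at least one true voxel.
#' @return list of class \code{bounding_box} with integer vectors
#'   \code{start} and \code{stop} (half-open, 0-based).
#' @export
largest_component_bbox <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  labels <- label_components(mask, 26L)
  n <- max(labels)
  if (n == 0L) stop("no foreground")
  sizes <- tabulate(labels, nbins = n)
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # deterministic tie-break: smallest axial start
    ax_start <- vapply(biggest, function(l) {
      min(which(apply(labels == l, 1L, any)))
    }, 1L)
    biggest <- biggest[which.min(ax_start)]
  } else biggest <- biggest[[1L]]
  idx <- which(labels == biggest, arr.ind = TRUE)
  structure(
    list(start = as.integer(apply(idx, 2L, min) - 1L),
         stop  = as.integer(apply(idx, 2L, max))),
    class = "bounding_box"
  )
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding_box: [%d,%d) x [%d,%d) x [%d,%d)\n",
              x$start[1], x$stop[1], x$start[2], x$stop[2],
              x$start[3], x$stop[3]))
  invisible(x)
}

#' Crop a volume to a bounding box
#'
#' @param volume a [voxel_volume()].
#' @param box a \code{bounding_box} from [largest_component_bbox()].
#' @return A [voxel_volume()] whose shape equals the box extents;
#'   \code{origin_index} is advanced by the axial start so cropped slice
#'   indices remain traceable to the parent volume.
#' @export
crop_to_bbox <- function(volume, box) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(box, "bounding_box"))
  d <- dim(volume$data)
  if (any(box$start < 0L) || any(box$stop > d) || any(box$start >= box$stop))
    stop("bbox outside volume")
  data <- volume$data[(box$start[1] + 1L):box$stop[1],
                      (box$start[2] + 1L):box$stop[2],
                      (box$start[3] + 1L):box$stop[3], drop = FALSE]
  voxel_volume(data, volume$voxel_size_um,
               origin_index = volume$origin_index + box$start[1])
}

#' Crop a volume to the tooth
#'
#' Full cropping stage: fixed-threshold foreground segmentation, 3D speckle
#' removal, then cropping to the bounding box of the largest remaining
#' object (the tooth). Metal-filling artefacts reaching the volume border are
#' not special-cased; the box may equal the full volume.
#'
#' @inheritParams foreground_mask
#' @inheritParams remove_small_components_3d
#' @return list with elements \code{volume} (the cropped [voxel_volume()]),
#'   \code{bbox} and \code{tooth_mask} (cropped foreground mask).
#' @export
crop_volume <- function(volume, threshold = 25, min_voxels = 1000L) {
  mask <- foreground_mask(volume, threshold)
  mask <- remove_small_components_3d(mask, min_voxels)
  box <- largest_component_bbox(mask)
  cropped <- crop_to_bbox(volume, box)
  tooth <- mask[(box$start[1] + 1L):box$stop[1],
                (box$start[2] + 1L):box$stop[2],
                (box$start[3] + 1L):box$stop[3], drop = FALSE]
  list(volume = cropped, bbox = box, tooth_mask = tooth)
}
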