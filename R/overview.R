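#' Middle slice of each anatomical plane
#'
#' The middle slice along an axis of length n is the slice at index
#' floor(n/2) (0-based), a fixed deterministic convention. Because the teeth
#' are scanned rotationally unoriented, "coronal" and "sagittal" simply name
#' the two dataset axes orthogonal to axial.
#'
#' @param volume a [voxel_volume()].
#' @return list of three gray-value matrices: \code{axial}, \code{coronal},
#'   \code{sagittal}.
#' @export
middle_slices <- function(volume) {
  d <- dim(volume$data)
  m <- d %/% 2L + 1L  # floor(n/2), 1-based
  list(axial    = volume$data[m[1], , ],
       coronal  = volume$data[, m[2], ],
       sagittal = volume$data[, , m[3]])
}

#' Maximum intensity projection
#'
#' Collapses the volume to a 2D overview by taking the element-wise maximum
#' gray value along one anatomical axis.
#'
#' @param volume a [voxel_volume()].
#' @param axis one of \code{"axial"}, \code{"coronal"}, \code{"sagittal"}.
#' @return gray-value matrix.
#' @export
max_intensity_projection <- function(volume,
                                     axis = c("axial", "coronal", "sagittal")) {
  axis <- match.arg(axis)
  ax <- match(axis, c("axial", "coronal", "sagittal"))
  keep <- setdiff(1:3, ax)
  apply(volume$data, keep, max)
}

#' Tile 2D preview images into a montage grid
#'
#' Lays the images out row-major on a uniform tile grid sized to the largest
#' image; smaller images and missing trailing cells are zero-padded.
#'
#' @param previews list of gray-value matrices.
#' @param columns number of grid columns.
#' @return gray-value matrix.
#' @export
montage <- function(previews, columns = ceiling(sqrt(length(previews)))) {
  stopifnot(length(previews) >= 1L, columns >= 1L)
  th <- max(vapply(previews, nrow, 1L))
  tw <- max(vapply(previews, ncol, 1L))
  rows <- ceiling(length(previews) / columns)
  out <- matrix(0, nrow = rows * th, ncol = columns * tw)
  for (i in seq_along(previews)) {
    r <- (i - 1L) %/% columns
    c <- (i - 1L) %% columns
    img <- previews[[i]]
    out[r * th + seq_len(nrow(img)), c * tw + seq_len(ncol(img))] <- img
  }
  out
}

#' Write a gray-value image to PNG
#'
#' @param image numeric matrix with values in \code{[0, 255]}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}
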