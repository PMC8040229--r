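#' Exact Euclidean distance transform of the canal
#'
#' Labels each canal voxel with its exact Euclidean distance to the nearest
#' background (non-canal) voxel, scaled to micrometres. Twice the maximum
#' distance over a canal cross-section is the diameter of the largest sphere
#' inscribed in the canal there, which is how the foramen diameter is read.
#'
#' @param canal_mask logical 3D array.
#' @param voxel_size_um isometric voxel size; defaults to the mask's
#'   \code{voxel_size_um} attribute.
#' @return numeric 3D array of distances in micrometres, zero outside the
#'   canal, with \code{voxel_size_um} attached as an attribute.
#' @export
euclidean_distance_map <- function(canal_mask,
                                   voxel_size_um = attr(canal_mask, "voxel_size_um")) {
  stopifnot(length(dim(canal_mask)) == 3L)
  if (is.null(voxel_size_um)) stop("voxel_size_um required")
  if (all(canal_mask)) stop("no background")
  d2 <- .edt_squared(as.logical(canal_mask), as.integer(dim(canal_mask)))
  edt <- sqrt(d2) * voxel_size_um
  attr(edt, "voxel_size_um") <- voxel_size_um
  edt
}

#' Extract the apical region of a tooth
#'
#' Cuts the axial window of \code{height_mm} ending at \code{bottom_index}
#' (3.5 mm = 350 slices at 10 um voxels), clipped at the top of the volume.
#' Working on this small apical sub-volume makes foramen assessment cheap.
#'
#' @param volume a [voxel_volume()].
#' @param bottom_index axial index of the lowest tooth slice.
#' @param height_mm apical window height in millimetres.
#' @return a [voxel_volume()] whose last slice is \code{bottom_index};
#'   \code{origin_index} is advanced accordingly.
#' @export
extract_bottom_region <- function(volume, bottom_index, height_mm = 3.5) {
  nz <- dim(volume$data)[1]
  stopifnot(bottom_index >= 1L, bottom_index <= nz)
  n <- as.integer(round(height_mm * 1000 / volume$voxel_size_um))
  start <- max(1L, bottom_index - n + 1L)
  voxel_volume(volume$data[start:bottom_index, , , drop = FALSE],
               volume$voxel_size_um,
               origin_index = volume$origin_index + start - 1L)
}

#' Reorder a volume between axial and sagittal slice order
#'
#' Axial order stores slices along axis 1 (crown to apex); sagittal order
#' stores the slices cut along the third dataset axis. The two functions are
#' exact inverses.
#'
#' @param a 3D array in axial (resp. sagittal) order.
#' @return the reordered 3D array.
#' @export
axial_to_sagittal <- function(a) aperm(a, c(3, 1, 2))

#' @rdname axial_to_sagittal
#' @export
sagittal_to_axial <- function(a) aperm(a, c(2, 3, 1))

#' Overlay the canal distance transform on the reconstruction
#'
#' Merges the reconstructed gray values with the canal EDT: non-canal voxels
#' keep their reconstruction gray value, canal voxels carry
#' \code{encode_base + round(EDT in voxels)} (clipped to 255), so the radius
#' of the largest inscribed sphere at any canal point can be read off in any
#' image viewer. The merged volume is returned reformatted into sagittal
#' slices, which cut along the canal and show the whole apical course at
#' once.
#'
#' @param recon a [voxel_volume()] (reconstruction, axial order).
#' @param edt distance map from [euclidean_distance_map()], same shape.
#' @param encode_base gray level marking a canal voxel of radius 0; levels
#'   above it encode the radius in voxels.
#' @return a [voxel_volume()] in sagittal slice order.
#' @export
overlay_edt <- function(recon, edt, encode_base = 200L) {
  stopifnot(inherits(recon, "voxel_volume"))
  if (!identical(dim(recon$data), dim(edt))) stop("misaligned inputs")
  vs <- attr(edt, "voxel_size_um")
  if (is.null(vs)) vs <- recon$voxel_size_um
  out <- recon$data
  canal <- edt > 0
  out[canal] <- pmin(255L, encode_base + as.integer(round(edt[canal] / vs)))
  voxel_volume(axial_to_sagittal(out), recon$voxel_size_um,
               origin_index = recon$origin_index)
}

#' Detect and classify apical foramina
#'
#' Finds every 26-connected canal component whose lowest (most apical) slice
#' lies inside the apical window and measures its exits. A canal that
#' bifurcates above the apex is a single 3D component with several apical
#' openings, so the component's lowest-slice cross-section is split into its
#' 8-connected in-plane parts and each part is one exit; this keeps the count
#' of measurements equal to the number of apical exit cross-sections. The
#' exit diameter is twice the maximum in-plane (2D) distance transform over
#' the exit cross-section — the largest circle inscribed in the opening,
#' which is what an operator scrolling axial slices measures. (The 3D EDT is
#' unsuitable here: immediately above an open foramen it measures the
#' distance to the air below the exit rather than the canal calibre.) When a
#' 3D distance map is supplied, the largest inscribed-sphere diameter at the
#' exit is reported alongside as \code{sphere_diameter_um}. Openings with a
#' diameter of \code{min_diameter_um} (0.20 mm) or more are physiological
#' (main) foramina; smaller ones are accessory. The diameter is read at the
#' lowest closed cross-section because per-slice border clearing removes the
#' canal where it opens into outside air.
#'
#' @param canal_mask logical 3D canal mask.
#' @param edt optional matching 3D distance map from
#'   [euclidean_distance_map()]; adds the \code{sphere_diameter_um} column.
#' @param apex_window_slices integer vector of axial indices forming the
#'   apical window (e.g. the slices of [extract_bottom_region()]).
#' @param min_diameter_um physiological/accessory threshold (inclusive).
#' @param voxel_size_um isometric voxel size; defaults to the mask's (or the
#'   distance map's) \code{voxel_size_um} attribute.
#' @return data frame with one row per foramen: \code{exit_slice},
#'   \code{exit_row}, \code{exit_col} (centroid of the exit cross-section),
#'   \code{diameter_um}, \code{kind} ("physiological" or "accessory"), plus
#'   \code{sphere_diameter_um} when \code{edt} is given.
#' @export
detect_foramina <- function(canal_mask, edt = NULL, apex_window_slices,
                            min_diameter_um = 200,
                            voxel_size_um = attr(canal_mask, "voxel_size_um")) {
  stopifnot(length(dim(canal_mask)) == 3L)
  if (!is.null(edt)) {
    stopifnot(identical(dim(canal_mask), dim(edt)))
    if (is.null(voxel_size_um)) voxel_size_um <- attr(edt, "voxel_size_um")
  }
  if (is.null(voxel_size_um)) stop("voxel_size_um required")
  labels <- label_components(canal_mask, 26L)
  n <- max(labels)
  empty <- data.frame(exit_slice = integer(0), exit_row = numeric(0),
                      exit_col = numeric(0), diameter_um = numeric(0),
                      kind = character(0))
  if (!is.null(edt)) empty$sphere_diameter_um <- numeric(0)
  if (n == 0L) return(empty)
  rows <- list()
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  d2 <- dim(canal_mask)[2:3]
  for (l in seq_len(n)) {
    vox <- idx[lab == l, , drop = FALSE]
    exit_slice <- max(vox[, 1])
    if (!(exit_slice %in% apex_window_slices)) next
    cross2d <- labels[exit_slice, , ] == l
    xlab <- label_components(cross2d, 8L)
    for (x in seq_len(max(xlab))) {
      part <- xlab == x
      pix <- which(part, arr.ind = TRUE)
      inplane <- sqrt(.edt_squared(as.logical(part), c(1L, d2)))
      diameter <- 2 * max(inplane[part]) * voxel_size_um
      row <- data.frame(
        exit_slice = exit_slice,
        exit_row = mean(pix[, 1]),
        exit_col = mean(pix[, 2]),
        diameter_um = diameter,
        kind = if (diameter >= min_diameter_um) "physiological" else "accessory"
      )
      if (!is.null(edt))
        row$sphere_diameter_um <- 2 * max(edt[cbind(exit_slice, pix)])
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) empty else do.call(rbind, rows)
}
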