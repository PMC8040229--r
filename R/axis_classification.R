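#' Mean brightness along the tooth axis
#'
#' The axial brightness profile: the mean gray value of every axial slice of
#' a cropped tooth volume. The enamel cap is markedly brighter than dentin,
#' so the profile drops sharply at the enamel--dentin border (EDB).
#'
#' @param volume a cropped [voxel_volume()].
#' @return object of class \code{axis_profile} with \code{raw} (one value per
#'   axial slice); \code{smoothed} and \code{derivative} are filled in by
#'   [smooth_profile()].
#' @export
brightness_profile <- function(volume) {
  nz <- dim(volume$data)[1]
  raw <- rowMeans(matrix(as.numeric(volume$data), nrow = nz))
  structure(list(raw = raw, smoothed = NULL, derivative = NULL),
            class = "axis_profile")
}

#' Smooth an axial brightness profile
#'
#' Locally weighted scatterplot smoothing (LOWESS) of the raw profile against
#' the slice index. The smoother-span fraction must be large enough to span
#' slice-to-slice noise but small enough not to blur the EDB edge; the
#' default of 0.05 works at full reconstruction scale (thousands of slices)
#' and for the scaled-down phantoms alike. The smoothed curve is clamped to
#' the raw profile's range, and the first difference of the smoothed curve is
#' stored (padded with 0 at the apex end so all three series share one
#' length).
#'
#' @param profile an \code{axis_profile} from [brightness_profile()].
#' @param frac LOWESS smoother span as a fraction of the axis length.
#' @return the profile with \code{smoothed} and \code{derivative} populated.
#' @export
smooth_profile <- function(profile, frac = 0.05) {
  stopifnot(inherits(profile, "axis_profile"), frac > 0, frac <= 1)
  n <- length(profile$raw)
  if (n < 10L) stop("profile too short")
  sm <- lowess(seq_len(n), profile$raw, f = frac)$y
  sm <- pmin(pmax(sm, min(profile$raw)), max(profile$raw))
  profile$smoothed <- sm
  profile$derivative <- c(diff(sm), 0)
  profile
}

#' Detect the enamel--dentin border
#'
#' The EDB is the axial index of the maximal absolute first difference of the
#' smoothed brightness profile — the strongest brightness edge along the
#' tooth axis, which for an intact crown is the enamel-to-dentin drop. Ties
#' are broken toward the smallest index. Metal fillings can relocate the
#' strongest edge; for such teeth pass a manual index to [plan_slices()]
#' instead.
#'
#' @param profile an \code{axis_profile} with \code{smoothed} populated.
#' @return axial slice index (1-based).
#' @export
detect_edb <- function(profile) {
  stopifnot(inherits(profile, "axis_profile"))
  if (is.null(profile$smoothed)) stop("smoothed profile required; run smooth_profile()")
  a <- abs(profile$derivative)
  if (max(a) <= .Machine$double.eps * max(1, max(abs(profile$smoothed))))
    stop("no EDB detectable: flat profile")
  which.max(a)
}

#' Lowest axial slice containing tooth foreground
#'
#' @param tooth_mask logical 3D tooth mask.
#' @return the largest axial index (1-based) whose slice has at least one
#'   foreground voxel.
#' @export
find_bottom <- function(tooth_mask) {
  stopifnot(length(dim(tooth_mask)) == 3L)
  nz <- dim(tooth_mask)[1]
  any_fg <- rowSums(matrix(tooth_mask, nrow = nz)) > 0
  if (!any(any_fg)) stop("no foreground")
  max(which(any_fg))
}

#' Plan the four classification slices
#'
#' The four slices used for root canal configuration coding sit at the EDB,
#' the bottom of the tooth, and equidistantly between:
#' \code{e + round(k (b - e) / 3)} for k = 0..3.
#'
#' @param edb_index axial index of the enamel--dentin border.
#' @param bottom_index axial index of the lowest tooth slice; must exceed
#'   \code{edb_index} by more than 3.
#' @param window_um width of the minimum-gray projection window around each
#'   slice (micrometres).
#' @param edb_source \code{"automatic"} ([detect_edb()]) or \code{"manual"}
#'   (operator override, e.g. for metal-filled crowns).
#' @return object of class \code{slice_plan}: \code{edb_index},
#'   \code{bottom_index}, \code{slice_indices} (4 ordered axial indices),
#'   \code{window_um}, \code{edb_source}.
#' @export
plan_slices <- function(edb_index, bottom_index, window_um = 400,
                        edb_source = c("automatic", "manual")) {
  edb_source <- match.arg(edb_source)
  e <- as.integer(edb_index); b <- as.integer(bottom_index)
  if (!(e < b - 3L)) stop("invalid axis landmarks")
  idx <- as.integer(e + round((0:3) * (b - e) / 3))
  structure(list(edb_index = e, bottom_index = b, slice_indices = idx,
                 window_um = window_um, edb_source = edb_source),
            class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat(sprintf("slice_plan: EDB %d (%s), bottom %d; slices %s; window %g um\n",
              x$edb_index, x$edb_source, x$bottom_index,
              paste(x$slice_indices, collapse = ", "), x$window_um))
  invisible(x)
}

#' Minimum-gray projection window around a slice
#'
#' Writes the element-wise minimum gray value over a window of total width
#' \code{window_um} centred on \code{center_index} (400 um = 40 slices at
#' 10 um voxels, 20 on each side), clipped at the volume edges. The minimum
#' carries fine dark structures — accessory canals — into the projected
#' image, which is why it is used for the classification report figures.
#'
#' @param volume a [voxel_volume()].
#' @param center_index axial index at the window centre.
#' @param window_um total window width in micrometres.
#' @return gray-value matrix.
#' @export
window_min_projection <- function(volume, center_index, window_um = 400) {
  nz <- dim(volume$data)[1]
  w <- max(1L, as.integer(round(window_um / volume$voxel_size_um)))
  start <- center_index - w %/% 2L
  idx <- seq(start, start + w - 1L)
  idx <- idx[idx >= 1L & idx <= nz]
  apply(volume$data[idx, , , drop = FALSE], c(2, 3), min)
}

#' Count root canals in one axial slice
#'
#' Number of 8-connected components of the canal mask in this slice.
#'
#' @param canal_slice logical matrix.
#' @return integer count.
#' @export
count_canals <- function(canal_slice) {
  max(label_components(canal_slice, 8L))
}

#' Construct a 4-digit root canal configuration code
#'
#' The code \code{"a-b-c/d"} gives the canal counts at three levels along the
#' root plus the number of main (physiological) foramina, e.g.
#' \code{"1-2-2/2"} for a canal that bifurcates and exits through two main
#' foramina.
#'
#' @param counts integer vector of 3 canal counts.
#' @param main_foramina number of main foramina.
#' @return object of class \code{canal_code}.
#' @export
canal_code <- function(counts, main_foramina) {
  stopifnot(length(counts) == 3L, all(counts >= 0), main_foramina >= 0)
  structure(list(counts = as.integer(counts),
                 main_foramina = as.integer(main_foramina)),
            class = "canal_code")
}

#' @export
format.canal_code <- function(x, ...) {
  sprintf("%d-%d-%d/%d", x$counts[1], x$counts[2], x$counts[3], x$main_foramina)
}

#' @export
print.canal_code <- function(x, ...) {
  cat("canal configuration:", format(x), "\n")
  invisible(x)
}

#' Derive the root canal configuration code
#'
#' Counts the canal components at the EDB slice and the two intermediate
#' planned slices (the three code digits), and appends the supplied
#' main-foramina count as the fourth digit. Counting happens on the canal
#' mask at the exact planned slice — the minimum-gray window is a
#' visualization aid only. The automatic code is advisory: it aids, not
#' replaces, classification by a trained observer.
#'
#' @param canal_mask logical 3D canal mask aligned with the plan's volume.
#' @param plan a [plan_slices()] result.
#' @param main_foramina number of main foramina (from [detect_foramina()] or
#'   manual reading).
#' @return a [canal_code()].
#' @export
classify_configuration <- function(canal_mask, plan, main_foramina) {
  stopifnot(length(dim(canal_mask)) == 3L, inherits(plan, "slice_plan"))
  counts <- vapply(plan$slice_indices[1:3],
                   function(i) count_canals(canal_mask[i, , ]), 1L)
  canal_code(counts, main_foramina)
}
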