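#' Otsu threshold of a gray-value image
#'
#' Computes the classic Otsu threshold over the 256-bin histogram: the gray
#' value t (0--254) that minimizes the intra-class variance (equivalently,
#' maximizes the between-class variance) of the split into pixels <= t and
#' pixels > t. Ties are broken toward the smallest threshold.
#'
#' @param image numeric matrix of gray values in \code{[0, 255]}.
#' @return integer threshold; foreground is \code{image > threshold}.
#' @export
otsu_threshold <- function(image) {
  v <- as.integer(round(image))
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L) stop("degenerate histogram")
  n <- sum(h)
  levels <- 0:255
  w0 <- cumsum(h)                       # pixels <= t, for t = 0..255
  w1 <- n - w0
  s0 <- cumsum(h * levels)
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (s0[256] - s0) / w1, 0)
  between <- w0 * w1 * (mu0 - mu1)^2    # maximizing this minimizes within-class var
  cand <- 1:255                          # t = 0..254 (both classes can be non-empty)
  t <- cand[which.max(between[cand])] - 1L
  as.integer(t)
}

# labels (8-connected) of a 2D mask that touch the image border
.border_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  b <- c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc])
  unique(b[b > 0L])
}

#' Extract the root-canal lumen from one axial slice
#'
#' The per-slice canal extraction: (1) split tooth from background with an
#' Otsu threshold; (2) invert, selecting all that is not tooth; (3) clear
#' every inverted component that touches the image border (the surrounding
#' air); (4) remove speckles with area strictly less than \code{min_area_px};
#' (5) fill enclosed holes with area strictly less than \code{max_hole_px}.
#' Components use 8-connectivity; holes are 4-connected background regions.
#' A slice with a degenerate (single-level) histogram yields an empty mask
#' rather than an error, so pure-air slices do not fail a batch.
#'
#' @param image numeric matrix: one axial gray-value slice.
#' @param min_area_px smallest surviving canal component, in pixels.
#' @param max_hole_px holes strictly smaller than this are filled.
#' @return logical matrix: the canal mask for this slice.
#' @export
extract_canal_slice <- function(image, min_area_px = 64L, max_hole_px = 100L) {
  thr <- tryCatch(otsu_threshold(image), error = function(e) NULL)
  if (is.null(thr)) return(matrix(FALSE, nrow(image), ncol(image)))
  inv <- !(image > thr)

  labels <- label_components(inv, 8L)
  drop <- .border_labels(labels)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels)
    small <- which(sizes < min_area_px)
    keep_tab <- rep(TRUE, max(labels))
    keep_tab[drop] <- FALSE
    keep_tab[small] <- FALSE
    canal <- array(labels > 0L & keep_tab[pmax(labels, 1L)], dim = dim(labels))
  } else {
    canal <- matrix(FALSE, nrow(image), ncol(image))
  }

  # fill enclosed holes (< max_hole_px) inside the retained canal mask
  bg <- label_components(!canal, 4L)
  if (max(bg) > 0L) {
    open_lbl <- .border_labels(bg)
    bg_sizes <- tabulate(bg)
    fill <- setdiff(which(bg_sizes < max_hole_px), open_lbl)
    if (length(fill) > 0L)
      canal[bg %in% fill] <- TRUE
  }
  canal
}

#' Extract the root-canal system of a whole volume
#'
#' Applies [extract_canal_slice()] to every axial slice of a cropped tooth
#' volume and stacks the results into a binary canal volume. Otsu is computed
#' per slice, exactly as in the original procedure, so the tooth/background
#' split adapts along the tooth axis.
#'
#' @param volume a cropped [voxel_volume()].
#' @inheritParams extract_canal_slice
#' @return logical 3D array aligned with \code{volume}, with the voxel size
#'   attached as attribute \code{voxel_size_um}.
#' @export
extract_canal_volume <- function(volume, min_area_px = 64L, max_hole_px = 100L) {
  d <- dim(volume$data)
  mask <- array(FALSE, dim = d)
  for (i in seq_len(d[1]))
    mask[i, , ] <- extract_canal_slice(volume$data[i, , ], min_area_px, max_hole_px)
  attr(mask, "voxel_size_um") <- volume$voxel_size_um
  mask
}

#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 for identical masks. Two empty masks
#' score 1 by convention.
#'
#' @param a,b logical arrays of identical shape.
#' @return numeric in \code{[0, 1]}.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
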