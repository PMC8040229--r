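#' Specify a synthetic tooth phantom
#'
#' A phantom emulates a single-rooted tooth in an 8-bit micro-CT
#' reconstruction: a bright enamel cap over a darker dentin frustum that
#' tapers toward the apex, near-background-intensity canal lumina of given
#' radii with branch/merge topology, surrounding air, and optional additive
#' Gaussian noise. Every geometric fact needed by the pipeline (canal mask,
#' enamel--dentin border, bottom slice, configuration code, foramen
#' diameters) is known analytically, so phantoms provide exact ground truth.
#'
#' Canal geometry is a list of tube segments, each a list with
#' \code{start_slice}, \code{end_slice} (axial, inclusive),
#' \code{start_center}, \code{end_center} (in-plane (row, col), linearly
#' interpolated between the end slices) and \code{radius_um}. Segments that
#' share an end slice and centre are continuous; segments ending at the apex
#' slice are canal exits.
#'
#' @param shape volume dimensions (axial, row, col).
#' @param voxel_size_um isometric voxel size (default 10, the working
#'   resolution of the reconstructions this pipeline targets).
#' @param body_start,apex_slice first and last axial slice of the tooth body.
#' @param enamel_end_slice last axial slice of the enamel cap (the ground
#'   truth EDB).
#' @param body_radius_top,body_radius_apex in-plane tooth radius (voxels) at
#'   \code{body_start} and \code{apex_slice}; linear taper between.
#' @param gray named gray levels \code{air}, \code{canal}, \code{dentin},
#'   \code{enamel}; must satisfy enamel > dentin > canal ~ air.
#' @param canal_tree list of tube segments (see Details).
#' @param noise_sigma standard deviation of additive Gaussian noise (gray
#'   levels).
#' @param seed RNG seed making the rendering reproducible.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(170L, 100L, 100L), voxel_size_um = 10,
                         body_start = 3L, apex_slice = shape[1] - 2L,
                         enamel_end_slice = 40L,
                         body_radius_top = 38, body_radius_apex = 26,
                         gray = c(air = 5, canal = 10, dentin = 120, enamel = 220),
                         canal_tree = list(), noise_sigma = 0, seed = 1L) {
  stopifnot(length(shape) == 3L, voxel_size_um > 0,
            body_start >= 1L, apex_slice <= shape[1],
            enamel_end_slice > body_start, enamel_end_slice < apex_slice,
            gray["enamel"] > gray["dentin"], gray["dentin"] > gray["canal"],
            noise_sigma >= 0)
  structure(list(shape = as.integer(shape), voxel_size_um = voxel_size_um,
                 body_start = as.integer(body_start),
                 apex_slice = as.integer(apex_slice),
                 enamel_end_slice = as.integer(enamel_end_slice),
                 body_radius_top = body_radius_top,
                 body_radius_apex = body_radius_apex,
                 gray = gray, canal_tree = canal_tree,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# in-plane body radius at axial slice z (linear frustum taper)
.body_radius <- function(spec, z) {
  f <- (z - spec$body_start) / max(1L, spec$apex_slice - spec$body_start)
  spec$body_radius_top + f * (spec$body_radius_apex - spec$body_radius_top)
}

# disk centre/radius (voxels) of a segment at slice z, or NULL if not covered
.segment_disk <- function(seg, z, voxel_size_um) {
  if (z < seg$start_slice || z > seg$end_slice) return(NULL)
  f <- if (seg$end_slice == seg$start_slice) 0 else
    (z - seg$start_slice) / (seg$end_slice - seg$start_slice)
  list(center = seg$start_center + f * (seg$end_center - seg$start_center),
       radius = seg$radius_um / voxel_size_um)
}

# number of disjoint canal cross-sections at slice z, from geometry alone:
# disks are grouped when their analytic extents come within two voxels of
# each other (the suite geometry keeps real gaps at >= 3 voxels, so this
# grouping is unambiguous)
.analytic_canal_count <- function(spec, z) {
  disks <- Filter(Negate(is.null),
                  lapply(spec$canal_tree, .segment_disk, z = z,
                         voxel_size_um = spec$voxel_size_um))
  n <- length(disks)
  if (n == 0L) return(0L)
  group <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      dist <- sqrt(sum((disks[[i]]$center - disks[[j]]$center)^2))
      if (dist < disks[[i]]$radius + disks[[j]]$radius + 2) {
        g <- group[j]; group[group == g] <- group[i]
      }
    }
  }
  length(unique(group))
}

#' Render a phantom volume and its ground truth
#'
#' Deterministic for a fixed seed. The ground truth is computed from the tube
#' geometry, never by segmenting the rendered image, so tests against it are
#' not circular.
#'
#' @param spec a [phantom_spec()].
#' @return list with \code{volume} (a [voxel_volume()]) and \code{truth}, a
#'   list holding \code{canal_mask} (logical array, analytic),
#'   \code{edb_slice}, \code{bottom_slice}, \code{first_tooth_slice} (all in
#'   uncropped 1-based axial indices), \code{code} (a [canal_code()]),
#'   \code{counts} (the three analytic slice counts) and \code{foramina}
#'   (data frame of exit diameters and kinds).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  bc <- (d[2:3] + 1) / 2  # in-plane body centre

  # validate: every segment disk inside the body at both end slices
  for (seg in spec$canal_tree) {
    for (z in c(seg$start_slice, seg$end_slice)) {
      disk <- .segment_disk(seg, z, spec$voxel_size_um)
      off <- sqrt(sum((disk$center - bc)^2))
      if (z < spec$body_start || z > spec$apex_slice ||
          off + disk$radius > .body_radius(spec, z) - 1)
        stop("invalid spec: canal segment outside tooth body")
    }
  }

  rr <- matrix(rep(seq_len(d[2]), d[3]), d[2], d[3])
  cc <- matrix(rep(seq_len(d[3]), each = d[2]), d[2], d[3])
  body_d2 <- (rr - bc[1])^2 + (cc - bc[2])^2

  vol <- array(spec$gray[["air"]], dim = d)
  canal_mask <- array(FALSE, dim = d)
  for (z in spec$body_start:spec$apex_slice) {
    R <- .body_radius(spec, z)
    body <- body_d2 < R^2
    tissue <- if (z <= spec$enamel_end_slice) spec$gray[["enamel"]] else
      spec$gray[["dentin"]]
    slice <- matrix(spec$gray[["air"]], d[2], d[3])
    slice[body] <- tissue
    cmask <- matrix(FALSE, d[2], d[3])
    for (seg in spec$canal_tree) {
      disk <- .segment_disk(seg, z, spec$voxel_size_um)
      if (is.null(disk)) next
      cmask <- cmask | ((rr - disk$center[1])^2 + (cc - disk$center[2])^2 <
                          disk$radius^2)
    }
    slice[cmask] <- spec$gray[["canal"]]
    vol[z, , ] <- slice
    canal_mask[z, , ] <- cmask
  }

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    vol <- vol + rnorm(length(vol), 0, spec$noise_sigma)
  }
  vol <- round(pmin(pmax(vol, 0), 255))

  # analytic truth
  edb_c <- spec$enamel_end_slice - spec$body_start + 1L
  bottom_c <- spec$apex_slice - spec$body_start + 1L
  plan_c <- as.integer(edb_c + round((0:3) * (bottom_c - edb_c) / 3))
  plan_u <- plan_c + spec$body_start - 1L
  counts <- vapply(plan_u[1:3], function(z) .analytic_canal_count(spec, z), 1L)

  exits <- Filter(function(s) s$end_slice == spec$apex_slice, spec$canal_tree)
  diam <- vapply(exits, function(s) 2 * s$radius_um, 1.0)
  foramina <- data.frame(
    diameter_um = diam,
    kind = ifelse(diam >= 200, "physiological", "accessory"))
  n_main <- sum(foramina$kind == "physiological")

  attr(canal_mask, "voxel_size_um") <- spec$voxel_size_um
  list(
    volume = voxel_volume(vol, spec$voxel_size_um),
    truth = list(
      canal_mask = canal_mask,
      edb_slice = spec$enamel_end_slice,
      bottom_slice = spec$apex_slice,
      first_tooth_slice = spec$body_start,
      counts = counts,
      code = canal_code(counts, n_main),
      foramina = foramina
    )
  )
}

# canal trees realizing the suite configuration codes; all trees live in the
# default 170 x 100 x 100 geometry (body centre row/col 50.5, apex slice 168)
.suite_canal_tree <- function(code) {
  seg <- function(z0, z1, c0, c1, r_um)
    list(start_slice = z0, end_slice = z1, start_center = c0, end_center = c1,
         radius_um = r_um)
  # integer voxel-centre coordinates: an exit tube of radius r voxels then has
  # an exact inscribed-sphere radius of r at its axis, so ground-truth foramen
  # diameters are reproduced exactly by the distance transform
  ctr <- c(50, 50); L <- c(50, 38); R <- c(50, 62)
  main <- 120; branch <- 100  # radii in um (12 and 10 voxels at 10 um)
  switch(code,
    "1-1-1/1" = list(seg(20, 168, ctr, ctr, main)),
    "2-2-2/2" = list(seg(20, 168, L, L, branch), seg(20, 168, R, R, branch)),
    "1-2-2/2" = list(seg(20, 50, ctr, ctr, main),
                     seg(50, 70, ctr, L, branch), seg(70, 168, L, L, branch),
                     seg(50, 70, ctr, R, branch), seg(70, 168, R, R, branch)),
    "1-2-1/1" = list(seg(20, 50, ctr, ctr, main),
                     seg(50, 70, ctr, L, branch), seg(70, 100, L, L, branch),
                     seg(100, 120, L, ctr, branch),
                     seg(50, 70, ctr, R, branch), seg(70, 100, R, R, branch),
                     seg(100, 120, R, ctr, branch),
                     seg(120, 168, ctr, ctr, main)),
    "2-1-1/1" = list(seg(20, 50, L, L, branch), seg(50, 70, L, ctr, branch),
                     seg(20, 50, R, R, branch), seg(50, 70, R, ctr, branch),
                     seg(70, 168, ctr, ctr, main)),
    "1-1-2/2" = list(seg(20, 100, ctr, ctr, main),
                     seg(100, 120, ctr, L, branch), seg(120, 168, L, L, branch),
                     seg(100, 120, ctr, R, branch), seg(120, 168, R, R, branch)),
    stop("unknown suite code: ", code)
  )
}

#' Default phantom suite
#'
#' Twelve phantom specifications: six distinct root canal configuration
#' codes (1-1-1/1, 1-2-1/1, 1-2-2/2, 2-2-2/2, 2-1-1/1, 1-1-2/2), each
#' rendered noiselessly and with additive Gaussian noise of sigma = 10 gray
#' levels, under fixed seeds. This is the standard validation surface for the
#' whole pipeline.
#'
#' @return list of [phantom_spec()] objects; each carries attributes
#'   \code{code} and \code{noise_sigma} for convenience.
#' @export
default_phantom_suite <- function() {
  codes <- c("1-1-1/1", "1-2-1/1", "1-2-2/2", "2-2-2/2", "2-1-1/1", "1-1-2/2")
  specs <- list()
  for (i in seq_along(codes)) {
    for (sigma in c(0, 10)) {
      sp <- phantom_spec(canal_tree = .suite_canal_tree(codes[i]),
                         noise_sigma = sigma, seed = 100L + i)
      attr(sp, "code") <- codes[i]
      specs[[length(specs) + 1L]] <- sp
    }
  }
  specs
}

#' Write a phantom as a slice stack directory
#'
#' Writes the phantom as zero-padded PNG axial slices plus a minimal
#' scanner-style log file (carrying the voxel size) and a \code{truth.json}
#' sidecar, producing a directory directly consumable by
#' [read_reconstruction_stack()] and [process_tooth()].
#'
#' @param phantom result of [generate_phantom()].
#' @param directory output directory (created if missing).
#' @return \code{directory}, invisibly.
#' @export
write_phantom_stack <- function(phantom, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(phantom$volume$data)
  for (i in seq_len(d[1]))
    write_image(phantom$volume$data[i, , ],
                file.path(directory, sprintf("slice%06d.png", i)))
  writeLines(c("[Acquisition]",
               sprintf("Pixel Size (um)=%g", phantom$volume$voxel_size_um),
               "Source Voltage (kV)=80", "Source Current (uA)=125"),
             file.path(directory, "scan.log"))
  truth <- phantom$truth
  truth$canal_mask <- NULL  # geometry summary only; the mask is re-derivable
  truth$code <- format(truth$code)
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(directory)
}
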