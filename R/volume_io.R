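#' Construct a voxel volume
#'
#' A voxel volume is the carrier object between all pipeline stages: a 3D
#' 8-bit gray-value array with isometric physical voxel size. Axis 1 is the
#' axial (slice) direction and increases from crown toward apex; axes 2 and 3
#' are the in-plane row/column directions.
#'
#' @param data 3D numeric/integer array of gray values in \code{[0, 255]};
#'   dimension order (axial, row, column).
#' @param voxel_size_um physical edge length of the isometric voxel, in
#'   micrometres. Must be positive.
#' @param origin_index axial index (0-based) of slice 1 in the uncropped
#'   parent volume, for traceability after cropping.
#' @return An object of class \code{voxel_volume} with elements \code{data},
#'   \code{voxel_size_um} and \code{origin_index}.
#' @export
voxel_volume <- function(data, voxel_size_um, origin_index = 0L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      is.na(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  storage.mode(data) <- "integer"
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         origin_index = as.integer(origin_index)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "voxel_volume: %d x %d x %d voxels (axial x row x col), %.3g um/voxel, origin slice %d\n",
    d[1], d[2], d[3], x$voxel_size_um, x$origin_index))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# read one slice image as an 8-bit gray matrix (values 0..255)
read_slice_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("png"))
      png::readPNG(path, info = TRUE)
    else if (ext %in% c("tif", "tiff"))
      tiff::readTIFF(path, info = TRUE)
    else
      stop("unsupported extension")
  }, error = function(e) {
    stop(sprintf("decode failure: %s (%s)", basename(path), conditionMessage(e)),
         call. = FALSE)
  })
  info <- attr(img, "info")
  b <- if (!is.null(info)) info[["bit.depth"]] else NULL   # png
  if (is.null(b)) b <- attr(img, "bits.per.sample")        # tiff
  bits <- if (is.null(b)) 8L else as.integer(b[1])
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # gray stored with channels
  if (bits > 8L)
    warning(sprintf("%s is %d-bit; linearly rescaled to 8-bit", basename(path), bits))
  round(img * 255)
}

#' Read a reconstructed axial slice stack
#'
#' Reads every PNG/TIFF image in \code{directory} as one axial slice, in
#' strict lexicographic file-name order (scanner output is zero-padded, so
#' this reproduces acquisition order deterministically). All slices must share
#' one width/height. 16-bit images are linearly rescaled to 8-bit with a
#' warning.
#'
#' @param directory path containing the slice images.
#' @param voxel_size_um isometric voxel size in micrometres (typically parsed
#'   from the scanner log; see [parse_scan_log()]).
#' @return A [voxel_volume()] with \code{origin_index = 0}.
#' @export
read_reconstruction_stack <- function(directory, voxel_size_um) {
  files <- list.files(directory, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) stop("no slices in ", directory)
  files <- files[order(basename(files), method = "radix")]
  first <- read_slice_image(files[[1L]])
  d <- dim(first)
  data <- array(0L, dim = c(length(files), d[1], d[2]))
  data[1L, , ] <- first
  if (length(files) > 1L) {
    for (i in 2:length(files)) {
      m <- read_slice_image(files[[i]])
      if (!identical(dim(m), d))
        stop(sprintf("ragged stack: %s is %dx%d, expected %dx%d",
                     basename(files[[i]]), dim(m)[1], dim(m)[2], d[1], d[2]))
      data[i, , ] <- m
    }
  }
  voxel_volume(data, voxel_size_um, origin_index = 0L)
}

# Scanner-log key synonyms. The log dialect is INI-style "Key=Value" lines;
# keys are matched case-insensitively after stripping section headers. The
# synonym list is a maintained guess at common scanner-log vocabularies and
# can be extended.
.scan_log_keys <- list(
  tube_voltage_kv      = c("source voltage (kv)", "voltage (kv)", "source voltage"),
  tube_current_ua      = c("source current (ua)", "current (ua)", "source current"),
  filter_description   = c("filter", "filter description"),
  exposure_ms          = c("exposure (ms)", "exposure time (ms)", "exposure"),
  rotation_step_deg    = c("rotation step (deg)", "rotation step"),
  frame_averaging      = c("frame averaging", "averaging"),
  voxel_size_um        = c("pixel size (um)", "image pixel size (um)", "voxel size (um)"),
  ring_artifact_setting = c("ring artifact correction", "ring artifacts"),
  stack_count          = c("number of connected scans", "stacks", "stack count")
)

#' Parse a scanner log file
#'
#' Extracts acquisition metadata from INI-style scanner log text
#' (\code{Key=Value} lines, optional \code{[Section]} headers). Key matching
#' is case-insensitive over a documented synonym list; unknown keys are
#' ignored. The voxel size is mandatory because every physical measurement
#' downstream depends on it.
#'
#' @param log_text character: the log file contents (one element per line, or
#'   a single string with newlines).
#' @return A list of class \code{scan_metadata} with fields
#'   \code{tube_voltage_kv}, \code{tube_current_ua}, \code{filter_description},
#'   \code{exposure_ms}, \code{rotation_step_deg}, \code{frame_averaging},
#'   \code{voxel_size_um}, \code{ring_artifact_setting}, \code{stack_count}.
#'   Unmatched numeric fields are \code{NA}.
#' @export
parse_scan_log <- function(log_text) {
  lines <- unlist(strsplit(paste(log_text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  kv <- kv[vapply(kv, length, 1L) == 3L]
  keys <- tolower(trimws(vapply(kv, `[[`, "", 2L)))
  vals <- trimws(vapply(kv, `[[`, "", 3L))

  pick <- function(synonyms) {
    hit <- which(keys %in% synonyms)
    if (length(hit) == 0L) NA_character_ else vals[hit[[1L]]]
  }
  as_num <- function(x) suppressWarnings(as.numeric(x))

  md <- list(
    tube_voltage_kv       = as_num(pick(.scan_log_keys$tube_voltage_kv)),
    tube_current_ua       = as_num(pick(.scan_log_keys$tube_current_ua)),
    filter_description    = pick(.scan_log_keys$filter_description),
    exposure_ms           = as_num(pick(.scan_log_keys$exposure_ms)),
    rotation_step_deg     = as_num(pick(.scan_log_keys$rotation_step_deg)),
    frame_averaging       = as_num(pick(.scan_log_keys$frame_averaging)),
    voxel_size_um         = as_num(pick(.scan_log_keys$voxel_size_um)),
    ring_artifact_setting = as_num(pick(.scan_log_keys$ring_artifact_setting)),
    stack_count           = as_num(pick(.scan_log_keys$stack_count))
  )
  if (is.na(md$voxel_size_um))
    stop("incomplete log: no pixel/voxel size entry found")
  class(md) <- "scan_metadata"
  md
}

#' Write a volume to a chunked, compressed on-disk store
#'
#' Stores the volume as a directory of gzip-compressed chunks of axial
#' slices plus a JSON attribute sidecar carrying shape, chunking and voxel
#' size, mirroring chunked-array conventions. Default chunking is one axial
#' slice per chunk, matching the per-slice access pattern of canal
#' extraction.
#'
#' @param volume a [voxel_volume()].
#' @param store_path directory to create (overwritten if it exists).
#' @param chunk_slices axial slices per chunk.
#' @return \code{store_path}, invisibly.
#' @export
write_chunked_store <- function(volume, store_path, chunk_slices = 1L) {
  stopifnot(inherits(volume, "voxel_volume"), chunk_slices >= 1L)
  unlink(store_path, recursive = TRUE)
  dir.create(file.path(store_path, "chunks"), recursive = TRUE)
  d <- dim(volume$data)
  starts <- seq(1L, d[1], by = chunk_slices)
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + chunk_slices - 1L, d[1])
    chunk <- volume$data[idx, , , drop = FALSE]
    raw_bytes <- as.raw(as.integer(chunk))
    writeBin(memCompress(raw_bytes, type = "gzip"),
             file.path(store_path, "chunks", sprintf("c%06d.gz", k - 1L)))
  }
  attrs <- list(
    shape = d, dtype = "uint8", chunk_slices = as.integer(chunk_slices),
    n_chunks = length(starts), voxel_size_um = volume$voxel_size_um,
    origin_index = volume$origin_index
  )
  jsonlite::write_json(attrs, file.path(store_path, "attrs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(store_path)
}

#' Read a volume from a chunked store
#'
#' Inverse of [write_chunked_store()]; the round trip is voxel-identical,
#' including the voxel-size and origin metadata.
#'
#' @param store_path directory written by [write_chunked_store()].
#' @return A [voxel_volume()].
#' @export
read_chunked_store <- function(store_path) {
  attrs_file <- file.path(store_path, "attrs.json")
  if (!file.exists(attrs_file)) stop("store unreadable: missing attrs.json")
  attrs <- tryCatch(jsonlite::read_json(attrs_file, simplifyVector = TRUE),
                    error = function(e) stop("store unreadable: bad attrs.json"))
  d <- as.integer(attrs$shape)
  data <- array(0L, dim = d)
  starts <- seq(1L, d[1], by = attrs$chunk_slices)
  for (k in seq_along(starts)) {
    f <- file.path(store_path, "chunks", sprintf("c%06d.gz", k - 1L))
    if (!file.exists(f)) stop("store unreadable: missing chunk ", basename(f))
    idx <- starts[k]:min(starts[k] + attrs$chunk_slices - 1L, d[1])
    comp <- readBin(f, "raw", n = file.info(f)$size)
    raw_bytes <- memDecompress(comp, type = "gzip")
    data[idx, , ] <- array(as.integer(raw_bytes),
                           dim = c(length(idx), d[2], d[3]))
  }
  voxel_volume(data, attrs$voxel_size_um, origin_index = attrs$origin_index)
}
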