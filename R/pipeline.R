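#' Default pipeline configuration
#'
#' One flat list holding every threshold of the pipeline, with the working
#' defaults: fixed crop threshold 25 (of 255), 3D speckles < 1000 voxels,
#' per-slice canal speckles < 64 px and holes < 100 px, LOWESS span 0.05,
#' 400 um projection windows, 3.5 mm apical window and the 0.20 mm
#' physiological-foramen rule. \code{edb_slice} (NULL = automatic) is the
#' manual enamel--dentin-border override for metal-filled crowns.
#'
#' @param ... named overrides of individual entries.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    voxel_size_um = 10,        # fallback when no scanner log is present
    crop_threshold = 25,
    crop_min_voxels = 1000L,
    min_area_px = 64L,
    max_hole_px = 100L,
    lowess_frac = 0.05,
    window_um = 400,
    bottom_mm = 3.5,
    min_diameter_um = 200,
    edb_slice = NULL,
    chunk_slices = 8L,
    write_images = TRUE
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.config_stamp <- function(config) {
  as.character(jsonlite::toJSON(config[order(names(config))],
                                auto_unbox = TRUE, null = "null", digits = NA))
}

#' Process one tooth directory end to end
#'
#' Runs the full per-tooth workflow on a directory of reconstructed axial
#' slices: read (voxel size from the scanner log when present), crop to the
#' tooth, overview images, root-canal extraction, enamel--dentin-border
#' detection and slice planning, configuration coding, and physiological
#' foramen geometry. All artifacts (chunked stores, overview and report
#' images, JSON report) are written under \code{output_dir}. Re-running on a
#' completed directory with an identical configuration returns the stored
#' report without recomputation (\code{status = "cached"}); any config change
#' invalidates the cache. A stage failure is recorded in the report
#' (\code{status = "failed"}, with the stage name) instead of raised, so
#' batches keep going.
#'
#' @param directory tooth slice directory.
#' @param config configuration list from [default_config()].
#' @param output_dir artifact directory (default: \code{<directory>/output}).
#' @return the tooth report, a list (also persisted as
#'   \code{report.json}).
#' @export
process_tooth <- function(directory, config = default_config(),
                          output_dir = file.path(directory, "output")) {
  report_path <- file.path(output_dir, "report.json")
  stamp <- .config_stamp(config)
  if (file.exists(report_path)) {
    prev <- tryCatch(jsonlite::read_json(report_path, simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) && identical(prev$config_stamp, stamp) &&
        identical(prev$status, "complete")) {
      prev$status <- "cached"
      return(prev)
    }
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  report <- list(tooth_id = basename(normalizePath(directory)),
                 status = "complete", failed_stage = NULL,
                 config_stamp = stamp)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$status <<- "failed"
      report$failed_stage <<- name
      report$error <<- conditionMessage(e)
      NULL
    })
  }

  md <- NULL
  log_file <- list.files(directory, pattern = "\\.log$", full.names = TRUE)
  if (length(log_file) > 0L)
    md <- stage("log", parse_scan_log(readLines(log_file[[1L]], warn = FALSE)))
  vs <- if (!is.null(md)) md$voxel_size_um else config$voxel_size_um
  report$metadata <- md
  report$voxel_size_um <- vs

  vol <- stage("read", read_reconstruction_stack(directory, vs))
  if (report$status == "failed") { .persist_report(report, report_path); return(report) }

  cropped <- stage("crop", crop_volume(vol, config$crop_threshold,
                                       config$crop_min_voxels))
  if (report$status == "failed") { .persist_report(report, report_path); return(report) }
  report$bbox <- list(start = cropped$bbox$start, stop = cropped$bbox$stop)
  write_chunked_store(cropped$volume, file.path(output_dir, "cropped.store"),
                      config$chunk_slices)

  if (isTRUE(config$write_images)) {
    stage("overview", {
      mid <- middle_slices(cropped$volume)
      mips <- lapply(c("axial", "coronal", "sagittal"),
                     function(ax) max_intensity_projection(cropped$volume, ax))
      write_image(montage(c(mid, mips), columns = 3L),
                  file.path(output_dir, "overview.png"))
    })
  }

  canal <- stage("canal", extract_canal_volume(cropped$volume,
                                               config$min_area_px,
                                               config$max_hole_px))
  if (report$status == "failed") { .persist_report(report, report_path); return(report) }
  canal_vol <- voxel_volume(array(as.integer(canal) * 255L, dim = dim(canal)),
                            vs, cropped$volume$origin_index)
  write_chunked_store(canal_vol, file.path(output_dir, "canal.store"),
                      config$chunk_slices)

  res <- stage("classify", {
    bottom <- find_bottom(cropped$tooth_mask)
    if (!is.null(config$edb_slice)) {
      edb <- as.integer(config$edb_slice); src <- "manual"
    } else {
      prof <- smooth_profile(brightness_profile(cropped$volume),
                             config$lowess_frac)
      edb <- detect_edb(prof); src <- "automatic"
    }
    plan <- plan_slices(edb, bottom, config$window_um, src)
    apical <- extract_bottom_region(cropped$volume, bottom, config$bottom_mm)
    apex_idx <- seq(apical$origin_index - cropped$volume$origin_index + 1L,
                    bottom)
    edt <- euclidean_distance_map(canal, vs)
    foramina <- detect_foramina(canal, edt, apex_idx, config$min_diameter_um)
    code <- classify_configuration(canal, plan,
                                   sum(foramina$kind == "physiological"))
    if (isTRUE(config$write_images)) {
      windows <- lapply(plan$slice_indices, function(i)
        window_min_projection(cropped$volume, i, config$window_um))
      write_image(montage(windows, columns = 4L),
                  file.path(output_dir, "classification_windows.png"))
      ov <- overlay_edt(
        voxel_volume(apical$data, vs, apical$origin_index),
        euclidean_distance_map(
          canal[apex_idx, , , drop = FALSE], vs))
      mid_sag <- dim(ov$data)[1] %/% 2L + 1L
      write_image(ov$data[mid_sag, , ], file.path(output_dir, "apical_overlay.png"))
    }
    list(plan = plan, foramina = foramina, code = code, bottom = bottom)
  })
  if (report$status == "failed") { .persist_report(report, report_path); return(report) }

  report$edb_index <- res$plan$edb_index
  report$edb_source <- res$plan$edb_source
  report$bottom_index <- res$bottom
  report$slice_indices <- res$plan$slice_indices
  report$canal_counts <- res$code$counts
  report$main_foramina <- res$code$main_foramina
  report$code <- format(res$code)
  report$foramina <- res$foramina
  report$length_mm <- res$bottom * vs / 1000
  report$artifacts <- list(
    cropped_store = file.path(output_dir, "cropped.store"),
    canal_store = file.path(output_dir, "canal.store"),
    report = report_path)
  .persist_report(report, report_path)
  report
}

.persist_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows", force = TRUE)
}

#' Process a cohort of tooth directories
#'
#' Discovers every immediate subdirectory of \code{root_directory} that
#' contains slice images, processes each with [process_tooth()], and writes a
#' cohort table (CSV + JSON) plus a montage of axial projections. Per-tooth
#' failures are recorded in their row, never raised, and completed teeth are
#' skipped on re-runs, so the batch can be re-invoked as new scans arrive.
#'
#' @param root_directory directory of tooth directories.
#' @param config configuration list from [default_config()].
#' @return data frame with one row per tooth: id, status, code, EDB/bottom
#'   indices, tooth length (mm), foramina counts.
#' @export
batch <- function(root_directory, config = default_config()) {
  dirs <- list.dirs(root_directory, recursive = FALSE)
  dirs <- dirs[vapply(dirs, function(d)
    length(list.files(d, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)) > 0,
    logical(1))]
  rows <- lapply(dirs, function(d) {
    rep <- process_tooth(d, config)
    data.frame(
      tooth_id = rep$tooth_id,
      status = rep$status,
      code = if (!is.null(rep$code)) rep$code else NA_character_,
      edb_index = if (!is.null(rep$edb_index)) rep$edb_index else NA_integer_,
      bottom_index = if (!is.null(rep$bottom_index)) rep$bottom_index else NA_integer_,
      length_mm = if (!is.null(rep$length_mm)) rep$length_mm else NA_real_,
      n_physiological = if (!is.null(rep$foramina))
        sum(rep$foramina$kind == "physiological") else NA_integer_,
      n_accessory = if (!is.null(rep$foramina))
        sum(rep$foramina$kind == "accessory") else NA_integer_,
      stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(tooth_id = character(0), status = character(0),
               code = character(0), edb_index = integer(0),
               bottom_index = integer(0), length_mm = numeric(0),
               n_physiological = integer(0), n_accessory = integer(0))
  out_dir <- file.path(root_directory, "cohort")
  dir.create(out_dir, showWarnings = FALSE)
  utils::write.csv(tab, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(tab, file.path(out_dir, "cohort.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  tab
}
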