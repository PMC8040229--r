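test_that("slice stacks read in lexicographic order with shape bookkeeping", {
  dir <- withr::local_tempdir()
  imgs <- list(
    s002 = matrix(2 / 255, 4, 5),
    s001 = matrix(1 / 255, 4, 5),
    s003 = matrix(3 / 255, 4, 5)
  )
  # write in non-sorted creation order; read order must not depend on it
  for (nm in names(imgs))
    png::writePNG(imgs[[nm]], file.path(dir, paste0(nm, ".png")))
  vol <- read_reconstruction_stack(dir, 10)
  expect_s3_class(vol, "voxel_volume")
  expect_identical(dim(vol$data), c(3L, 4L, 5L))
  expect_identical(vol$origin_index, 0L)
  expect_true(all(vol$data[1, , ] == 1))
  expect_true(all(vol$data[2, , ] == 2))
  expect_true(all(vol$data[3, , ] == 3))
})

test_that("stack reading rejects empty and ragged inputs", {
  empty <- withr::local_tempdir()
  expect_error(read_reconstruction_stack(empty, 10), "no slices")

  ragged <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 4, 5), file.path(ragged, "a.png"))
  png::writePNG(matrix(0.5, 6, 5), file.path(ragged, "b.png"))
  expect_error(read_reconstruction_stack(ragged, 10), "ragged stack")

  bad <- withr::local_tempdir()
  writeLines("not a png", file.path(bad, "x.png"))
  expect_error(read_reconstruction_stack(bad, 10), "decode failure.*x.png")
})

test_that("16-bit slices are rescaled to 8-bit with a warning", {
  dir <- withr::local_tempdir()
  m <- matrix(seq(0, 1, length.out = 20), 4, 5)
  png::writePNG(m, file.path(dir, "a.png"), dpi = NULL)  # default 8-bit
  tiff::writeTIFF(m, file.path(dir, "b.tif"), bits.per.sample = 16L)
  expect_warning(vol <- read_reconstruction_stack(dir, 10), "16-bit")
  expect_true(all(vol$data >= 0 & vol$data <= 255))
  # both slices carry the same scene, so 8-bit contents agree after rescale
  expect_lte(max(abs(vol$data[1, , ] - vol$data[2, , ])), 1)
})

test_that("scanner logs parse with case-insensitive synonyms and unit fidelity", {
  log <- c(
    "[System]",
    "Scanner=SkyScan 1272",
    "[Acquisition]",
    "Source Voltage (kV)=80",
    "SOURCE CURRENT (uA)=125",
    "Filter=Al 1mm",
    "Exposure (ms)=950",
    "Rotation Step (deg)=0.4",
    "Frame Averaging=3",
    "Pixel Size (um)=10.0",
    "Ring Artifact Correction=14",
    "Unknown Key=ignored"
  )
  md <- parse_scan_log(log)
  expect_s3_class(md, "scan_metadata")
  expect_equal(md$tube_voltage_kv, 80)
  expect_equal(md$tube_current_ua, 125)
  expect_equal(md$voxel_size_um, 10.0)
  expect_equal(md$exposure_ms, 950)
  expect_equal(md$rotation_step_deg, 0.4)
  expect_equal(md$frame_averaging, 3)
  expect_equal(md$ring_artifact_setting, 14)
  expect_equal(md$filter_description, "Al 1mm")
})

test_that("a log without a voxel size is rejected as incomplete", {
  expect_error(parse_scan_log("Source Voltage (kV)=80"), "incomplete log")
})

test_that("chunked store round-trips voxels and metadata bit-identically", {
  set.seed(42)
  vol <- voxel_volume(array(sample(0:255, 1000, replace = TRUE), c(10, 10, 10)),
                      voxel_size_um = 10.0, origin_index = 7L)
  store <- file.path(withr::local_tempdir(), "v.store")
  for (chunk in c(1L, 4L)) {
    write_chunked_store(vol, store, chunk_slices = chunk)
    back <- read_chunked_store(store)
    expect_identical(back$data, vol$data)
    expect_identical(back$voxel_size_um, vol$voxel_size_um)
    expect_identical(back$origin_index, vol$origin_index)
  }
  expect_error(read_chunked_store(file.path(tempdir(), "nope")),
               "store unreadable")
})

test_that("the chunked store compresses an all-zero volume below its PNG stack", {
  vol <- voxel_volume(array(0L, c(100, 100, 100)), 10)
  tmp <- withr::local_tempdir()
  write_chunked_store(vol, file.path(tmp, "z.store"))
  png_dir <- file.path(tmp, "pngs")
  dir.create(png_dir)
  for (i in 1:100)
    png::writePNG(matrix(0, 100, 100), file.path(png_dir, sprintf("s%03d.png", i)))
  store_bytes <- sum(file.info(list.files(file.path(tmp, "z.store"),
                                          recursive = TRUE, full.names = TRUE))$size)
  png_bytes <- sum(file.info(list.files(png_dir, full.names = TRUE))$size)
  expect_lt(store_bytes, png_bytes)
})

test_that("voxel volume construction enforces its invariants", {
  expect_error(voxel_volume(matrix(0, 2, 2), 10), "3D")
  expect_error(voxel_volume(array(0, c(2, 2, 2)), -1), "positive")
  expect_error(voxel_volume(array(0, c(2, 2, 2)), 0), "positive")
})
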