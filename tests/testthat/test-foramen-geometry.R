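test_that("EDT handles the degenerate masks and scales to micrometres", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  attr(m, "voxel_size_um") <- 10
  edt <- euclidean_distance_map(m)
  expect_equal(edt[3, 3, 3], 10)           # 1 voxel = 10 um
  expect_true(all(edt[!m] == 0))

  empty <- array(FALSE, c(4, 4, 4))
  expect_true(all(euclidean_distance_map(empty, 10) == 0))
  expect_error(euclidean_distance_map(array(TRUE, c(3, 3, 3)), 10),
               "no background")
})

test_that("EDT matches brute-force nearest-background search exactly", {
  set.seed(13)
  for (rep in 1:12) {
    dims <- sample(5:12, 3, replace = TRUE)
    m <- random_mask(dims, p_salt = 0.2, n_blobs = 2)
    if (all(m)) m[1, 1, 1] <- FALSE
    got <- euclidean_distance_map(m, 1)
    want <- brute_edt(m)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("cylinder max EDT per slice sits within [r-1, r] voxels", {
  for (r in c(5, 8, 12)) {
    m <- cylinder_mask(nz = 30, side = 2 * r + 9, r = r)
    edt <- euclidean_distance_map(m, 10)
    # interior slices (away from the open cylinder ends)
    for (z in 12:18) {
      mx <- max(edt[z, , ]) / 10
      expect_gte(mx, r - 1)
      expect_lte(mx, r)
    }
  }
})

test_that("the apical window is 3.5 mm (350 slices at 10 um), clipped at the top", {
  vol <- voxel_volume(array(0L, c(400, 4, 4)), 10)
  apical <- extract_bottom_region(vol, 400)
  expect_equal(dim(apical$data)[1], 350L)
  expect_equal(apical$origin_index, 50L)

  short <- voxel_volume(array(0L, c(100, 4, 4)), 10)
  clipped <- extract_bottom_region(short, 100)
  expect_equal(dim(clipped$data)[1], 100L)

  # window ends exactly at the requested bottom slice
  vol$data[333, 2, 2] <- 99L
  expect_equal(extract_bottom_region(vol, 333)$origin_index, 0L)
  expect_equal(dim(extract_bottom_region(vol, 333)$data)[1], 333L)
})

test_that("the EDT overlay encodes canal radii and reformats losslessly", {
  set.seed(17)
  recon_data <- array(sample(0:150, 20 * 15 * 12, TRUE), c(20, 15, 12))
  recon <- voxel_volume(recon_data, 10)

  # empty canal: overlay equals the reformatted reconstruction
  zero_edt <- array(0, dim = dim(recon_data))
  attr(zero_edt, "voxel_size_um") <- 10
  ov0 <- overlay_edt(recon, zero_edt)
  expect_identical(ov0$data, axial_to_sagittal(recon$data))

  # sagittal reformat round-trips exactly
  expect_identical(sagittal_to_axial(axial_to_sagittal(recon_data)), recon_data)

  # cylinder: the maximum encoded radius equals the cylinder radius within 1
  rr <- matrix(rep(1:15, 12), 15, 12)
  cc <- matrix(rep(1:12, each = 15), 15, 12)
  disk <- (rr - 8)^2 + (cc - 6)^2 < 16   # radius 4 at (8, 6)
  m <- array(FALSE, c(20, 15, 12))
  for (z in 1:20) m[z, , ] <- disk
  edt <- euclidean_distance_map(m, 10)
  ov <- overlay_edt(recon, edt, encode_base = 200L)
  enc <- sagittal_to_axial(ov$data)
  expect_identical(enc[edt == 0], recon_data[edt == 0])
  max_radius <- max(enc[edt > 0]) - 200L
  expect_gte(max_radius, 3L)
  expect_lte(max_radius, 4L)

  bad <- array(0, c(2, 2, 2))
  expect_error(overlay_edt(recon, bad), "misaligned inputs")
})

test_that("foramina classify by the inclusive 0.20 mm diameter rule", {
  # radius 10 voxels at 10 um -> inscribed diameter exactly 200 um: physiological
  big <- cylinder_mask(nz = 20, side = 33, r = 10)
  f_big <- detect_foramina(big, apex_window_slices = 15:20)
  expect_equal(nrow(f_big), 1L)
  expect_equal(f_big$diameter_um, 200)
  expect_equal(f_big$kind, "physiological")

  # radius 9 -> 180 um < 200 um: accessory
  small <- cylinder_mask(nz = 20, side = 33, r = 9)
  f_small <- detect_foramina(small, apex_window_slices = 15:20)
  expect_equal(f_small$diameter_um, 180)
  expect_equal(f_small$kind, "accessory")
})

test_that("a two-tube apex yields one physiological and one accessory foramen", {
  side <- 61
  m <- cylinder_mask(nz = 30, side = side, r = 15, centre = c(31, 20)) |
    cylinder_mask(nz = 30, side = side, r = 5, centre = c(31, 48))
  attr(m, "voxel_size_um") <- 10
  edt <- euclidean_distance_map(m, 10)
  f <- detect_foramina(m, edt, apex_window_slices = 25:30)
  f <- f[order(f$diameter_um, decreasing = TRUE), ]
  expect_equal(nrow(f), 2L)
  expect_equal(f$kind, c("physiological", "accessory"))
  expect_equal(f$diameter_um, c(300, 100))
  # sum rule: physiological + accessory = number of apical exit components
  expect_equal(sum(f$kind == "physiological") + sum(f$kind == "accessory"), 2L)
})

test_that("foramen measurements depend only on the mask, not reconstruction noise", {
  ph_clean <- generate_phantom(default_phantom_suite()[[5]])  # 1-2-2/2 sigma 0
  f <- detect_foramina(ph_clean$truth$canal_mask,
                       apex_window_slices = seq_len(dim(ph_clean$truth$canal_mask)[1]))
  expect_equal(nrow(f), nrow(ph_clean$truth$foramina))
  expect_equal(sort(f$diameter_um), sort(ph_clean$truth$foramina$diameter_um))
  expect_equal(sort(f$kind), sort(ph_clean$truth$foramina$kind))
})
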