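ramp_volume <- function(n = 20, side = 6) {
  data <- array(0L, c(n, side, side))
  for (i in seq_len(n)) data[i, , ] <- i
  voxel_volume(data, 10)
}

test_that("brightness profile is the per-slice mean", {
  vol <- ramp_volume()
  prof <- brightness_profile(vol)
  expect_equal(prof$raw, as.numeric(1:20))

  const <- voxel_volume(array(7L, c(12, 5, 5)), 10)
  pc <- smooth_profile(brightness_profile(const), frac = 0.3)
  expect_true(all(pc$derivative == 0))
})

test_that("LOWESS smoothing preserves lines, respects symmetry, damps noise", {
  prof <- smooth_profile(brightness_profile(ramp_volume(40)), frac = 0.2)
  expect_equal(prof$smoothed[5:35], prof$raw[5:35], tolerance = 1e-6)

  # symmetric profile stays symmetric under a full-span smoother
  sym <- structure(list(raw = c(1:10, 10:1), smoothed = NULL, derivative = NULL),
                   class = "axis_profile")
  ssym <- smooth_profile(sym, frac = 1)
  expect_equal(ssym$smoothed, rev(ssym$smoothed), tolerance = 1e-8)

  # noisy step: smoothed variance over the flat segments drops below raw
  set.seed(9)
  raw <- c(rep(200, 60), rep(100, 60)) + rnorm(120, 0, 5)
  noisy <- structure(list(raw = raw, smoothed = NULL, derivative = NULL),
                     class = "axis_profile")
  sm <- smooth_profile(noisy, frac = 0.1)
  expect_lt(var(sm$smoothed[10:50]), var(raw[10:50]))
  expect_lt(var(sm$smoothed[70:110]), var(raw[70:110]))

  short <- structure(list(raw = 1:5, smoothed = NULL, derivative = NULL),
                     class = "axis_profile")
  expect_error(smooth_profile(short), "profile too short")
})

test_that("EDB detection finds a step edge and is translation-equivariant", {
  step_profile <- function(k, n = 120) {
    structure(list(raw = c(rep(200, k), rep(100, n - k)),
                   smoothed = NULL, derivative = NULL), class = "axis_profile")
  }
  for (k in c(30, 60, 90)) {
    edb <- detect_edb(smooth_profile(step_profile(k), frac = 0.05))
    expect_lte(abs(edb - k), 2)
  }
  # shifting the step by 17 slices shifts the detection by 17
  e1 <- detect_edb(smooth_profile(step_profile(40), frac = 0.05))
  e2 <- detect_edb(smooth_profile(step_profile(57), frac = 0.05))
  expect_equal(e2 - e1, 17)

  flat <- structure(list(raw = rep(5, 50), smoothed = NULL, derivative = NULL),
                    class = "axis_profile")
  expect_error(detect_edb(smooth_profile(flat, frac = 0.2)), "no EDB")
})

test_that("EDB detection recovers the phantom enamel cap within 3 slices", {
  for (k in c(1, 2)) {  # sigma 0 and sigma 10 renderings of the same tooth
    ph <- generate_phantom(default_phantom_suite()[[k]])
    cr <- crop_volume(ph$volume)
    prof <- smooth_profile(brightness_profile(cr$volume))
    edb <- detect_edb(prof) + cr$volume$origin_index
    expect_lte(abs(edb - ph$truth$edb_slice), 3)
  }
})

test_that("the tooth bottom is the lowest foreground slice", {
  m <- array(FALSE, c(120, 5, 5))
  m[1:100, 2, 2] <- TRUE
  expect_equal(find_bottom(m), 100)
  m2 <- array(FALSE, c(60, 5, 5))
  m2[43, 3, 3] <- TRUE
  expect_equal(find_bottom(m2), 43)
  expect_error(find_bottom(array(FALSE, c(4, 4, 4))), "no foreground")
})

test_that("slice planning is equidistant within rounding", {
  p <- plan_slices(0, 9)
  expect_identical(p$slice_indices, c(0L, 3L, 6L, 9L))

  # the published worked example: EDB 911, bottom 2341
  p2 <- plan_slices(911, 2341)
  expect_identical(p2$slice_indices, c(911L, 1388L, 1864L, 2341L))
  gaps <- diff(p2$slice_indices)
  expect_lte(max(gaps) - min(gaps), 1L)

  expect_error(plan_slices(100, 100), "invalid axis landmarks")
  expect_error(plan_slices(100, 103), "invalid axis landmarks")
})

test_that("minimum-gray windows darken where fine structures pass through", {
  # 400 um at 10 um voxels spans 40 slices
  vol <- ramp_volume(60, side = 8)
  w <- window_min_projection(vol, 30, window_um = 400)
  expect_true(all(w == 10))  # minimum of slices 10..49

  # window of a single slice is the slice itself
  w1 <- window_min_projection(vol, 30, window_um = 10)
  expect_true(all(w1 == 30))

  # a fine accessory canal spanning part of the window shows up darker
  data <- array(120L, c(50, 20, 20))
  data[20:28, 10, 10] <- 10L   # short dark thread above the centre slice
  vol2 <- voxel_volume(data, 10)
  centre_only <- vol2$data[35, , ]
  w2 <- window_min_projection(vol2, 35, window_um = 400)
  expect_lt(w2[10, 10], centre_only[10, 10])

  # constant volume projects to a constant image, clipped at edges without error
  const <- voxel_volume(array(9L, c(15, 4, 4)), 10)
  expect_true(all(window_min_projection(const, 2, 400) == 9))
})

test_that("canal counting matches the flood-fill oracle on random slices", {
  set.seed(31)
  expect_equal(count_canals(matrix(FALSE, 10, 10)), 0L)
  two <- matrix(FALSE, 20, 20)
  two[3:5, 3:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_equal(count_canals(two), 2L)
  for (rep in 1:8) {
    m <- matrix(runif(40 * 40) < 0.25, 40, 40)
    expect_equal(count_canals(m), max(flood_fill_label(m, 8L)))
  }
})

test_that("configuration codes render as a-b-c/d and recover phantom truth", {
  expect_equal(format(canal_code(c(1, 2, 2), 2)), "1-2-2/2")
  empty <- array(FALSE, c(30, 10, 10))
  plan <- plan_slices(2, 28)
  expect_equal(format(classify_configuration(empty, plan, 0)), "0-0-0/0")

  # every suite phantom, noiseless: exact code recovery
  suite <- default_phantom_suite()
  for (sp in suite[vapply(suite, function(s) s$noise_sigma == 0, TRUE)]) {
    ph <- generate_phantom(sp)
    cr <- crop_volume(ph$volume)
    canal <- extract_canal_volume(cr$volume)
    prof <- smooth_profile(brightness_profile(cr$volume))
    plan <- plan_slices(detect_edb(prof), find_bottom(cr$tooth_mask))
    f <- detect_foramina(canal, apex_window_slices = seq_len(dim(canal)[1]))
    code <- classify_configuration(canal, plan, sum(f$kind == "physiological"))
    expect_equal(format(code), attr(sp, "code"))
  }
})
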