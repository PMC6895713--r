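test_that("circularity enforces order and positivity", {
  expect_equal(circularity(10, 10), 1)
  expect_equal(circularity(16, 10), 1.6)
  expect_equal(circularity(10, 16), 1.6)    # order invariance
  expect_error(circularity(10, 0), "> 0")
  expect_error(circularity(-1, 2), "> 0")
})

test_that("moment-equivalent axes recover disks and ellipses to half a pixel", {
  sp <- 0.5
  disk <- make_test_slice(raster_ellipse(5, 5, spacing = sp), spacing = sp)
  m <- measure_axes(disk, smoothing_sigma = 0)
  expect_equal(m$d1, 10, tolerance = sp / 2 / 10)
  expect_equal(m$d2, 10, tolerance = sp / 2 / 10)
  ell <- make_test_slice(raster_ellipse(8, 5, spacing = sp), spacing = sp)
  m <- measure_axes(ell, smoothing_sigma = 0)
  expect_equal(m$d1, 16, tolerance = sp / 2 / 16)
  expect_equal(m$d2, 10, tolerance = sp / 2 / 10)
  expect_gte(m$d1, m$d2)
})

test_that("measured axes are invariant to in-plane rotation (half pixel)", {
  sp <- 0.5
  for (ang in c(0, 0.3, pi / 4, 1.2)) {
    img <- raster_ellipse(8, 5, spacing = sp, angle = ang)
    m <- measure_axes(make_test_slice(img, spacing = sp), smoothing_sigma = 0)
    expect_equal(m$d1, 16, tolerance = sp / 16)
    expect_equal(m$d2, 10, tolerance = sp / 10)
  }
})

test_that("hole filling makes an annulus measure as its outer envelope", {
  sp <- 0.5
  outer_img <- raster_ellipse(7, 7, spacing = sp)
  inner <- raster_ellipse(4, 4, spacing = sp, n = nrow(outer_img))
  ring <- outer_img * (1 - inner)
  m <- measure_axes(make_test_slice(ring, spacing = sp), smoothing_sigma = 0)
  expect_equal(m$d1, 14, tolerance = sp / 2 / 14)
  expect_equal(m$d2, 14, tolerance = sp / 2 / 14)
})

test_that("Otsu-based measurement is invariant to intensity scaling", {
  sp <- 0.5
  img <- raster_ellipse(6, 4, spacing = sp) * 37 + 1
  m1 <- measure_axes(make_test_slice(img, spacing = sp), smoothing_sigma = 0)
  m2 <- measure_axes(make_test_slice(img * 251, spacing = sp), smoothing_sigma = 0)
  expect_equal(m1$d1, m2$d1)
  expect_equal(m1$d2, m2$d2)
  expect_equal(m1$n_pixels, m2$n_pixels)
})

test_that("empty or off-centre slices raise the documented error", {
  sp <- 1
  img <- matrix(0, 31, 31)
  img[2:6, 2:6] <- 1                         # blob far from the centre
  expect_error(measure_axes(make_test_slice(img, sp), smoothing_sigma = 0),
               "tube not found at slice center")
})

test_that("border-touching components are flagged as truncated", {
  img <- raster_ellipse(10, 10, spacing = 1, pad = -2, n = 19)
  expect_warning(
    m <- measure_axes(make_test_slice(img, 1), smoothing_sigma = 0),
    "truncation")
  expect_true(m$truncated)
})

test_that("feret estimator agrees with moments on convex shapes", {
  sp <- 0.25
  img <- raster_ellipse(8, 5, spacing = sp)
  mf <- measure_axes(make_test_slice(img, sp), smoothing_sigma = 0,
                     method = "feret")
  expect_equal(mf$d1, 16, tolerance = 0.05)
  expect_equal(mf$d2, 10, tolerance = 0.05)
})

test_that("preprocess_for_tracing dilates and smooths as specified", {
  arr <- array(0, dim = c(21, 21, 21))
  arr[11, 11, 11] <- 1
  vol <- voxel_volume(arr, c(1, 1, 1))
  ## identity at zero radius and sigma
  same <- preprocess_for_tracing(vol, 0, 0)
  expect_equal(same$data, arr)
  ## single bright voxel spans ~ 2 r / spacing + 1 voxels after dilation
  dil <- preprocess_for_tracing(vol, dilation_radius = 3, gaussian_sigma = 0)
  prof <- dil$data[, 11, 11]
  expect_equal(sum(prof > 0), 7)
  ## two granules 3 um apart merge into one component with radius 2
  arr2 <- array(0, dim = c(21, 21, 21))
  arr2[9, 11, 11] <- 1
  arr2[12, 11, 11] <- 1
  merged <- preprocess_for_tracing(voxel_volume(arr2, c(1, 1, 1)),
                                   dilation_radius = 2, gaussian_sigma = 0)
  bridge <- merged$data[9:12, 11, 11]
  expect_true(all(bridge == 1))
  expect_error(preprocess_for_tracing(vol, -1, 0), ">= 0")
})

test_that("granular annulus recovers the generating axis ratio within 10%", {
  fx <- make_rendered_cylinder(d = 12, seed = 4, ellipticity = 1.5)
  gt <- fx$ground_truth
  i <- which.min(abs(gt$s - 35))
  sl <- extract_slice(fx$volume, origin = unclass(gt$centerline_dense)[i, ],
                      normal = gt$tangent[i, ], half_width = 20)
  m <- measure_axes(sl)
  expect_equal(m$d1 / m$d2, 1.5, tolerance = 0.10)
  expect_equal((m$d1 + m$d2) / 2, 12, tolerance = 0.10)
})

test_that("measure_sst composes the pipeline and reports sample context on error", {
  fx <- make_rendered_cylinder(d = 10, seed = 2)
  rec <- measure_sst(fx$volume, fx$side_a, fx$side_b)
  expect_s3_class(rec, "sst_record")
  expect_equal(nrow(rec$measurements), 10L)        # default n_points = 10
  expect_true(all(rec$measurements$d1_um >= rec$measurements$d2_um))
  expect_true(all(rec$measurements$circularity >= 1))
  expect_equal(rec$measurements$s_um[1L], 0)
  tab <- sst_measurement_table(rec)
  expect_named(tab, c("bird_id", "sst_id", "point_index", "s_um", "d1_um",
                      "d2_um", "circularity", "mean_diameter_um",
                      "total_length_um"))
  ## traces outside the volume are rejected up front
  far <- polyline3d(unclass(fx$side_a) + 500)
  expect_error(measure_sst(fx$volume, far, fx$side_b), "volume bounds")
})

test_that("noise-free cylinders measure without bias across diameters", {
  ## mean-diameter bias under 1 voxel for d in {6, 10, 20, 30} um
  for (d in c(6, 10, 20, 30)) {
    fx <- make_rendered_cylinder(d = d, seed = 1, L = 50)
    rec <- suppressWarnings(measure_sst(fx$volume, fx$side_a, fx$side_b))
    bias <- mean(rec$measurements$mean_diameter_um) - d
    expect_lt(abs(bias), 1.0, label = sprintf("bias at d = %g", d))
  }
})

test_that("quadratic-profile tubule has its smallest diameter at the orifice", {
  straight <- polyline3d(cbind(seq(12, 132, length.out = 150L), 30, 30))
  ## strict minimum at s = 0 (the blind end stays wider than the orifice)
  geom <- sst_geometry(straight, diameter_profile = c(10.1, 25.2, -20),
                       ellipticity = 1)
  rc <- render_config(volume_shape = c(144L, 60L, 60L), voxel_spacing = c(1, 1, 1),
                      granule_density = 250, shot_noise = FALSE,
                      noise_read_sd = 0, seed = 6)
  ren <- render_sst(geom, rc)
  tr <- simulate_side_traces(ren$ground_truth, jitter_sd = 0, seed = 7)
  rec <- measure_sst(ren$volume, tr$side_a, tr$side_b)
  md <- rec$measurements$mean_diameter_um
  expect_equal(which.min(md), 1L)
  expect_gt(max(md), md[1L] + 3)           # mid-tube visibly wider
})
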