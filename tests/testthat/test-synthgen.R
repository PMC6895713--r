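test_that("make_centerline honours length, straightness, determinism", {
  straight <- make_centerline(seed = 1, total_length = 100, tortuosity = 0)
  expect_equal(arclength(straight)$total, 100, tolerance = 1e-9)
  ## zero tortuosity is a straight line: chord length == arc length
  chord <- sqrt(sum((straight[nrow(straight), ] - straight[1L, ])^2))
  expect_equal(chord, 100, tolerance = 1e-9)
  curved <- make_centerline(seed = 1, total_length = 100, tortuosity = 0.3)
  expect_equal(arclength(curved)$total, 100, tolerance = 0.005 * 100)
  expect_lt(sqrt(sum((curved[nrow(curved), ] - curved[1L, ])^2)), 100)
  ## determinism
  again <- make_centerline(seed = 1, total_length = 100, tortuosity = 0.3)
  expect_identical(unclass(curved), unclass(again))
  other <- make_centerline(seed = 2, total_length = 100, tortuosity = 0.3)
  expect_false(isTRUE(all.equal(unclass(curved), unclass(other))))
  expect_error(make_centerline(1, -5, 0), "total_length")
  expect_error(make_centerline(1, 50, -0.1), "tortuosity")
})

test_that("geometry and config constructors enforce their invariants", {
  line <- polyline3d(cbind(seq(0, 50, 5), 0, 0))
  expect_error(sst_geometry(line, diameter_profile = c(1, -10, 0)), "positive")
  expect_error(sst_geometry(line, ellipticity = 0.8), "ellipticity")
  expect_error(render_config(voxel_spacing = c(1, -1, 1)), "spacing")
  g <- sst_geometry(line)
  expect_equal(g$total_length, 50)
  expect_equal(sstmorph:::profile_diameter(g, c(0, 0.5, 1)),
               c(10.1, 16.4, 10.1))
})

test_that("render_sst is deterministic and confines granules to the shell", {
  fx1 <- make_rendered_cylinder(d = 10, seed = 3, L = 40)
  fx2 <- make_rendered_cylinder(d = 10, seed = 3, L = 40)
  expect_identical(fx1$volume$data, fx2$volume$data)
  gt <- fx1$ground_truth
  ## conservation: floor(density x arc length) granules
  expect_equal(gt$n_granules, floor(20 * 10 * 40))
  ## noise-free wide-lumen render: lumen interior stays below the granule
  ## intensity floor (thin epithelium so the lumen is genuinely open)
  line <- polyline3d(cbind(seq(15, 65, length.out = 60L), 24, 24))
  rc <- render_config(volume_shape = c(80L, 48L, 48L), voxel_spacing = c(1, 1, 1),
                      granule_density = 300, epithelium_thickness = 2,
                      shot_noise = FALSE, noise_read_sd = 0, seed = 2)
  ren <- render_sst(sst_geometry(line, c(16, 0, 0), ellipticity = 1), rc)
  vol <- ren$volume
  inner <- vol$data[25:55, 23:25, 23:25]     # within ~2 um of the axis
  expect_lt(max(inner), 0.05 * max(vol$data))
  ## granule-free render contains only background
  rc0 <- render_config(volume_shape = c(64L, 48L, 48L), voxel_spacing = c(1, 1, 1),
                       granule_density = 0,
                       shot_noise = FALSE, noise_read_sd = 0, seed = 1)
  line <- polyline3d(cbind(seq(15, 55, length.out = 50L), 24, 24))
  ren0 <- render_sst(sst_geometry(line, c(8, 0, 0), ellipticity = 1), rc0)
  expect_true(all(ren0$volume$data == 0))
  expect_equal(ren0$ground_truth$n_granules, 0L)
})

test_that("render_sst rejects tubes that leave the volume, naming the arc position", {
  line <- polyline3d(cbind(seq(5, 120, length.out = 60L), 24, 24))
  rc <- render_config(volume_shape = c(64L, 48L, 48L), seed = 1)
  expect_error(render_sst(sst_geometry(line, c(8, 0, 0)), rc),
               "leaves the volume.*s = ")
})

test_that("side traces bracket the centerline and midpoints are unbiased", {
  fx <- make_rendered_cylinder(d = 10, seed = 5, L = 60)
  tr <- simulate_side_traces(fx$ground_truth, jitter_sd = 0, seed = 1)
  a <- unclass(tr$side_a); b <- unclass(tr$side_b)
  ## straight cylinder radius 5: parallel lines 10 um apart
  gaps <- sqrt(rowSums((a - b)^2))
  expect_equal(gaps, rep(10, nrow(a)), tolerance = 1e-9)
  ## jitter-free pair midpoints lie on the true centerline (< 0.1 um)
  mid <- (a + b) / 2
  ctr <- unclass(fx$ground_truth$centerline_dense)
  d_to_line <- sqrt((mid[, 2L] - ctr[1L, 2L])^2 + (mid[, 3L] - ctr[1L, 3L])^2)
  expect_lt(max(d_to_line), 0.1)
  ## jittered midpoints are unbiased: mean distance to centerline < jitter sd
  tr_j <- simulate_side_traces(fx$ground_truth, jitter_sd = 0.5, seed = 2,
                               n_points = 200L)
  mid_j <- (unclass(tr_j$side_a) + unclass(tr_j$side_b)) / 2
  dist_j <- sqrt((mid_j[, 2L] - ctr[1L, 2L])^2 + (mid_j[, 3L] - ctr[1L, 3L])^2)
  expect_lt(mean(dist_j), 0.5)
  expect_error(simulate_side_traces(fx$ground_truth, jitter_sd = -1), "jitter_sd")
})

test_that("measurement tables have the stated schema, size, determinism", {
  tab <- make_measurement_table(n_birds = 10L, n_points = 10L, seed = 9)
  expect_equal(nrow(tab), 100L)
  expect_named(tab, c("bird_id", "sst_id", "point_index", "s_um", "d1_um",
                      "d2_um", "circularity", "mean_diameter_um",
                      "total_length_um"))
  expect_equal(length(unique(tab$bird_id)), 10L)
  expect_true(all(tab$d1_um >= tab$d2_um))
  expect_true(all(tab$s_um >= 0))
  expect_identical(tab, make_measurement_table(n_birds = 10L, n_points = 10L,
                                               seed = 9))
  expect_error(make_measurement_table(n_birds = 1L), "n_birds")
  expect_error(make_measurement_table(n_points = 2L), "n_points")
})

test_that("zero-noise tables reproduce the quadratic exactly", {
  tab <- make_measurement_table(noise_sd = 0, intercept_sd = 0,
                                circ_noise_sd = 0, circ_intercept_sd = 0,
                                seed = 1)
  sn <- tab$s_um / tab$total_length_um
  expect_equal(tab$mean_diameter_um, 10.1 + 25.2 * sn - 25.2 * sn^2,
               tolerance = 1e-12)
  expect_equal(tab$circularity, rep(1.6, nrow(tab)), tolerance = 1e-12)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::rnorm(5)
  set.seed(123)
  invisible(make_measurement_table(seed = 77))
  invisible(make_centerline(seed = 77, 100, 0.3))
  after <- stats::rnorm(5)
  expect_identical(before, after)
})
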