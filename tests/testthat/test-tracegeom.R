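test_that("arclength matches hand and closed-form values", {
  expect_equal(arclength(polyline3d(rbind(c(0, 0, 0), c(0, 0, 10))))$total, 10)
  path345 <- polyline3d(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  al <- arclength(path345)
  expect_equal(al$total, 7)
  expect_equal(al$cumulative, c(0, 3, 7))
  ## dense polygonal helix, radius 3, unit rise per radian, two turns
  hx <- make_helix(r = 3, c = 1, t_max = 4 * pi, n = 2000L)
  expect_equal(arclength(hx)$total, helix_length(3, 1, 4 * pi), tolerance = 1e-3)
})

test_that("arclength rejects degenerate input and is rigid-motion invariant", {
  expect_error(polyline3d(matrix(c(1, 2, 3), nrow = 1)), "at least 2")
  expect_error(polyline3d(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
  set.seed(42)
  hx <- make_helix(n = 300L)
  for (i in 1:5) {
    R <- random_rotation()
    shift <- stats::rnorm(3, sd = 50)
    moved <- polyline3d(sweep(unclass(hx) %*% t(R), 2L, shift, "+"))
    expect_equal(arclength(moved)$total, arclength(hx)$total, tolerance = 1e-9)
  }
})

test_that("resample_equidistant places points at k L / (n - 1)", {
  line <- polyline3d(rbind(c(0, 0, 0), c(0, 90, 0)))
  rs <- resample_equidistant(line, 10L)
  expect_equal(nrow(rs), 10L)
  spacing <- sqrt(rowSums(diff(unclass(rs))^2))
  expect_equal(spacing, rep(10, 9), tolerance = 1e-9)
  ## n = 2 returns the endpoints exactly
  hx <- make_helix(n = 500L)
  ends <- resample_equidistant(hx, 2L)
  expect_equal(unclass(ends), unclass(hx)[c(1L, 500L), ], ignore_attr = TRUE)
  ## circle arc: resampled points sit at analytically equal angles
  arc <- make_arc(r = 10, ang = pi / 2, n = 4000L)
  rs5 <- resample_equidistant(arc, 5L)
  expect_equal(atan2(rs5[, 2L], rs5[, 1L]), seq(0, pi / 2, length.out = 5),
               tolerance = 1e-3)
  expect_error(resample_equidistant(line, 1L), "n must be >= 2")
})

test_that("consecutive resampled spacings are equal to 1e-6 relative", {
  ## strict spacing contract on straight polylines with uneven vertices,
  ## where chord spacing equals arc spacing exactly
  line <- polyline3d(cbind(seq(0, 1, length.out = 17)^2 * 100, 0, 0))
  rs <- resample_equidistant(line, 11L)
  spacing <- sqrt(rowSums(diff(unclass(rs))^2))
  expect_lt(max(abs(spacing / mean(spacing) - 1)), 1e-6)
  ## on curves, resampled vertices interpolate the original polyline: each
  ## output point lies on some input segment (distance ~ 0)
  curve <- make_centerline(seed = 3, total_length = 200, tortuosity = 0.4)
  rs <- resample_equidistant(curve, 10L)
  p <- unclass(curve)
  seg_dist <- function(pt) {
    a <- p[-nrow(p), , drop = FALSE]
    d <- p[-1L, , drop = FALSE] - a
    tt <- rowSums(sweep(a, 2L, pt, function(x, y) (y - x)) * d) / rowSums(d^2)
    tt <- pmin(pmax(tt, 0), 1)
    proj <- a + d * tt
    sqrt(min(rowSums(sweep(proj, 2L, pt, "-")^2)))
  }
  expect_lt(max(apply(unclass(rs), 1L, seg_dist)), 1e-9)
})

test_that("resample_equidistant is idempotent on its own output", {
  line <- polyline3d(cbind(c(0, 7, 13, 40), 0, 0))
  r1 <- resample_equidistant(line, 8L)
  r2 <- resample_equidistant(r1, 8L)
  expect_equal(unclass(r1), unclass(r2), tolerance = 1e-12)
  ## smooth dense curve: second pass moves points by < 0.1 um
  hx <- make_helix(n = 2000L)
  r1 <- resample_equidistant(hx, 10L)
  r2 <- resample_equidistant(r1, 10L)
  expect_lt(max(sqrt(rowSums((unclass(r1) - unclass(r2))^2))), 0.1)
})

test_that("average_trace gives the midline and is symmetric", {
  a <- polyline3d(cbind(seq(0, 50, length.out = 20), -5, 0))
  b <- polyline3d(cbind(seq(0, 50, length.out = 35), 5, 0))
  mid <- average_trace(a, b, n_dense = 100L)
  expect_equal(max(abs(mid[, 2L])), 0, tolerance = 1e-9)
  expect_equal(range(mid[, 1L]), c(0, 50), tolerance = 1e-9)
  ## symmetric in its arguments
  m1 <- average_trace(a, b, n_dense = 73L)
  m2 <- average_trace(b, a, n_dense = 73L)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-12)
  ## degenerate identity
  same <- average_trace(a, a, n_dense = 20L)
  expect_equal(unclass(same), unclass(resample_equidistant(a, 20L)),
               tolerance = 1e-12)
})

test_that("average_trace of concentric arcs is the mid-radius arc", {
  inner <- make_arc(r = 8, ang = pi / 2, n = 1500L)
  outer <- make_arc(r = 12, ang = pi / 2, n = 2500L)
  mid <- average_trace(inner, outer, n_dense = 400L)
  radii <- sqrt(mid[, 1L]^2 + mid[, 2L]^2)
  expect_lt(max(abs(radii - 10)) / 10, 0.01)
})

test_that("average_trace rejects opposite orientations with guidance", {
  a <- polyline3d(cbind(seq(0, 50, length.out = 20), -5, 0))
  b_rev <- polyline3d(cbind(seq(50, 0, length.out = 20), 5, 0))
  expect_error(average_trace(a, b_rev), "reverse")
})

test_that("refining n_dense changes the averaged centerline by < 0.1 um", {
  set.seed(11)
  curve <- make_centerline(seed = 5, total_length = 150, tortuosity = 0.35)
  offs <- matrix(stats::rnorm(3), nrow = 1L)
  offs <- offs / sqrt(sum(offs^2)) * 4
  a <- polyline3d(sweep(unclass(curve), 2L, offs, "+"))
  b <- polyline3d(sweep(unclass(curve), 2L, offs, "-"))
  m1 <- resample_equidistant(average_trace(a, b, n_dense = 200L), 50L)
  m2 <- resample_equidistant(average_trace(a, b, n_dense = 400L), 50L)
  expect_lt(max(sqrt(rowSums((unclass(m1) - unclass(m2))^2))), 0.1)
})

test_that("tangent_at matches analytic tangents", {
  line <- polyline3d(cbind(0, 0, seq(0, 30, length.out = 7)))
  for (i in 1:7) expect_equal(tangent_at(line, i), c(0, 0, 1))
  ## circle in the xy-plane, counterclockwise, at (r, 0, 0)
  circ <- make_arc(r = 5, ang = 2 * pi, n = 3000L)
  expect_equal(tangent_at(circ, 1L), c(0, 1, 0), tolerance = 1e-2)
  ## helix, 1000 vertices: worst angular deviation below 0.5 degrees
  hx <- make_helix(r = 3, c = 1, t_max = 4 * pi, n = 1000L)
  t_par <- seq(0, 4 * pi, length.out = 1000L)
  truth <- helix_tangent(t_par)
  worst <- 0
  for (i in seq(1L, 1000L, by = 13L)) {
    ang <- acos(min(1, sum(tangent_at(hx, i) * truth[i, ])))
    worst <- max(worst, ang * 180 / pi)
  }
  expect_lt(worst, 0.5)
  expect_error(tangent_at(line, 99L), "out of range")
})

test_that("sample_centerline returns N samples with s, unit tangents", {
  line <- polyline3d(cbind(0, seq(0, 90, length.out = 31), 0))
  cs <- sample_centerline(line)              # default n = 10
  expect_equal(nrow(cs), 10L)
  expect_equal(cs$s_um, seq(0, 90, by = 10))
  expect_equal(attr(cs, "total_length_um"), 90)
  norms <- sqrt(cs$tx^2 + cs$ty^2 + cs$tz^2)
  expect_equal(norms, rep(1, 10L), tolerance = 1e-9)
  expect_true(all(diff(cs$s_um) > 0))
})
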