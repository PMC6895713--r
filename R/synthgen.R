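#' Ground-truth tubule geometry
#'
#' The stated world of the synthetic generator: a smooth 3D centerline, a
#' quadratic diameter profile on normalized arc length
#' `d(s) = c0 + c1 s + c2 s^2`, `s in [0, 1]` (the diameter enclosed by the
#' autofluorescent epithelium, um; minimum at the orifice), a constant
#' cross-sectional ellipticity (major/minor >= 1), and a fixed major-axis
#' orientation about the local tangent. With ellipticity `e`, the ground
#' truth axis diameters at arc position s are `d1 = 2 e d(s) / (1 + e)` and
#' `d2 = 2 d(s) / (1 + e)`, so `(d1 + d2)/2 = d(s)` and `d1/d2 = e`.
#'
#' Defaults are the study's reported morphology: orifice diameter 10.1 um,
#' widest section 16.4 um at the midpoint (profile `c(10.1, 25.2, -25.2)`),
#' ellipticity 1.6.
#'
#' @param centerline a [polyline3d()]; its arc length defines `total_length`.
#' @param diameter_profile numeric `c(c0, c1, c2)`, um.
#' @param ellipticity major/minor axis ratio, >= 1 (default 1.6).
#' @param major_axis_orientation angle of the major axis about the tangent,
#'   radians (default 0).
#' @return object of class `sst_geometry`.
#' @export
sst_geometry <- function(centerline, diameter_profile = c(10.1, 25.2, -25.2),
                         ellipticity = 1.6, major_axis_orientation = 0) {
  centerline <- as_polyline3d(centerline)
  dp <- as.numeric(diameter_profile)
  if (length(dp) != 3L) stop("sst_geometry: diameter_profile must be c(c0, c1, c2)")
  s <- seq(0, 1, length.out = 201L)
  if (any(dp[1L] + dp[2L] * s + dp[3L] * s^2 <= 0))
    stop("sst_geometry: diameter profile must be positive on [0, 1]")
  if (ellipticity < 1) stop("sst_geometry: ellipticity must be >= 1")
  L <- arclength(centerline)$total
  structure(list(centerline = centerline, total_length = L,
                 diameter_profile = dp, ellipticity = ellipticity,
                 major_axis_orientation = major_axis_orientation),
            class = "sst_geometry")
}

## d(s_norm) for a geometry
profile_diameter <- function(geom, s_norm) {
  dp <- geom$diameter_profile
  dp[1L] + dp[2L] * s_norm + dp[3L] * s_norm^2
}

#' Rendering configuration for synthetic SPIM volumes
#'
#' @param volume_shape voxels `(nx, ny, nz)`.
#' @param voxel_spacing um/voxel `(x, y, z)`; anisotropic z allowed.
#' @param granule_density autofluorescent granules per um of tube length
#'   (default 250; the study reports no quantitative density, so this is a
#'   free parameter set to about 20 granules per um of length per um of
#'   diameter for the default 10-16 um profile -- dense enough that the
#'   punctate shell reads as continuous, as it does in the source images).
#' @param granule_sigma Gaussian radius of one granule, um (default 0.75,
#'   sub-micron as for lysosome-sized organelles).
#' @param granule_intensity peak intensity of one granule (default 100).
#' @param epithelium_thickness radial depth of the granule-bearing shell, um
#'   (default 3.4, half the difference between the reported autofluorescence
#'   and lumen diameters at the orifice).
#' @param blur_sigma extra whole-volume Gaussian blur, um (default 0).
#' @param noise_poisson_background Poisson background rate, photons/voxel
#'   (default 2).
#' @param noise_read_sd additive Gaussian read noise SD (default 1).
#' @param shot_noise apply Poisson shot noise to signal + background
#'   (default TRUE; FALSE gives a deterministic noise-free render).
#' @param seed RNG seed; a fixed seed makes the rendered volume
#'   bit-reproducible.
#' @return object of class `render_config`.
#' @export
render_config <- function(volume_shape = c(96L, 96L, 64L),
                          voxel_spacing = c(1, 1, 1.5),
                          granule_density = 250, granule_sigma = 0.75,
                          granule_intensity = 100,
                          epithelium_thickness = 3.4,
                          blur_sigma = 0,
                          noise_poisson_background = 2, noise_read_sd = 1,
                          shot_noise = TRUE, seed = 1L) {
  if (any(voxel_spacing <= 0)) stop("render_config: voxel_spacing must be > 0")
  if (granule_density < 0 || granule_sigma <= 0 || epithelium_thickness <= 0)
    stop("render_config: densities and sizes must be positive")
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 granule_density = granule_density,
                 granule_sigma = granule_sigma,
                 granule_intensity = granule_intensity,
                 epithelium_thickness = epithelium_thickness,
                 blur_sigma = blur_sigma,
                 noise_poisson_background = noise_poisson_background,
                 noise_read_sd = noise_read_sd,
                 shot_noise = isTRUE(shot_noise), seed = as.integer(seed)),
            class = "render_config")
}

#' Generate a smooth random centerline of exact arc length
#'
#' Emulates the convoluted path of a tubule through the mucosal fold: a
#' straight segment along +x perturbed by low-frequency random Fourier modes
#' in y and z with amplitude proportional to `tortuosity`, then rescaled so
#' the polygonal arc length equals `total_length` exactly. `tortuosity = 0`
#' yields a straight line.
#'
#' @param seed RNG seed (same seed, same polyline).
#' @param total_length target arc length, um (> 0).
#' @param tortuosity dimensionless amplitude of the wiggle (>= 0; ~0.3 gives
#'   gently convoluted paths).
#' @param n_points vertices in the returned polyline (default 400).
#' @return a [polyline3d()] starting at the origin.
#' @export
make_centerline <- function(seed, total_length, tortuosity = 0.3,
                            n_points = 400L) {
  if (!is.numeric(total_length) || total_length <= 0)
    stop("make_centerline: total_length must be > 0")
  if (tortuosity < 0) stop("make_centerline: tortuosity must be >= 0")
  t <- seq(0, 1, length.out = n_points)
  pts <- cbind(x = total_length * t, y = 0 * t, z = 0 * t)
  if (tortuosity > 0) {
    rng <- local_rng(seed)
    n_modes <- 3L
    for (axis in 2:3) {
      amp <- rng$rnorm(n_modes) * tortuosity * total_length / (2 * seq_len(n_modes))
      phase <- rng$runif(n_modes, 0, 2 * pi)
      for (m in seq_len(n_modes))
        pts[, axis] <- pts[, axis] + amp[m] * sin(pi * m * t + phase[m]) * sin(pi * t)
    }
  }
  p <- polyline3d(pts)
  scale <- total_length / arclength(p)$total
  p <- polyline3d(unclass(p) * scale)
  polyline3d(sweep(unclass(p), 2L, unclass(p)[1L, ], "-"))  # start at origin
}

## Seed-scoped RNG: draws come from a private RNG state so generators are
## deterministic without touching the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rnorm = draw(stats::rnorm), runif = draw(stats::runif),
       rpois = draw(stats::rpois), with = draw(function(expr_fn) expr_fn()))
}

## Dense arc-length sampling of a geometry with a parallel-transported frame.
## Returns positions, s (um), normalized s, tangents, and the unit major- and
## minor-axis directions at each sample.
densify_geometry <- function(geom, step_um = 0.5) {
  L <- geom$total_length
  n <- max(200L, ceiling(L / step_um) + 1L)
  rs <- resample_equidistant(geom$centerline, n)
  s <- seq(0, L, length.out = n)
  tg <- t(vapply(seq_len(n), function(i) tangent_at(rs, i), numeric(3)))
  u <- matrix(0, n, 3L)
  fr <- plane_basis(tg[1L, ])
  u[1L, ] <- fr$u
  for (i in 2:n) {
    ui <- u[i - 1L, ] - sum(u[i - 1L, ] * tg[i, ]) * tg[i, ]
    nu <- sqrt(sum(ui^2))
    if (nu < 1e-12) {            # tangent flipped ~90 deg in one step
      ui <- plane_basis(tg[i, ])$u
      nu <- sqrt(sum(ui^2))
    }
    u[i, ] <- ui / nu
  }
  v <- t(vapply(seq_len(n), function(i) cross3(tg[i, ], u[i, ]), numeric(3)))
  phi <- geom$major_axis_orientation
  major <- cos(phi) * u + sin(phi) * v
  minor <- -sin(phi) * u + cos(phi) * v
  sn <- s / L
  d <- profile_diameter(geom, sn)
  e <- geom$ellipticity
  list(points = unclass(rs), s = s, s_norm = sn, tangent = tg,
       major_dir = major, minor_dir = minor,
       d = d, semi_major = d * e / (1 + e), semi_minor = d / (1 + e))
}

#' Render a synthetic SPIM-like volume of one tubule
#'
#' Places `floor(granule_density * total_length)` punctate granules
#' (isotropic Gaussians) in the epithelial shell around the lumen -- between
#' the luminal surface and the autofluorescence envelope `d(s)`, never inside
#' the lumen interior -- then applies optional whole-volume blur and a
#' Poisson shot + Gaussian read noise model. The exact centerline, diameter
#' profile, axis orientations, and granule positions used are returned as a
#' ground-truth record.
#'
#' @param geometry an [sst_geometry()]; the centerline must be positioned in
#'   volume coordinates (um, corner origin).
#' @param config a [render_config()].
#' @return list with `volume` (a [voxel_volume()]) and `ground_truth`
#'   (class `sst_ground_truth`).
#' @export
render_sst <- function(geometry, config) {
  dn <- densify_geometry(geometry)
  sp <- config$voxel_spacing
  shape <- config$volume_shape
  ext <- shape * sp
  margin <- 3 * config$granule_sigma + config$blur_sigma
  ## bounds check over the centerline plus the axial shell overhang at the
  ## two ends (epithelium cap, see granule placement below)
  n_dn <- nrow(dn$points)
  cap <- config$epithelium_thickness
  chk_p <- rbind(dn$points[1L, ] - cap * dn$tangent[1L, ], dn$points,
                 dn$points[n_dn, ] + cap * dn$tangent[n_dn, ])
  chk_t <- rbind(dn$tangent[1L, ], dn$tangent, dn$tangent[n_dn, ])
  chk_a <- c(dn$semi_major[1L], dn$semi_major, dn$semi_major[n_dn])
  chk_s <- c(dn$s[1L], dn$s, dn$s[n_dn])
  for (ax in 1:3) {
    ## envelope extends in the normal plane: radial reach along a global axis
    ## shrinks with the tangent component on that axis
    reach <- chk_a * sqrt(pmax(1 - chk_t[, ax]^2, 0)) + margin
    bad <- chk_p[, ax] - reach < 0 | chk_p[, ax] + reach > ext[ax]
    if (any(bad))
      stop(sprintf("render_sst: tube leaves the volume (with %.2f um margin) first at arc position s = %.2f um on axis %s",
                   margin, chk_s[which(bad)[1L]], c("x", "y", "z")[ax]))
  }

  rng <- local_rng(config$seed)
  L <- geometry$total_length
  n_gran <- floor(config$granule_density * L)
  arr <- array(0, dim = shape)

  if (n_gran > 0) {
    ## epithelium continues past the orifice and caps the blind end: granule
    ## arc positions overhang both ends by one epithelium thickness so end
    ## sections see a full shell (the count stays floor(density * L))
    cap <- config$epithelium_thickness
    s_g <- rng$runif(n_gran, -cap, L + cap)
    theta <- rng$runif(n_gran, 0, 2 * pi)
    depth <- rng$runif(n_gran, 0, 1)
    idx <- pmin(pmax(round(s_g / L * (length(dn$s) - 1L)) + 1L, 1L), length(dn$s))
    sig <- config$granule_sigma
    rad <- ceiling(3 * sig / sp)             # rasterization box, voxels/axis
    for (g in seq_len(n_gran)) {
      i <- idx[g]
      a <- dn$semi_major[i]; b <- dn$semi_minor[i]
      th_eff <- min(config$epithelium_thickness, b - 0.05)
      delta <- depth[g] * th_eff             # 0 = envelope, th_eff = lumen wall
      pos <- dn$points[i, ] + (s_g[g] - dn$s[i]) * dn$tangent[i, ] +
        (a - delta) * cos(theta[g]) * dn$major_dir[i, ] +
        (b - delta) * sin(theta[g]) * dn$minor_dir[i, ]
      ctr <- pos / sp + 0.5                  # continuous 1-based voxel index
      i0 <- pmax(round(ctr) - rad, 1L)
      i1 <- pmin(round(ctr) + rad, shape)
      xs <- i0[1L]:i1[1L]; ys <- i0[2L]:i1[2L]; zs <- i0[3L]:i1[3L]
      gx <- exp(-((xs - 0.5) * sp[1L] - pos[1L])^2 / (2 * sig^2))
      gy <- exp(-((ys - 0.5) * sp[2L] - pos[2L])^2 / (2 * sig^2))
      gz <- exp(-((zs - 0.5) * sp[3L] - pos[3L])^2 / (2 * sig^2))
      arr[xs, ys, zs] <- arr[xs, ys, zs] +
        config$granule_intensity * (gx %o% gy %o% gz)
    }
  } else {
    s_g <- numeric(0); theta <- numeric(0); depth <- numeric(0)
  }

  if (config$blur_sigma > 0)
    arr <- blur3d(arr, config$blur_sigma / sp)
  if (config$shot_noise)
    arr <- array(rng$rpois(length(arr), lambda = arr + config$noise_poisson_background),
                 dim = shape)
  if (config$noise_read_sd > 0)
    arr <- arr + array(rng$rnorm(length(arr), 0, config$noise_read_sd), dim = shape)

  gt <- structure(list(geometry = geometry, config = config,
                       centerline_dense = polyline3d(dn$points),
                       s = dn$s, s_norm = dn$s_norm, d = dn$d,
                       semi_major = dn$semi_major, semi_minor = dn$semi_minor,
                       tangent = dn$tangent, major_dir = dn$major_dir,
                       minor_dir = dn$minor_dir,
                       n_granules = n_gran,
                       granule_s = s_g, granule_theta = theta,
                       granule_depth = depth),
                  class = "sst_ground_truth")
  list(volume = voxel_volume(arr, sp), ground_truth = gt)
}

#' Simulate the two semiautomatic side traces of a tubule
#'
#' Two polylines offset from the true centerline on opposite sides at the
#' local envelope radius (along the major axis, the widest visible sides of
#' the tubule), with optional iid Gaussian jitter emulating tracing error.
#' Both run orifice to blind end; with zero jitter, pointwise midpoints of
#' the pair lie exactly on the ground-truth centerline.
#'
#' @param ground_truth an `sst_ground_truth` from [render_sst()].
#' @param jitter_sd per-coordinate Gaussian jitter SD, um (>= 0).
#' @param seed RNG seed.
#' @param n_points vertices per trace (default 100).
#' @return list with [polyline3d()] elements `side_a` and `side_b`.
#' @export
simulate_side_traces <- function(ground_truth, jitter_sd = 0.5, seed = 1L,
                                 n_points = 100L) {
  if (jitter_sd < 0) stop("simulate_side_traces: jitter_sd must be >= 0")
  n_all <- length(ground_truth$s)
  keep <- round(seq(1L, n_all, length.out = n_points))
  ctr <- unclass(ground_truth$centerline_dense)[keep, , drop = FALSE]
  off <- ground_truth$semi_major[keep] * ground_truth$major_dir[keep, , drop = FALSE]
  a <- ctr + off
  b <- ctr - off
  if (jitter_sd > 0) {
    rng <- local_rng(seed)
    a <- a + matrix(rng$rnorm(length(a), 0, jitter_sd), ncol = 3L)
    b <- b + matrix(rng$rnorm(length(b), 0, jitter_sd), ncol = 3L)
  }
  list(side_a = polyline3d(a), side_b = polyline3d(b))
}

#' Simulate a per-bird, per-point measurement table
#'
#' Generates the table the measurement pipeline would produce for a cohort,
#' at known ground truth: for bird i with tubule length `L_i ~ N(length_mean,
#' length_sd)` (truncated at `length_min`), the mean diameter at normalized
#' arc position `s` is `c0 + c1 s + c2 s^2 + length_effect * L_i + b_i + eps`
#' with bird-level random intercept `b_i ~ N(0, intercept_sd^2)` and residual
#' `eps ~ N(0, noise_sd^2)`. Circularity is generated independently of all
#' covariates (the null of the ellipticity analysis):
#' `ellipticity + b'_i + eps'`, truncated at 1. d1/d2 are reconstructed from
#' mean diameter and circularity.
#'
#' Defaults are the study's stated world: profile `c(10.1, 25.2, -25.2)` um,
#' ellipticity 1.6 (SD 0.2 split between bird and residual), and
#' bird/residual diameter SDs (2.86, 4.35 um) chosen so the variance
#' partition matches the reported marginal/conditional r2 (0.1584 / 0.4123)
#' at the study design of 10 birds x 10 points.
#'
#' @param n_birds number of birds (>= 2; one tubule per bird, default 10).
#' @param n_points sample points per tubule (>= 3, default 10).
#' @param profile_params quadratic profile `c(c0, c1, c2)`, um.
#' @param noise_sd residual SD of mean diameter, um.
#' @param seed RNG seed (same seed, same table).
#' @param intercept_sd bird random-intercept SD, um.
#' @param length_effect fixed effect of total length on diameter (um per um;
#'   default 0, the study found no length effect).
#' @param length_mean,length_sd,length_min tubule length distribution, um.
#' @param ellipticity mean circularity index (default 1.6).
#' @param circ_intercept_sd,circ_noise_sd bird and residual SD of circularity.
#' @return data.frame in the measurement schema, `n_birds * n_points` rows.
#' @export
make_measurement_table <- function(n_birds = 10L, n_points = 10L,
                                   profile_params = c(10.1, 25.2, -25.2),
                                   noise_sd = 4.35, seed = 1L,
                                   intercept_sd = 2.86, length_effect = 0,
                                   length_mean = 300, length_sd = 80,
                                   length_min = 120,
                                   ellipticity = 1.6,
                                   circ_intercept_sd = 0.1,
                                   circ_noise_sd = 0.173) {
  if (n_birds < 2L) stop("make_measurement_table: need n_birds >= 2")
  if (n_points < 3L) stop("make_measurement_table: need n_points >= 3")
  rng <- local_rng(seed)
  L <- pmax(rng$rnorm(n_birds, length_mean, length_sd), length_min)
  b_diam <- rng$rnorm(n_birds, 0, intercept_sd)
  b_circ <- rng$rnorm(n_birds, 0, circ_intercept_sd)
  sn <- seq(0, 1, length.out = n_points)
  cp <- profile_params
  rows <- lapply(seq_len(n_birds), function(i) {
    mu <- cp[1L] + cp[2L] * sn + cp[3L] * sn^2 + length_effect * L[i] + b_diam[i]
    m <- mu + rng$rnorm(n_points, 0, noise_sd)
    m <- pmax(m, 0.5)                       # diameters stay physical
    circ <- pmax(ellipticity + b_circ[i] + rng$rnorm(n_points, 0, circ_noise_sd), 1)
    d1 <- 2 * m * circ / (1 + circ)
    d2 <- 2 * m / (1 + circ)
    data.frame(bird_id = sprintf("bird%02d", i), sst_id = sprintf("sst%02d", i),
               point_index = seq_len(n_points), s_um = sn * L[i],
               d1_um = d1, d2_um = d2, circularity = circ,
               mean_diameter_um = m, total_length_um = L[i])
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(profile = cp, length_effect = length_effect,
                             intercept_sd = intercept_sd, noise_sd = noise_sd,
                             ellipticity = ellipticity)
  out
}

#' Position a centerline inside a rendering volume
#'
#' Translates a centerline so its bounding box is centred in the physical
#' extent of the volume described by `config`, and errors if the tube (with
#' its envelope and rendering margin) cannot fit.
#'
#' @param centerline a [polyline3d()].
#' @param config a [render_config()].
#' @param envelope_radius largest envelope semi-axis to allow for, um.
#' @return translated [polyline3d()].
#' @export
center_in_volume <- function(centerline, config, envelope_radius = 10) {
  p <- unclass(as_polyline3d(centerline))
  ext <- config$volume_shape * config$voxel_spacing
  margin <- envelope_radius + 3 * config$granule_sigma + config$blur_sigma
  lo <- apply(p, 2L, min); hi <- apply(p, 2L, max)
  if (any(hi - lo + 2 * margin > ext))
    stop(sprintf("center_in_volume: centerline span (%.1f, %.1f, %.1f) um + %.1f um margin exceeds volume extent (%.1f, %.1f, %.1f) um",
                 hi[1] - lo[1], hi[2] - lo[2], hi[3] - lo[3], margin,
                 ext[1], ext[2], ext[3]))
  shift <- (ext - (hi - lo)) / 2 - lo
  polyline3d(sweep(p, 2L, shift, "+"))
}
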