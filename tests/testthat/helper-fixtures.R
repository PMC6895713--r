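## Shared geometric fixtures, built in code.

## Polygonal helix x = r cos t, y = r sin t, z = c t, t in [0, t_max].
make_helix <- function(r = 3, c = 1, t_max = 4 * pi, n = 1000L) {
  t <- seq(0, t_max, length.out = n)
  polyline3d(cbind(r * cos(t), r * sin(t), c * t))
}

helix_length <- function(r = 3, c = 1, t_max = 4 * pi) t_max * sqrt(r^2 + c^2)

helix_tangent <- function(t, r = 3, c = 1) {
  v <- cbind(-r * sin(t), r * cos(t), rep(c, length(t)))
  v / sqrt(r^2 + c^2)
}

## Planar circular arc of radius r spanning [0, ang], dense polygonal sampling.
make_arc <- function(r, ang = pi / 2, n = 2000L, z = 0) {
  t <- seq(0, ang, length.out = n)
  polyline3d(cbind(r * cos(t), r * sin(t), rep(z, n)))
}

## Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

## Solid bright cylinder along z, centred in an n x n x nz voxel grid.
make_cylinder_volume <- function(radius = 8, n = 64L, nz = 48L, spacing = c(1, 1, 1),
                                 value = 100) {
  arr <- array(0, dim = c(n, n, nz))
  cx <- n * spacing[1L] / 2
  cy <- n * spacing[2L] / 2
  xs <- (seq_len(n) - 0.5) * spacing[1L]
  ys <- (seq_len(n) - 0.5) * spacing[2L]
  disk <- outer(xs, ys, function(x, y) (x - cx)^2 + (y - cy)^2 <= radius^2)
  for (z in seq_len(nz)) arr[, , z] <- disk * value
  voxel_volume(arr, spacing)
}

## Rendered granular-shell cylinder plus jitter-free side traces.
make_rendered_cylinder <- function(d = 10, seed = 1L, ellipticity = 1,
                                   density_per_um = 20 * d, noise = FALSE,
                                   L = 70) {
  ny <- max(64L, 2L * ceiling(d / 2 + 12))
  straight <- polyline3d(cbind(seq(12, 12 + L, length.out = 100L), ny / 2, ny / 2))
  geom <- sst_geometry(straight, diameter_profile = c(d, 0, 0),
                       ellipticity = ellipticity)
  rc <- render_config(volume_shape = c(ceiling(L + 24), ny, ny),
                      voxel_spacing = c(1, 1, 1),
                      granule_density = density_per_um,
                      shot_noise = noise, noise_read_sd = if (noise) 1 else 0,
                      seed = seed)
  ren <- render_sst(geom, rc)
  traces <- simulate_side_traces(ren$ground_truth, jitter_sd = 0, seed = seed + 100L)
  list(volume = ren$volume, ground_truth = ren$ground_truth,
       side_a = traces$side_a, side_b = traces$side_b, geom = geom, config = rc)
}

## Wrap a plain image matrix as an oblique_slice for measurement tests.
## Rows index v, columns u; the slice centre is the matrix centre.
make_test_slice <- function(img, spacing = 1) {
  structure(list(image = img,
                 valid = matrix(TRUE, nrow(img), ncol(img)),
                 in_plane_spacing = spacing,
                 center_pixel = c(row = (nrow(img) + 1L) %/% 2L,
                                  col = (ncol(img) + 1L) %/% 2L),
                 basis_u = c(1, 0, 0), basis_v = c(0, 1, 0),
                 normal = c(0, 0, 1), origin = c(0, 0, 0)),
            class = "oblique_slice")
}

## Rasterized filled ellipse image (semi-axes in um), value 1 inside.
raster_ellipse <- function(a, b, spacing = 1, pad = 4, angle = 0, n = NULL) {
  if (is.null(n)) n <- 2L * ceiling((max(a, b) + pad) / spacing) + 1L
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * spacing
  img <- outer(xs, xs, function(u, v) {
    ur <- cos(angle) * u + sin(angle) * v
    vr <- -sin(angle) * u + cos(angle) * v
    as.numeric((ur / a)^2 + (vr / b)^2 <= 1)
  })
  t(img)   # rows = v, cols = u
}
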