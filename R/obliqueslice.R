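#' Deterministic in-plane basis for a slicing plane
#'
#' Given a plane normal, returns a right-handed orthonormal frame
#' `(u, v, normal)`. The rule is deterministic: `e` is the global axis least
#' parallel to the normal (ties broken in the order x, y, z),
#' `u = normalize(normal x e)`, `v = normal x u`.
#'
#' @param normal 3-vector (any nonzero length; normalized internally).
#' @return list with unit vectors `u`, `v`, `normal`.
#' @export
plane_basis <- function(normal) {
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (!is.finite(nn) || nn == 0) stop("plane_basis: zero-length normal")
  n <- n / nn
  e <- diag(3)[, which.min(abs(n))]
  u <- cross3(n, e)
  u <- u / sqrt(sum(u^2))
  v <- cross3(n, u)
  list(u = u, v = v, normal = n)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Extract an oblique 2D section from a volume
#'
#' Samples a square plane of side `2 * half_width` centred at `origin` and
#' normal to `normal`, by trilinear interpolation at physical positions
#' `origin + a u + b v` (the in-plane frame comes from [plane_basis()]).
#' Pixels falling outside the volume receive `fill` and are flagged in the
#' validity mask, so downstream measurement knows which pixels are
#' extrapolated. Trilinear interpolation never overshoots: every sampled
#' intensity lies within the range of its 8 surrounding voxels.
#'
#' @param volume a [voxel_volume()].
#' @param origin 3-vector, plane centre in um; must lie inside the volume.
#' @param normal 3-vector, plane normal (the local tube direction).
#' @param half_width half side length in um (default 30, which covers the
#'   widest tubule sections reported for this system).
#' @param spacing in-plane pixel spacing in um; default the smallest voxel
#'   spacing of the source volume, so no resolution is invented.
#' @param fill value for out-of-volume pixels (default 0).
#' @return object of class `oblique_slice`: `image` (matrix, rows index the
#'   v axis, columns the u axis), `valid` (logical matrix), `in_plane_spacing`,
#'   `center_pixel` (row, col mapping to `origin`), `basis_u`, `basis_v`,
#'   `normal`, `origin`.
#' @export
extract_slice <- function(volume, origin, normal, half_width = 30,
                          spacing = min(volume$spacing), fill = 0) {
  if (!is.numeric(half_width) || half_width <= 0)
    stop("extract_slice: half_width must be > 0")
  if (!is.numeric(spacing) || spacing <= 0)
    stop("extract_slice: spacing must be > 0")
  origin <- as.numeric(origin)
  ext <- volume_extent(volume)
  if (any(origin < 0) || any(origin > ext))
    stop(sprintf("extract_slice: origin (%.3g, %.3g, %.3g) um lies outside the volume extent (%.3g, %.3g, %.3g) um",
                 origin[1], origin[2], origin[3], ext[1], ext[2], ext[3]))
  fr <- plane_basis(normal)
  m <- floor(half_width / spacing)
  coords <- seq(-m, m) * spacing          # symmetric grid through the origin
  npix <- length(coords)
  ab <- expand.grid(a = coords, b = coords)  # a fastest: column-major image
  pts <- outer(ab$a, fr$u) + outer(ab$b, fr$v)
  pts <- sweep(pts, 2L, origin, "+")
  smp <- interp_trilinear(volume, pts, fill = fill)
  ## image[row, col]: row = v index, col = u index
  img <- matrix(smp$values, nrow = npix, ncol = npix, byrow = TRUE)
  msk <- matrix(smp$valid, nrow = npix, ncol = npix, byrow = TRUE)
  structure(list(image = img, valid = msk, in_plane_spacing = spacing,
                 center_pixel = c(row = m + 1L, col = m + 1L),
                 basis_u = fr$u, basis_v = fr$v, normal = fr$normal,
                 origin = origin),
            class = "oblique_slice")
}

#' @export
print.oblique_slice <- function(x, ...) {
  cat(sprintf("<oblique_slice> %d x %d px at %.3g um/px, origin (%.4g, %.4g, %.4g) um, %.1f%% valid\n",
              nrow(x$image), ncol(x$image), x$in_plane_spacing,
              x$origin[1], x$origin[2], x$origin[3], 100 * mean(x$valid)))
  invisible(x)
}

#' Physical position of a slice pixel
#' @param slice an `oblique_slice`.
#' @param row,col pixel indices (1-based).
#' @return 3-vector, um.
#' @export
slice_pixel_position <- function(slice, row, col) {
  a <- (col - slice$center_pixel[["col"]]) * slice$in_plane_spacing
  b <- (row - slice$center_pixel[["row"]]) * slice$in_plane_spacing
  slice$origin + a * slice$basis_u + b * slice$basis_v
}

#' Export an oblique slice as TIFF + JSON sidecar for audit
#' @param slice an `oblique_slice`.
#' @param path output TIFF path; `<path>.json` gets origin/basis/spacing.
#' @return `path`, invisibly.
#' @export
write_slice_tiff <- function(slice, path) {
  vol <- voxel_volume(array(t(slice$image),
                            dim = c(ncol(slice$image), nrow(slice$image), 1L)),
                      rep(slice$in_plane_spacing, 3L))
  write_volume_tiff(vol, path, sidecar = FALSE)
  jsonlite::write_json(list(origin = slice$origin, basis_u = slice$basis_u,
                            basis_v = slice$basis_v, normal = slice$normal,
                            in_plane_spacing = slice$in_plane_spacing,
                            center_pixel = slice$center_pixel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
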