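#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D intensity grid with physical voxel spacing, the
#' imaging unit of the pipeline (a SPIM stack covers up to about
#' 480 x 480 x 100 um of tissue). Data are stored as an R array with
#' dimensions `(nx, ny, nz)` and spacing `(sx, sy, sz)` in micrometres per
#' voxel; anisotropic z spacing (light-sheet stacks) is allowed.
#'
#' Physical coordinates are micrometres with the volume corner at the origin:
#' the centre of voxel `(i, j, k)` (1-based) is at
#' `((i - 0.5) sx, (j - 0.5) sy, (k - 0.5) sz)`.
#'
#' @param data numeric 3D array, dimensions `(nx, ny, nz)`.
#' @param spacing numeric length-3, um per voxel along x, y, z; all > 0.
#' @return object of class `voxel_volume` with elements `data` and `spacing`.
#' @export
voxel_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("voxel_volume: 'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_volume: 'spacing' must be 3 positive values (um/voxel)")
  structure(list(data = data, spacing = spacing), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um, extent (%.4g, %.4g, %.4g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3]))
  invisible(x)
}

## physical extent (um) along each axis
volume_extent <- function(vol) dim(vol$data) * vol$spacing

## TRUE for each row of the n x 3 point matrix inside the physical bounds
points_in_volume <- function(vol, pts) {
  ext <- volume_extent(vol)
  apply(pts, 1L, function(p) all(p >= 0) && all(p <= ext))
}

#' Trilinear interpolation of a volume at physical positions
#'
#' Samples the volume at arbitrary (x, y, z) micrometre positions using
#' trilinear (order-1) interpolation on voxel centres. Positions where the
#' full 8-voxel neighbourhood is unavailable (outside the grid of voxel
#' centres) receive `fill` and are flagged invalid.
#'
#' @param vol a [voxel_volume()].
#' @param pts n x 3 matrix of positions in um.
#' @param fill value for out-of-volume samples (default 0).
#' @return list with `values` (length n) and `valid` (logical length n).
#' @export
interp_trilinear <- function(vol, pts, fill = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  d <- dim(vol$data)
  ## continuous 1-based voxel-centre index along each axis
  cx <- pts[, 1L] / vol$spacing[1L] + 0.5
  cy <- pts[, 2L] / vol$spacing[2L] + 0.5
  cz <- pts[, 3L] / vol$spacing[3L] + 0.5
  valid <- cx >= 1 & cx <= d[1L] & cy >= 1 & cy <= d[2L] & cz >= 1 & cz <= d[3L]
  vals <- rep(fill, nrow(pts))
  if (any(valid)) {
    cxv <- cx[valid]; cyv <- cy[valid]; czv <- cz[valid]
    i0 <- pmin(floor(cxv), d[1L] - 1); i0 <- pmax(i0, 1)
    j0 <- pmin(floor(cyv), d[2L] - 1); j0 <- pmax(j0, 1)
    k0 <- pmin(floor(czv), d[3L] - 1); k0 <- pmax(k0, 1)
    fx <- cxv - i0; fy <- cyv - j0; fz <- czv - k0
    at <- function(di, dj, dk)
      vol$data[cbind(i0 + di, j0 + dj, k0 + dk)]
    v <- at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
         at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
         at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
         at(1, 1, 0) * fx       * fy       * (1 - fz) +
         at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
         at(1, 0, 1) * fx       * (1 - fy) * fz +
         at(0, 1, 1) * (1 - fx) * fy       * fz +
         at(1, 1, 1) * fx       * fy       * fz
    vals[valid] <- v
  }
  list(values = vals, valid = valid)
}
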