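## Low-level grid image operations shared by preprocessing and measurement:
## separable Gaussian smoothing, grayscale ball dilation, Otsu thresholding,
## 4-connected flood fill and hole filling. Implemented on plain R arrays;
## grids in this pipeline are small (slices ~100 px, volumes <= ~200 voxels
## per axis) so vectorized whole-grid passes are fast enough.

## 1D Gaussian smoothing matrix with renormalized (truncated) boundaries.
gauss_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma_vox^2)))
  K[abs(row(K) - col(K)) > ceiling(4 * sigma_vox)] <- 0
  K / rowSums(K)
}

## Gaussian blur of a 2D matrix, sigma in pixels (scalar or per-axis).
blur2d <- function(mat, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 2L)
  if (sigma_vox[1L] > 0) mat <- gauss_matrix(nrow(mat), sigma_vox[1L]) %*% mat
  if (sigma_vox[2L] > 0) mat <- mat %*% t(gauss_matrix(ncol(mat), sigma_vox[2L]))
  mat
}

## Gaussian blur of a 3D array, sigma in voxels per axis.
blur3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(arr)
  if (sigma_vox[1L] > 0) {
    arr <- array(gauss_matrix(d[1L], sigma_vox[1L]) %*% matrix(arr, d[1L]), d)
  }
  if (sigma_vox[2L] > 0) {
    a2 <- aperm(arr, c(2L, 1L, 3L))
    a2 <- array(gauss_matrix(d[2L], sigma_vox[2L]) %*% matrix(a2, d[2L]), dim(a2))
    arr <- aperm(a2, c(2L, 1L, 3L))
  }
  if (sigma_vox[3L] > 0) {
    a3 <- aperm(arr, c(3L, 2L, 1L))
    a3 <- array(gauss_matrix(d[3L], sigma_vox[3L]) %*% matrix(a3, d[3L]), dim(a3))
    arr <- aperm(a3, c(3L, 2L, 1L))
  }
  arr
}

## Grayscale dilation of a 3D array with an ellipsoidal (physical ball)
## structuring element: radius um converted per axis to voxels.
dilate_ball3d <- function(arr, radius_um, spacing) {
  if (radius_um <= 0) return(arr)
  r_vox <- floor(radius_um / spacing)
  offs <- expand.grid(dx = -r_vox[1L]:r_vox[1L],
                      dy = -r_vox[2L]:r_vox[2L],
                      dz = -r_vox[3L]:r_vox[3L])
  keep <- (offs$dx * spacing[1L])^2 + (offs$dy * spacing[2L])^2 +
          (offs$dz * spacing[3L])^2 <= radius_um^2
  offs <- offs[keep, , drop = FALSE]
  d <- dim(arr)
  out <- array(-Inf, d)
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]; dz <- offs$dz[i]
    xs <- max(1L, 1L + dx):min(d[1L], d[1L] + dx)
    ys <- max(1L, 1L + dy):min(d[2L], d[2L] + dy)
    zs <- max(1L, 1L + dz):min(d[3L], d[3L] + dz)
    out[xs, ys, zs] <- pmax(out[xs, ys, zs],
                            arr[xs - dx, ys - dy, zs - dz])
  }
  out
}

#' Otsu threshold of an intensity sample
#'
#' Classic histogram-based Otsu threshold (256 bins, maximal between-class
#' variance). Because the criterion depends only on intensity ranks within
#' the histogram, scaling all intensities by a positive constant moves the
#' threshold by the same factor and leaves the segmentation unchanged.
#'
#' @param x numeric vector of intensities.
#' @param n_bins histogram resolution (default 256).
#' @return threshold value; pixels `>= threshold` are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("otsu_threshold: constant intensities, no threshold exists")
  brk <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (brk[-1L] + brk[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  ## bimodal histograms give a plateau of maximizing bins; take its middle
  ## (the conventional tie-break) rather than the lowest bin
  peak <- which(sigma_b >= max(sigma_b) * (1 - 1e-9))
  k <- peak[ceiling(length(peak) / 2)]
  brk[k + 1L]          # upper edge of the chosen bin separates the classes
}

## 4-connected binary flood fill from seed pixels; returns logical matrix of
## reached mask pixels. Iterative whole-grid dilation-and-mask.
flood4 <- function(mask, seeds) {
  reached <- seeds & mask
  if (!any(reached)) return(reached)
  nr <- nrow(mask)
  nc <- ncol(mask)
  repeat {
    grow <- reached
    grow[-1L, ] <- grow[-1L, ] | reached[-nr, ]
    grow[-nr, ] <- grow[-nr, ] | reached[-1L, ]
    grow[, -1L] <- grow[, -1L] | reached[, -nc]
    grow[, -nc] <- grow[, -nc] | reached[, -1L]
    grow <- grow & mask
    if (!any(grow & !reached)) return(reached)
    reached <- grow
  }
}

## Fill internal holes of a binary mask: background not 4-connected to the
## image border (invalid pixels count as border-connected background).
fill_holes4 <- function(mask, valid = NULL) {
  bg <- !mask
  if (!is.null(valid)) bg <- bg | !valid
  seeds <- matrix(FALSE, nrow(mask), ncol(mask))
  seeds[1L, ] <- TRUE; seeds[nrow(mask), ] <- TRUE
  seeds[, 1L] <- TRUE; seeds[, ncol(mask)] <- TRUE
  if (!is.null(valid)) seeds <- seeds | !valid
  outside <- flood4(bg, seeds)
  mask | (bg & !outside)
}
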