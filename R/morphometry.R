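#' Preprocess a volume for centerline tracing
#'
#' Grayscale morphological dilation with a physical ball structuring element
#' followed by Gaussian smoothing, the standard way to turn punctate
#' epithelial autofluorescence into a smooth tube-like intensity for
#' semiautomatic tracing. Measurement always runs on the *undilated* volume;
#' this preprocessed version is only a tracing aid.
#'
#' @param volume a [voxel_volume()].
#' @param dilation_radius ball radius in um (0 = no dilation).
#' @param gaussian_sigma isotropic smoothing sigma in um (0 = none).
#' @return a [voxel_volume()] of the same shape and spacing.
#' @export
preprocess_for_tracing <- function(volume, dilation_radius = 2, gaussian_sigma = 1) {
  if (dilation_radius < 0 || gaussian_sigma < 0)
    stop("preprocess_for_tracing: radius and sigma must be >= 0")
  arr <- dilate_ball3d(volume$data, dilation_radius, volume$spacing)
  if (gaussian_sigma > 0)
    arr <- blur3d(arr, gaussian_sigma / volume$spacing)
  voxel_volume(arr, volume$spacing)
}

#' Circularity index of a cross-section
#'
#' Major axis diameter divided by minor axis diameter; 1 indicates a
#' circular cross-section, larger values an elliptical one. Arguments are
#' swapped if given in the wrong order, so the index is always >= 1.
#'
#' @param d1,d2 axis diameters in um (both > 0).
#' @return dimensionless circularity `max(d1, d2) / min(d1, d2)`.
#' @export
circularity <- function(d1, d2) {
  if (any(d2 <= 0) || any(d1 <= 0))
    stop("circularity: diameters must be > 0")
  pmax(d1, d2) / pmin(d1, d2)
}

#' Measure major and minor axis diameters on an oblique section
#'
#' The section is Gaussian-smoothed, thresholded (Otsu on valid pixels by
#' default), and the 4-connected foreground component containing the slice
#' centre -- after filling internal holes, since the autofluorescence forms a
#' granular shell around a dark lumen -- is summarized by its
#' moment-equivalent ellipse: `d1`, `d2` are the major/minor axis lengths of
#' the ellipse with the same second central moments as the filled region,
#' converted to micrometres. An alternative Feret (caliper) estimator is
#' available for sensitivity analysis.
#'
#' @param slice an `oblique_slice` from [extract_slice()].
#' @param smoothing_sigma in-plane smoothing sigma in um (default 1).
#' @param threshold_method `"otsu"` (default), or a number / `"fixed:<value>"`
#'   for an absolute threshold.
#' @param method `"moment"` (default) or `"feret"`.
#' @return list with `d1`, `d2` (um, `d1 >= d2`), `threshold`, `n_pixels`,
#'   and `truncated` (TRUE if the measured component touches the slice border
#'   or invalid pixels, i.e. possible truncation).
#' @export
measure_axes <- function(slice, smoothing_sigma = 1,
                         threshold_method = "otsu",
                         method = c("moment", "feret")) {
  method <- match.arg(method)
  sp <- slice$in_plane_spacing
  img0 <- slice$image
  img0[!slice$valid] <- 0
  img <- if (smoothing_sigma > 0) blur2d(img0, smoothing_sigma / sp) else img0

  ctr <- slice$center_pixel
  segment_at <- function(thr, image = img) {
    bw <- image >= thr & slice$valid
    filled <- fill_holes4(bw, slice$valid)
    if (!filled[ctr[["row"]], ctr[["col"]]]) return(NULL)
    seeds <- matrix(FALSE, nrow(filled), ncol(filled))
    seeds[ctr[["row"]], ctr[["col"]]] <- TRUE
    flood4(filled, seeds)
  }
  ## robustness ladder: if the shell does not close around the centre at the
  ## requested smoothing, retry with progressively stronger smoothing before
  ## declaring the tube absent (punctate shells fragment on noisy sections)
  segment_robust <- function(threshold_of) {
    for (mult in c(1, 2, 4)) {
      sig <- max(smoothing_sigma, sp / 2) * mult
      image <- if (mult == 1) img else blur2d(img0, sig / sp)
      thr <- threshold_of(image)
      comp <- segment_at(thr, image)
      if (!is.null(comp)) return(list(comp = comp, thr = thr, image = image))
    }
    stop("tube not found at slice center")
  }
  if (is.numeric(threshold_method) || grepl("^fixed:", threshold_method)) {
    thr_fixed <- if (is.numeric(threshold_method)) threshold_method
                 else as.numeric(sub("^fixed:", "", threshold_method))
    seg <- segment_robust(function(image) thr_fixed)
    thr <- thr_fixed
    comp <- seg$comp
  } else if (identical(threshold_method, "otsu")) {
    ## two-pass Otsu: a global pass finds the tube, then the threshold is
    ## re-estimated in the component's neighbourhood so the large empty
    ## background cannot dilute the histogram and push the boundary outward
    seg <- segment_robust(function(image) otsu_threshold(image[slice$valid]))
    comp <- seg$comp
    thr <- seg$thr
    idx <- which(comp, arr.ind = TRUE)
    pad <- ceiling(3 / sp)
    rr <- max(1L, min(idx[, 1L]) - pad):min(nrow(img), max(idx[, 1L]) + pad)
    cc <- max(1L, min(idx[, 2L]) - pad):min(ncol(img), max(idx[, 2L]) + pad)
    win <- seg$image[rr, cc][slice$valid[rr, cc]]
    thr2 <- tryCatch(otsu_threshold(win), error = function(e) NULL)
    if (!is.null(thr2)) {
      comp2 <- segment_at(thr2, seg$image)
      if (!is.null(comp2)) {
        thr <- thr2
        comp <- comp2
      }
    }
  } else stop("measure_axes: unknown threshold_method ", dQuote(threshold_method))

  border <- matrix(FALSE, nrow(comp), ncol(comp))
  border[1L, ] <- TRUE; border[nrow(comp), ] <- TRUE
  border[, 1L] <- TRUE; border[, ncol(comp)] <- TRUE
  truncated <- any(comp & (border | !slice$valid))
  if (truncated)
    warning("measured component touches the slice border; possible truncation")

  idx <- which(comp, arr.ind = TRUE)
  a <- (idx[, 2L] - ctr[["col"]]) * sp       # u axis, um
  b <- (idx[, 1L] - ctr[["row"]]) * sp       # v axis, um
  if (method == "moment") {
    n <- length(a)
    ma <- mean(a); mb <- mean(b)
    ## second central moments of the pixel region, plus the moment of a unit
    ## square pixel (sp^2/12) so rasterized shapes measure at true size
    cov <- matrix(c(sum((a - ma)^2) / n + sp^2 / 12,
                    sum((a - ma) * (b - mb)) / n,
                    sum((a - ma) * (b - mb)) / n,
                    sum((b - mb)^2) / n + sp^2 / 12), 2L)
    ev <- eigen(cov, symmetric = TRUE)$values
    d1 <- 4 * sqrt(max(ev))
    d2 <- 4 * sqrt(max(min(ev), 0))
  } else {
    pts <- cbind(a, b)
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    dmat <- as.matrix(stats::dist(hull))
    d1 <- max(dmat) + sp                     # + one pixel footprint
    nh <- nrow(hull)
    widths <- vapply(seq_len(nh), function(i) {
      p1 <- hull[i, ]; p2 <- hull[if (i == nh) 1L else i + 1L, ]
      edge <- p2 - p1
      len <- sqrt(sum(edge^2))
      if (len == 0) return(Inf)
      nrm <- c(-edge[2L], edge[1L]) / len
      max(abs((hull[, 1L] - p1[1L]) * nrm[1L] + (hull[, 2L] - p1[2L]) * nrm[2L]))
    }, numeric(1))
    d2 <- min(widths) + sp
  }
  if (d2 > d1) { tmp <- d1; d1 <- d2; d2 <- tmp }
  list(d1 = d1, d2 = d2, threshold = thr, n_pixels = sum(comp),
       truncated = truncated)
}

#' Measure one tubule end to end
#'
#' The full single-tubule pipeline: average the two side traces into a
#' luminal centerline, sample it at `n_points` equidistant arc-length
#' positions, extract an oblique section normal to the local direction at
#' each position (from the undilated volume), and measure `d1`/`d2` on every
#' section.
#'
#' @param volume a [voxel_volume()] (the original, undilated stack).
#' @param side_a,side_b side traces ([polyline3d()]), orifice first.
#' @param n_points number of sample points (default 10).
#' @param bird_id,sst_id identifiers recorded in the output.
#' @param half_width slice half width, um (default 30).
#' @param slice_spacing in-plane pixel spacing, um (default: smallest voxel
#'   spacing).
#' @param smoothing_sigma,threshold_method,method passed to [measure_axes()].
#' @param n_dense dense correspondence points for [average_trace()].
#' @return object of class `sst_record`: `bird_id`, `sst_id`,
#'   `total_length_um`, `centerline`, and `measurements` (data.frame with one
#'   row per sample point: `point_index`, `s_um`, `d1_um`, `d2_um`,
#'   `circularity`, `mean_diameter_um`, `truncated`).
#' @export
measure_sst <- function(volume, side_a, side_b, n_points = 10L,
                        bird_id = "bird01", sst_id = "sst01",
                        half_width = 30, slice_spacing = min(volume$spacing),
                        smoothing_sigma = 1, threshold_method = "otsu",
                        method = "moment", n_dense = 200L) {
  for (tr in list(side_a, side_b)) {
    p <- as_polyline3d(tr)
    if (!all(points_in_volume(volume, p)))
      stop("measure_sst: side trace leaves the volume bounds")
  }
  center <- average_trace(side_a, side_b, n_dense = n_dense)
  samples <- sample_centerline(center, n = n_points)
  L <- attr(samples, "total_length_um")

  rows <- lapply(seq_len(nrow(samples)), function(i) {
    smp <- samples[i, ]
    res <- tryCatch({
      sl <- extract_slice(volume, origin = c(smp$x, smp$y, smp$z),
                          normal = c(smp$tx, smp$ty, smp$tz),
                          half_width = half_width, spacing = slice_spacing)
      suppressWarnings(
        measure_axes(sl, smoothing_sigma = smoothing_sigma,
                     threshold_method = threshold_method, method = method))
    }, error = function(e)
      stop(sprintf("measure_sst: sample %d (s = %.2f um): %s",
                   i, smp$s_um, conditionMessage(e)), call. = FALSE))
    data.frame(point_index = i, s_um = smp$s_um, d1_um = res$d1, d2_um = res$d2,
               circularity = res$d1 / res$d2,
               mean_diameter_um = (res$d1 + res$d2) / 2,
               truncated = res$truncated)
  })
  meas <- do.call(rbind, rows)
  structure(list(bird_id = bird_id, sst_id = sst_id, total_length_um = L,
                 centerline = center, measurements = meas),
            class = "sst_record")
}

#' @export
print.sst_record <- function(x, ...) {
  cat(sprintf("<sst_record> %s / %s: length %.1f um, %d sections, mean diameter %.2f um, mean circularity %.2f\n",
              x$bird_id, x$sst_id, x$total_length_um, nrow(x$measurements),
              mean(x$measurements$mean_diameter_um),
              mean(x$measurements$circularity)))
  invisible(x)
}

#' Flatten tubule records into the shared measurement table
#' @param records an `sst_record` or list of them.
#' @return data.frame in the measurement schema (`bird_id`, `sst_id`,
#'   `point_index`, `s_um`, `d1_um`, `d2_um`, `circularity`,
#'   `mean_diameter_um`, `total_length_um`).
#' @export
sst_measurement_table <- function(records) {
  if (inherits(records, "sst_record")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    df <- r$measurements
    data.frame(bird_id = r$bird_id, sst_id = r$sst_id,
               point_index = df$point_index, s_um = df$s_um,
               d1_um = df$d1_um, d2_um = df$d2_um,
               circularity = df$circularity,
               mean_diameter_um = df$mean_diameter_um,
               total_length_um = r$total_length_um, row.names = NULL)
  }))
}
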