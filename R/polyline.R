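#' Construct a 3D polyline
#'
#' A `polyline3d` is an ordered sequence of 3D points in micrometres, the
#' common representation for semiautomatically traced tubule sides and for
#' averaged luminal centerlines. Points are stored as an `n x 3` matrix with
#' columns `x`, `y`, `z`; the first point is the tubule orifice, the last the
#' blind end.
#'
#' @param points numeric matrix (or data.frame) with 3 columns, one point per
#'   row, in micrometres, ordered orifice to blind end.
#' @return an object of class `polyline3d`.
#' @details Invariants enforced: at least 2 points, all coordinates finite,
#'   no two consecutive points coincident (so cumulative arc length is
#'   strictly increasing).
#' @export
polyline3d <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 3L)
    stop("polyline3d: 'points' must be an n x 3 matrix of (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) < 2L)
    stop("polyline3d: need at least 2 points")
  if (!all(is.finite(points)))
    stop("polyline3d: non-finite coordinates")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    stop("polyline3d: consecutive points must be distinct (zero-length segment at index ",
         which(seg == 0)[1L], ")")
  colnames(points) <- c("x", "y", "z")
  structure(points, class = c("polyline3d", "matrix", "array"))
}

#' @export
print.polyline3d <- function(x, ...) {
  al <- arclength(x)
  cat(sprintf("<polyline3d> %d points, arc length %.3f um\n", nrow(x), al$total))
  invisible(x)
}

as_polyline3d <- function(x) {
  if (inherits(x, "polyline3d")) x else polyline3d(x)
}

#' Arc length of a polyline
#'
#' Total polygonal arc length (sum of Euclidean segment lengths) and the
#' cumulative arc length at every vertex. "Distance from the orifice" used
#' throughout the pipeline is arc length along the averaged luminal trace.
#'
#' @param trace a [polyline3d()] (or coercible matrix).
#' @return list with `total` (scalar, um) and `cumulative` (numeric vector,
#'   one entry per vertex, starting at 0, non-decreasing).
#' @export
arclength <- function(trace) {
  p <- as_polyline3d(trace)
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  list(total = cum[length(cum)], cumulative = cum)
}

## Linear interpolation of a polyline at arbitrary arc-length positions s.
## Returns the 3D points; s outside [0, L] is an error.
interp_at_arclength <- function(p, s) {
  cum <- arclength(p)$cumulative
  L <- cum[length(cum)]
  if (any(s < -1e-9 | s > L + 1e-9))
    stop("arc-length position outside [0, total length]")
  s <- pmin(pmax(s, 0), L)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(p) - 1L)
  seg_len <- cum[idx + 1L] - cum[idx]
  frac <- (s - cum[idx]) / seg_len
  p[idx, , drop = FALSE] * (1 - frac) + p[idx + 1L, , drop = FALSE] * frac
}

#' Resample a polyline at equidistant arc-length positions
#'
#' Places `n` points at arc lengths `s_k = k L / (n - 1)`, `k = 0 .. n-1`,
#' by piecewise-linear interpolation between the input vertices. The first
#' output point is the first input vertex (the orifice) and the last is the
#' final vertex.
#'
#' @param trace a [polyline3d()].
#' @param n number of output points (>= 2).
#' @return a [polyline3d()] with `n` points.
#' @export
resample_equidistant <- function(trace, n) {
  p <- as_polyline3d(trace)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("resample_equidistant: n must be >= 2")
  n <- as.integer(n)
  L <- arclength(p)$total
  s <- seq(0, L, length.out = n)
  out <- interp_at_arclength(p, s)
  out[1L, ] <- p[1L, ]          # exact endpoints, no rounding drift
  out[n, ] <- p[nrow(p), ]
  polyline3d(out)
}

#' Average two side traces into a luminal centerline
#'
#' Both side traces are resampled to `n_dense` points at equal normalized
#' arc-length positions; the averaged trace is the pointwise midpoint of the
#' i-th pair. This pairs points by fractional position along each trace, so
#' traces with different vertex counts or densities are handled without any
#' tuning parameter, and the operation is symmetric in its two arguments.
#'
#' @param side_a,side_b [polyline3d()] traces, both ordered orifice to blind
#'   end along opposite sides of the tubule lumen.
#' @param n_dense number of correspondence points (default 200).
#' @return a [polyline3d()] centerline with `n_dense` points.
#' @export
average_trace <- function(side_a, side_b, n_dense = 200L) {
  a <- as_polyline3d(side_a)
  b <- as_polyline3d(side_b)
  ## orientation guard: first point of one trace must be nearer the other's
  ## first point than its last point
  d_ff <- sqrt(sum((a[1L, ] - b[1L, ])^2))
  d_fl <- sqrt(sum((a[1L, ] - b[nrow(b), ])^2))
  if (d_fl < d_ff)
    stop("average_trace: side traces appear to run in opposite directions; ",
         "reverse one so both start at the orifice")
  ra <- resample_equidistant(a, n_dense)
  rb <- resample_equidistant(b, n_dense)
  polyline3d((unclass(ra) + unclass(rb)) / 2)
}

#' Local direction (unit tangent) at a polyline vertex
#'
#' The direction of the tubule at a trace point, from its nearest neighboring
#' points: central difference `p[i+1] - p[i-1]` at interior vertices and a
#' one-sided difference at the two endpoints, normalized to unit length.
#'
#' @param trace a [polyline3d()].
#' @param index vertex index (1-based).
#' @return unit 3-vector.
#' @export
tangent_at <- function(trace, index) {
  p <- as_polyline3d(trace)
  n <- nrow(p)
  if (index < 1L || index > n) stop("tangent_at: index out of range")
  if (index == 1L) {
    d <- p[2L, ] - p[1L, ]
  } else if (index == n) {
    d <- p[n, ] - p[n - 1L, ]
  } else {
    d <- p[index + 1L, ] - p[index - 1L, ]
  }
  nd <- sqrt(sum(d^2))
  if (nd == 0)
    stop("tangent_at: coincident neighboring points, direction undefined")
  unname(d / nd)
}

#' Sample a centerline at equidistant points with arc lengths and tangents
#'
#' The standard sampling scheme of the pipeline: the averaged luminal trace is
#' interpolated at `n` equidistant points (the first at the orifice, the last
#' at the blind end), and at each point the local direction is estimated from
#' its nearest neighboring points on the resampled trace.
#'
#' @param trace a [polyline3d()] centerline.
#' @param n number of sample points (default 10, the study design).
#' @return data.frame with columns `index`, `x`, `y`, `z`, `s_um` (arc length
#'   from the orifice), `tx`, `ty`, `tz` (unit tangent), of class
#'   `centerline_samples`; attribute `total_length_um`.
#' @export
sample_centerline <- function(trace, n = 10L) {
  rs <- resample_equidistant(trace, n)
  L <- arclength(trace)$total
  s <- seq(0, L, length.out = n)
  tg <- t(vapply(seq_len(n), function(i) tangent_at(rs, i), numeric(3)))
  out <- data.frame(index = seq_len(n),
                    x = rs[, 1L], y = rs[, 2L], z = rs[, 3L],
                    s_um = s, tx = tg[, 1L], ty = tg[, 2L], tz = tg[, 3L])
  attr(out, "total_length_um") <- L
  class(out) <- c("centerline_samples", "data.frame")
  out
}
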