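## Plain-text interchange: flat YAML configs/sidecars, SWC traces, CSV tables.
## The YAML support is deliberately a flat `key: value` subset (the only form
## the pipeline emits or consumes); there is no YAML parser in the target
## environment.

#' Read a flat YAML mapping
#'
#' Parses a file of `key: value` lines (comments `#`, blank lines allowed).
#' Values that look numeric become numbers, `true`/`false` become logicals,
#' everything else stays character. Nested structures are not supported and
#' raise a line-numbered error.
#'
#' @param path file path.
#' @return named list.
#' @export
yaml_read <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    if (!grepl("^[A-Za-z0-9_.-]+[[:space:]]*:", ln))
      stop(sprintf("%s:%d: expected 'key: value', got %s", path, i,
                   dQuote(trimws(lines[i]))), call. = FALSE)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (val == "")
      stop(sprintf("%s:%d: key %s has no value (nested YAML is not supported)",
                   path, i, dQuote(key)), call. = FALSE)
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
                  else val
  }
  out
}

#' Write a flat YAML mapping
#' @param x named list of scalars.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
yaml_write <- function(x, path) {
  stopifnot(length(names(x)) == length(x))
  fmt <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 15)
    else if (is.logical(v)) tolower(as.character(v))
    else as.character(v)
  }, character(1))
  writeLines(paste0(names(x), ": ", fmt), path)
  invisible(path)
}

#' Write a polyline as an SWC trace
#'
#' Standard 7-column SWC (node id, structure type, x, y, z, radius, parent),
#' a simple unbranched path from orifice to blind end, as exported by neurite
#' tracing tools.
#'
#' @param trace a [polyline3d()].
#' @param path output path.
#' @param radius per-node radius column, recycled (um; default 1).
#' @param type SWC structure type code (default 0, undefined).
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path, radius = 1, type = 0L) {
  p <- as_polyline3d(trace)
  n <- nrow(p)
  radius <- rep_len(radius, n)
  df <- data.frame(id = seq_len(n), type = type,
                   x = p[, 1L], y = p[, 2L], z = p[, 3L],
                   radius = radius, parent = c(-1L, seq_len(n - 1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC trace, coordinates in micrometres, orifice first", con)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SWC trace as a polyline
#'
#' Reads a 7-column SWC file; nodes are ordered by following parent links
#' from the root (parent -1). Branched files are rejected (branched tubules
#' are outside the scope of the pipeline).
#'
#' @param path SWC file path.
#' @return a [polyline3d()].
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  if (anyDuplicated(df$parent[df$parent != -1]))
    stop("read_swc: branched SWC structure; only unbranched traces are supported")
  root <- df$id[df$parent == -1]
  if (length(root) != 1L) stop("read_swc: expected exactly one root node")
  child_of <- stats::setNames(df$id, as.character(df$parent))
  ord <- integer(nrow(df)); ord[1L] <- root
  for (i in seq_len(nrow(df) - 1L)) {
    nxt <- child_of[as.character(ord[i])]
    if (is.na(nxt)) stop("read_swc: broken parent chain at node ", ord[i])
    ord[i + 1L] <- nxt
  }
  rows <- match(ord, df$id)
  polyline3d(as.matrix(df[rows, c("x", "y", "z")]))
}

#' Write a polyline as plain CSV
#' @param trace a [polyline3d()].
#' @param path output path. Columns `x,y,z` in um, one point per row,
#'   orifice first.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  p <- as_polyline3d(trace)
  utils::write.csv(as.data.frame(unclass(p)), path, row.names = FALSE)
  invisible(path)
}

#' Read a polyline from plain CSV (columns x, y, z in um)
#' @param path CSV file path.
#' @return a [polyline3d()].
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("read_trace_csv: expected columns x, y, z in ", path)
  polyline3d(as.matrix(df[, need]))
}

#' Read a measurement table CSV
#'
#' The shared measurement schema: one row per tubule per sample point with
#' columns `bird_id`, `sst_id`, `point_index`, `s_um`, `d1_um`, `d2_um`,
#' `circularity`, `mean_diameter_um`, `total_length_um`. Missing derived
#' columns (`circularity`, `mean_diameter_um`) are recomputed from d1/d2.
#'
#' @param path CSV file path.
#' @return data.frame in the measurement schema.
#' @export
read_measurement_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  normalize_measurement_table(df)
}

## Accepts the canonical schema or the bare-name variant (bird_id, s, d1, d2,
## total_length) and returns the canonical schema with derived columns.
normalize_measurement_table <- function(df) {
  ren <- c(s = "s_um", d1 = "d1_um", d2 = "d2_um", total_length = "total_length_um",
           mean_diameter = "mean_diameter_um")
  for (old in names(ren))
    if (old %in% names(df) && !(ren[[old]] %in% names(df)))
      names(df)[names(df) == old] <- ren[[old]]
  need <- c("bird_id", "s_um", "d1_um", "d2_um", "total_length_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement table is missing columns: ", paste(miss, collapse = ", "))
  ## enforce d1 >= d2
  swap <- df$d1_um < df$d2_um
  if (any(swap)) {
    tmp <- df$d1_um[swap]
    df$d1_um[swap] <- df$d2_um[swap]
    df$d2_um[swap] <- tmp
  }
  df$mean_diameter_um <- (df$d1_um + df$d2_um) / 2
  df$circularity <- df$d1_um / df$d2_um
  if (!"sst_id" %in% names(df)) df$sst_id <- df$bird_id
  df
}
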