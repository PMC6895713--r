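## Minimal baseline TIFF support (uncompressed, little-endian, single-sample
## grayscale, multi-page). No TIFF package exists in the target environment,
## so the subset needed for SPIM-style z-stacks is implemented here: float32
## (default), uint16 or uint8 pages, ImageJ-style ImageDescription carrying
## the z spacing, and X/YResolution rationals carrying the in-plane spacing.
## A flat YAML sidecar (see yaml_write) duplicates the spacing for audit.

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Write a voxel volume as a multi-page TIFF
#'
#' Pages are z-slices (row = y, column = x), written uncompressed in
#' little-endian byte order. Voxel spacing is recorded in the ImageJ-style
#' ImageDescription (`spacing=` for z, `unit=micron`) and the X/YResolution
#' tags (pixels per micrometre); [write_spacing_sidecar()] writes the same
#' information as a plain-text sidecar.
#'
#' @param vol a [voxel_volume()].
#' @param path output file path.
#' @param format one of "float32" (default), "uint16", "uint8".
#' @param sidecar write `<path>.yaml` with the voxel spacing (default TRUE).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, format = c("float32", "uint16", "uint8"),
                              sidecar = TRUE) {
  format <- match.arg(format)
  d <- dim(vol$data)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  sp <- vol$spacing
  bps <- switch(format, float32 = 32L, uint16 = 16L, uint8 = 8L)
  sfmt <- switch(format, float32 = 3L, uint16 = 1L, uint8 = 1L)
  bytes_pp <- bps / 8L
  strip_bytes <- nx * ny * bytes_pp

  desc <- sprintf("ImageJ=1.53t\nimages=%d\nslices=%d\nunit=micron\nspacing=%.9g\nloop=false\n",
                  nz, nz, sp[3L])
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  ## layout: header | description | 2 rationals | nz strips | nz IFDs
  off_desc <- 8L
  off_rat <- off_desc + length(desc_raw)
  off_strip1 <- off_rat + 16L
  strip_off <- off_strip1 + (seq_len(nz) - 1L) * strip_bytes
  n_entries <- ifelse(seq_len(nz) == 1L, 13L, 12L)
  ifd_sizes <- 2L + 12L * n_entries + 4L
  off_ifd <- off_strip1 + nz * strip_bytes + c(0L, cumsum(ifd_sizes))[seq_len(nz)]

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(off_ifd[1L])
  writeBin(desc_raw, con)
  ## rationals: pixels per micrometre = 1 / spacing
  w32(1000000L); w32(as.integer(round(sp[1L] * 1e6)))
  w32(1000000L); w32(as.integer(round(sp[2L] * 1e6)))

  for (z in seq_len(nz)) {
    page <- as.vector(vol$data[, , z])
    if (format == "float32") {
      writeBin(as.numeric(page), con, size = 4L, endian = "little")
    } else {
      maxv <- if (format == "uint16") 65535 else 255
      page <- pmin(pmax(round(page), 0), maxv)
      if (format == "uint16") {
        ## writeBin has no unsigned 16-bit: wrap values >= 2^15 manually
        page <- ifelse(page >= 32768, page - 65536, page)
        writeBin(as.integer(page), con, size = 2L, endian = "little")
      } else {
        writeBin(as.raw(page), con)
      }
    }
  }

  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count); w32(value)
  }
  short_entry <- function(tag, value) {       # SHORT value is left-justified
    w16(tag); w16(3L); w32(1L)
    w16(value); w16(0L)
  }
  for (z in seq_len(nz)) {
    w16(n_entries[z])
    entry(256L, 4L, 1L, nx)
    entry(257L, 4L, 1L, ny)
    short_entry(258L, bps)
    short_entry(259L, 1L)
    short_entry(262L, 1L)
    if (z == 1L) entry(270L, 2L, length(desc_raw), off_desc)
    entry(273L, 4L, 1L, strip_off[z])
    short_entry(277L, 1L)
    entry(278L, 4L, 1L, ny)
    entry(279L, 4L, 1L, strip_bytes)
    entry(282L, 5L, 1L, off_rat)
    entry(283L, 5L, 1L, off_rat + 8L)
    short_entry(339L, sfmt)
    w32(if (z < nz) off_ifd[z + 1L] else 0L)
  }
  if (sidecar) write_spacing_sidecar(vol, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page grayscale TIFF into a voxel volume
#'
#' Supports the subset written by [write_volume_tiff()] plus uncompressed
#' single-sample files from ImageJ: little- or big-endian, 8/16-bit unsigned
#' or 32-bit float, any strip layout. Voxel spacing is recovered from the
#' resolution tags and ImageJ description; if absent, from the YAML sidecar
#' `<path>.yaml`; otherwise `default_spacing` is used.
#'
#' @param path TIFF file path.
#' @param default_spacing fallback spacing, um/voxel (x, y, z).
#' @return a [voxel_volume()].
#' @export
read_volume_tiff <- function(path, default_spacing = c(1, 1, 1)) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  endian <- if (rawToChar(buf[1:2]) == "II") "little"
            else if (rawToChar(buf[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  rd <- function(off, size, n = 1L, what = "integer", signed = TRUE)
    readBin(buf[(off + 1L):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = signed)
  u16 <- function(off, n = 1L) rd(off, 2L, n, signed = FALSE)
  u32 <- function(off, n = 1L) {
    v <- rd(off, 4L, n)
    ifelse(v < 0, v + 2^32, v)
  }
  if (u16(2L) != 42L) stop("bad TIFF magic in ", path)

  read_values <- function(type, count, off_field) {
    size <- tiff_type_size[[as.character(type)]]
    total <- size * count
    voff <- if (total <= 4L) off_field else u32(off_field)
    if (type == 3L) u16(voff, count)
    else if (type == 4L) u32(voff, count)
    else if (type == 5L) {
      num <- u32(voff, 1L); den <- u32(voff + 4L, 1L)
      num / den
    } else if (type == 2L) {
      rawToChar(buf[(voff + 1L):(voff + count)][buf[(voff + 1L):(voff + count)] != 0])
    } else if (type == 1L) as.integer(buf[(voff + 1L):(voff + count)])
    else stop("unsupported TIFF tag type ", type)
  }

  pages <- list()
  desc <- NULL; xres <- NA_real_; yres <- NA_real_
  ifd <- u32(4L)
  while (ifd != 0L) {
    n_ent <- u16(ifd)
    tags <- list()
    for (e in seq_len(n_ent)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
      tags[[as.character(tag)]] <- read_values(type, count, off + 8L)
    }
    g <- function(tag, default = NULL)
      if (!is.null(tags[[as.character(tag)]])) tags[[as.character(tag)]] else default
    if (!identical(as.integer(g(259L, 1L)), 1L))
      stop("read_volume_tiff: only uncompressed TIFF is supported")
    nx <- as.integer(g(256L)); ny <- as.integer(g(257L))
    bps <- as.integer(g(258L, 1L))[1L]
    sfmt <- as.integer(g(339L, 1L))[1L]
    if (is.null(desc)) desc <- g(270L)
    if (is.na(xres)) xres <- as.numeric(g(282L, NA_real_))
    if (is.na(yres)) yres <- as.numeric(g(283L, NA_real_))
    offs <- g(273L); cnts <- g(279L)
    raw_page <- unlist(lapply(seq_along(offs), function(i)
      buf[(offs[i] + 1L):(offs[i] + cnts[i])]), use.names = FALSE)
    vals <- if (bps == 32L && sfmt == 3L) {
      readBin(raw_page, "numeric", n = nx * ny, size = 4L, endian = endian)
    } else if (bps == 16L) {
      readBin(raw_page, "integer", n = nx * ny, size = 2L, endian = endian,
              signed = FALSE)
    } else if (bps == 8L) {
      as.integer(raw_page)
    } else stop("unsupported TIFF bit depth/sample format: ", bps, "/", sfmt)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = nx, ncol = ny)
    ifd <- u32(ifd + 2L + n_ent * 12L)
  }

  nz <- length(pages)
  arr <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), nz))
  for (z in seq_len(nz)) arr[, , z] <- pages[[z]]

  sp <- default_spacing
  if (is.finite(xres) && xres > 0) sp[1L] <- 1 / xres
  if (is.finite(yres) && yres > 0) sp[2L] <- 1 / yres
  if (!is.null(desc) && grepl("spacing=", desc)) {
    sz <- suppressWarnings(as.numeric(sub(".*spacing=([0-9.eE+-]+).*", "\\1", desc)))
    if (is.finite(sz) && sz > 0) sp[3L] <- sz
  } else if (file.exists(paste0(path, ".yaml"))) {
    side <- yaml_read(paste0(path, ".yaml"))
    for (i in 1:3)
      sp[i] <- as.numeric(side[[c("spacing_x", "spacing_y", "spacing_z")[i]]] %||% sp[i])
  }
  voxel_volume(arr, sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the voxel spacing sidecar for a volume
#' @param vol a [voxel_volume()].
#' @param path output path (conventionally `<tiff>.yaml`).
#' @return `path`, invisibly.
#' @export
write_spacing_sidecar <- function(vol, path) {
  d <- dim(vol$data)
  yaml_write(list(spacing_x = vol$spacing[1L], spacing_y = vol$spacing[2L],
                  spacing_z = vol$spacing[3L], size_x = d[1L], size_y = d[2L],
                  size_z = d[3L], unit = "micron"), path)
}
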