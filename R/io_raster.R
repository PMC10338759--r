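#' Read a raster grid (ESRI ASCII or TIFF)
#'
#' ESRI ASCII grids (`.asc`) are parsed directly. TIFF rasters (`.tif`,
#' `.tiff`) are read with the `tiff` package and georeferenced from an ESRI
#' world file (`.tfw`) next to the raster; without a world file the grid is
#' anchored at (0, 0) with unit cell size and a warning.
#'
#' @param path raster file path.
#' @param nodata value treated as missing (default -9999; cells become `NA`).
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, nodata = -9999) {
  if (!file.exists(path)) stop("cannot read raster: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) read_raster_tiff(path, nodata)
  else read_raster_asc(path)
}

read_raster_asc <- function(path) {
  lines <- readLines(path, n = 7L)
  hdr <- list()
  nh <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nh <- nh + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  if (!is.null(hdr$xllcorner)) {
    ox <- hdr$xllcorner; oy <- hdr$yllcorner
  } else {
    ox <- hdr$xllcenter - hdr$cellsize / 2
    oy <- hdr$yllcenter - hdr$cellsize / 2
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(path, skip = nh, quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop("ESRI ASCII grid has wrong cell count in ", path)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  m <- m[nrows:1, , drop = FALSE]     # file is north-up; store south-up
  raster_grid(m, ox, oy, hdr$cellsize, nodata = nodata)
}

read_raster_tiff <- function(path, nodata = -9999) {
  # float TIFFs come back as stored; as.is is only meaningful for integers
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) tiff::readTIFF(path))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  tfw <- paste0(tools::file_path_sans_ext(path), ".tfw")
  if (file.exists(tfw)) {
    w <- as.numeric(readLines(tfw, n = 6))
    cs <- w[1]
    # world file references the center of the upper-left pixel
    ox <- w[5] - cs / 2
    oy <- w[6] - (nrow(img) - 0.5) * cs
  } else {
    warning("no world file (.tfw) found for ", path,
            "; using origin (0,0) and the raster's pixel size 1 m")
    cs <- 1; ox <- 0; oy <- 0
  }
  m <- img[nrow(img):1, , drop = FALSE]          # store south-up
  m[m == nodata] <- NA_real_
  raster_grid(m, ox, oy, cs, nodata = nodata)
}

#' Write a raster grid (ESRI ASCII or TIFF)
#'
#' TIFF output is a minimal uncompressed 32-bit float grayscale TIFF plus an
#' ESRI world file (`.tfw`) carrying the georeferencing; `NA` cells are
#' stored as the grid's nodata value in either format.
#'
#' @param grid a [raster_grid()].
#' @param path output path (`.asc`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) write_raster_tiff(grid, path)
  else write_raster_asc(grid, path)
  invisible(path)
}

write_raster_asc <- function(grid, path) {
  m <- grid$values[grid$n_rows:1, , drop = FALSE]   # north-up for export
  m[!is.finite(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$origin_x),
               sprintf("yllcorner %.10g", grid$origin_y),
               sprintf("cellsize %.10g", grid$cell_size),
               sprintf("NODATA_value %.10g", grid$nodata)), con)
  write.table(format(m, trim = TRUE, digits = 10, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
}

write_raster_tiff <- function(grid, path) {
  m <- grid$values[grid$n_rows:1, , drop = FALSE]
  m[!is.finite(m)] <- grid$nodata
  nr <- nrow(m); nc <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * nr * nc
  ifd_offset <- 8L + data_bytes
  writeChar("II", con, 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  # pixel data, row-major from the top row
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(tag, con, size = 2, endian = "little")
    writeBin(type, con, size = 2, endian = "little")
    writeBin(count, con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: value left-justified in 4 bytes
      writeBin(value, con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(value, con, size = 4, endian = "little")
    }
  }
  writeBin(9L, con, size = 2, endian = "little")   # number of IFD entries
  entry(256L, 4L, 1L, nc)                # ImageWidth
  entry(257L, 4L, 1L, nr)                # ImageLength
  entry(258L, 3L, 1L, 32L)               # BitsPerSample
  entry(259L, 3L, 1L, 1L)                # Compression: none
  entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
  entry(273L, 4L, 1L, 8L)                # StripOffsets
  entry(278L, 4L, 1L, nr)                # RowsPerStrip
  entry(279L, 4L, 1L, data_bytes)        # StripByteCounts
  entry(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")   # no next IFD
  tfw <- paste0(tools::file_path_sans_ext(path), ".tfw")
  top_center_y <- grid$origin_y + (grid$n_rows - 0.5) * grid$cell_size
  writeLines(sprintf("%.10f", c(grid$cell_size, 0, 0, -grid$cell_size,
                                grid$origin_x + grid$cell_size / 2,
                                top_center_y)), tfw)
}
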