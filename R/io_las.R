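#' Read a point cloud from LAS or XYZ
#'
#' Supports uncompressed LAS 1.2--1.4 (point formats 0--10; only x, y, z and
#' classification are interpreted) and delimited XYZ text (whitespace or
#' comma separated, an optional header line is auto-detected by a non-numeric
#' first token). LAS class 2 points are flagged as ground. Coordinates are
#' returned as doubles with the LAS scale/offset applied.
#'
#' @param path input file path.
#' @param format `"auto"` (by extension), `"las"` or `"xyz"`.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "las", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("las", "laz")) "las" else "xyz"
  }
  if (format == "las") read_las(path) else read_xyz(path)
}

read_xyz <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first)))
    stop("empty point cloud file: ", path)
  tok <- strsplit(trimws(first), "[,;[:space:]]+")[[1]][1]
  has_header <- is.na(suppressWarnings(as.numeric(tok)))
  dt <- data.table::fread(path, header = has_header, data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty point cloud file: ", path)
  if (ncol(dt) < 3L) stop("XYZ file needs at least 3 columns: ", path)
  point_cloud(dt[[1]], dt[[2]], dt[[3]])
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file (bad signature): ", path)
  invisible(readBin(con, "raw", n = 20))           # source id..GUID
  ver <- readBin(con, "integer", n = 2, size = 1, signed = FALSE)
  invisible(readBin(con, "raw", n = 64))           # sysid + software
  invisible(readBin(con, "integer", n = 2, size = 2, signed = FALSE))
  header_size <- readBin(con, "integer", n = 1, size = 2, signed = FALSE)
  point_offset <- readBin(con, "integer", n = 1, size = 4)
  invisible(readBin(con, "integer", n = 1, size = 4)) # n VLRs
  fmt <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
  if (bitwAnd(fmt, 128L) != 0L)
    stop("compressed LAZ input is not supported; decompress to LAS first")
  rec_len <- readBin(con, "integer", n = 1, size = 2, signed = FALSE)
  n_legacy <- readBin(con, "integer", n = 1, size = 4)
  invisible(readBin(con, "integer", n = 5, size = 4))
  scale <- readBin(con, "double", n = 3)
  offset <- readBin(con, "double", n = 3)
  invisible(readBin(con, "double", n = 6))
  n <- n_legacy
  if (ver[1] == 1L && ver[2] >= 4L && header_size >= 375L) {
    seek(con, 247)
    n64 <- readBin(con, "double", n = 1, size = 8)   # not exact > 2^53, fine
    seek(con, 247)
    lo <- readBin(con, "integer", n = 2, size = 4)
    n_ext <- (if (lo[1] >= 0) lo[1] else lo[1] + 2^32) + lo[2] * 2^32
    if (n == 0L) n <- as.integer(n_ext)
  }
  if (is.na(n) || n <= 0L) stop("LAS file contains no points: ", path)
  seek(con, point_offset)
  rawpts <- readBin(con, "raw", n = as.numeric(n) * rec_len)
  if (length(rawpts) < n * rec_len) stop("truncated LAS point data: ", path)
  rec <- matrix(rawpts, nrow = rec_len)
  int_field <- function(rows) {
    readBin(as.vector(rec[rows, , drop = FALSE]), "integer", n = n, size = 4,
            endian = "little")
  }
  xi <- int_field(1:4); yi <- int_field(5:8); zi <- int_field(9:12)
  x <- xi * scale[1] + offset[1]
  y <- yi * scale[2] + offset[2]
  z <- zi * scale[3] + offset[3]
  cls_byte <- if (fmt >= 6L) 17L else 16L
  cls <- as.integer(rec[cls_byte, ])
  if (fmt < 6L) cls <- bitwAnd(cls, 31L)
  point_cloud(x, y, z, ground = cls == 2L)
}

#' Write a point cloud to LAS or XYZ
#'
#' LAS output is version 1.2, point format 0, with millimeter coordinate
#' resolution. Ground flags are stored as classification 2, tree labels in
#' the point-source-id field; for XYZ/CSV portability labels are also
#' written to `<path>_labels.csv` (`point_index,tree_id`) when present.
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param format `"auto"`, `"las"` or `"xyz"`.
#' @param label_csv write the label sidecar CSV when labels are present
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "las", "xyz"),
                              label_csv = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "las") "las" else "xyz"
  }
  if (format == "las") write_las(cloud, path) else {
    df <- data.frame(x = cloud$x, y = cloud$y, z = cloud$z)
    data.table::fwrite(df, path, sep = " ", col.names = FALSE)
  }
  if (label_csv && !is.null(cloud$tree_label)) {
    side <- paste0(tools::file_path_sans_ext(path), "_labels.csv")
    data.table::fwrite(data.frame(point_index = seq_len(nrow(cloud)),
                                  tree_id = cloud$tree_label), side)
  }
  invisible(path)
}

write_las <- function(cloud, path) {
  n <- nrow(cloud)
  scale <- 0.001
  off <- c(floor(min(cloud$x)), floor(min(cloud$y)), floor(min(cloud$z)))
  xi <- as.integer(round((cloud$x - off[1]) / scale))
  yi <- as.integer(round((cloud$y - off[2]) / scale))
  zi <- as.integer(round((cloud$z - off[3]) / scale))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2)                       # source id, encoding
  writeBin(raw(16), con)                                    # GUID
  writeBin(c(1L, 2L), con, size = 1)                        # version 1.2
  writeChar(formatC("canopycce", width = -32), con, 32, eos = NULL)
  writeChar(formatC("canopycce", width = -32), con, 32, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2)                     # day, year
  writeBin(227L, con, size = 2)                             # header size
  writeBin(227L, con, size = 4)                             # point data offset
  writeBin(0L, con, size = 4)                               # no VLRs
  writeBin(0L, con, size = 1)                               # point format 0
  writeBin(20L, con, size = 2)                              # record length
  writeBin(n, con, size = 4)
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4)
  writeBin(rep(scale, 3), con)
  writeBin(as.double(off), con)
  writeBin(c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
             max(cloud$z), min(cloud$z)), con)
  rec <- matrix(as.raw(0), nrow = 20L, ncol = n)
  pack4 <- function(v) matrix(writeBin(v, raw(), size = 4, endian = "little"),
                              nrow = 4)
  rec[1:4, ] <- pack4(xi); rec[5:8, ] <- pack4(yi); rec[9:12, ] <- pack4(zi)
  rec[15, ] <- as.raw(1L)                                   # return 1 of 1
  cls <- rep(1L, n)
  if (!is.null(cloud$ground)) cls[cloud$ground] <- 2L
  rec[16, ] <- as.raw(cls)
  if (!is.null(cloud$tree_label)) {
    lab <- pmin(pmax(cloud$tree_label, 0L), 65535L)
    rec[19:20, ] <- matrix(writeBin(as.integer(lab), raw(), size = 2,
                                    endian = "little"), nrow = 2)
  }
  writeBin(as.vector(rec), con)
  invisible(path)
}
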