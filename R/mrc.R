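# MRC/CCP4 2014 map I/O.
#
# The 1024-byte header is parsed word-by-word; only the fields that affect
# geometry are interpreted (dimensions, mode, start indices, sampling, cell,
# axis order, origin record). Data are stored column-fastest in file order;
# on read the array is permuted so axis order is always (x, y, z).

MRC_MAGIC <- charToRaw("MAP ")

cellFromParameters <- function(abc, angles) {
  ca <- cos(angles[1] * pi / 180); cb <- cos(angles[2] * pi / 180)
  cg <- cos(angles[3] * pi / 180); sg <- sin(angles[3] * pi / 180)
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(abc[1], 0, 0,
           abc[2] * cg, abc[2] * sg, 0,
           abc[3] * cb, abc[3] * (ca - cb * cg) / sg, abc[3] * v / sg),
         nrow = 3)
}

cellToParameters <- function(cell) {
  lens <- sqrt(colSums(cell^2))
  ang <- function(u, v) acos(sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))) * 180 / pi
  list(abc = lens,
       angles = c(ang(cell[, 2], cell[, 3]), ang(cell[, 1], cell[, 3]),
                  ang(cell[, 1], cell[, 2])))
}

#' Read a density map from an MRC/CCP4 file
#'
#' Reads modes 0 (int8), 1 (int16) and 2 (float32). The axis order stored in
#' the file (MAPC/MAPR/MAPS) is normalized so the returned array is always
#' indexed (x, y, z); the origin is taken from the ORIGIN record plus the
#' start indices times the grid step. Both little- and big-endian files are
#' handled via the machine stamp.
#'
#' @param path path to an MRC/CCP4 map file.
#' @param sourceKind provenance tag, "xray_diff" (default) or "cryoem_diff".
#' @return A \linkS4class{DensityMap}.
#' @export
readDensityMap <- function(path, sourceKind = "xray_diff") {
  if (!file.exists(path))
    lbFormatError(sprintf("file does not exist: %s", path))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    lbFormatError(sprintf("not an MRC file (size %d < 1024 bytes): %s", sz, path))

  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  if (!identical(hdr[209:212], MRC_MAGIC))
    lbFormatError(sprintf("missing 'MAP ' magic at word 53: %s", path))
  stamp <- hdr[213]
  endian <- if (identical(as.integer(stamp), 0x11L)) "big" else "little"

  word_i <- function(w, n = 1L)
    readBin(hdr[((w - 1L) * 4L + 1L):((w + n - 1L) * 4L)], "integer",
            n = n, size = 4L, endian = endian)
  word_f <- function(w, n = 1L)
    readBin(hdr[((w - 1L) * 4L + 1L):((w + n - 1L) * 4L)], "numeric",
            n = n, size = 4L, endian = endian)

  nd      <- word_i(1L, 3L)           # extents in file axis order
  mode    <- word_i(4L)
  nstart  <- word_i(5L, 3L)           # start indices, file axis order
  mxyz    <- word_i(8L, 3L)           # sampling along cell axes x, y, z
  cella   <- word_f(11L, 3L)
  angles  <- word_f(14L, 3L)
  mapcrs  <- word_i(17L, 3L)
  nsymbt  <- word_i(24L)
  originw <- word_f(50L, 3L)

  if (any(nd < 1L)) lbFormatError("non-positive grid dimensions")
  if (!all(sort(mapcrs) == 1:3))
    lbFormatError(sprintf("invalid axis order (%s)", paste(mapcrs, collapse = ",")))
  if (any(cella <= 0) || any(mxyz < 1L))
    lbValidationError("non-positive cell dimensions or sampling")
  nvox <- prod(nd)
  bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L)[as.character(mode)]
  if (is.na(bytes))
    lbFormatError(sprintf("unsupported MRC mode %d", mode))
  if (sz < 1024 + nsymbt + nvox * bytes)
    lbFormatError(sprintf("truncated MRC file: %s", path))

  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  data <- if (mode == 2L) {
    readBin(con, "numeric", n = nvox, size = 4L, endian = endian)
  } else {
    readBin(con, "integer", n = nvox, size = bytes, signed = TRUE,
            endian = endian)
  }
  arr <- array(as.numeric(data), dim = nd)

  # permute so axis k of the result is crystal axis k
  perm <- order(mapcrs)
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)
  startXyz <- nstart[perm]

  spacing <- cella / mxyz
  cell <- cellFromParameters(cella, angles)
  unitAxes <- sweep(cell, 2, sqrt(colSums(cell^2)), "/")
  origin <- originw + as.vector(unitAxes %*% (startXyz * spacing))

  new("DensityMap", values = arr, spacing = spacing, origin = origin,
      cell = cell, sourceKind = sourceKind)
}

#' Write a density map to an MRC/CCP4 2014 file
#'
#' Writes mode 2 (float32), axis order (x, y, z), little-endian, with the
#' map origin stored in the ORIGIN record.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDensityMap <- function(map, path) {
  stopifnot(is(map, "DensityMap"))
  vals <- map@values
  d <- dim(vals)
  pars <- cellToParameters(map@cell)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wi(d)                       # NX NY NZ
  wi(2L)                      # MODE float32
  wi(c(0L, 0L, 0L))           # N*START
  wi(d)                       # MX MY MZ
  wf(d * map@spacing)         # CELLA
  wf(pars$angles)             # CELLB
  wi(1:3)                     # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(1L, 0L))               # ISPG, NSYMBT
  writeBin(raw(100L), con)    # EXTRA (words 26-50 up to origin)
  wf(map@origin)              # ORIGIN
  writeBin(MRC_MAGIC, con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(as.vector(vals)))
  wi(1L)                      # NLABL
  lab <- charToRaw(format("ligandblob map", width = 80))
  writeBin(lab, con)
  writeBin(raw(9L * 80L), con)
  wf(as.vector(vals))
  invisible(path)
}
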