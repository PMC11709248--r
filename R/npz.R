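# Compressed-array container I/O for preprocessed blobs.
#
# One container per blob, holding the value array plus a flat metadata
# record. The container is a STORE-method zip of .npy members ("npz
# dialect"), so the files interoperate with numpy: np.load() reads them and
# np.savez() output is readable here. Members: values.npy (float64, Fortran
# order), spacing.npy, origin.npy, meta.npy (JSON bytes).

packU16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
packU32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
unpackU16 <- function(r) sum(as.integer(r) * c(1, 256))
unpackU32 <- function(r) sum(as.numeric(as.integer(r)) * c(1, 256, 65536, 16777216))

# ---- npy -------------------------------------------------------------------

npyBytes <- function(x) {
  if (is.raw(x)) {
    descr <- sprintf("|S%d", length(x))
    shape <- "()"
    payload <- x
  } else {
    d <- if (is.null(dim(x))) length(x) else dim(x)
    shape <- if (length(d) == 1L) sprintf("(%d,)", d)
             else sprintf("(%s)", paste(d, collapse = ", "))
    descr <- "<f8"
    payload <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
  }
  dict <- sprintf("{'descr': '%s', 'fortran_order': True, 'shape': %s, }",
                  descr, shape)
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  hlen <- length(charToRaw(dict)) + 1L
  pad <- (64L - ((10L + hlen) %% 64L)) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")
  c(charToRaw("\x93NUMPY"), as.raw(c(1L, 0L)), packU16(nchar(header)),
    charToRaw(header), payload)
}

parseNpy <- function(bytes) {
  if (length(bytes) < 10L || !identical(bytes[2:6], charToRaw("NUMPY")))
    lbFormatError("member is not an npy array")
  major <- as.integer(bytes[7])
  if (major == 1L) {
    hlen <- unpackU16(bytes[9:10]); off <- 10L
  } else {
    hlen <- unpackU32(bytes[9:12]); off <- 12L
  }
  header <- rawToChar(bytes[(off + 1L):(off + hlen)])
  payload <- bytes[(off + hlen + 1L):length(bytes)]

  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  shape <- shape[!is.na(shape)]

  if (grepl("^\\|S", descr)) {
    return(payload)
  }
  n <- if (length(shape)) prod(shape) else 1L
  vals <- switch(descr,
    "<f8" = readBin(payload, "numeric", n = n, size = 8L, endian = "little"),
    "<f4" = readBin(payload, "numeric", n = n, size = 4L, endian = "little"),
    "<i4" = as.numeric(readBin(payload, "integer", n = n, size = 4L,
                               endian = "little")),
    "<i8" = readBinInt64(payload, n),
    lbFormatError(sprintf("unsupported npy dtype '%s'", descr)))
  if (length(shape) > 1L) {
    if (fortran) {
      vals <- array(vals, dim = shape)
    } else {
      vals <- aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
    }
  }
  vals
}

readBinInt64 <- function(payload, n) {
  lo <- readBin(payload, "integer", n = 2L * n, size = 4L, endian = "little")
  lo32 <- lo[seq(1L, 2L * n, by = 2L)]
  hi32 <- lo[seq(2L, 2L * n, by = 2L)]
  as.numeric(hi32) * 2^32 + ifelse(lo32 < 0, as.numeric(lo32) + 2^32, lo32)
}

# ---- STORE zip -------------------------------------------------------------

writeStoreZip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  central <- list()
  pos <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crc <- .crc32_raw(data)
    local <- c(packU32(0x04034b50), packU16(20), packU16(0), packU16(0),
               packU16(0), packU16(0), packU32(crc), packU32(length(data)),
               packU32(length(data)), packU16(length(name)), packU16(0),
               name)
    offsets[i] <- pos
    writeBin(local, con); writeBin(data, con)
    pos <- pos + length(local) + length(data)
    central[[i]] <- c(packU32(0x02014b50), packU16(20), packU16(20),
                      packU16(0), packU16(0), packU16(0), packU16(0),
                      packU32(crc), packU32(length(data)),
                      packU32(length(data)), packU16(length(name)),
                      packU16(0), packU16(0), packU16(0), packU16(0),
                      packU32(0), packU32(offsets[i]), name)
  }
  cd <- do.call(c, central)
  writeBin(cd, con)
  eocd <- c(packU32(0x06054b50), packU16(0), packU16(0),
            packU16(length(entries)), packU16(length(entries)),
            packU32(length(cd)), packU32(pos), packU16(0))
  writeBin(eocd, con)
  invisible(path)
}

readStoreZip <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 22)
    lbFormatError(sprintf("not a zip container: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  tailLen <- min(sz, 65557)
  seek(con, sz - tailLen)
  tail <- readBin(con, "raw", n = tailLen)
  sig <- packU32(0x06054b50)
  eocd <- NA
  for (i in (length(tail) - 21L):1L) {
    if (identical(tail[i:(i + 3L)], sig)) { eocd <- i; break }
  }
  if (is.na(eocd)) lbFormatError(sprintf("zip end record not found: %s", path))
  nEntries <- unpackU16(tail[(eocd + 10L):(eocd + 11L)])
  cdOffset <- unpackU32(tail[(eocd + 16L):(eocd + 19L)])

  seek(con, cdOffset)
  entries <- list()
  for (k in seq_len(nEntries)) {
    h <- readBin(con, "raw", n = 46L)
    if (!identical(h[1:4], packU32(0x02014b50)))
      lbFormatError("corrupt zip central directory")
    method <- unpackU16(h[11:12])
    csize <- unpackU32(h[21:24])
    fnlen <- unpackU16(h[29:30])
    extlen <- unpackU16(h[31:32])
    cmtlen <- unpackU16(h[33:34])
    offset <- unpackU32(h[43:46])
    name <- rawToChar(readBin(con, "raw", n = fnlen))
    if (extlen + cmtlen > 0) readBin(con, "raw", n = extlen + cmtlen)
    if (method != 0L)
      lbFormatError(sprintf("zip member '%s' is compressed (method %d); only STORE is supported",
                            name, method))
    entries[[name]] <- c(offset = offset, csize = csize)
  }
  out <- list()
  for (name in names(entries)) {
    seek(con, entries[[name]][["offset"]])
    lh <- readBin(con, "raw", n = 30L)
    fnlen <- unpackU16(lh[27:28]); extlen <- unpackU16(lh[29:30])
    seek(con, entries[[name]][["offset"]] + 30 + fnlen + extlen)
    out[[name]] <- readBin(con, "raw", n = entries[[name]][["csize"]])
  }
  out
}

# ---- blob archive ----------------------------------------------------------

#' Write a blob grid with metadata to a compressed-array container
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param metadata named list or vector of flat metadata (deposit, chain,
#'   residue, resolution, ...).
#' @param path output path (conventionally .npz).
#' @return \code{path}, invisibly.
#' @export
writeBlobGrid <- function(grid, metadata = list(), path) {
  stopifnot(is(grid, "VoxelGrid"))
  metaJson <- jsonlite::toJSON(as.list(metadata), auto_unbox = TRUE,
                               digits = NA)
  entries <- list(
    "values.npy"  = npyBytes(grid@values),
    "spacing.npy" = npyBytes(grid@spacing),
    "origin.npy"  = npyBytes(grid@origin),
    "meta.npy"    = npyBytes(charToRaw(as.character(metaJson))))
  writeStoreZip(entries, path)
}

#' Read a blob grid and its metadata from a container
#'
#' @param path path to a container written by \code{\link{writeBlobGrid}} (or
#'   an uncompressed numpy .npz with the same member names).
#' @param requiredMeta metadata keys that must be present; a missing key is a
#'   validation error.
#' @return A list with elements \code{grid} (\linkS4class{VoxelGrid}) and
#'   \code{metadata} (named list).
#' @export
readBlobGrid <- function(path, requiredMeta = character()) {
  members <- readStoreZip(path)
  names(members) <- sub("\\.npy$", "", names(members))  # numpy key dialect
  for (need in c("values", "spacing", "origin")) {
    if (is.null(members[[need]]))
      lbValidationError(sprintf("container is missing required member '%s'", need))
  }
  vals <- parseNpy(members[["values"]])
  if (length(dim(vals)) != 3L)
    lbValidationError("values member must be a 3D array")
  spacing <- parseNpy(members[["spacing"]])
  origin <- parseNpy(members[["origin"]])
  metadata <- list()
  if (!is.null(members[["meta"]])) {
    metadata <- jsonlite::fromJSON(rawToChar(parseNpy(members[["meta"]])))
  }
  missing <- setdiff(requiredMeta, names(metadata))
  if (length(missing))
    lbValidationError(sprintf("missing required metadata keys: %s",
                              paste(missing, collapse = ", ")))
  list(grid = VoxelGrid(vals, spacing = spacing[1], origin = origin),
       metadata = metadata)
}
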