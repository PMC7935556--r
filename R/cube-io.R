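#' Construct a HyperCube
#'
#' @param data numeric 3D array in \code{(x, y, band)} order: \code{x} is the
#'   scan direction, \code{y} the field-of-view line (detector row) direction.
#' @param wavelengths per-band wavelength in nm, strictly increasing.
#' @param valueKind \code{"dn"} (raw digital numbers) or \code{"reflectance"}.
#' @param metadata optional named list of free-form metadata.
#' @return a [HyperCube-class]
#' @examples
#' cube <- HyperCube(array(runif(10 * 8 * 5), c(10, 8, 5)),
#'                   wavelengths = seq(400, 1000, length.out = 5),
#'                   valueKind = "reflectance")
#' dim(cube)
#' @export
HyperCube <- function(data, wavelengths, valueKind = c("dn", "reflectance"),
                      metadata = list()) {
  valueKind <- match.arg(valueKind)
  storage.mode(data) <- "double"
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      valueKind = valueKind, metadata = metadata)
}

#' Construct a BinaryMask
#'
#' @param grid logical matrix indexed \code{(x, y)}.
#' @return a [BinaryMask-class]
#' @export
BinaryMask <- function(grid) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  mode(grid) <- "logical"
  new("BinaryMask", grid = grid)
}

#' Construct a PlateRegion
#'
#' @param reflectance plate reflectance, a fraction in \eqn{(0, 1]}; scalar
#'   for a spectrally flat plate or one value per band.
#' @param xInterval,yInterval 1-based inclusive pixel ranges
#'   \code{c(first, last)} of the plate footprint.
#' @return a [PlateRegion-class]
#' @export
PlateRegion <- function(reflectance, xInterval, yInterval) {
  new("PlateRegion", reflectance = as.numeric(reflectance),
      xInterval = as.integer(xInterval), yInterval = as.integer(yInterval))
}

.checkRange <- function(range, maxlen, what) {
  if (is.null(range)) return(c(1L, maxlen))
  range <- as.integer(range)
  if (length(range) != 2L || any(is.na(range)))
    stop(sprintf("%s must be c(first, last)", what), call. = FALSE)
  if (range[1L] < 1L || range[2L] > maxlen || range[2L] < range[1L])
    stop(sprintf("%s [%d, %d] out of bounds or empty (extent %d)",
                 what, range[1L], range[2L], maxlen), call. = FALSE)
  range
}

#' Crop a cube spatially and/or spectrally
#'
#' Ranges are 1-based and inclusive; \code{NULL} keeps the full extent.
#' Wavelengths are sliced consistently with \code{bandRange}.
#'
#' @param cube a [HyperCube-class]
#' @param xRange,yRange,bandRange \code{c(first, last)} or \code{NULL}.
#' @return the cropped [HyperCube-class]
#' @export
cropCube <- function(cube, xRange = NULL, yRange = NULL, bandRange = NULL) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  xr <- .checkRange(xRange, d[1L], "xRange")
  yr <- .checkRange(yRange, d[2L], "yRange")
  br <- .checkRange(bandRange, d[3L], "bandRange")
  HyperCube(cube@data[xr[1L]:xr[2L], yr[1L]:yr[2L], br[1L]:br[2L],
                      drop = FALSE],
            cube@wavelengths[br[1L]:br[2L]], cube@valueKind, cube@metadata)
}

## ----------------------------------------------------------------------
## ENVI raster I/O (.hdr companion + flat binary, interleave bsq/bil/bip)
## ----------------------------------------------------------------------

.enviDtype <- c(`1` = "uint8", `2` = "int16", `3` = "int32",
                `4` = "float32", `5` = "float64", `12` = "uint16")

.enviHeaderPath <- function(path) {
  cand <- c(paste0(path, ".hdr"), sub("\\.[^.]*$", ".hdr", path))
  for (h in cand) if (file.exists(h)) return(h)
  cand[1L]
}

.parseEnviHeader <- function(hdr) {
  txt <- readChar(hdr, file.info(hdr)$size, useBytes = TRUE)
  if (!grepl("^\\s*ENVI", txt))
    stop("not an ENVI header (missing ENVI magic line): ", hdr, call. = FALSE)
  txt <- sub("^\\s*ENVI\\s*", "", txt)
  # key = value pairs; {...} values may span lines
  fields <- list()
  pat <- "([^=\\n]+)=\\s*(\\{[^}]*\\}|[^\\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- trimws(sub("=.*", "", piece))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[tolower(key)]] <- val
  }
  fields
}

.enviList <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

.readFlat <- function(path, n, dtype) {
  con <- file(path, "rb")
  on.exit(close(con))
  switch(dtype,
    uint8 = as.double(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    int16 = as.double(readBin(con, "integer", n, size = 2L, signed = TRUE,
                              endian = "little")),
    int32 = as.double(readBin(con, "integer", n, size = 4L,
                              endian = "little")),
    uint16 = as.double(readBin(con, "integer", n, size = 2L, signed = FALSE,
                               endian = "little")),
    float32 = readBin(con, "double", n, size = 4L, endian = "little"),
    float64 = readBin(con, "double", n, size = 8L, endian = "little"),
    stop("unsupported dtype: ", dtype, call. = FALSE))
}

.readEnvi <- function(path, wavelengths = NULL) {
  hdr <- .enviHeaderPath(path)
  if (!file.exists(hdr))
    stop("missing ENVI header for ", path, call. = FALSE)
  f <- .parseEnviHeader(hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(f))
  if (length(miss))
    stop("ENVI header lacks required fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ny <- as.integer(f$samples); nx <- as.integer(f$lines)
  nb <- as.integer(f$bands)
  interleave <- tolower(f$interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave: ", interleave, call. = FALSE)
  dtype <- .enviDtype[[f[["data type"]]]]
  if (is.null(dtype))
    stop("unsupported ENVI data type: ", f[["data type"]], call. = FALSE)
  if (!is.null(f[["byte order"]]) && as.integer(f[["byte order"]]) != 0L)
    stop("only little-endian (byte order = 0) ENVI files are supported",
         call. = FALSE)
  if (is.null(wavelengths)) {
    if (is.null(f$wavelength))
      stop("no wavelength list in header and none supplied", call. = FALSE)
    wavelengths <- .enviList(f$wavelength)
  }
  if (length(wavelengths) != nb)
    stop(sprintf("wavelength count [%d] != band count [%d]",
                 length(wavelengths), nb), call. = FALSE)
  raw <- .readFlat(path, nx * ny * nb, dtype)
  # fastest-varying axis first, then aperm to canonical (x, y, band)
  data <- switch(interleave,
    bsq = aperm(array(raw, c(ny, nx, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(raw, c(ny, nb, nx)), c(3L, 1L, 2L)),
    bip = aperm(array(raw, c(nb, ny, nx)), c(3L, 2L, 1L)))
  vk <- f[["value kind"]]
  if (is.null(vk) || !vk %in% c("dn", "reflectance")) vk <- "dn"
  known <- c(need, "byte order", "wavelength", "value kind", "header offset",
             "file type", "wavelength units", "description")
  extra <- f[setdiff(names(f), known)]
  meta <- c(list(source_interleave = interleave, source_dtype = dtype),
            extra)
  HyperCube(data, wavelengths, vk, meta)
}

.writeEnvi <- function(cube, path, interleave = "bsq", dtype = "float64") {
  d <- dim(cube@data)
  nx <- d[1L]; ny <- d[2L]; nb <- d[3L]
  code <- names(.enviDtype)[match(dtype, .enviDtype)]
  if (is.na(code)) stop("unsupported dtype: ", dtype, call. = FALSE)
  arr <- switch(interleave,
    bsq = aperm(cube@data, c(2L, 1L, 3L)),
    bil = aperm(cube@data, c(2L, 3L, 1L)),
    bip = aperm(cube@data, c(3L, 2L, 1L)),
    stop("unsupported interleave: ", interleave, call. = FALSE))
  vec <- as.vector(arr)
  con <- file(path, "wb")
  size <- switch(dtype, uint8 = 1L, int16 = , uint16 = 2L,
                 int32 = , float32 = 4L, float64 = 8L)
  if (dtype %in% c("float32", "float64")) {
    writeBin(vec, con, size = size, endian = "little")
  } else {
    writeBin(as.integer(round(vec)), con, size = size, endian = "little")
  }
  close(con)
  extra <- cube@metadata
  extra <- extra[setdiff(names(extra),
                         c("source_interleave", "source_dtype"))]
  lines <- c(
    "ENVI",
    "description = {written by cubeprep}",
    sprintf("samples = %d", ny),
    sprintf("lines = %d", nx),
    sprintf("bands = %d", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %s", code),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("value kind = %s", cube@valueKind),
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube@wavelengths, digits = 15, trim = TRUE,
                         scientific = FALSE), collapse = ", ")))
  chr <- vapply(extra, function(v) is.character(v) && length(v) == 1L,
                logical(1))
  if (any(chr))
    lines <- c(lines, sprintf("%s = %s", names(extra)[chr],
                              unlist(extra[chr])))
  writeLines(lines, paste0(path, ".hdr"))
  invisible(NULL)
}

## ----------------------------------------------------------------------
## Single-file array container: one JSON header line, then little-endian
## float64 payload in canonical (x, y, band) order (x fastest).
## ----------------------------------------------------------------------

.writeContainer <- function(path, type, dims, payload, wavelengths = NULL,
                            valueKind = NULL, metadata = NULL) {
  hdr <- list(format = "cubeprep-array", version = 1L, type = type,
              dims = as.integer(dims), dtype = "float64")
  if (!is.null(wavelengths)) hdr$wavelengths <- wavelengths
  if (!is.null(valueKind)) hdr$value_kind <- valueKind
  if (!is.null(metadata) && length(metadata)) hdr$metadata <- metadata
  json <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(json, "\n")), con)
  writeBin(as.numeric(payload), con, size = 8L, endian = "little")
  invisible(NULL)
}

.readContainer <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  nl <- which(bytes == as.raw(0x0A))[1L]
  if (is.na(nl))
    stop("not a cubeprep array container (no header line): ", path,
         call. = FALSE)
  hdr <- jsonlite::fromJSON(rawToChar(bytes[seq_len(nl - 1L)]),
                            simplifyVector = TRUE)
  if (!identical(hdr$format, "cubeprep-array"))
    stop("not a cubeprep array container: ", path, call. = FALSE)
  n <- prod(hdr$dims)
  payload <- readBin(bytes[-seq_len(nl)], "double", n, size = 8L,
                     endian = "little")
  list(header = hdr, payload = payload)
}

#' Read a hyperspectral cube from disk
#'
#' Supports ENVI rasters (flat binary plus \code{.hdr} companion, interleaves
#' \code{bsq}/\code{bil}/\code{bip}, little-endian, dtypes uint8/int16/int32/
#' uint16/float32/float64) and the package's single-file array container
#' written by [writeCube()]. Whatever the on-disk interleave, the returned
#' cube is in canonical \code{(x, y, band)} order with \code{x} = ENVI lines
#' (scan direction) and \code{y} = ENVI samples (pixels along the
#' field-of-view line); metadata records the source interleave and dtype.
#' Unknown ENVI header keys are preserved verbatim in metadata.
#'
#' @param path data file path (for ENVI, the header is looked up at
#'   \code{<path>.hdr}, then \code{<basename>.hdr}).
#' @param format \code{"envi"} or \code{"array"}.
#' @param wavelengths optional wavelength vector overriding/supplying the
#'   header's list.
#' @return a [HyperCube-class]
#' @export
readCube <- function(path, format = c("envi", "array"), wavelengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "envi") return(.readEnvi(path, wavelengths))
  x <- .readContainer(path)
  h <- x$header
  if (!identical(h$type, "cube"))
    stop("container holds a ", h$type, ", not a cube", call. = FALSE)
  meta <- if (is.null(h$metadata)) list() else as.list(h$metadata)
  HyperCube(array(x$payload, h$dims), h$wavelengths, h$value_kind, meta)
}

#' Write a hyperspectral cube to disk
#'
#' @param cube a [HyperCube-class]
#' @param path output data file (ENVI header written to \code{<path>.hdr}).
#' @param format \code{"envi"} or \code{"array"}.
#' @param interleave ENVI interleave, one of \code{"bsq"}, \code{"bil"},
#'   \code{"bip"}.
#' @param dtype on-disk element type for ENVI; \code{"float64"} (default,
#'   lossless round trip), \code{"float32"} or \code{"uint16"} (values are
#'   rounded).
#' @return invisibly \code{NULL}
#' @export
writeCube <- function(cube, path, format = c("envi", "array"),
                      interleave = "bsq", dtype = "float64") {
  stopifnot(is(cube, "HyperCube"))
  format <- match.arg(format)
  if (format == "envi") return(.writeEnvi(cube, path, interleave, dtype))
  meta <- cube@metadata
  meta <- meta[vapply(meta, function(v)
    (is.character(v) || is.numeric(v) || is.logical(v)), logical(1))]
  .writeContainer(path, "cube", dim(cube@data), cube@data,
                  wavelengths = cube@wavelengths, valueKind = cube@valueKind,
                  metadata = meta)
}

#' Read / write a binary mask
#'
#' Masks travel either as 8-bit PNG (foreground 255, background 0; PNG rows
#' are \code{y}, columns are \code{x}) or in the package's array container.
#'
#' @param path file path.
#' @param format \code{"png"} or \code{"array"}.
#' @return [readMask()]: a [BinaryMask-class].
#' @export
readMask <- function(path, format = c("png", "array")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(BinaryMask(t(img) > 0.5))
  }
  x <- .readContainer(path)
  if (!identical(x$header$type, "mask"))
    stop("container holds a ", x$header$type, ", not a mask", call. = FALSE)
  BinaryMask(matrix(x$payload > 0.5, x$header$dims[1L], x$header$dims[2L]))
}

#' @param mask a [BinaryMask-class]
#' @rdname readMask
#' @export
writeMask <- function(mask, path, format = c("png", "array")) {
  stopifnot(is(mask, "BinaryMask"))
  format <- match.arg(format)
  if (format == "png") {
    png::writePNG(t(mask@grid) * 1.0, path)
  } else {
    .writeContainer(path, "mask", dim(mask@grid), as.numeric(mask@grid))
  }
  invisible(NULL)
}
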