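# Reading/writing projection stacks, masks and volumes; geometry configs;
# structured logging.  All image files are TIFF: 8/16-bit unsigned input is
# read as raw counts without rescaling, float data is written as 32-bit IEEE
# float, slice (or frame) per page.

#' Emit a structured log line
#'
#' Prints `[bstdmar] <stage> | <details>` through [message()] when the
#' option `bstdmar.verbose` is `TRUE` (default off).
#'
#' @param stage short stage name.
#' @param ... further fields, pasted with `" | "`.
#' @return invisibly, the formatted line.
#' @export
bstdLog <- function(stage, ...) {
  line <- paste(c(sprintf("[bstdmar] %s", stage), ...), collapse = " | ")
  if (isTRUE(getOption("bstdmar.verbose", FALSE))) message(line)
  invisible(line)
}

## --- minimal float32 TIFF writer -------------------------------------------
## The CRAN tiff package only writes [0,1]-normalized integer samples, so
## 32-bit float pages (SampleFormat = 3) are encoded here directly:
## little-endian, uncompressed, one strip per page.  tiff::readTIFF reads
## the result (and any other float TIFF) back bit-exactly.

.tiffEntry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {  # SHORT, left-justified in the 4-byte value field
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

writeFloatTIFF <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  dataOffsets <- integer(length(pages))
  nbytes <- vapply(pages, function(p) 4L * length(p), integer(1))
  # header (8) then all pixel data, then the IFD chain
  off <- 8L
  for (i in seq_along(pages)) {
    dataOffsets[i] <- off
    off <- off + nbytes[i]
  }
  ifdSize <- 2L + 10L * 12L + 4L
  ifdOffsets <- off + ifdSize * (seq_along(pages) - 1L)
  writeBin(ifdOffsets[1L], con, size = 4, endian = "little")
  for (p in pages)  # TIFF is row-major
    writeBin(as.vector(t(p)), con, size = 4, endian = "little")
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    writeBin(10L, con, size = 2, endian = "little")
    .tiffEntry(con, 256, 4, 1, ncol(p))         # ImageWidth
    .tiffEntry(con, 257, 4, 1, nrow(p))         # ImageLength
    .tiffEntry(con, 258, 3, 1, 32)              # BitsPerSample
    .tiffEntry(con, 259, 3, 1, 1)               # Compression = none
    .tiffEntry(con, 262, 3, 1, 1)               # Photometric = BlackIsZero
    .tiffEntry(con, 273, 4, 1, dataOffsets[i])  # StripOffsets
    .tiffEntry(con, 277, 3, 1, 1)               # SamplesPerPixel
    .tiffEntry(con, 278, 4, 1, nrow(p))         # RowsPerStrip
    .tiffEntry(con, 279, 4, 1, nbytes[i])       # StripByteCounts
    .tiffEntry(con, 339, 3, 1, 3)               # SampleFormat = IEEE float
    nxt <- if (i < length(pages)) ifdOffsets[i + 1L] else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }
  invisible(path)
}

## --- format plug-in registry ------------------------------------------------

.readers <- new.env(parent = emptyenv())

#' Register a projection-stack reader plug-in
#'
#' Extends [readProjectionStack()] with a new on-disk format.  `predicate`
#' receives the path and returns `TRUE` when the reader applies; `reader`
#' receives the path and must return a list of numeric frame matrices in
#' angle order.  Registered readers are tried before the built-in TIFF
#' readers.
#'
#' @param name reader name (overwrites an existing entry of the same name).
#' @param predicate `function(path) -> logical(1)`.
#' @param reader `function(path) -> list of matrices`.
#' @return invisibly, the reader name.
#' @export
registerStackReader <- function(name, predicate, reader) {
  assign(name, list(predicate = predicate, reader = reader), envir = .readers)
  invisible(name)
}

.listTIFFs <- function(dir) {
  files <- list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  # explicit C-locale sort: frame order must not depend on the platform locale
  files[order(basename(files), method = "radix")]
}

.readFrames <- function(path) {
  for (nm in ls(.readers)) {
    entry <- get(nm, envir = .readers)
    if (isTRUE(entry$predicate(path))) return(entry$reader(path))
  }
  if (dir.exists(path)) {
    files <- .listTIFFs(path)
    if (!length(files)) stop("no TIFF files found in ", path)
    frames <- lapply(files, function(f) {
      p <- tryCatch(tiff::readTIFF(f, as.is = TRUE),
                    error = function(e) tiff::readTIFF(f))
      if (length(dim(p)) != 2L)
        stop("frame is not single-channel 2D: ", f)
      p
    })
    shapes <- vapply(frames, function(p) paste(dim(p), collapse = "x"), "")
    if (length(unique(shapes)) != 1L)
      stop("inconsistent frame shapes; first offending file: ",
           files[which(shapes != shapes[1L])[1L]])
    return(frames)
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  frames <- .readTIFFPages(path)
  if (is.matrix(frames)) frames <- list(frames)
  frames
}

# as.is = TRUE keeps integer TIFFs in raw counts but is rejected by libtiff
# for float pages, which already come back unscaled
.readTIFFPages <- function(path) {
  tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
           error = function(e) tiff::readTIFF(path, all = TRUE))
}

#' Read a projection stack from disk
#'
#' Accepts a multi-page TIFF or a directory of per-angle TIFF files
#' (lexicographic file order, C locale, is the angle order); additional
#' formats can be added with [registerStackReader()].  8/16-bit unsigned
#' pages are read as raw counts without rescaling; 32-bit float pages keep
#' their values.  Angles are taken from `geometry` (uniform,
#' endpoint-exclusive spacing over its rotation range) unless a sidecar
#' `angles.txt` (one angle in degrees per line) sits next to the input.
#'
#' @param path multi-page TIFF file or directory of TIFFs.
#' @param geometry a [ScanGeometry-class]; its rotation range sets the
#'   uniform angle grid.
#' @param pixelPitch detector pixel pitch in mm.
#' @param domain value domain of the data (default `"raw_counts"`).
#' @return A [ProjectionStack-class].
#' @export
readProjectionStack <- function(path, geometry = NULL, pixelPitch = 1,
                                domain = "raw_counts") {
  frames <- .readFrames(path)
  sidecar <- file.path(if (dir.exists(path)) path else dirname(path),
                       "angles.txt")
  if (file.exists(sidecar)) {
    ang <- scan(sidecar, quiet = TRUE)
    if (length(ang) != length(frames))
      stop("angle sidecar length does not match frame count")
  } else if (!is.null(geometry)) {
    ang <- uniformAngles(length(frames), geometry@rotationRange)
  } else {
    stop("missing angle information: supply a geometry or an angles.txt sidecar")
  }
  bstdLog("read_stack", path, paste(length(frames), "frames"))
  ProjectionStack(frames, angles = ang, pixelPitch = pixelPitch,
                  domain = domain)
}

#' Write a projection stack to a multi-page TIFF
#'
#' Raw-count stacks are stored as 16-bit unsigned pages (values must lie in
#' 0..65535); all other domains as 32-bit float pages, which round-trip
#' bit-exactly through [readProjectionStack()].
#'
#' @param stack a [ProjectionStack-class].
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
writeProjectionStack <- function(stack, path) {
  fr <- frames(stack)
  pages <- lapply(seq_len(dim(fr)[1L]), function(i) fr[i, , ])
  if (stackDomain(stack) == "raw_counts") {
    if (max(fr) > 65535) stop("raw counts exceed 16-bit range")
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
  } else {
    writeFloatTIFF(pages, path)
  }
  bstdLog("write_stack", path)
  invisible(path)
}

#' Write a reconstructed volume
#'
#' Stores the volume as a slice-per-page 32-bit float TIFF plus a YAML
#' sidecar `<path>.meta.yaml` recording the voxel size; [readVolume()]
#' restores it bit-exactly (at float32 precision).
#'
#' @param vol a [CTVolume-class] with finite voxels.
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
writeVolume <- function(vol, path) {
  v <- voxels(vol)
  if (!all(is.finite(v))) stop("volume contains non-finite voxels")
  pages <- lapply(seq_len(dim(v)[3L]), function(k) v[, , k])
  writeFloatTIFF(pages, path)
  yaml::write_yaml(list(voxel_size_mm = voxelSize(vol),
                        dims = dim(v)),
                   paste0(path, ".meta.yaml"))
  bstdLog("write_volume", path)
  invisible(path)
}

#' Read a volume written by [writeVolume()]
#'
#' @param path TIFF path (the `<path>.meta.yaml` sidecar must be present).
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  pages <- .readTIFFPages(path)
  if (is.matrix(pages)) pages <- list(pages)
  v <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) v[, , k] <- pages[[k]]
  CTVolume(v, voxelSize = meta$voxel_size_mm)
}

#' Read / write a scan geometry config
#'
#' YAML files with keys `beam_type`, `detector_rows`, `detector_cols`,
#' `source_object_dist_mm`, `source_detector_dist_mm`, `rotation_range_deg`.
#'
#' @param path YAML file path.
#' @return `readScanGeometry`: a [ScanGeometry-class].
#' @export
readScanGeometry <- function(path) {
  g <- yaml::read_yaml(path)
  ScanGeometry(detectorRows = g$detector_rows,
               detectorCols = g$detector_cols,
               beamType = g$beam_type,
               sourceObjectDist = g$source_object_dist_mm %||% NA_real_,
               sourceDetectorDist = g$source_detector_dist_mm %||% NA_real_,
               rotationRange = g$rotation_range_deg %||% 360)
}

#' @rdname readScanGeometry
#' @param geometry a [ScanGeometry-class].
#' @export
writeScanGeometry <- function(geometry, path) {
  yaml::write_yaml(list(
    beam_type = geometry@beamType,
    detector_rows = geometry@detectorRows,
    detector_cols = geometry@detectorCols,
    source_object_dist_mm = geometry@sourceObjectDist,
    source_detector_dist_mm = geometry@sourceDetectorDist,
    rotation_range_deg = geometry@rotationRange), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `expr` under a fixed RNG state without disturbing the caller's stream
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
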