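# Volume file I/O: multi-page TIFF and NRRD.
#
# No TIFF or NRRD reader ships with this R installation, so both formats are
# implemented here at the subset the pipeline needs: uncompressed grayscale
# baseline TIFF (8/16-bit unsigned or 32-bit float, one sample per pixel,
# little- or big-endian on read, little-endian on write) and 3D NRRD with
# raw or gzip encoding. Within a TIFF page, row r / column c maps to array
# element [c, r]; page k is slice [, , k].

#' Read a 3D volume from TIFF or NRRD
#'
#' Loads a multi-page TIFF stack or an NRRD volume into an [axon_volume()].
#' Integer-typed files are rescaled to `[0, 1]` by the maximum of their
#' dtype (255 for 8-bit, 65535 for 16-bit); float data is taken as-is and
#' must already lie in `[0, 1]`. A voxel size stated by the caller overrides
#' any spacing recorded in the file (file spacing metadata, especially in
#' TIFF, is unreliable), with a warning when the two disagree.
#'
#' @param path file path; format chosen by extension (`.nrrd` vs
#'   `.tif`/`.tiff`).
#' @param voxel_size_um voxel pitch in micrometres; required for TIFF,
#'   optional for NRRD (whose header carries spacings).
#' @param axis_map anatomical axis convention (see [axon_volume()]).
#' @param origin_um world origin (default 0).
#' @return an [axon_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL,
                        axis_map = c(ML = 1L, DV = 2L, RC = 3L),
                        origin_um = c(0, 0, 0)) {
  raw <- read_volume_raw(path)
  vs <- resolve_spacing(voxel_size_um, raw$spacing_um, path)
  values <- rescale_to_unit(raw$values, raw$kind)
  if (anyNA(values) || any(!is.finite(values))) {
    stop(sprintf("format error in %s: NaN values", path), call. = FALSE)
  }
  axon_volume(values, vs, axis_map = axis_map, origin_um = origin_um)
}

#' Read a 3D integer label atlas from TIFF or NRRD
#'
#' Like [read_volume()] but without the probability rescaling: voxel values
#' are kept as integer region labels.
#'
#' @inheritParams read_volume
#' @param region_table data.frame with `label`, `acronym`, `name`; if
#'   `NULL`, looked up in a sidecar CSV `<path>.regions.csv` (written by
#'   [write_atlas()]).
#' @return a [label_atlas()].
#' @export
read_atlas <- function(path, region_table = NULL, voxel_size_um = NULL,
                       axis_map = c(ML = 1L, DV = 2L, RC = 3L),
                       origin_um = c(0, 0, 0)) {
  raw <- read_volume_raw(path)
  vs <- resolve_spacing(voxel_size_um, raw$spacing_um, path)
  if (is.null(region_table)) {
    sidecar <- paste0(path, ".regions.csv")
    if (!file.exists(sidecar)) {
      stop(sprintf("no region table given and no sidecar found at %s", sidecar),
           call. = FALSE)
    }
    region_table <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
  }
  labels <- raw$values
  storage.mode(labels) <- "integer"
  label_atlas(labels, region_table, vs, axis_map = axis_map, origin_um = origin_um)
}

#' Write a volume to TIFF or NRRD
#'
#' NRRD (which carries voxel spacing in its header) is the preferred
#' format; TIFF is provided for compatibility with microscope export
#' toolchains. Probability data is stored as float32, binary data as uint8.
#'
#' @param volume an [axon_volume()].
#' @param path output path ending in `.nrrd`, `.tif` or `.tiff`.
#' @param dtype `"double"`, `"float"`, `"uint8"` or `"uint16"`; integer
#'   dtypes store `round(value * dtype_max)`. Defaults to `"double"` for
#'   NRRD (lossless for R numerics) and `"float"` for TIFF (baseline TIFF
#'   has no 64-bit float).
#' @param encoding NRRD encoding, `"raw"` or `"gzip"` (ignored for TIFF).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, dtype = NULL,
                         encoding = c("raw", "gzip")) {
  stopifnot(inherits(volume, "axon_volume"))
  is_tiff <- tolower(tools::file_ext(path)) %in% c("tif", "tiff")
  if (is.null(dtype)) dtype <- if (is_tiff) "float" else "double"
  dtype <- match.arg(dtype, c("double", "float", "uint8", "uint16"))
  if (is_tiff && dtype == "double") {
    stop("baseline TIFF has no 64-bit float; use dtype = 'float'", call. = FALSE)
  }
  vals <- volume$values
  data <- switch(dtype,
                 double = vals,
                 float = vals,
                 uint8 = round(vals * 255),
                 uint16 = round(vals * 65535))
  write_grid(data, dtype, path, volume$voxel_size_um, match.arg(encoding))
}

#' Write a label atlas (labels volume plus region-table sidecar CSV)
#'
#' @param atlas a [label_atlas()].
#' @param path output path (`.nrrd`, `.tif` or `.tiff`); the region table is
#'   written next to it as `<path>.regions.csv`.
#' @inheritParams write_volume
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path, encoding = c("raw", "gzip")) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (max(atlas$labels) > 65535L || min(atlas$labels) < 0L) {
    stop("atlas labels must fit in uint16", call. = FALSE)
  }
  write_grid(atlas$labels, "uint16", path, atlas$voxel_size_um,
             match.arg(encoding))
  utils::write.csv(atlas$region_table, paste0(path, ".regions.csv"),
                   row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# shared helpers

resolve_spacing <- function(stated, from_file, path) {
  if (!is.null(stated)) {
    stated <- as_len3(stated, "voxel_size_um")
    if (any(stated <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
    if (!is.null(from_file) && any(abs(stated - from_file) > 1e-6)) {
      warning(sprintf("%s: stated voxel size (%s um) overrides file spacing (%s um)",
                      basename(path),
                      paste(signif(stated, 6), collapse = "x"),
                      paste(signif(from_file, 6), collapse = "x")))
    }
    return(stated)
  }
  if (is.null(from_file)) {
    stop(sprintf("format error in %s: no voxel size stated and none in file",
                 path), call. = FALSE)
  }
  from_file
}

rescale_to_unit <- function(values, kind) {
  switch(kind,
         uint8 = values / 255,
         uint16 = values / 65535,
         int16 = values / 32767,
         int32 = values / 2147483647,
         float = values,
         double = values,
         stop(sprintf("unsupported voxel type: %s", kind), call. = FALSE))
}

read_volume_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read volume: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nrrd = read_nrrd(path),
         tif = ,
         tiff = read_tiff(path),
         stop(sprintf("format error in %s: unknown extension '%s'", path, ext),
              call. = FALSE))
}

write_grid <- function(data, dtype, path, voxel_size_um, encoding = "raw") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nrrd = write_nrrd(data, dtype, path, voxel_size_um, encoding),
         tif = ,
         tiff = write_tiff(data, dtype, path),
         stop(sprintf("cannot write %s: unknown extension '%s'", path, ext),
              call. = FALSE))
  invisible(path)
}

# ---------------------------------------------------------------------------
# NRRD

nrrd_types <- list(
  uint8 = list(names = c("uchar", "unsigned char", "uint8", "uint8_t"),
               what = "integer", size = 1L, signed = FALSE),
  int16 = list(names = c("short", "short int", "signed short", "int16", "int16_t"),
               what = "integer", size = 2L, signed = TRUE),
  uint16 = list(names = c("ushort", "unsigned short", "uint16", "uint16_t"),
                what = "integer", size = 2L, signed = FALSE),
  int32 = list(names = c("int", "signed int", "int32", "int32_t"),
               what = "integer", size = 4L, signed = TRUE),
  float = list(names = "float", what = "double", size = 4L, signed = TRUE),
  double = list(names = "double", what = "double", size = 8L, signed = TRUE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic)) {
    stop(sprintf("format error in %s: not an NRRD file", path), call. = FALSE)
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      stop(sprintf("format error in %s: header not terminated", path), call. = FALSE)
    }
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  dimension <- as.integer(fields$dimension %||% NA)
  if (is.na(dimension) || dimension != 3L) {
    stop(sprintf("format error in %s: non-3D data (dimension %s)",
                 path, fields$dimension %||% "missing"), call. = FALSE)
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type_name <- fields$type
  kind <- NULL
  for (k in names(nrrd_types)) {
    if (type_name %in% nrrd_types[[k]]$names) kind <- k
  }
  if (is.null(kind)) {
    stop(sprintf("format error in %s: unsupported type '%s'", path, type_name),
         call. = FALSE)
  }
  tp <- nrrd_types[[kind]]
  endian <- fields$endian %||% "little"
  encoding <- fields$encoding %||% "raw"
  n <- prod(sizes)
  if (encoding == "raw") {
    vec <- readBin(con, tp$what, n = n, size = tp$size, endian = endian,
                   signed = if (tp$what == "integer" && tp$size <= 2L) tp$signed else TRUE)
  } else if (encoding %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.info(path)$size)
    vec <- readBin(memDecompress(comp, type = "gzip"), tp$what, n = n,
                   size = tp$size, endian = endian,
                   signed = if (tp$what == "integer" && tp$size <= 2L) tp$signed else TRUE)
  } else {
    stop(sprintf("format error in %s: unsupported encoding '%s'", path, encoding),
         call. = FALSE)
  }
  if (length(vec) != n) {
    stop(sprintf("format error in %s: truncated data", path), call. = FALSE)
  }
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(dirs) == 3L) {
      spacing <- vapply(seq_len(3L), function(i) {
        v <- as.numeric(strsplit(gsub("[()]", "", dirs[i]), ",")[[1]])
        sqrt(sum(v^2))
      }, 0)
    }
  }
  list(values = array(vec, sizes), kind = kind, spacing_um = spacing)
}

write_nrrd <- function(data, dtype, path, voxel_size_um, encoding = "raw") {
  tp <- nrrd_types[[dtype]]
  sizes <- dim(data)
  header <- c(
    "NRRD0004",
    "# axolat volume",
    sprintf("type: %s", tp$names[1]),
    "dimension: 3",
    sprintf("sizes: %s", paste(sizes, collapse = " ")),
    sprintf("spacings: %s", paste(format(voxel_size_um, digits = 15), collapse = " ")),
    sprintf("encoding: %s", encoding),
    "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  vec <- as.vector(data)
  if (tp$what == "integer") vec <- as.integer(round(vec))
  if (encoding == "raw") {
    writeBin(vec, con, size = tp$size, endian = "little")
  } else {
    tmp <- writeBin(vec, raw(), size = tp$size, endian = "little")
    writeBin(memCompress(tmp, type = "gzip"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# TIFF (baseline grayscale, uncompressed)

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

read_tiff <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  order_mark <- rawToChar(bytes[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop(sprintf("format error in %s: not a TIFF file", path),
                        call. = FALSE))
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(bytes[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = if (size <= 2L) signed else TRUE)
  }
  if (rd(2L, "integer", 1L, 2L) != 42L) {
    stop(sprintf("format error in %s: bad TIFF magic", path), call. = FALSE)
  }
  ifd_off <- rd(4L, "integer", 1L, 4L)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- rd(ifd_off, "integer", 1L, 2L, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd(eo, "integer", 1L, 2L, signed = FALSE)
      typ <- rd(eo + 2L, "integer", 1L, 2L, signed = FALSE)
      cnt <- rd(eo + 4L, "integer", 1L, 4L)
      sz <- c(1L, 1L, 2L, 4L)[match(typ, c(1L, 2L, 3L, 4L))]
      if (is.na(sz)) next  # rational/other types are not needed
      total <- sz * cnt
      voff <- if (total <= 4L) eo + 8L else rd(eo + 8L, "integer", 1L, 4L)
      vals <- rd(voff, "integer", cnt, sz, signed = FALSE)
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- rd(ifd_off + 2L + n_entries * 12L, "integer", 1L, 4L)
  }
  if (length(pages) < 2L) {
    stop(sprintf("format error in %s: non-3D data (%d TIFF page%s)",
                 path, length(pages), if (length(pages) == 1L) "" else "s"),
         call. = FALSE)
  }
  g <- function(tags, name, default = NULL) {
    tags[[as.character(TIFF_TAGS[[name]])]] %||% default
  }
  first <- pages[[1]]
  width <- g(first, "ImageWidth")
  height <- g(first, "ImageLength")
  bits <- g(first, "BitsPerSample", 1L)
  fmt <- g(first, "SampleFormat", 1L)
  if ((g(first, "Compression", 1L)) != 1L) {
    stop(sprintf("format error in %s: compressed TIFF not supported", path),
         call. = FALSE)
  }
  if ((g(first, "SamplesPerPixel", 1L)) != 1L) {
    stop(sprintf("format error in %s: only single-sample TIFF supported", path),
         call. = FALSE)
  }
  kind <- if (fmt == 3L && bits == 32L) "float"
  else if (fmt %in% c(1L, 4L) && bits == 8L) "uint8"
  else if (fmt %in% c(1L, 4L) && bits == 16L) "uint16"
  else stop(sprintf("format error in %s: unsupported sample format (%d-bit, fmt %d)",
                    path, bits, fmt), call. = FALSE)
  what <- if (kind == "float") "double" else "integer"
  size <- as.integer(bits / 8L)
  arr <- array(0, c(width, height, length(pages)))
  for (k in seq_along(pages)) {
    tags <- pages[[k]]
    offs <- g(tags, "StripOffsets")
    counts <- g(tags, "StripByteCounts", width * height * size)
    vec <- unlist(lapply(seq_along(offs), function(s) {
      if (what == "double") {
        readBin(bytes[(offs[s] + 1):(offs[s] + counts[s])], "double",
                n = counts[s] / size, size = size, endian = endian)
      } else {
        readBin(bytes[(offs[s] + 1):(offs[s] + counts[s])], "integer",
                n = counts[s] / size, size = size, endian = endian,
                signed = FALSE)
      }
    }), use.names = FALSE)
    if (length(vec) != width * height) {
      stop(sprintf("format error in %s: truncated page %d", path, k), call. = FALSE)
    }
    arr[, , k] <- vec
  }
  list(values = arr, kind = kind, spacing_um = NULL)
}

write_tiff <- function(data, dtype, path) {
  d <- dim(data)
  if (length(d) != 3L) stop("non-3D data: TIFF writer requires a 3D array", call. = FALSE)
  width <- d[1]; height <- d[2]; npages <- d[3]
  size <- switch(dtype, uint8 = 1L, uint16 = 2L, float = 4L)
  bits <- size * 8L
  fmt <- if (dtype == "float") 3L else 1L
  page_bytes <- width * height * size
  ifd_bytes <- 2L + 10L * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + npages * page_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_start), con, size = 4L, endian = "little")
  for (k in seq_len(npages)) {
    vec <- as.vector(data[, , k])
    if (dtype == "float") {
      writeBin(as.numeric(vec), con, size = 4L, endian = "little")
    } else {
      writeBin(as.integer(round(vec)), con, size = size, endian = "little")
    }
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (k in seq_len(npages)) {
    entry_count <- 10L
    writeBin(entry_count, con, size = 2L, endian = "little")
    entry(256L, 4L, 1L, width)
    entry(257L, 4L, 1L, height)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)          # no compression
    entry(262L, 3L, 1L, 1L)          # BlackIsZero
    entry(273L, 4L, 1L, data_start + (k - 1L) * page_bytes)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, height)      # one strip per page
    entry(279L, 4L, 1L, page_bytes)
    entry(339L, 3L, 1L, fmt)
    next_ifd <- if (k < npages) ifd_start + k * ifd_bytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
  }
  invisible(path)
}
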