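#' Volume file IO: raw + sidecar header, and NRRD
#'
#' `write_volume()` / `read_volume()` round-trip a [scalar_field] through two
#' on-disk dialects common for gridded volume data:
#' \describe{
#'   \item{raw}{a flat binary payload (`.raw`) plus a plain-text sidecar
#'     header (`.hdr`) of `key: value` lines (`dims`, `dtype`, `spacing`,
#'     `byteorder`). Voxels are stored x-fastest, 0-based.}
#'   \item{nrrd}{a minimal NRRD0004 file (detached headers not supported)
#'     with `raw` or `ascii` encoding.}
#' }
#' Supported dtypes: `uint8`, `uint16`, `float32`. Float payloads are written
#' as-is; integer dtypes require values within the dtype's range.
#'
#' @param field a [scalar_field].
#' @param path output path; format inferred from the extension (`.nrrd` vs
#'   anything else = raw) unless `format` is given.
#' @param format `"raw"` or `"nrrd"`.
#' @param dtype payload element type.
#' @param encoding NRRD payload encoding, `"raw"` or `"ascii"`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a [scalar_field].
#' @name volume_io
NULL

.dtype_info <- function(dtype) {
  switch(dtype,
    uint8   = list(size = 1L, what = "integer", signed = FALSE),
    uint16  = list(size = 2L, what = "integer", signed = FALSE),
    float32 = list(size = 4L, what = "numeric", signed = TRUE),
    stop(sprintf("unknown dtype '%s' (supported: uint8, uint16, float32)", dtype)))
}

.check_int_range <- function(values, dtype) {
  lim <- switch(dtype, uint8 = 255, uint16 = 65535)
  if (any(values < 0 | values > lim) || any(values != round(values))) {
    stop(sprintf("values must be integers in [0, %d] for dtype %s", lim, dtype))
  }
}

#' @rdname volume_io
#' @export
write_volume <- function(field, path, format = NULL,
                         dtype = "float32", encoding = "raw") {
  stopifnot_field(field)
  if (is.null(format)) {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "raw"
  }
  info <- .dtype_info(dtype)
  vals <- as.vector(field$values)
  if (dtype != "float32") .check_int_range(vals, dtype)

  if (format == "raw") {
    hdr_path <- sub("\\.raw$", "", path)
    hdr_path <- paste0(hdr_path, ".hdr")
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    if (info$what == "integer") {
      writeBin(as.integer(vals), con, size = info$size, endian = "little")
    } else {
      writeBin(as.numeric(vals), con, size = 4L, endian = "little")
    }
    writeLines(c(
      sprintf("dims: %d %d %d", field$dims[1], field$dims[2], field$dims[3]),
      sprintf("dtype: %s", dtype),
      sprintf("spacing: %.10g %.10g %.10g",
              field$spacing[1], field$spacing[2], field$spacing[3]),
      "byteorder: little",
      "order: x-fastest"), hdr_path)
  } else if (format == "nrrd") {
    type <- switch(dtype, uint8 = "uint8", uint16 = "uint16", float32 = "float")
    header <- c(
      "NRRD0004",
      "# minimal NRRD written by topolight",
      sprintf("type: %s", type),
      "dimension: 3",
      sprintf("sizes: %d %d %d", field$dims[1], field$dims[2], field$dims[3]),
      sprintf("spacings: %.10g %.10g %.10g",
              field$spacing[1], field$spacing[2], field$spacing[3]),
      "endian: little",
      sprintf("encoding: %s", encoding),
      "")
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    if (encoding == "ascii") {
      writeBin(charToRaw(paste(format(vals, digits = 17, trim = TRUE,
                                      scientific = FALSE),
                               collapse = "\n")), con)
    } else if (encoding == "raw") {
      if (info$what == "integer") {
        writeBin(as.integer(vals), con, size = info$size, endian = "little")
      } else {
        writeBin(as.numeric(vals), con, size = 4L, endian = "little")
      }
    } else stop("encoding must be 'raw' or 'ascii'")
  } else stop("format must be 'raw' or 'nrrd'")
  invisible(path)
}

.read_header_kv <- function(lines) {
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[tolower(trimws(m[2]))]] <- trimws(m[3])
  out
}

#' @rdname volume_io
#' @param header for raw volumes, path to the sidecar header; defaults to
#'   `path` with its extension replaced by `.hdr`.
#' @export
read_volume <- function(path, header = NULL, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "raw"
  }
  if (format == "raw") {
    if (is.null(header)) header <- paste0(sub("\\.raw$", "", path), ".hdr")
    if (!file.exists(header)) stop(sprintf("header not found: %s", header))
    h <- .read_header_kv(readLines(header))
    dims <- as.integer(strsplit(h$dims, "\\s+")[[1]])
    dtype <- h$dtype
    spacing <- if (!is.null(h$spacing)) as.numeric(strsplit(h$spacing, "\\s+")[[1]]) else c(1, 1, 1)
    info <- .dtype_info(dtype)
    n <- prod(dims)
    expected <- n * info$size
    actual <- file.size(path)
    if (actual != expected) {
      stop(sprintf("payload size mismatch: expected %d bytes (%d voxels x %d), found %d",
                   expected, n, info$size, actual))
    }
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    vals <- if (info$what == "integer") {
      readBin(con, "integer", n = n, size = info$size, signed = info$signed,
              endian = "little")
    } else {
      readBin(con, "numeric", n = n, size = 4L, endian = "little")
    }
    return(scalar_field(vals, dims, spacing))
  }

  # NRRD: header is text lines up to the first blank line, then the payload
  raw_bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw_bytes == as.raw(10L))
  sep <- nl[c(diff(nl) == 1L, FALSE)][1]  # first "\n\n"
  if (is.na(sep)) stop("malformed NRRD: no blank line terminating the header")
  h_lines <- strsplit(rawToChar(raw_bytes[seq_len(sep - 1L)]), "\n")[[1]]
  if (!grepl("^NRRD", h_lines[1])) stop("not an NRRD file")
  h <- .read_header_kv(h_lines[-1])
  dims <- as.integer(strsplit(h$sizes, "\\s+")[[1]])
  if (length(dims) == 2L) dims <- c(dims, 1L)
  spacing <- if (!is.null(h$spacings)) {
    sp <- as.numeric(strsplit(h$spacings, "\\s+")[[1]])
    if (length(sp) == 2L) c(sp, 1) else sp
  } else c(1, 1, 1)
  dtype <- switch(h$type,
                  uint8 = "uint8", "unsigned char" = "uint8",
                  uint16 = "uint16", "unsigned short" = "uint16",
                  float = "float32", float32 = "float32",
                  stop(sprintf("unsupported NRRD type '%s'", h$type)))
  info <- .dtype_info(dtype)
  n <- prod(dims)
  payload_start <- sep + 2L  # byte offset of payload (1-based)
  if (identical(h$encoding, "ascii") || identical(h$encoding, "text")) {
    txt <- rawToChar(raw_bytes[payload_start:length(raw_bytes)])
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
    if (length(vals) != n) {
      stop(sprintf("payload size mismatch: expected %d ascii values, found %d",
                   n, length(vals)))
    }
  } else if (identical(h$encoding, "raw")) {
    payload <- raw_bytes[payload_start:length(raw_bytes)]
    if (length(payload) != n * info$size) {
      stop(sprintf("payload size mismatch: expected %d bytes, found %d",
                   n * info$size, length(payload)))
    }
    vals <- if (info$what == "integer") {
      readBin(payload, "integer", n = n, size = info$size,
              signed = info$signed, endian = "little")
    } else {
      readBin(payload, "numeric", n = n, size = 4L, endian = "little")
    }
  } else stop(sprintf("unsupported NRRD encoding '%s'", h$encoding))
  scalar_field(vals, dims, spacing)
}

#' Write a segmentation map as a label volume
#'
#' Labels are written as `uint16` raw + header (or NRRD), with branch ids as
#' stored in the map.
#' @param seg a `segmentation_map` (see [segment_field()]).
#' @param path output path (`.nrrd` for NRRD, else raw + `.hdr` sidecar).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  if (!inherits(seg, "segmentation_map")) stop("expected a `segmentation_map`")
  f <- scalar_field(as.vector(seg$labels), seg$dims, seg$spacing)
  write_volume(f, path, dtype = "uint16")
}
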