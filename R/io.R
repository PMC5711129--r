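# NRRD and MetaImage (.mha/.mhd) I/O for scalar volumes, masks and vector
# fields. Only axis-aligned grids are supported: spacing and origin are
# carried in the header ("space directions" diagonal + "space origin" for
# NRRD, ElementSpacing + Offset for MetaImage). Data are little-endian,
# x fastest. Vector fields are NRRD only, stored as a 4D payload with the
# 3-vector axis first.

nrrd_type_info <- function(type) {
  switch(type,
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" =
      list(what = "integer", size = 1L, signed = FALSE),
    "short" = , "int16" = , "int16_t" = , "signed short" =
      list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "uint16" = , "uint16_t" =
      list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "int32" = , "int32_t" =
      list(what = "integer", size = 4L, signed = TRUE),
    "float" = list(what = "double", size = 4L, signed = TRUE),
    "double" = list(what = "double", size = 8L, signed = TRUE),
    abort(sprintf("unsupported NRRD type '%s'", type)))
}

parse_nrrd_vector <- function(txt) {
  txt <- gsub("[()]", "", trimws(txt))
  as.numeric(strsplit(txt, ",")[[1]])
}

read_nrrd_raw <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing file: '%s'", path))
  bytes <- readBin(path, what = "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L || (p == prev + 2L && bytes[p - 1L] == as.raw(13L))) {
      hdr_end <- p
      break
    }
    prev <- p
  }
  if (is.na(hdr_end)) abort("malformed NRRD: no blank line after header")
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) abort("not an NRRD file (bad magic)")
  fields <- list()
  for (line in hdr[-1]) {
    if (line == "" || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  required <- c("type", "dimension", "sizes", "encoding")
  for (f in required)
    if (is.null(fields[[f]])) abort(sprintf("NRRD header missing field '%s'", f))
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  dimension <- as.integer(fields$dimension)
  if (length(sizes) != dimension) abort("NRRD 'sizes' does not match 'dimension'")
  payload <- bytes[(hdr_end + 1L):length(bytes)]
  info <- nrrd_type_info(fields$type)
  n <- prod(sizes)
  encoding <- tolower(fields$encoding)
  endian <- if (!is.null(fields$endian) && tolower(fields$endian) == "big")
    "big" else "little"
  values <- switch(encoding,
    "raw" = readBin(payload, what = info$what, n = n, size = info$size,
                    signed = info$signed, endian = endian),
    "gzip" = , "gz" = readBin(memDecompress(payload, type = "gzip"),
                              what = info$what, n = n, size = info$size,
                              signed = info$signed, endian = endian),
    "ascii" = , "txt" = , "text" =
      as.numeric(scan(text = rawToChar(payload), quiet = TRUE)),
    abort(sprintf("unsupported NRRD encoding '%s'", encoding)))
  if (length(values) < n) abort("NRRD payload shorter than 'sizes' imply")
  values <- as.numeric(values[seq_len(n)])

  # spacing/origin: prefer 'space directions' (diagonal), else 'spacings'
  domain_axes <- seq_len(dimension)
  spacing <- NULL
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("none|\\([^)]*\\)", fields[["space directions"]]))[[1]]
    domain_axes <- which(toks != "none")
    dirs <- lapply(toks[domain_axes], parse_nrrd_vector)
    spacing <- vapply(seq_along(dirs), function(i) {
      v <- dirs[[i]]
      if (any(abs(v[-i]) > 0))
        abort("oblique grids are not supported (non-diagonal space directions)")
      v[i]
    }, numeric(1))
  } else if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
    domain_axes <- which(!is.na(sp))
    spacing <- sp[domain_axes]
  } else {
    spacing <- rep(1, dimension)
  }
  origin <- if (!is.null(fields[["space origin"]]))
    parse_nrrd_vector(fields[["space origin"]]) else rep(0, length(domain_axes))
  list(values = values, sizes = sizes, domain_axes = domain_axes,
       spacing = spacing, origin = origin, fields = fields)
}

check_spacing_positive <- function(spacing) {
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort(sprintf("non-positive spacing: header spacing is (%s)",
                  paste(signif(spacing, 6), collapse = ", ")))
}

#' Read a 3D scalar volume from NRRD or MetaImage
#'
#' @param path File path ending in `.nrrd`, `.mha` or `.mhd`.
#' @param kind Unit tag to attach: `"dimensionless"`, `"HU"` or `"Gy"`.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, kind = c("dimensionless", "HU", "Gy")) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    "nrrd" = read_nrrd_raw(path),
    "mha" = , "mhd" = read_meta_raw(path),
    abort(sprintf("unsupported volume format '.%s'", ext)))
  if (length(parsed$sizes) != 3L || length(parsed$domain_axes) != 3L)
    abort(sprintf("non-3D payload: file has %d axes", length(parsed$sizes)))
  check_spacing_positive(parsed$spacing)
  grid <- grid3d(parsed$sizes, parsed$spacing, parsed$origin)
  scalar_volume(array(parsed$values, dim = parsed$sizes), grid, unit = kind)
}

#' Write a 3D scalar volume to NRRD or MetaImage
#'
#' Values are stored as little-endian doubles (raw encoding), so volumes
#' round-trip bit-exactly through [read_volume()].
#'
#' @param vol A [scalar_volume()].
#' @param path Output path ending in `.nrrd` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "nrrd" = write_nrrd(as.numeric(vol$values), vol$grid$shape, vol$grid,
                        "double", path),
    "mha" = write_meta(as.numeric(vol$values), vol$grid$shape, vol$grid,
                       "MET_DOUBLE", path),
    abort(sprintf("unsupported output format '.%s'", ext)))
  invisible(path)
}

write_nrrd <- function(values, sizes, grid, type, path, vector_axis = FALSE) {
  dirs <- sprintf("(%g,0,0) (0,%g,0) (0,0,%g)",
                  grid$spacing[1], grid$spacing[2], grid$spacing[3])
  if (vector_axis) dirs <- paste("none", dirs)
  kinds <- if (vector_axis) "vector domain domain domain"
           else "domain domain domain"
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           sprintf("dimension: %d", length(sizes)),
           sprintf("sizes: %s", paste(sizes, collapse = " ")),
           sprintf("kinds: %s", kinds),
           "encoding: raw",
           "endian: little",
           "space dimension: 3",
           sprintf("space directions: %s", dirs),
           sprintf("space origin: (%g,%g,%g)",
                   grid$origin[1], grid$origin[2], grid$origin[3]),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (type == "double")
    writeBin(as.numeric(values), con, size = 8L, endian = "little")
  else if (type == "uchar")
    writeBin(as.integer(values), con, size = 1L, endian = "little")
  else abort(sprintf("unsupported write type '%s'", type))
  invisible(path)
}

read_meta_raw <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing file: '%s'", path))
  bytes <- readBin(path, what = "raw", n = file.size(path))
  # header is line-oriented "Key = Value"; data start after ElementDataFile
  nl <- c(0L, which(bytes == as.raw(10L)))
  fields <- list()
  data_start <- NA_integer_
  for (i in seq_len(length(nl) - 1L)) {
    line_raw <- bytes[(nl[i] + 1L):(nl[i + 1L] - 1L)]
    line <- trimws(rawToChar(line_raw[line_raw != as.raw(13L)]))
    m <- regmatches(line, regexec("^([^=]+)=(.*)$", line))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2])
      fields[[key]] <- trimws(m[3])
      if (key == "ElementDataFile") {
        data_start <- nl[i + 1L] + 1L
        break
      }
    }
  }
  if (is.na(data_start)) abort("malformed MetaImage: no ElementDataFile line")
  if (!is.null(fields$CompressedData) &&
      tolower(fields$CompressedData) == "true")
    abort("compressed MetaImage is not supported; write uncompressed data")
  sizes <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields$ElementSpacing %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(fields$Offset %||%
                                  fields$Position %||% "0 0 0", "\\s+")[[1]])
  info <- switch(fields$ElementType,
    "MET_UCHAR" = list(what = "integer", size = 1L, signed = FALSE),
    "MET_SHORT" = list(what = "integer", size = 2L, signed = TRUE),
    "MET_USHORT" = list(what = "integer", size = 2L, signed = FALSE),
    "MET_INT" = list(what = "integer", size = 4L, signed = TRUE),
    "MET_FLOAT" = list(what = "double", size = 4L, signed = TRUE),
    "MET_DOUBLE" = list(what = "double", size = 8L, signed = TRUE),
    abort(sprintf("unsupported ElementType '%s'", fields$ElementType)))
  endian <- if (!is.null(fields$BinaryDataByteOrderMSB) &&
                tolower(fields$BinaryDataByteOrderMSB) == "true")
    "big" else "little"
  datafile <- fields$ElementDataFile
  payload <- if (identical(toupper(datafile), "LOCAL")) {
    bytes[data_start:length(bytes)]
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path))
      abort(sprintf("missing file: '%s' (ElementDataFile)", raw_path))
    readBin(raw_path, what = "raw", n = file.size(raw_path))
  }
  n <- prod(sizes)
  values <- readBin(payload, what = info$what, n = n, size = info$size,
                    signed = info$signed, endian = endian)
  if (length(values) < n) abort("MetaImage payload shorter than DimSize implies")
  list(values = as.numeric(values[seq_len(n)]), sizes = sizes,
       domain_axes = seq_along(sizes), spacing = spacing, origin = origin,
       fields = fields)
}

write_meta <- function(values, sizes, grid, type, path) {
  hdr <- c("ObjectType = Image",
           sprintf("NDims = %d", length(sizes)),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %g %g %g",
                   grid$origin[1], grid$origin[2], grid$origin[3]),
           sprintf("ElementSpacing = %g %g %g",
                   grid$spacing[1], grid$spacing[2], grid$spacing[3]),
           sprintf("DimSize = %s", paste(sizes, collapse = " ")),
           sprintf("ElementType = %s", type),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (type == "MET_DOUBLE")
    writeBin(as.numeric(values), con, size = 8L, endian = "little")
  else if (type == "MET_UCHAR")
    writeBin(as.integer(values), con, size = 1L, endian = "little")
  else abort(sprintf("unsupported write type '%s'", type))
  invisible(path)
}

#' Read / write a structure mask (uint8 0/1 volume)
#'
#' @param path File path (`.nrrd` or `.mha`).
#' @param name Structure label to attach on read.
#' @return `read_mask()` returns a [structure_mask()]; `write_mask()`
#'   returns `path` invisibly.
#' @export
read_mask <- function(path, name = "structure") {
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    "nrrd" = read_nrrd_raw(path),
    "mha" = , "mhd" = read_meta_raw(path),
    abort(sprintf("unsupported volume format '.%s'", ext)))
  if (length(parsed$sizes) != 3L)
    abort(sprintf("non-3D payload: file has %d axes", length(parsed$sizes)))
  check_spacing_positive(parsed$spacing)
  grid <- grid3d(parsed$sizes, parsed$spacing, parsed$origin)
  structure_mask(array(parsed$values != 0, dim = parsed$sizes), grid, name)
}

#' @rdname read_mask
#' @param mask A [structure_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  ext <- tolower(tools::file_ext(path))
  vals <- as.integer(mask$member)
  switch(ext,
    "nrrd" = write_nrrd(vals, mask$grid$shape, mask$grid, "uchar", path),
    "mha" = write_meta(vals, mask$grid$shape, mask$grid, "MET_UCHAR", path),
    abort(sprintf("unsupported output format '.%s'", ext)))
  invisible(path)
}

#' Read / write a displacement vector field (3-component NRRD)
#'
#' Fields are stored as a 4D NRRD with the 3-vector axis first
#' (`sizes: 3 nx ny nz`, `kinds: vector domain domain domain`), components
#' in mm in the fixed (LR, AP, SI) axis order.
#'
#' @param path File path (`.nrrd`).
#' @return `read_vector_field()` returns a [vector_field()];
#'   `write_vector_field()` returns `path` invisibly.
#' @export
read_vector_field <- function(path) {
  parsed <- read_nrrd_raw(path)
  if (length(parsed$sizes) != 4L || parsed$sizes[1] != 3L)
    abort("vector field files must have sizes 3 x nx x ny x nz")
  if (length(parsed$domain_axes) != 3L)
    abort("vector field files must have exactly 3 domain axes")
  check_spacing_positive(parsed$spacing)
  shape <- parsed$sizes[-1]
  grid <- grid3d(shape, parsed$spacing, parsed$origin)
  arr <- array(parsed$values, dim = parsed$sizes)
  vector_field(array(arr[1, , , ], dim = shape),
               array(arr[2, , , ], dim = shape),
               array(arr[3, , , ], dim = shape), grid)
}

#' @rdname read_vector_field
#' @param field A [vector_field()].
#' @export
write_vector_field <- function(field, path) {
  stopifnot(inherits(field, "vector_field"))
  if (tolower(tools::file_ext(path)) != "nrrd")
    abort("vector fields are written as NRRD only")
  shape <- field$grid$shape
  arr <- array(0, dim = c(3L, shape))
  arr[1, , , ] <- field$ux
  arr[2, , , ] <- field$uy
  arr[3, , , ] <- field$uz
  write_nrrd(as.numeric(arr), c(3L, shape), field$grid, "double", path,
             vector_axis = TRUE)
  invisible(path)
}
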