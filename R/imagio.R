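#' Read an image stack
#'
#' Supports multi-page TIFF stacks (with a JSON sidecar carrying the voxel
#' size), NRRD (raw encoding) and MetaImage (`.mha`, or `.mhd` with a detached
#' raw file). NRRD and MetaImage are self-describing; for TIFF the voxel size
#' comes from the `<path>.json` sidecar or, failing that, the `voxel_size`
#' argument (a warning is emitted and the override required).
#'
#' @param path File path.
#' @param format One of `"tiff"`, `"nrrd"`, `"mha"`; inferred from the
#'   extension when `NULL`.
#' @param voxel_size Voxel size override in micrometres (TIFF without sidecar).
#' @param as_labels Return a [label_volume()] instead of a
#'   [grayscale_volume()].
#' @return A volume object.
#' @export
read_stack <- function(path, format = NULL, voxel_size = NULL, as_labels = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- format %||% infer_format(path)
  out <- switch(format,
    tiff = read_tiff_stack(path, voxel_size),
    nrrd = read_nrrd(path),
    mha = read_metaimage(path),
    stopf("unsupported format '%s'", format))
  if (as_labels) label_volume(out$data, out$voxel_size, out$origin) else out
}

#' Write an image stack
#'
#' Lossless round-trip: NRRD and MetaImage store raw doubles (or 32-bit
#' integers for label volumes); TIFF stacks are 16-bit and therefore require
#' integer intensities in `[0, 65535]` (use NRRD for floating-point data). A
#' JSON sidecar `<path>.json` with voxel size (um), origin (mm) and axis
#' order accompanies TIFF output.
#'
#' @param volume A [grayscale_volume()] or [label_volume()].
#' @param path Output path.
#' @param format As in [read_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, format = NULL) {
  stopifnot(inherits(volume, "volume"))
  format <- format %||% infer_format(path)
  switch(format,
    tiff = write_tiff_stack(volume, path),
    nrrd = write_nrrd(volume, path),
    mha = write_metaimage(volume, path),
    stopf("unsupported format '%s'", format))
  invisible(path)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = "tiff",
    nrrd = "nrrd",
    mha = , mhd = "mha",
    stopf("cannot infer image format from extension '.%s'", ext))
}

# --- TIFF ------------------------------------------------------------------

write_tiff_stack <- function(volume, path) {
  a <- volume$data
  if (any(a != round(a)) || min(a) < 0 || max(a) > 65535)
    stopf("TIFF stacks are 16-bit: intensities must be integers in [0, 65535]; use NRRD for float data")
  slices <- lapply(seq_len(dim(a)[3]), function(k) t(a[, , k]) / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  sidecar <- list(voxel_size_um = volume$voxel_size, origin_mm = volume$origin,
                  axis_order = "zyx")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_tiff_stack <- function(path, voxel_size = NULL) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  dims2 <- vapply(slices, dim, integer(2))
  if (any(dims2[1, ] != dims2[1, 1]) || any(dims2[2, ] != dims2[2, 1]))
    stopf("inconsistent slice dimensions in TIFF stack (%s)",
          paste(unique(apply(dims2, 2, paste, collapse = "x")), collapse = ", "))
  a <- array(0, dim = c(dims2[2, 1], dims2[1, 1], length(slices)))
  for (k in seq_along(slices)) a[, , k] <- t(slices[[k]])
  side <- paste0(path, ".json")
  origin <- c(0, 0, 0)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    vs <- meta$voxel_size_um
    origin <- as.numeric(meta$origin_mm %||% origin)
  } else {
    warning("no JSON sidecar with voxel-size metadata next to ", path,
            "; supply voxel_size explicitly", call. = FALSE)
    vs <- NULL
  }
  vs <- voxel_size %||% vs
  if (is.null(vs)) stopf("voxel size unknown: missing sidecar and no override given")
  grayscale_volume(a, vs, origin)
}

# --- NRRD (raw encoding subset) --------------------------------------------

nrrd_type <- function(volume) if (inherits(volume, "label_volume")) "int" else "double"

write_nrrd <- function(volume, path) {
  a <- volume$data
  type <- nrrd_type(volume)
  d <- dim(a)
  sp <- vox_mm(volume$voxel_size)
  hdr <- c("NRRD0004",
           "# written by trabevalid",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.9g %.9g %.9g", sp, sp, sp),
           sprintf("space origin: (%.9g,%.9g,%.9g)",
                   volume$origin[1], volume$origin[2], volume$origin[3]),
           "encoding: raw",
           "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (type == "int") writeBin(as.integer(a), con, size = 4L, endian = "little")
  else writeBin(as.numeric(a), con, size = 8L, endian = "little")
  invisible(path)
}

# Read a whole file and split it at the end of its text header.
split_header <- function(path, terminator) {
  bytes <- readBin(path, "raw", file.size(path))
  term <- charToRaw(terminator)
  nt <- length(term)
  limit <- min(length(bytes), 65536L)
  pos <- NA_integer_
  for (i in seq_len(limit - nt + 1L)) {
    if (bytes[i] == term[1] && identical(bytes[i:(i + nt - 1L)], term)) {
      pos <- i + nt - 1L
      break
    }
  }
  if (is.na(pos)) stopf("could not locate end of header in %s", path)
  list(header = strsplit(rawToChar(bytes[seq_len(pos)]), "\n")[[1]],
       data = bytes[-seq_len(pos)])
}

read_nrrd <- function(path) {
  parts <- split_header(path, "\n\n")
  hdr <- parts$header
  hdr <- hdr[hdr != ""]
  if (!grepl("^NRRD", hdr[1])) stopf("%s is not an NRRD file", path)
  fields <- hdr[grepl(":", hdr) & !grepl("^#", hdr)]
  keys <- tolower(trimws(sub(":.*$", "", fields)))
  vals <- trimws(sub("^[^:]*:=?", "", fields))
  getf <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  if (!identical(getf("encoding"), "raw"))
    stopf("only raw-encoded NRRD is supported")
  sizes <- as.integer(strsplit(getf("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L) stopf("only 3D NRRD volumes are supported")
  type <- getf("type")
  spac <- getf("spacings")
  vs <- if (!is.null(spac)) as.numeric(strsplit(spac, "\\s+")[[1]])[1] * 1000 else NULL
  if (is.null(vs)) stopf("NRRD header lacks spacings")
  so <- getf("space origin")
  origin <- if (!is.null(so))
    as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]]) else c(0, 0, 0)
  n <- prod(sizes)
  a <- decode_raw(parts$data, type_map_nrrd(type), n, path)
  grayscale_volume(array(as.numeric(a), dim = sizes), vs, origin)
}

type_map_nrrd <- function(type) {
  switch(type,
    "double" = "double", "float" = "float",
    "int" = , "int32" = , "signed int" = "int32",
    "short" = , "int16" = "int16",
    "uchar" = , "uint8" = "uint8",
    stopf("unsupported NRRD type '%s'", type))
}

decode_raw <- function(bytes, type, n, path) {
  a <- switch(type,
    double = readBin(bytes, "numeric", n, size = 8L, endian = "little"),
    float = readBin(bytes, "numeric", n, size = 4L, endian = "little"),
    int32 = readBin(bytes, "integer", n, size = 4L, endian = "little"),
    int16 = readBin(bytes, "integer", n, size = 2L, endian = "little"),
    uint8 = as.integer(bytes[seq_len(min(n, length(bytes)))]))
  if (length(a) < n) stopf("truncated image data in %s", path)
  a
}

# --- MetaImage (MHD/MHA) ---------------------------------------------------

write_metaimage <- function(volume, path) {
  a <- volume$data
  d <- dim(a)
  sp <- vox_mm(volume$voxel_size)
  int_type <- inherits(volume, "label_volume")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementType = %s", if (int_type) "MET_INT" else "MET_DOUBLE"),
           sprintf("ElementSpacing = %.9g %.9g %.9g", sp, sp, sp),
           sprintf("Offset = %.9g %.9g %.9g",
                   volume$origin[1], volume$origin[2], volume$origin[3]),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (int_type) writeBin(as.integer(a), con, size = 4L, endian = "little")
  else writeBin(as.numeric(a), con, size = 8L, endian = "little")
  invisible(path)
}

read_metaimage <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  # header ends at the newline that closes the ElementDataFile line
  marker <- charToRaw("ElementDataFile")
  limit <- min(length(bytes), 65536L)
  hits <- which(bytes[seq_len(limit)] == marker[1])
  pos <- NA_integer_
  for (i in hits) {
    if (i + length(marker) - 1L <= limit &&
        identical(bytes[i:(i + length(marker) - 1L)], marker)) { pos <- i; break }
  }
  if (is.na(pos)) stopf("MetaImage header in %s lacks ElementDataFile", path)
  nl <- pos + which(bytes[pos:limit] == charToRaw("\n"))[1] - 1L
  if (is.na(nl)) nl <- limit
  head_lines <- strsplit(rawToChar(bytes[seq_len(nl)]), "\n")[[1]]
  hdr <- list()
  for (line in head_lines) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    hdr[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  sizes <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])[1]
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  n <- prod(sizes)
  type <- switch(hdr[["ElementType"]],
    MET_DOUBLE = "double", MET_FLOAT = "float", MET_INT = "int32",
    MET_SHORT = "int16", MET_UCHAR = "uint8",
    stopf("unsupported MetaImage element type '%s'", hdr[["ElementType"]]))
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    bytes <- bytes[-seq_len(nl)]
  } else {
    raw_path <- file.path(dirname(path), datafile)
    bytes <- readBin(raw_path, "raw", file.size(raw_path))
  }
  a <- decode_raw(bytes, type, n, path)
  grayscale_volume(array(as.numeric(a), dim = sizes), sp * 1000, origin)
}

# --- Preprocessing ---------------------------------------------------------

#' Block-mean downsampling
#'
#' Each output voxel is the arithmetic mean of its `factor^3` input block
#' (anti-aliased, preserving the partial-volume behaviour that thresholding
#' acts on). The voxel size is multiplied by `factor`, the origin preserved.
#' Dimensions not divisible by `factor` are padded with the volume's minimum
#' intensity (logged via a message).
#'
#' @param volume A [grayscale_volume()].
#' @param factor Positive integer downsampling factor.
#' @return A [grayscale_volume()] at the coarser resolution.
#' @export
downsample_mean <- function(volume, factor) {
  stopifnot(inherits(volume, "grayscale_volume"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 || factor != round(factor))
    stopf("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(volume)
  a <- volume$data
  d <- dim(a)
  pad <- (factor - d %% factor) %% factor
  if (any(pad > 0L)) {
    message(sprintf("downsample_mean: padding volume by (%d, %d, %d) voxels with background",
                    pad[1], pad[2], pad[3]))
    bg <- min(a)
    b <- array(bg, dim = d + pad)
    b[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    a <- b
    d <- dim(a)
  }
  # reduce one axis at a time: reshape so the block dimension leads, then mean
  reduce_axis <- function(a) {
    d <- dim(a)
    m <- matrix(a, nrow = factor)
    out <- array(colMeans(m), dim = c(d[1] %/% factor, d[2], d[3]))
    aperm(out, c(2, 3, 1))
  }
  # after three cyclic reductions the axis order is restored
  a <- reduce_axis(reduce_axis(reduce_axis(a)))
  out <- grayscale_volume(a, volume$voxel_size * factor, volume$origin)
  attributes(out)["specimen"] <- attributes(volume)["specimen"]
  out
}
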