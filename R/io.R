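#' Read a volumetric image (NIfTI or MetaImage)
#'
#' Reads `.nii`/`.nii.gz` through RNifti and `.mha`/`.mhd` MetaImage files
#' through a built-in reader. The unit is attached from the caller (image
#' files do not carry one); a sidecar JSON written by [write_image()] is
#' consulted only for consistency checking, never silently overriding
#' `expected_unit`.
#'
#' @param path file path.
#' @param expected_unit unit tag to attach, see [scalar_image()].
#' @return A [scalar_image()].
#' @export
read_image <- function(path, expected_unit = "dimensionless") {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha|\\.mhd)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    nii <- RNifti::readNifti(path)
    vals <- array(as.numeric(nii), dim = dim(nii))
    spacing <- RNifti::pixdim(nii)[1:3]
    xf <- try(RNifti::xform(nii), silent = TRUE)
    origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  } else if (ext %in% c(".mha", ".mhd")) {
    meta <- read_metaimage(path)
    vals <- meta$values
    spacing <- meta$spacing
    origin <- meta$origin
  } else {
    stop(sprintf("unsupported image format: '%s'", path), call. = FALSE)
  }
  img <- scalar_image(vals, spacing, origin, expected_unit)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$unit) && !identical(meta$unit, expected_unit)) {
      warning(sprintf("sidecar declares unit '%s' but '%s' was requested",
                      meta$unit, expected_unit), call. = FALSE)
    }
  }
  img
}

#' Write a volumetric image (NIfTI or MetaImage)
#'
#' Voxel data are stored as 32-bit float for MetaImage and 64-bit float for
#' NIfTI. A sidecar JSON (`<path>.json`) records the unit and an optional
#' energy-window tag.
#'
#' @param img a [scalar_image()].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @param window optional window tag recorded in the sidecar (e.g.
#'   `"peak171"`, `"scatter209"`, `"peak245"`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, window = NULL) {
  stopifnot(inherits(img, "scalar_image"))
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha|\\.mhd)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    nii <- RNifti::asNifti(img$values)
    RNifti::pixdim(nii) <- img$spacing
    m <- diag(c(img$spacing, 1))
    m[1:3, 4] <- img$origin
    RNifti::qform(nii) <- structure(m, code = 2L)
    RNifti::writeNifti(nii, path)
  } else if (ext %in% c(".mha", ".mhd")) {
    write_metaimage(img, path)
  } else {
    stop(sprintf("unsupported image format: '%s'", path), call. = FALSE)
  }
  jsonlite::write_json(
    list(path = basename(path), unit = img$unit, window = window),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Write a VOI mask as an 8-bit volume with a provenance record
#'
#' The mask is stored as a uint8 NIfTI (0/1) and a sidecar
#' `<path>.provenance.json` logging how it was derived, its voxel count
#' and volume.
#'
#' @param mask a [voi_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param parameters optional list of the selection parameters used,
#'   stored verbatim in the provenance record.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, parameters = NULL) {
  stopifnot(inherits(mask, "voi_mask"))
  nii <- RNifti::asNifti(array(as.numeric(mask$values),
                               dim = dim(mask$values)))
  RNifti::pixdim(nii) <- mask$spacing
  m <- diag(c(mask$spacing, 1))
  m[1:3, 4] <- mask$origin
  RNifti::qform(nii) <- structure(m, code = 2L)
  RNifti::writeNifti(nii, path, datatype = "uint8")
  jsonlite::write_json(
    list(path = basename(path), provenance = mask$provenance,
         n_voxels = sum(mask$values), volume_mL = mask_volume_mL(mask),
         parameters = parameters),
    paste0(path, ".provenance.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(path)
}

#' Read back a VOI mask written by `write_mask`
#'
#' @param path mask image path; the provenance sidecar is consulted when
#'   present.
#' @return A [voi_mask()].
#' @export
read_mask <- function(path) {
  img <- read_image(path, expected_unit = "dimensionless")
  prov <- "manual"
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    prov <- jsonlite::read_json(sidecar)$provenance %||% "manual"
  }
  voi_mask(img$values != 0, img$spacing, img$origin, prov)
}

## --- MetaImage dialect -------------------------------------------------
## Minimal ITK MetaImage support: uncompressed, axis-aligned, 3-D,
## MET_FLOAT/MET_DOUBLE/MET_UCHAR/MET_SHORT element types, data LOCAL
## (.mha) or in a companion raw file (.mhd).

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header", call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line,
                               call. = FALSE)
    hdr[[kv[2L]]] <- trimws(kv[3L])
    if (kv[2L] == "ElementDataFile") break
  }
  if (identical(hdr$CompressedData, "True")) {
    stop("compressed MetaImage data not supported", call. = FALSE)
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1L]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1L]])
  type <- hdr$ElementType %||% "MET_FLOAT"
  rd <- switch(type,
    MET_FLOAT  = list(what = "numeric", size = 4L),
    MET_DOUBLE = list(what = "numeric", size = 8L),
    MET_UCHAR  = list(what = "integer", size = 1L),
    MET_SHORT  = list(what = "integer", size = 2L),
    stop("unsupported MetaImage element type: ", type, call. = FALSE))
  n <- prod(dims)
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True") ||
    identical(hdr$ElementByteOrderMSB, "True")
  endian <- if (msb) "big" else "little"
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, rd$what, n = n, size = rd$size, endian = endian,
                   signed = rd$size > 1L)
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) {
      stop(sprintf("MetaImage data file '%s' not found", rawpath),
           call. = FALSE)
    }
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, rd$what, n = n, size = rd$size, endian = endian,
                   signed = rd$size > 1L)
  }
  if (length(raw) != n) stop("truncated MetaImage voxel data", call. = FALSE)
  list(values = array(as.numeric(raw), dim = dims),
       spacing = spacing, origin = origin)
}

write_metaimage <- function(img, path) {
  d <- dim(img$values)
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                 ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.9g %.9g %.9g", img$origin[1L], img$origin[2L],
            img$origin[3L]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", img$spacing[1L],
            img$spacing[2L], img$spacing[3L]),
    sprintf("DimSize = %d %d %d", d[1L], d[2L], d[3L]),
    "ElementType = MET_FLOAT",
    paste0("ElementDataFile = ", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local) {
    writeBin(as.numeric(img$values), con, size = 4L, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(img$values), rcon, size = 4L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
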