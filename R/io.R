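#' Read a 3-D volume from NIfTI, NRRD, or a DICOM series directory
#'
#' Geometry (voxel spacing and origin, mm) is taken from the file headers.
#' A DICOM series directory is read slice by slice, sorted by slice position;
#' non-uniform slice spacing is a geometry error.
#'
#' @param path file (`.nii`, `.nii.gz`, `.nrrd`) or DICOM series directory.
#' @param modality `"CT"` or `"DOSE"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "DOSE")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop("format error: '", path, "' does not exist", call. = FALSE)
  if (dir.exists(path)) {
    v <- read_dicom_series(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- read_nifti_raw(path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    v <- read_nrrd_raw(path)
  } else {
    stop("format error: unrecognised extension for '", path, "'", call. = FALSE)
  }
  image_volume(v$voxels, v$spacing, v$origin, modality)
}

#' Load an ROI label volume aligned to a reference volume
#'
#' Any nonzero label is foreground. The label grid must match the reference
#' geometry within 1e-3 mm.
#'
#' @param path label volume file or DICOM directory.
#' @param reference the paired [image_volume()].
#' @param roi_name label attached to the mask.
#' @return An [roi_mask()].
#' @export
load_mask <- function(path, reference, roi_name = "ROI") {
  if (!file.exists(path))
    stop("format error: '", path, "' does not exist", call. = FALSE)
  v <- if (dir.exists(path)) read_dicom_series(path)
       else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) read_nifti_raw(path)
       else read_nrrd_raw(path)
  if (!identical(dim(v$voxels), dim(reference$voxels)))
    stop("geometry error: mask shape (", paste(dim(v$voxels), collapse = "x"),
         ") differs from reference (", paste(dim(reference$voxels), collapse = "x"),
         ")", call. = FALSE)
  if (any(abs(v$spacing - reference$spacing) > 1e-3) ||
      any(abs(v$origin - reference$origin) > 1e-3))
    stop("geometry error: mask spacing/origin differ from reference beyond 1e-3 mm",
         call. = FALSE)
  roi_mask(v$voxels, reference$spacing, reference$origin, roi_name)
}

#' Write a volume or mask to NIfTI, NRRD, or a DICOM series
#'
#' The output format follows the extension (`.nii`, `.nii.gz`, `.nrrd`);
#' a path without extension is written as a DICOM series directory.
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  voxels <- x$voxels
  storage.mode(voxels) <- "double"
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti_raw(voxels, x$spacing, x$origin, path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd_raw(voxels, x$spacing, x$origin, path)
  } else {
    write_dicom_series(voxels, x$spacing, x$origin, path,
                       modality = if (identical(x$modality, "DOSE")) "RTDOSE" else "CT")
  }
  invisible(path)
}

## ---- NIfTI (RNifti) ----

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("format error: expected a 3-D NIfTI volume", call. = FALSE)
  vox <- array(as.double(img)[seq_len(prod(d))], dim = d)
  if (!all(is.finite(vox)))
    stop("volume contains non-finite voxels (NaN/Inf)", call. = FALSE)
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(sp == 0)) sp <- abs(RNifti::pixdim(img)[1:3])
  list(voxels = vox, spacing = sp, origin = as.numeric(xf[1:3, 4]))
}

write_nifti_raw <- function(voxels, spacing, origin, path) {
  img <- RNifti::asNifti(voxels)
  aff <- diag(4)
  aff[1, 1] <- spacing[1]; aff[2, 2] <- spacing[2]; aff[3, 3] <- spacing[3]
  aff[1:3, 4] <- origin
  img <- RNifti::`pixdim<-`(img, spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
}

## ---- NRRD (minimal codec: raw / gzip encodings, 3-D scalar data) ----

read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic))
    stop("format error: not an NRRD file", call. = FALSE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("format error: truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    hdr[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  if (as.integer(hdr$dimension) != 3L)
    stop("format error: only 3-D NRRD supported", call. = FALSE)
  sizes <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  type <- tolower(hdr$type)
  rtype <- switch(type,
    "double" = list(what = "double", size = 8L),
    "float"  = list(what = "double", size = 4L),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2L),
    "int" = , "int32" = , "signed int" = list(what = "integer", size = 4L),
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1L),
    stop("format error: unsupported NRRD type '", type, "'", call. = FALSE))
  n <- prod(sizes)
  enc <- tolower(hdr$encoding %||% "raw")
  if (enc == "raw") {
    vox <- readBin(con, rtype$what, n = n, size = rtype$size, endian = "little",
                   signed = !(type %in% c("uchar", "uint8", "unsigned char")))
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.size(path))
    raw <- memDecompress(comp, type = "gzip")
    vox <- readBin(raw, rtype$what, n = n, size = rtype$size, endian = "little",
                   signed = !(type %in% c("uchar", "uint8", "unsigned char")))
  } else {
    stop("format error: unsupported NRRD encoding '", enc, "'", call. = FALSE)
  }
  if (length(vox) != n)
    stop("format error: NRRD data shorter than header promises", call. = FALSE)
  if (!all(is.finite(vox)))
    stop("volume contains non-finite voxels (NaN/Inf)", call. = FALSE)
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  if (!is.null(hdr[["space directions"]])) {
    dirs <- parse_nrrd_vectors(hdr[["space directions"]])
    spacing <- vapply(seq_len(3), function(i) sqrt(sum(dirs[[i]]^2)), 0)
  } else if (!is.null(hdr[["spacings"]])) {
    spacing <- as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(hdr[["space origin"]]))
    origin <- parse_nrrd_vectors(hdr[["space origin"]])[[1]]
  list(voxels = array(as.double(vox), dim = sizes), spacing = spacing, origin = origin)
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

write_nrrd_raw <- function(voxels, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(voxels)
  hdr <- c(
    "NRRD0004",
    "# written by perturbrad",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(d, collapse = " ")),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            spacing[1], spacing[2], spacing[3]),
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)", origin[1], origin[2], origin[3]),
    "")
  writLines <- paste0(paste(hdr, collapse = "\n"), "\n")
  writeBin(charToRaw(writLines), con)
  writeBin(as.double(voxels), con, size = 8L, endian = "little")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- DICOM series (minimal codec: explicit VR little endian, uncompressed
##      monochrome 16-bit slices, no sequences) ----

dcm_element <- function(group, element, vr, value_raw) {
  len <- length(value_raw)
  head <- writeBin(c(as.integer(group), as.integer(element)), raw(),
                   size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(len), raw(), size = 4L, endian = "little"), value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(as.integer(len), raw(), size = 2L, endian = "little"), value_raw)
  }
}

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, charToRaw(" "))
  r
}

write_dicom_series <- function(voxels, spacing, origin, dir, modality = "CT") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(voxels)
  # 16-bit signed storage with per-series rescale covering the dynamic range
  lo <- min(voxels); hi <- max(voxels)
  slope <- if (hi > lo) (hi - lo) / 60000 else 1
  intercept <- lo
  for (z in seq_len(d[3])) {
    slice <- voxels[, , z]
    stored <- as.integer(round((slice - intercept) / slope)) - 30000L
    pix <- writeBin(stored, raw(), size = 2L, endian = "little")
    ds <- c(
      dcm_element(0x0008, 0x0060, "CS", dcm_str(modality)),
      dcm_element(0x0020, 0x0013, "IS", dcm_str(as.character(z))),
      dcm_element(0x0020, 0x0032, "DS", dcm_str(sprintf("%.10g\\%.10g\\%.10g",
        origin[1], origin[2], origin[3] + (z - 1) * spacing[3]))),
      dcm_element(0x0020, 0x0037, "DS", dcm_str("1\\0\\0\\0\\1\\0")),
      dcm_element(0x0028, 0x0002, "US", writeBin(1L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0010, "US", writeBin(as.integer(d[2]), raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0011, "US", writeBin(as.integer(d[1]), raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0030, "DS", dcm_str(sprintf("%.10g\\%.10g", spacing[2], spacing[1]))),
      dcm_element(0x0028, 0x0100, "US", writeBin(16L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0101, "US", writeBin(16L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0102, "US", writeBin(15L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0103, "US", writeBin(1L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x1052, "DS", dcm_str(sprintf("%.10g", intercept + 30000 * slope))),
      dcm_element(0x0028, 0x1053, "DS", dcm_str(sprintf("%.10g", slope))),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    meta_body <- c(
      dcm_element(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1")))
    meta <- c(
      dcm_element(0x0002, 0x0000, "UL",
                  writeBin(length(meta_body), raw(), size = 4L, endian = "little")),
      meta_body)
    con <- file(file.path(dir, sprintf("slice%04d.dcm", z)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(dir)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("format error: '", path, "' is not a DICOM file", call. = FALSE)
  pos <- 133L
  u16 <- function(p) readBin(raw[p:(p + 1)], "integer", size = 2L,
                             endian = "little", signed = FALSE)
  u32 <- function(p) readBin(raw[p:(p + 3)], "integer", size = 4L, endian = "little")
  tags <- list()
  n <- length(raw)
  while (pos + 7 <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_at <- pos + 8L
    }
    if (len < 0 || data_at + len - 1 > n)
      stop("format error: corrupt DICOM element in '", path, "'", call. = FALSE)
    key <- sprintf("%04X,%04X", group, element)
    tags[[key]] <- list(vr = vr, data = raw[data_at:(data_at + len - 1L)])
    pos <- data_at + len
  }
  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$data))
  }
  get_us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    readBin(t$data, "integer", size = 2L, endian = "little", signed = FALSE)
  }
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  ps <- as.numeric(strsplit(get_str("0028,0030"), "\\\\")[[1]])
  ipp <- as.numeric(strsplit(get_str("0020,0032"), "\\\\")[[1]])
  slope <- as.numeric(get_str("0028,1053") %||% "1")
  intercept <- as.numeric(get_str("0028,1052") %||% "0")
  signed <- identical(get_us("0028,0103"), 1L)
  pix <- tags[["7FE0,0010"]]
  if (is.null(pix)) stop("format error: no pixel data in '", path, "'", call. = FALSE)
  stored <- readBin(pix$data, "integer", n = rows * cols, size = 2L,
                    endian = "little", signed = signed)
  slice <- matrix(stored * slope + intercept, nrow = cols, ncol = rows)
  list(slice = slice, position = ipp, spacing_xy = c(ps[2], ps[1]))
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("format error: no DICOM files in '", dir, "'", call. = FALSE)
  slices <- lapply(files, read_dicom_file)
  zs <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  if (length(slices) > 1L) {
    dz <- diff(zs)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3)
      stop("geometry error: inconsistent slice spacing in DICOM series", call. = FALSE)
    sz <- mean(dz)
  } else sz <- 1
  d1 <- slices[[1]]
  vox <- array(0, dim = c(dim(d1$slice), length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]$slice
  if (!all(is.finite(vox)))
    stop("volume contains non-finite voxels (NaN/Inf)", call. = FALSE)
  list(voxels = vox,
       spacing = c(d1$spacing_xy, sz),
       origin = d1$position)
}
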