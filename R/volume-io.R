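#' Read a 3-D medical volume
#'
#' Dispatches on the path: a directory is read as a DICOM series, files by
#' extension as MetaImage (`.mha`, `.mhd`) or NIfTI-1 (`.nii`, `.nii.gz`).
#' All readers map into the package's fixed coordinate convention (LPS
#' world frame, millimetres, 0-based voxel-center indices); NIfTI's RAS
#' frame is flipped accordingly. World geometry is taken from the file and
#' never silently defaulted: a missing spacing is an error.
#'
#' For DICOM series the slice spacing is measured from the inter-slice
#' positions; a disagreeing SpacingBetweenSlices tag (0018,0088), or a
#' SliceThickness (0018,0050) different from the measured spacing, raises a
#' warning with the measured spacing authoritative. Non-uniform slice
#' positions (e.g. a missing slice) and inconsistent slice orientations are
#' errors.
#'
#' @param path file or DICOM directory path.
#' @param modality override the modality hint (`"CT"`, `"MRI"`); by default
#'   taken from the DICOM Modality tag where available, else `"unknown"`.
#' @return A [med_volume()].
#' @export
read_volume <- function(path, modality = NULL) {
  if (dir.exists(path)) return(read_dicom_series(path, modality = modality))
  if (!file.exists(path)) stop("volume file not found: ", path)
  lp <- tolower(path)
  if (grepl("\\.(mha|mhd)$", lp)) return(read_metaimage(path, modality = modality))
  if (grepl("\\.(nii|nii\\.gz)$", lp)) return(read_nifti_volume(path, modality = modality))
  stop("unsupported volume format: ", basename(path),
       " (supported: .mha/.mhd, .nii/.nii.gz, DICOM series directory)")
}

#' Write a volume as MetaImage
#'
#' Writes `.mha` (header and raw data in one file) or `.mhd` plus a sibling
#' `.raw`. Geometry round-trips exactly at the default `MET_DOUBLE` element
#' type.
#'
#' @param volume a [med_volume()].
#' @param path output path ending in `.mha` or `.mhd`.
#' @param element_type on-disk scalar type: `"MET_DOUBLE"`, `"MET_FLOAT"` or
#'   `"MET_SHORT"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, element_type = "MET_DOUBLE") {
  stopifnot(inherits(volume, "med_volume"))
  lp <- tolower(path)
  if (!grepl("\\.(mha|mhd)$", lp))
    stop("write_volume() writes MetaImage only (.mha or .mhd)")
  element_type <- match.arg(element_type, c("MET_DOUBLE", "MET_FLOAT", "MET_SHORT"))
  local <- grepl("\\.mha$", lp)
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  d <- dim(volume$voxels)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(format(as.vector(volume$direction), digits = 17), collapse = " ")),
    paste("Offset =", paste(format(volume$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(volume$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", datafile))
  vals <- as.double(volume$voxels)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  write_raw_values <- function(con2) {
    switch(element_type,
      MET_DOUBLE = writeBin(vals, con2, size = 8, endian = "little"),
      MET_FLOAT = writeBin(vals, con2, size = 4, endian = "little"),
      MET_SHORT = writeBin(as.integer(round(pmax(pmin(vals, 32767), -32768))),
                           con2, size = 2, endian = "little"))
  }
  if (local) {
    write_raw_values(con)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    con2 <- file(rawpath, "wb")
    on.exit(close(con2), add = TRUE)
    write_raw_values(con2)
  }
  invisible(path)
}

read_metaimage <- function(path, modality = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  # header is plain text up to the ElementDataFile line; binary data may
  # follow, so lines are decoded individually from the raw bytes
  head_n <- min(length(raw), 8192L)
  nl <- which(raw[seq_len(head_n)] == as.raw(10L))
  kv <- list(); data_offset <- NA_integer_; datafile <- NULL
  start <- 1L
  for (end in nl) {
    ln <- if (end > start) rawToChar(raw[start:(end - 1L)]) else ""
    start <- end + 1L
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) < 3) next
    kv[[m[2]]] <- m[3]
    if (m[2] == "ElementDataFile") {
      datafile <- m[3]
      data_offset <- end  # bytes up to and incl. this line's newline
      break
    }
  }
  if (is.null(datafile)) stop("not a MetaImage header (no ElementDataFile key): ", path)
  if (!is.null(kv$NDims) && as.integer(kv$NDims) != 3L)
    stop("only 3-D MetaImage volumes are supported")
  if (identical(kv$CompressedData, "True"))
    stop("compressed MetaImage data is not supported")
  if (is.null(kv$DimSize)) stop("MetaImage header is missing DimSize")
  if (is.null(kv$ElementSpacing) && is.null(kv$ElementSize))
    stop("MetaImage header is missing ElementSpacing; refusing to default the voxel size")
  d <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(kv$ElementSpacing %||% kv$ElementSize, "\\s+")[[1]])
  origin <- if (!is.null(kv$Offset)) as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  direction <- if (!is.null(kv$TransformMatrix))
    matrix(as.numeric(strsplit(kv$TransformMatrix, "\\s+")[[1]]), 3L, 3L) else diag(3)
  msb <- identical(kv$BinaryDataByteOrderMSB, "True") || identical(kv$ElementByteOrderMSB, "True")
  endian <- if (msb) "big" else "little"
  type <- kv$ElementType %||% "MET_DOUBLE"
  n <- prod(d)
  read_vals <- function(src, offset) {
    sz <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
                 MET_USHORT = 2L, MET_UCHAR = 1L, MET_CHAR = 1L, MET_INT = 4L,
                 MET_UINT = 4L,
                 stop("unsupported MetaImage ElementType: ", type))
    what <- if (type %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
    signed <- !(type %in% c("MET_USHORT", "MET_UCHAR", "MET_UINT"))
    bytes <- src[offset + seq_len(n * sz)]
    if (length(bytes) < n * sz) stop("MetaImage data truncated: ", path)
    readBin(bytes, what, n = n, size = sz, signed = signed, endian = endian)
  }
  vals <- if (identical(datafile, "LOCAL")) {
    read_vals(raw, data_offset)
  } else {
    rp <- file.path(dirname(path), datafile)
    if (!file.exists(rp)) stop("MetaImage data file not found: ", rp)
    read_vals(readBin(rp, "raw", n = file.size(rp)), 0L)
  }
  med_volume(array(vals, dim = d), spacing = spacing, origin = origin,
             direction = direction, modality = modality %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_nifti_volume <- function(path, modality = NULL) {
  img <- RNifti::readNifti(path)
  a <- structure(RNifti::xform(img), code = NULL)  # voxel (0-based) -> RAS world
  a <- unclass(a)[1:4, 1:4]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop nifti bookkeeping attributes
  dm <- dim(arr)
  if (length(dm) == 4L && dm[4] == 1L) { dim(arr) <- dm[1:3]; dm <- dm[1:3] }
  if (length(dm) != 3L) stop("only 3-D NIfTI volumes are supported (got ",
                             length(dm), " dimensions)")
  a_lps <- diag(c(-1, -1, 1, 1)) %*% a  # RAS -> LPS
  lin <- a_lps[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  if (any(spacing <= 0)) stop("NIfTI volume has a zero voxel dimension")
  direction <- sweep(lin, 2L, spacing, "/")
  med_volume(arr, spacing = spacing, origin = a_lps[1:3, 4],
             direction = direction, modality = modality %||% "unknown")
}

# ---- minimal DICOM series support ------------------------------------------
# Uncompressed single-frame CT/MR series, explicit or implicit VR little
# endian, no sequences. Only the geometry and pixel tags needed to build a
# med_volume are interpreted; everything else is skipped by length.

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos + 1L]) + 256L * as.integer(raw[pos + 2L])
}
dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos + 1L]) + 256 * as.numeric(raw[pos + 2L]) +
    65536 * as.numeric(raw[pos + 3L]) + 16777216 * as.numeric(raw[pos + 4L])
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 132L  # 0-based offset past preamble + magic
  n <- length(raw)
  tags <- new.env(parent = emptyenv())
  transfer <- "1.2.840.10008.1.2.1"
  explicit_vrs_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  in_meta <- TRUE; explicit <- TRUE
  while (pos + 8 <= n) {
    group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
    if (in_meta && group != 2L) {
      in_meta <- FALSE
      explicit <- !identical(transfer, "1.2.840.10008.1.2")
      if (!(transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")))
        stop("unsupported DICOM transfer syntax ", transfer, " in ", path)
    }
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(raw[pos + 5:6])
      if (vr %in% explicit_vrs_long) {
        len <- dcm_u32(raw, pos + 8L); voff <- pos + 12L
      } else {
        len <- dcm_u16(raw, pos + 6L); voff <- pos + 8L
      }
    } else {
      len <- dcm_u32(raw, pos + 4L); voff <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements (sequences) are not supported: ", path)
    key <- sprintf("%04x%04x", group, elem)
    if (key %in% c("00020010", "00080060", "00180050", "00180088", "00200032",
                   "00200037", "00280010", "00280011", "00280030", "00280100",
                   "00280103", "00281052", "00281053", "7fe00010"))
      assign(key, raw[voff + seq_len(len)], envir = tags)
    pos <- voff + len
  }
  str_tag <- function(key) {
    if (!exists(key, envir = tags)) return(NULL)
    r <- get(key, envir = tags)
    trimws(rawToChar(r[r != as.raw(0)]))
  }
  num_tag <- function(key) {
    s <- str_tag(key)
    if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
  }
  u16_tag <- function(key) {
    if (!exists(key, envir = tags)) return(NULL)
    dcm_u16(get(key, envir = tags), 0L)
  }
  if (exists("00020010", envir = tags)) transfer <- str_tag("00020010")
  rows <- u16_tag("00280010"); cols <- u16_tag("00280011")
  bits <- u16_tag("00280100") %||% 16L
  pixrep <- u16_tag("00280103") %||% 1L
  if (is.null(rows) || is.null(cols)) stop("DICOM file has no Rows/Columns: ", path)
  ipp <- num_tag("00200032"); iop <- num_tag("00200037")
  ps <- num_tag("00280030")
  if (is.null(ipp) || is.null(iop)) stop("DICOM file lacks position/orientation tags: ", path)
  if (is.null(ps)) stop("DICOM file lacks PixelSpacing (0028,0030); refusing to default: ", path)
  if (!exists("7fe00010", envir = tags)) stop("DICOM file has no pixel data: ", path)
  pd <- get("7fe00010", envir = tags)
  vals <- if (bits == 16L) {
    readBin(pd, "integer", n = rows * cols, size = 2L, signed = (pixrep == 1L),
            endian = "little")
  } else if (bits == 8L) {
    readBin(pd, "integer", n = rows * cols, size = 1L, signed = FALSE)
  } else stop("unsupported DICOM bit depth: ", bits)
  slope <- (num_tag("00281053") %||% 1)[1]
  intercept <- (num_tag("00281052") %||% 0)[1]
  list(modality = str_tag("00080060"),
       thickness = (num_tag("00180050") %||% NA_real_)[1],
       spacing_tag = (num_tag("00180088") %||% NA_real_)[1],
       ipp = ipp, iop = iop, pixel_spacing = ps,
       rows = rows, cols = cols,
       pixels = matrix(vals * slope + intercept, nrow = cols, ncol = rows))
}

#' @rdname read_volume
#' @export
read_dicom_series <- function(path, modality = NULL) {
  files <- list.files(path, full.names = TRUE)
  files <- files[file.exists(files) & !dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", path)
  slices <- lapply(sort(files), read_dicom_file)
  iop0 <- slices[[1]]$iop
  for (s in slices)
    if (max(abs(s$iop - iop0)) > 1e-4 ||
        s$rows != slices[[1]]$rows || s$cols != slices[[1]]$cols)
      stop("DICOM series has inconsistent orientation or matrix size")
  xdir <- iop0[1:3]; ydir <- iop0[4:6]
  normal <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
              xdir[3] * ydir[1] - xdir[1] * ydir[3],
              xdir[1] * ydir[2] - xdir[2] * ydir[1])
  z <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  nz <- length(slices)
  if (nz >= 2L) {
    dz <- diff(z)
    if (any(dz < 1e-6)) stop("DICOM series contains duplicate slice positions")
    if (nz >= 3L && (max(dz) - min(dz)) > 0.02 * stats::median(dz))
      stop(sprintf("non-uniform slice spacing in DICOM series (gaps %.3f-%.3f mm); a slice may be missing",
                   min(dz), max(dz)))
    zsp <- mean(dz)
  } else {
    zsp <- slices[[1]]$thickness
    if (is.na(zsp)) stop("single-slice DICOM series without SliceThickness; cannot infer spacing")
  }
  tag_sp <- slices[[1]]$spacing_tag
  if (!is.na(tag_sp) && nz >= 2L && abs(tag_sp - zsp) > 1e-3)
    warning(sprintf("SpacingBetweenSlices tag (%.3f mm) disagrees with measured inter-slice spacing (%.3f mm); using the measured value", tag_sp, zsp))
  th <- slices[[1]]$thickness
  if (!is.na(th) && abs(th - zsp) > 1e-3)
    warning(sprintf("SliceThickness (%.3f mm) differs from slice spacing (%.3f mm); features spanning slice gaps may be under-sampled", th, zsp))
  ps <- slices[[1]]$pixel_spacing  # (row spacing, column spacing)
  arr <- array(0, dim = c(slices[[1]]$cols, slices[[1]]$rows, nz))
  for (k in seq_len(nz)) arr[, , k] <- slices[[k]]$pixels
  mod <- modality %||% switch(slices[[1]]$modality %||% "", CT = "CT", MR = "MRI", "unknown")
  med_volume(arr, spacing = c(ps[2], ps[1], zsp), origin = slices[[1]]$ipp,
             direction = cbind(xdir, ydir, normal), modality = mod)
}

# internal fixture writer: minimal explicit-VR little-endian CT-style series
write_dicom_series <- function(volume, dir, spacing_tag = NULL, thickness = NULL,
                               skip_slices = integer(0)) {
  stopifnot(inherits(volume, "med_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  enc_str <- function(group, elem, vr, s, nul_pad = FALSE) {
    v <- charToRaw(s)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(if (nul_pad) 0L else 32L))
    c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
      charToRaw(vr), writeBin(length(v), raw(), size = 2, endian = "little")[1:2], v)
  }
  enc_u16 <- function(group, elem, vr, val) {
    c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
      charToRaw(vr), as.raw(c(2, 0)),
      writeBin(as.integer(val), raw(), size = 2, endian = "little"))
  }
  ds <- function(x) paste(format(x, digits = 12, trim = TRUE, scientific = FALSE), collapse = "\\")
  for (k in seq_len(d[3])) {
    if (k %in% skip_slices) next
    ipp <- voxel_to_world(volume, c(0, 0, k - 1))
    pix <- as.integer(round(volume$voxels[, , k]))  # column index fastest = DICOM row-major
    pd_len <- length(pix) * 2L
    body <- c(
      enc_str(0x0008L, 0x0060L, "CS", if (volume$modality == "MRI") "MR" else "CT"),
      enc_str(0x0018L, 0x0050L, "DS", ds(thickness %||% volume$spacing[3])),
      enc_str(0x0018L, 0x0088L, "DS", ds(spacing_tag %||% volume$spacing[3])),
      enc_str(0x0020L, 0x0032L, "DS", ds(ipp)),
      enc_str(0x0020L, 0x0037L, "DS", ds(c(volume$direction[, 1], volume$direction[, 2]))),
      enc_u16(0x0028L, 0x0010L, "US", d[2]),  # Rows
      enc_u16(0x0028L, 0x0011L, "US", d[1]),  # Columns
      enc_str(0x0028L, 0x0030L, "DS", ds(c(volume$spacing[2], volume$spacing[1]))),
      enc_u16(0x0028L, 0x0100L, "US", 16L),
      enc_u16(0x0028L, 0x0103L, "US", 1L),
      c(writeBin(c(0x7fe0L, 0x0010L), raw(), size = 2, endian = "little"),
        charToRaw("OW"), as.raw(c(0, 0)),
        writeBin(pd_len, raw(), size = 4, endian = "little"),
        writeBin(pix, raw(), size = 2, endian = "little"))
    )
    meta <- enc_str(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1", nul_pad = TRUE)
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}
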